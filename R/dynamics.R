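# Continuous importance dynamics along thermal time: LOWESS smoothing of
# per-sample mid-canopy shares, group-bootstrap confidence bands, and the
# LFT2-LFT3 crossover with a bootstrap confidence interval.
#
# The LOWESS dialect is pinned for reproducibility: degree-1 local
# regression, tricube distance weights over the ceil(fraction * n) nearest
# rows (ties broken by row order after a stable sort), evaluated on a fixed
# grid, no robustness iterations.

#' Configuration for the importance-dynamics stage
#'
#' @param lowess_fraction Neighbourhood span as a fraction of the rows
#'   (default 0.25).
#' @param robustifying_iterations Robustness iterations; this dialect fixes
#'   them at 0 (transitions would otherwise be over-smoothed), and any other
#'   value is rejected.
#' @param grid_points Number of equally spaced evaluation points spanning
#'   the observed GDD range (default 220).
#' @param bootstrap_replicates Group-bootstrap replicates (default 800).
#' @param ci_percentiles Lower/upper percentiles of the pointwise bands and
#'   the crossover interval (default 2.5 and 97.5).
#' @param seed Integer seed for the bootstrap resampling.
#' @return A `dynamics_config` list.
#' @export
dynamics_config <- function(lowess_fraction = 0.25, robustifying_iterations = 0L,
                            grid_points = 220L, bootstrap_replicates = 800L,
                            ci_percentiles = c(2.5, 97.5), seed = 1L) {
  if (!is_number(lowess_fraction) || lowess_fraction <= 0 || lowess_fraction > 1) {
    stop_spadgdd("`lowess_fraction` must lie in (0, 1].", "config")
  }
  if (robustifying_iterations != 0L) {
    stop_spadgdd("this LOWESS dialect supports robustifying_iterations = 0 only.", "config")
  }
  if (grid_points < 2L) stop_spadgdd("`grid_points` must be >= 2.", "config")
  if (bootstrap_replicates < 1L) stop_spadgdd("`bootstrap_replicates` must be >= 1.", "config")
  if (length(ci_percentiles) != 2L || ci_percentiles[1] >= ci_percentiles[2] ||
    any(ci_percentiles < 0 | ci_percentiles > 100)) {
    stop_spadgdd("`ci_percentiles` must be an increasing pair within [0, 100].", "config")
  }
  structure(
    list(
      lowess_fraction = lowess_fraction,
      robustifying_iterations = as.integer(robustifying_iterations),
      grid_points = as.integer(grid_points),
      bootstrap_replicates = as.integer(bootstrap_replicates),
      ci_percentiles = ci_percentiles, seed = as.integer(seed)
    ),
    class = "dynamics_config"
  )
}

#' LOWESS smoothing on a fixed grid
#'
#' At each grid point, a degree-1 weighted least-squares line is fitted over
#' the `ceil(fraction * n)` nearest rows with tricube distance weights and
#' evaluated at the grid point. Exactly reproduces a straight line when the
#' data are collinear.
#'
#' @param x Predictor values (here, GDD per row).
#' @param y Response values (here, importance share per row).
#' @param grid Evaluation points.
#' @param config A [dynamics_config()] (only the span is used here).
#' @return Tibble with columns `gdd` (the grid) and `value`.
#' @export
lowess_smooth <- function(x, y, grid, config = dynamics_config()) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  k <- ceiling(config$lowess_fraction * n)
  if (n < max(3L, k)) {
    stop_spadgdd(
      sprintf("LOWESS needs at least %d rows for span %.2f; got %d.", max(3L, k), config$lowess_fraction, n),
      "sample_size"
    )
  }
  ord <- order(x) # stable: ties keep row order
  xs <- x[ord]
  ys <- y[ord]
  fitted <- vapply(grid, function(g) {
    d <- abs(xs - g)
    nb <- order(d)[seq_len(k)] # stable tie-break by (sorted) row order
    dn <- d[nb]
    dmax <- max(dn)
    w <- if (dmax > 0) (1 - (dn / dmax)^3)^3 else rep(1, k)
    xc <- xs[nb] - g # centre at the grid point: fit value is the intercept
    sw <- sum(w)
    swx <- sum(w * xc)
    swy <- sum(w * ys[nb])
    swxx <- sum(w * xc^2)
    swxy <- sum(w * xc * ys[nb])
    denom <- sw * swxx - swx^2
    if (!is.finite(denom) || denom <= .Machine$double.eps * sw * max(swxx, 1)) {
      swy / sw # degenerate neighbourhood: weighted mean
    } else {
      (swxx * swy - swx * swxy) / denom
    }
  }, numeric(1))
  tibble(gdd = as.numeric(grid), value = fitted)
}

#' First crossover of two smoothed curves
#'
#' Scans the shared grid for the first point where `curve_a - curve_b`
#' equals zero or changes sign strictly between adjacent grid points, and
#' returns the linearly interpolated zero. Returns `NA` when the curves
#' never cross.
#'
#' @param curve_a,curve_b Tibbles from [lowess_smooth()] on the same grid.
#' @return Crossover position (degree C days) or `NA_real_`.
#' @export
find_crossover <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$gdd, curve_b$gdd))) {
    stop_spadgdd("curves are not on the same grid.", "alignment")
  }
  g <- curve_a$gdd
  d <- curve_a$value - curve_b$value
  zero <- which(d == 0)
  change <- which(d[-length(d)] * d[-1] < 0)
  first_zero <- if (length(zero) > 0) zero[1] else Inf
  first_change <- if (length(change) > 0) change[1] else Inf
  if (is.infinite(first_zero) && is.infinite(first_change)) {
    return(NA_real_)
  }
  if (first_zero <= first_change) {
    return(g[first_zero])
  }
  i <- first_change
  g[i] + d[i] * (g[i + 1] - g[i]) / (d[i] - d[i + 1])
}

#' Bootstrap percentile interval for the crossover
#'
#' @param crossings Crossover per bootstrap replicate (`NA` where a
#'   replicate's curves never cross; those are excluded and counted).
#' @param point Full-data point estimate (degree C days).
#' @param config A [dynamics_config()] (percentiles).
#' @return A `crossover_estimate` list: `point_estimate`, `ci_low`,
#'   `ci_high`, `replicates_with_crossover`, `replicates_total`.
#' @export
crossover_ci <- function(crossings, point, config = dynamics_config()) {
  defined <- crossings[!is.na(crossings)]
  if (length(defined) == 0L) {
    stop_spadgdd(
      sprintf("no bootstrap replicate produced a crossover (0 of %d).", length(crossings)),
      "no_crossover", replicates_total = length(crossings)
    )
  }
  q <- quantile(defined, probs = config$ci_percentiles / 100, names = FALSE)
  structure(
    list(
      point_estimate = point, ci_low = q[1], ci_high = q[2],
      replicates_with_crossover = length(defined),
      replicates_total = length(crossings)
    ),
    class = "crossover_estimate"
  )
}

#' @export
print.crossover_estimate <- function(x, ...) {
  cat(sprintf(
    "<crossover_estimate> %.1f C d (95%% CI %.1f-%.1f; %d/%d replicates crossed)\n",
    x$point_estimate, x$ci_low, x$ci_high,
    x$replicates_with_crossover, x$replicates_total
  ))
  invisible(x)
}

#' Group-bootstrap smoothing of mid-canopy shares
#'
#' Smooths the LFT2-LFT4 shares along GDD on a common grid spanning the
#' observed range, then resamples experiments (groups) with replacement -
#' the same number of groups as observed, duplicated groups contributing
#' duplicated rows - and re-estimates the curves per replicate. Attribution
#' values are never recomputed per replicate. Pointwise bands are
#' percentiles over replicates; the LFT2-LFT3 crossover is extracted from
#' every replicate for [crossover_ci()].
#'
#' @param shares Output of [midcanopy_shares()] (needs `group`, `gdd` and
#'   the three share columns).
#' @param config A [dynamics_config()].
#' @return An `importance_dynamics` list: `grid`, `curves` (full-data
#'   tibble: gdd, lft2, lft3, lft4), `bands` (tibble: gdd, leaf, lower,
#'   upper), `crossover` (a `crossover_estimate`), `replicate_crossovers`,
#'   and `n_skipped_replicates`.
#' @export
group_bootstrap <- function(shares, config = dynamics_config()) {
  need <- c("group", "gdd", "share_lft2", "share_lft3", "share_lft4")
  missing_cols <- setdiff(need, names(shares))
  if (length(missing_cols) > 0L) {
    stop_spadgdd(
      paste0("shares table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  groups <- unique(shares$group)
  if (length(groups) < 2L) {
    stop_spadgdd("group bootstrap needs at least 2 groups.", "infeasible")
  }
  grid <- seq(min(shares$gdd), max(shares$gdd), length.out = config$grid_points)
  leaves <- c("share_lft2", "share_lft3", "share_lft4")

  smooth_all <- function(tab) {
    vapply(leaves, function(l) {
      lowess_smooth(tab$gdd, tab[[l]], grid, config)$value
    }, numeric(length(grid)))
  }
  full <- smooth_all(shares)
  curves <- tibble(
    gdd = grid, lft2 = full[, 1L], lft3 = full[, 2L], lft4 = full[, 3L]
  )

  rows_of <- split(seq_len(nrow(shares)), shares$group)
  min_rows <- 3L
  reps <- config$bootstrap_replicates
  rep_curves <- array(NA_real_, dim = c(reps, length(grid), 3L))
  crossings <- rep(NA_real_, reps)
  skipped <- logical(reps)
  with_local_seed(config$seed, {
    for (r in seq_len(reps)) {
      draw <- sample(groups, length(groups), replace = TRUE)
      idx <- unlist(rows_of[draw], use.names = FALSE)
      if (length(idx) < min_rows || length(unique(shares$gdd[idx])) < 2L) {
        skipped[r] <- TRUE
        next
      }
      sm <- smooth_all(shares[idx, , drop = FALSE])
      rep_curves[r, , ] <- sm
      crossings[r] <- find_crossover(
        tibble(gdd = grid, value = sm[, 1L]),
        tibble(gdd = grid, value = sm[, 2L])
      )
    }
  })
  ok <- !skipped
  probs <- config$ci_percentiles / 100
  bands <- dplyr::bind_rows(lapply(seq_along(leaves), function(j) {
    lo <- apply(rep_curves[ok, , j, drop = FALSE], 2L, quantile, probs = probs[1])
    hi <- apply(rep_curves[ok, , j, drop = FALSE], 2L, quantile, probs = probs[2])
    tibble(gdd = grid, leaf = sub("share_", "", leaves[j]), lower = lo, upper = hi)
  }))
  point <- find_crossover(
    tibble(gdd = grid, value = curves$lft2),
    tibble(gdd = grid, value = curves$lft3)
  )
  crossover <- crossover_ci(crossings[ok], point, config)
  structure(
    list(
      grid = grid, curves = curves, bands = bands, crossover = crossover,
      replicate_crossovers = crossings[ok],
      n_skipped_replicates = sum(skipped), config = config
    ),
    class = "importance_dynamics"
  )
}

#' @export
print.importance_dynamics <- function(x, ...) {
  cat(sprintf(
    "<importance_dynamics> %d-point grid over %.0f-%.0f C d, %d bootstrap replicates (%d skipped)\n",
    length(x$grid), min(x$grid), max(x$grid),
    x$config$bootstrap_replicates, x$n_skipped_replicates
  ))
  print(x$crossover)
  invisible(x)
}
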