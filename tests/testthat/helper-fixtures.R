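# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, enumeration, closed forms) and never call the code paths they check.

# simple contiguous weather table
make_weather <- function(tmax, tmin, start = as.Date("2020-05-01")) {
  tibble::tibble(date = start + seq_along(tmax) - 1L, tmax_c = tmax, tmin_c = tmin)
}

# brute-force day-by-day GDD summation (spreadsheet style)
oracle_gdd_sum <- function(tmax, tmin, t_base = 10) {
  total <- 0
  for (i in seq_along(tmax)) {
    inc <- (tmax[i] + tmin[i]) / 2 - t_base
    if (inc < 0) inc <- 0
    total <- total + inc
  }
  total
}

# small multi-experiment observation table with a known functional target;
# deterministic given the seed
make_small_obs <- function(n_groups = 6, per_group = 30, seed = 101,
                           noise_sd = 0) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    n <- n_groups * per_group
    gdd <- runif(n, 650, 1950)
    lnc <- runif(n, 2, 4.5)
    spad <- sapply(1:5, function(l) 40 + 2 * (lnc - 3) + rnorm(n, 0, noise_sd))
    pnc <- lnc - 1 + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    tibble::tibble(
      observation_id = sprintf("obs%04d", seq_len(n)),
      experiment_id = rep(sprintf("G%02d", seq_len(n_groups)), each = per_group),
      gdd_cd = gdd,
      lft1 = spad[, 1], lft2 = spad[, 2], lft3 = spad[, 3],
      lft4 = spad[, 4], lft5 = spad[, 5],
      dm_t_ha = 1 + 10 * (gdd - 650) / 1300,
      lnc_pct = lnc, pnc_pct = pnc,
      nni = pnc / (3.44 * (1 + 10 * (gdd - 650) / 1300)^-0.44)
    )
  })
}

# naive per-grid-point weighted least squares: the independent LOWESS oracle.
# Same pinned neighbourhood rule, but fitted with stats::lm on raw x.
oracle_lowess <- function(x, y, grid, fraction = 0.25) {
  n <- length(x)
  k <- ceiling(fraction * n)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  sapply(grid, function(g) {
    d <- abs(xs - g)
    nb <- order(d)[seq_len(k)]
    dmax <- max(d[nb])
    w <- if (dmax > 0) (1 - (d[nb] / dmax)^3)^3 else rep(1, k)
    if (sum(w > 0) < 2 || length(unique(xs[nb][w > 0])) < 2) {
      return(sum(w * ys[nb]) / sum(w))
    }
    fit <- stats::lm(yy ~ xx, data = data.frame(xx = xs[nb], yy = ys[nb]), weights = w)
    unname(stats::predict(fit, data.frame(xx = g)))
  })
}

# brute-force path-dependent Shapley for one tree over all feature subsets;
# expectation follows cover weights when a feature is out of the coalition
oracle_tree_shap <- function(fa, root, x, p) {
  expect <- function(node, S) {
    f <- fa$feature[node + 1L]
    if (f < 0) {
      return(fa$value[node + 1L])
    }
    l <- fa$child_left[node + 1L]
    r <- fa$child_right[node + 1L]
    if ((f + 1L) %in% S) {
      if (x[f + 1L] <= fa$split[node + 1L]) expect(l, S) else expect(r, S)
    } else {
      (fa$cover[l + 1L] * expect(l, S) + fa$cover[r + 1L] * expect(r, S)) /
        fa$cover[node + 1L]
    }
  }
  feats <- seq_len(p)
  subsets <- lapply(0:(2^p - 1), function(m) feats[bitwAnd(m, 2^(feats - 1)) > 0])
  phi <- numeric(p)
  for (j in feats) {
    for (S in subsets) {
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w * (expect(root, c(S, j)) - expect(root, S))
    }
  }
  phi
}
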