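# Phenological bias diagnostics: association between pooled out-of-fold
# residuals (observed - predicted) and thermal time.

#' Residual-versus-GDD trend
#'
#' Quantifies phenology-related systematic error as the Pearson correlation
#' and ordinary-least-squares slope of pooled out-of-fold residuals against
#' GDD. Residuals with zero variance (degenerate fixtures) report `r = 0`
#' with `zero_variance = TRUE` rather than failing.
#'
#' @param oof Out-of-fold prediction table from [run_grouped_cv()] (`$oof`),
#'   or any tibble with `gdd`, `observed`, `predicted`.
#' @return A `residual_trend` list: `pearson_r`, `slope` (target units per
#'   degree C day), `intercept`, `n`, `zero_variance`.
#' @export
residual_trend <- function(oof) {
  if (inherits(oof, "spad_cv")) oof <- oof$oof
  need <- c("gdd", "observed", "predicted")
  missing_cols <- setdiff(need, names(oof))
  if (length(missing_cols) > 0L) {
    stop_spadgdd(
      paste0("out-of-fold table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  ok <- is.finite(oof$gdd) & is.finite(oof$observed) & is.finite(oof$predicted)
  gdd <- oof$gdd[ok]
  res <- oof$observed[ok] - oof$predicted[ok]
  n <- length(res)
  if (n < 3L) stop_spadgdd("residual trend needs at least 3 finite rows.", "invalid_input")
  if (var(gdd) == 0) {
    stop_spadgdd("GDD has zero variance; the residual regressor is degenerate.", "degenerate_regressor")
  }
  zero_variance <- var(res) == 0
  fit <- stats::lm.fit(cbind(1, gdd), res)
  structure(
    list(
      pearson_r = if (zero_variance) 0 else cor(res, gdd),
      slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      n = n, zero_variance = zero_variance,
      ids = if ("observation_id" %in% names(oof)) sort(oof$observation_id[ok]) else NULL
    ),
    class = "residual_trend"
  )
}

#' @export
print.residual_trend <- function(x, ...) {
  cat(sprintf(
    "<residual_trend> r = %.3f, slope = %.2e per C d (n = %d)%s\n",
    x$pearson_r, x$slope, x$n,
    if (x$zero_variance) " [zero-variance residuals]" else ""
  ))
  invisible(x)
}

#' Compare residual trends between two formulations
#'
#' Reports how much of the residual-GDD association a GDD-augmented
#' formulation removes relative to a base formulation fitted on the same
#' observations: the ratio of absolute correlations and of absolute slopes
#' (augmented / base), alongside both trends.
#'
#' @param trend_base,trend_aug `residual_trend` objects computed on
#'   identical observation sets (checked when ids are available).
#' @return List with `r_ratio`, `slope_ratio`, `base`, `augmented`.
#' @export
compare_trends <- function(trend_base, trend_aug) {
  stopifnot(inherits(trend_base, "residual_trend"), inherits(trend_aug, "residual_trend"))
  if (!is.null(trend_base$ids) && !is.null(trend_aug$ids) &&
    !identical(trend_base$ids, trend_aug$ids)) {
    stop_spadgdd("trends were computed on different observation sets.", "alignment")
  }
  if (trend_base$n != trend_aug$n) {
    stop_spadgdd("trends were computed on different observation sets.", "alignment")
  }
  list(
    r_ratio = abs(trend_aug$pearson_r) / abs(trend_base$pearson_r),
    slope_ratio = abs(trend_aug$slope) / abs(trend_base$slope),
    base = trend_base, augmented = trend_aug
  )
}
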