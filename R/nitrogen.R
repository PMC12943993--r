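#' Critical nitrogen dilution curve
#'
#' Critical plant nitrogen concentration as a negative power law of
#' aboveground dry matter, `Nc = a * DM^-b`. The default coefficients
#' (`a = 3.44`, `b = 0.44`) are the published rice critical nitrogen
#' dilution curve used throughout this package. The bare power law is
#' applied for all `dm > 0`; no plateau is imposed at low dry matter
#' (some CNDC frameworks clamp the curve below 1 t/ha — this one does not).
#'
#' @param dm Aboveground dry matter (t/ha), `> 0`. Vectorised.
#' @param a Leading coefficient (% N at DM = 1 t/ha), `> 0`.
#' @param b Magnitude of the negative power exponent, `> 0` (a value of 0 is
#'   accepted and yields a flat curve).
#' @return Critical N concentration (% of dry mass), strictly decreasing in
#'   `dm` when `b > 0`.
#' @examples
#' critical_n(1)   # 3.44
#' critical_n(4)   # about 1.87
#' @export
critical_n <- function(dm, a = 3.44, b = 0.44) {
  if (!is_number(a) || a <= 0) stop_spadgdd("`a` must be a single number > 0.", "invalid_input")
  if (!is_number(b) || b < 0) stop_spadgdd("`b` must be a single number >= 0.", "invalid_input")
  if (!is.numeric(dm)) stop_spadgdd("`dm` must be numeric.", "invalid_input")
  if (any(is.finite(dm) & dm <= 0)) {
    stop_spadgdd(
      sprintf("dry matter must be > 0 (got %g).", dm[which(is.finite(dm) & dm <= 0)[1]]),
      "invalid_input"
    )
  }
  a * dm^(-b)
}

#' Nitrogen nutrition index
#'
#' NNI is the ratio of the measured plant nitrogen concentration to the
#' critical concentration from the dilution curve at the same dry matter:
#' `NNI = PNC / Nc`. Values below 1 indicate nitrogen deficiency, values
#' above 1 surplus, and exactly 1 optimal supply (the classification uses
#' the exact threshold 1).
#'
#' @param pnc Plant nitrogen concentration (% of dry mass), `> 0`. Vectorised.
#' @param dm Aboveground dry matter (t/ha), `> 0`. Vectorised, recycled
#'   against `pnc`.
#' @inheritParams critical_n
#' @return A tibble with columns `nc` (critical concentration, %), `nni`
#'   (dimensionless) and `status` (factor: deficient / optimal / surplus).
#' @examples
#' nni(pnc = 2.0, dm = 1)   # nni = 2/3.44, deficient
#' @export
nni <- function(pnc, dm, a = 3.44, b = 0.44) {
  if (!is.numeric(pnc)) stop_spadgdd("`pnc` must be numeric.", "invalid_input")
  if (any(is.finite(pnc) & pnc <= 0)) {
    stop_spadgdd("plant N concentration must be > 0.", "invalid_input")
  }
  nc <- critical_n(dm, a = a, b = b)
  value <- pnc / nc
  tibble(nc = nc, nni = value, status = nni_status(value))
}

#' Classify nitrogen status from an NNI value
#'
#' @param nni_value Numeric NNI values.
#' @return Factor with levels `deficient` (`< 1`), `optimal` (`= 1`),
#'   `surplus` (`> 1`).
#' @export
nni_status <- function(nni_value) {
  status <- ifelse(nni_value < 1, "deficient", ifelse(nni_value > 1, "surplus", "optimal"))
  factor(status, levels = c("deficient", "optimal", "surplus"))
}
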