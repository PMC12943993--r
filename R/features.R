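# Feature construction: the four SPAD/GDD formulations and the seven
# measurement protocols. Column sets are pinned:
#   formulation A: LFT1..LFT5                 (SPAD only)
#   formulation B: LFT1xGDD..LFT5xGDD         (multiplicative)
#   formulation C: LFT1..LFT5, GDD            (additive)
#   formulation D: B union C (11 columns)     (additive + interactions)
#   protocol full: LFT1..LFT5, GDD; A {LFT2,LFT3,GDD}; B {LFT2,LFT4,GDD};
#   C {LFT3,LFT4,GDD}; D {LFT2,GDD}; E {LFT3,GDD}; F {LFT4,GDD}

LFT_COLS <- c("lft1", "lft2", "lft3", "lft4", "lft5")
LFT_NAMES <- c("LFT1", "LFT2", "LFT3", "LFT4", "LFT5")
TARGET_COLS <- c(LNC = "lnc_pct", PNC = "pnc_pct", NNI = "nni")

#' Feature column names of a formulation
#' @param code One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return Character vector of feature column names.
#' @export
formulation_columns <- function(code) {
  code <- match.arg(toupper(code), c("A", "B", "C", "D"))
  prod_names <- paste0(LFT_NAMES, "xGDD")
  switch(code,
    A = LFT_NAMES,
    B = prod_names,
    C = c(LFT_NAMES, "GDD"),
    D = c(prod_names, LFT_NAMES, "GDD")
  )
}

#' Feature column names of a measurement protocol
#' @param code One of `"full"`, `"A"`..`"F"`.
#' @return Character vector of feature column names.
#' @export
protocol_columns <- function(code) {
  code <- match.arg(code, c("full", "A", "B", "C", "D", "E", "F"))
  switch(code,
    full = c(LFT_NAMES, "GDD"),
    A = c("LFT2", "LFT3", "GDD"),
    B = c("LFT2", "LFT4", "GDD"),
    C = c("LFT3", "LFT4", "GDD"),
    D = c("LFT2", "GDD"),
    E = c("LFT3", "GDD"),
    F = c("LFT4", "GDD")
  )
}

# shared assembly: pick/construct the named feature columns, attach target,
# group labels and GDD, drop rows with a missing target
build_feature_matrix <- function(table, feature_cols, target, code) {
  table <- as_tibble(table)
  target <- match.arg(toupper(target), names(TARGET_COLS))
  target_col <- TARGET_COLS[[target]]
  used_lft <- tolower(unique(sub("xGDD$", "", setdiff(feature_cols, "GDD"))))
  need <- c("observation_id", "experiment_id", "gdd_cd", used_lft, target_col)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    stop_spadgdd(
      paste0("observation table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  keep <- !is.na(table[[target_col]])
  table <- table[keep, , drop = FALSE]
  if (nrow(table) == 0L) stop_spadgdd("no rows left after removing missing targets.", "invalid_input")

  feats <- lapply(feature_cols, function(fc) {
    if (fc == "GDD") {
      table$gdd_cd
    } else if (grepl("xGDD$", fc)) {
      lft <- tolower(sub("xGDD$", "", fc))
      # products inherit missingness from the SPAD reading; they are imputed
      # downstream as predictor columns in their own right
      table[[lft]] * table$gdd_cd
    } else {
      table[[tolower(fc)]]
    }
  })
  names(feats) <- feature_cols
  structure(
    list(
      features = as_tibble(feats),
      target = table[[target_col]],
      target_name = target,
      groups = as.character(table$experiment_id),
      gdd = table$gdd_cd,
      ids = as.character(table$observation_id),
      code = code
    ),
    class = "feature_matrix"
  )
}

#' Build the feature matrix for one SPAD/GDD formulation
#'
#' @param table Observation table (see [read_observations()] for the schema);
#'   must contain `lft1`..`lft5` (`lft5` may be missing row-wise), `gdd_cd`
#'   and the requested target. Rows with a missing target are dropped.
#' @param code Formulation code `"A"` (SPAD only), `"B"` (SPAD x GDD
#'   products), `"C"` (SPAD + GDD) or `"D"` (B plus C).
#' @param target `"LNC"`, `"PNC"` or `"NNI"`.
#' @return A `feature_matrix`: named feature tibble plus aligned target,
#'   experiment group labels, GDD and observation ids.
#' @export
build_formulation <- function(table, code, target) {
  cols <- formulation_columns(code)
  build_feature_matrix(table, cols, target, paste0("formulation_", toupper(code)))
}

#' Build the feature matrix for one measurement protocol
#'
#' @inheritParams build_formulation
#' @param code `"full"` or a simplified protocol `"A"`..`"F"`.
#' @export
build_protocol <- function(table, code, target) {
  cols <- protocol_columns(code)
  build_feature_matrix(table, cols, target, paste0("protocol_", code))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %s -> %s: %d rows, %d features (%s), %d groups\n",
    x$code, x$target_name, nrow(x$features), ncol(x$features),
    paste(names(x$features), collapse = ", "), length(unique(x$groups))
  ))
  invisible(x)
}
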