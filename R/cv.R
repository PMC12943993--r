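# Leakage-safe grouped cross-validation. Observations sharing an experiment
# id always land in the same fold, and all preprocessing (median imputation,
# and standardisation for scale-sensitive families) is fitted on the training
# split only.

#' Plan grouped folds by experiment
#'
#' Deterministic balanced assignment: groups are sorted by size (descending),
#' ties by label (ascending), and each is assigned to the fold with the
#' fewest rows so far (ties to the lowest fold index). No group is ever
#' split across folds.
#'
#' @param groups Group label per observation row.
#' @param k Number of folds (default 10). With fewer groups than `k`, only
#'   `length(unique(groups))` folds are non-empty.
#' @return A `fold_plan`: list with `k` and named integer `assignment`
#'   (group label -> fold index).
#' @export
plan_group_folds <- function(groups, k = 10L) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) {
    stop_spadgdd("grouped cross-validation needs at least 2 distinct groups.", "infeasible")
  }
  k <- as.integer(k)
  if (k < 2L) stop_spadgdd("`k` must be >= 2.", "invalid_input")
  ord <- order(-as.integer(sizes), names(sizes))
  load <- numeric(k)
  assignment <- integer(length(sizes))
  names(assignment) <- names(sizes)[ord]
  for (i in seq_along(ord)) {
    f <- which.min(load) # ties -> lowest index
    assignment[i] <- f
    load[f] <- load[f] + as.integer(sizes[ord[i]])
  }
  structure(list(k = k, assignment = assignment), class = "fold_plan")
}

# fold-local preprocessing, fitted on the training split only and reused by
# both the CV engine and the out-of-fold attribution engine (leakage parity)
fit_fold_preprocessor <- function(X_train, scale_sensitive) {
  medians <- vapply(X_train, function(col) median(col, na.rm = TRUE), numeric(1))
  all_missing <- names(medians)[!is.finite(medians)]
  if (length(all_missing) > 0L) {
    stop_spadgdd(
      paste0(
        "training split has all-missing column(s): ",
        paste(all_missing, collapse = ", ")
      ),
      "imputation"
    )
  }
  center <- scl <- NULL
  if (scale_sensitive) {
    X_imp <- impute_with(X_train, medians)
    center <- vapply(X_imp, mean, numeric(1))
    scl <- vapply(X_imp, sd, numeric(1))
    scl[!is.finite(scl) | scl == 0] <- 1 # constant columns pass through
  }
  list(medians = medians, center = center, scale = scl)
}

impute_with <- function(X, medians) {
  for (j in names(medians)) {
    miss <- is.na(X[[j]])
    if (any(miss)) X[[j]][miss] <- medians[[j]]
  }
  X
}

apply_preprocessor <- function(X, prep) {
  X <- impute_with(X, prep$medians)
  M <- as.matrix(X)
  if (!is.null(prep$center)) {
    M <- sweep(M, 2L, prep$center[colnames(M)], "-")
    M <- sweep(M, 2L, prep$scale[colnames(M)], "/")
  }
  M
}

#' Regression metrics
#'
#' Standard definitions: `r2 = 1 - SS_res/SS_tot` with the total sum of
#' squares around the mean of the supplied observed values (so out-of-fold
#' `r2` can be negative), root mean squared error, and mean absolute error.
#'
#' @param observed,predicted Equal-length numeric vectors, length >= 2.
#' @return Named list with `r2`, `rmse`, `mae`.
#' @export
regression_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop_spadgdd("`observed` and `predicted` must be equal-length, length >= 2.", "invalid_input")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop_spadgdd("metrics require finite observed and predicted values.", "invalid_input")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop_spadgdd("r2 is undefined: all observed values are identical.", "undefined_r2")
  }
  res <- observed - predicted
  list(
    r2 = 1 - sum(res^2) / ss_tot,
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res))
  )
}

#' Run grouped cross-validation for one feature matrix and model family
#'
#' Per fold: column medians are fitted on the training rows only and used to
#' fill missing predictor values in both splits; for scale-sensitive families
#' (PLS, SVR) centring/scaling is likewise fitted on training rows only; the
#' model is fitted on the training rows and evaluated on the held-out rows.
#' Metrics are computed per fold and summarised as mean +/- SD; out-of-fold
#' predictions retain observation ids and GDD for the residual diagnostics
#' downstream.
#'
#' @param features A `feature_matrix` from [build_formulation()] or
#'   [build_protocol()].
#' @param model A [model_spec()].
#' @param plan A [plan_group_folds()] plan covering all groups in `features`;
#'   by default a fresh 10-fold plan is derived from the feature matrix.
#' @return A `spad_cv`: `fold_metrics` (tibble: fold, r2, rmse, mae, n_val),
#'   `oof` (tibble: observation_id, group, gdd, observed, predicted, fold),
#'   and `summary` (tibble: metric, mean, sd).
#' @export
run_grouped_cv <- function(features, model, plan = plan_group_folds(features$groups)) {
  stopifnot(inherits(features, "feature_matrix"), inherits(model, "model_spec"))
  fold_of <- check_plan_covers(plan, features$groups)
  folds <- sort(unique(fold_of))

  fold_rows <- list()
  oof_rows <- list()
  for (f in folds) {
    va <- which(fold_of == f)
    tr <- which(fold_of != f)
    prep <- fit_fold_preprocessor(features$features[tr, , drop = FALSE], model$scale_sensitive)
    X_tr <- apply_preprocessor(features$features[tr, , drop = FALSE], prep)
    X_va <- apply_preprocessor(features$features[va, , drop = FALSE], prep)
    fit <- fit_spad_model(model, X_tr, features$target[tr])
    pred <- predict_spad_model(fit, X_va)
    if (any(!is.finite(pred))) {
      stop_spadgdd(
        sprintf("model %s produced non-finite predictions in fold %d.", model$family, f),
        "model_failure"
      )
    }
    m <- regression_metrics(features$target[va], pred)
    fold_rows[[length(fold_rows) + 1L]] <- tibble(
      fold = f, r2 = m$r2, rmse = m$rmse, mae = m$mae, n_val = length(va)
    )
    oof_rows[[length(oof_rows) + 1L]] <- tibble(
      observation_id = features$ids[va], group = features$groups[va],
      gdd = features$gdd[va], observed = features$target[va],
      predicted = pred, fold = f
    )
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  oof <- dplyr::bind_rows(oof_rows)
  summary <- tibble(
    metric = c("r2", "rmse", "mae"),
    mean = c(mean(fold_metrics$r2), mean(fold_metrics$rmse), mean(fold_metrics$mae)),
    sd = c(sd(fold_metrics$r2), sd(fold_metrics$rmse), sd(fold_metrics$mae))
  )
  structure(
    list(
      fold_metrics = fold_metrics, oof = oof, summary = summary,
      target = features$target_name, family = model$family,
      feature_set = features$code
    ),
    class = "spad_cv"
  )
}

check_plan_covers <- function(plan, groups) {
  stopifnot(inherits(plan, "fold_plan"))
  missing_groups <- setdiff(unique(groups), names(plan$assignment))
  if (length(missing_groups) > 0L) {
    stop_spadgdd(
      paste0("fold plan does not cover group(s): ", paste(missing_groups, collapse = ", ")),
      "invalid_input"
    )
  }
  unname(plan$assignment[groups])
}

#' @export
print.spad_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<spad_cv> %s / %s / %s: R2 %.3f +/- %.3f, RMSE %.3f, MAE %.3f (%d folds)\n",
    x$feature_set, x$target, x$family,
    s$mean[s$metric == "r2"], s$sd[s$metric == "r2"],
    s$mean[s$metric == "rmse"], s$mean[s$metric == "mae"], nrow(x$fold_metrics)
  ))
  invisible(x)
}
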