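# Out-of-fold Shapley attributions for tree ensembles, and the two
# normalisations used downstream: global importance (% of total mean
# absolute contribution per target-model combination) and per-sample
# mid-canopy shares (LFT2 + LFT3 + LFT4 = 100%).

# flatten a fitted randomForest into the flat node arrays the C++ TreeSHAP
# kernel expects; cover is obtained by routing the fold's training rows
rf_forest_arrays <- function(rf, X_train) {
  ntree <- rf$ntree
  trees <- lapply(seq_len(ntree), function(k) {
    randomForest::getTree(rf, k, labelVar = FALSE)
  })
  sizes <- vapply(trees, nrow, integer(1))
  offsets <- c(0L, cumsum(sizes))
  cl <- cr <- feat <- integer(sum(sizes))
  split <- value <- numeric(sum(sizes))
  for (k in seq_len(ntree)) {
    tr <- trees[[k]]
    idx <- (offsets[k] + 1L):offsets[k + 1L]
    leaf <- tr[, "status"] == -1
    cl[idx] <- ifelse(leaf, -1L, tr[, "left daughter"] - 1L + offsets[k])
    cr[idx] <- ifelse(leaf, -1L, tr[, "right daughter"] - 1L + offsets[k])
    feat[idx] <- ifelse(leaf, -1L, tr[, "split var"] - 1L)
    split[idx] <- tr[, "split point"]
    value[idx] <- tr[, "prediction"]
  }
  roots <- offsets[seq_len(ntree)]
  cover <- cpp_forest_cover(cl, cr, feat, split, roots, as.matrix(X_train))
  list(
    child_left = cl, child_right = cr, feature = feat, split = split,
    value = value, cover = cover, roots = roots
  )
}

# signed contributions + base for held-out rows under one fitted fold model
tree_contributions <- function(fit, X_train, X_new) {
  if (fit$family == "RF") {
    fa <- rf_forest_arrays(fit$fit, X_train)
    contrib <- cpp_forest_shap(
      fa$child_left, fa$child_right, fa$feature, fa$split, fa$value,
      fa$cover, fa$roots, as.matrix(X_new),
      average = TRUE
    )
    colnames(contrib) <- c(colnames(X_new), "base")
    contrib
  } else { # XGB: the library's own exact TreeSHAP
    contrib <- predict(fit$fit, xgboost::xgb.DMatrix(as.matrix(X_new), nthread = 1L),
      predcontrib = TRUE
    )
    colnames(contrib)[ncol(contrib)] <- "base"
    contrib
  }
}

#' Out-of-fold Shapley feature attributions
#'
#' For each fold of the plan, the tree-ensemble model is fitted on the
#' training split (with exactly the same fold-local median imputation as
#' [run_grouped_cv()]) and exact path-dependent Shapley contributions are
#' computed for the held-out rows, then concatenated across folds. The
#' conditional expectations are tree-path-dependent (cover-weighted), with
#' no background dataset. Contributions satisfy local accuracy: per row,
#' `base + sum(contributions) = prediction`.
#'
#' @param features A `feature_matrix`.
#' @param model A [model_spec()] with a tree family (`"RF"` or `"XGB"`).
#' @param plan A [plan_group_folds()] plan; defaults to a fresh 10-fold plan.
#' @return An `attribution_table` tibble: `observation_id`, `group`, `gdd`,
#'   `fold`, `base` (fold model expectation, target units), and one signed
#'   contribution column per feature (target units). Every observation
#'   appears exactly once, attributed by the model not trained on its group.
#' @export
oof_attributions <- function(features, model, plan = plan_group_folds(features$groups)) {
  stopifnot(inherits(features, "feature_matrix"), inherits(model, "model_spec"))
  if (!model$tree_based) {
    stop_spadgdd(
      sprintf("attributions require a tree family (RF or XGB), not %s.", model$family),
      "unsupported_model"
    )
  }
  fold_of <- check_plan_covers(plan, features$groups)
  folds <- sort(unique(fold_of))
  out <- list()
  for (f in folds) {
    va <- which(fold_of == f)
    tr <- which(fold_of != f)
    prep <- fit_fold_preprocessor(features$features[tr, , drop = FALSE], FALSE)
    X_tr <- apply_preprocessor(features$features[tr, , drop = FALSE], prep)
    X_va <- apply_preprocessor(features$features[va, , drop = FALSE], prep)
    fit <- fit_spad_model(model, X_tr, features$target[tr])
    contrib <- tree_contributions(fit, X_tr, X_va)
    tab <- as_tibble(as.data.frame(contrib[, colnames(features$features), drop = FALSE]))
    out[[length(out) + 1L]] <- dplyr::bind_cols(
      tibble(
        observation_id = features$ids[va], group = features$groups[va],
        gdd = features$gdd[va], fold = f,
        base = contrib[, "base"]
      ),
      tab
    )
  }
  res <- dplyr::bind_rows(out)
  structure(res,
    class = c("attribution_table", class(res)),
    feature_names = colnames(features$features),
    target = features$target_name, family = model$family
  )
}

attr_features <- function(attr) {
  fn <- attr(attr, "feature_names")
  if (is.null(fn)) {
    fn <- setdiff(names(attr), c("observation_id", "group", "gdd", "fold", "base"))
  }
  fn
}

#' Global feature importance from attributions
#'
#' Mean absolute contribution per feature, rescaled to sum to 100% within
#' the target-model combination the attributions came from.
#'
#' @param attr An `attribution_table` from [oof_attributions()].
#' @return Tibble with `feature` and `importance_pct` (sums to 100).
#' @export
global_importance <- function(attr) {
  fn <- attr_features(attr)
  if (nrow(attr) == 0L) stop_spadgdd("attribution table is empty.", "invalid_input")
  imp <- unname(vapply(fn, function(f) mean(abs(attr[[f]])), numeric(1)))
  total <- sum(imp)
  if (total == 0) {
    stop_spadgdd("all attributions are zero; importance normalisation undefined.", "undefined_normalization")
  }
  tibble(feature = fn, importance_pct = 100 * imp / total)
}

#' Per-sample mid-canopy importance shares
#'
#' For each observation, the absolute contributions of the mid-canopy leaves
#' LFT2-LFT4 are normalised so that they sum to 100%. Rows where all three
#' contributions are exactly zero carry no attributable mid-canopy signal
#' and are dropped (their count is reported in the `n_dropped` attribute)
#' rather than assigned equal shares.
#'
#' @param attr An `attribution_table` whose features include `LFT2`, `LFT3`
#'   and `LFT4`.
#' @return Tibble: `observation_id`, `group`, `gdd`, `share_lft2`,
#'   `share_lft3`, `share_lft4` (percent, summing to 100 per row), with
#'   attribute `n_dropped`.
#' @export
midcanopy_shares <- function(attr) {
  need <- c("LFT2", "LFT3", "LFT4")
  missing_cols <- setdiff(need, names(attr))
  if (length(missing_cols) > 0L) {
    stop_spadgdd(
      paste0("attribution table lacks mid-canopy column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  a2 <- abs(attr$LFT2)
  a3 <- abs(attr$LFT3)
  a4 <- abs(attr$LFT4)
  total <- a2 + a3 + a4
  keep <- total > 0
  res <- tibble(
    observation_id = attr$observation_id[keep],
    group = attr$group[keep],
    gdd = attr$gdd[keep],
    share_lft2 = 100 * a2[keep] / total[keep],
    share_lft3 = 100 * a3[keep] / total[keep],
    share_lft4 = 100 * a4[keep] / total[keep]
  )
  attr(res, "n_dropped") <- sum(!keep)
  res
}
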