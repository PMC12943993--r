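# Thin wrappers over the four regression families with fixed hyperparameters.
# Hyperparameters are configuration, set once and reused unchanged across all
# targets and feature sets so formulation comparisons are fair.

#' Specify a regression model family with fixed hyperparameters
#'
#' @param family `"PLS"`, `"SVR"`, `"RF"` or `"XGB"`.
#' @param ... Hyperparameter overrides. Defaults: PLS `ncomp = 3` (capped at
#'   the number of features); SVR radial-basis kernel with `cost = 10`,
#'   `gamma = NULL` (then `1/(p * mean feature variance)`, the "scale"
#'   convention), `epsilon = 0.1`; RF `ntree = 500` and `mtry = NULL`
#'   (all features considered at every split - bagged regression trees,
#'   the convention of scikit-learn-style regression forests; with few,
#'   individually strong predictors this avoids flattening steep
#'   covariate trends); XGB `nrounds = 800`, `eta = 0.05`,
#'   `max_depth = 6`, `subsample = 0.8`, `colsample_bytree = 0.8`,
#'   `lambda = 1`.
#' @param seed Integer seed applied to every stochastic fit (RF, XGB).
#' @return A `model_spec` list; `scale_sensitive` is `TRUE` for PLS and SVR,
#'   which are standardised within each training fold, while tree ensembles
#'   see original feature scales.
#' @export
model_spec <- function(family = c("RF", "XGB", "PLS", "SVR"), ..., seed = 42L) {
  family <- match.arg(toupper(family[1]), c("RF", "XGB", "PLS", "SVR"))
  defaults <- switch(family,
    PLS = list(ncomp = 3L),
    SVR = list(cost = 10, gamma = NULL, epsilon = 0.1),
    RF = list(ntree = 500L, mtry = NULL),
    XGB = list(
      nrounds = 800L, eta = 0.05, max_depth = 6L,
      subsample = 0.8, colsample_bytree = 0.8, lambda = 1.0
    )
  )
  hyper <- modifyList(defaults, list(...))
  unknown <- setdiff(names(hyper), names(defaults))
  if (length(unknown) > 0L) {
    stop_spadgdd(
      sprintf("unknown %s hyperparameter(s): %s", family, paste(unknown, collapse = ", ")),
      "config"
    )
  }
  structure(
    list(
      family = family, hyper = hyper,
      scale_sensitive = family %in% c("PLS", "SVR"),
      tree_based = family %in% c("RF", "XGB"),
      seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

fit_spad_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  h <- spec$hyper
  fit <- switch(spec$family,
    PLS = {
      ncomp <- min(h$ncomp, ncol(X), nrow(X) - 1L)
      m <- mixOmics::pls(X, matrix(y, ncol = 1L),
        ncomp = ncomp,
        mode = "regression", scale = FALSE
      )
      list(model = m, ncomp = ncomp)
    },
    SVR = {
      gamma <- h$gamma
      if (is.null(gamma)) {
        v <- mean(apply(X, 2L, var))
        gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
      }
      e1071::svm(
        x = X, y = y, type = "eps-regression", kernel = "radial",
        cost = h$cost, gamma = gamma, epsilon = h$epsilon, scale = FALSE
      )
    },
    RF = {
      mtry <- if (is.null(h$mtry)) ncol(X) else h$mtry
      with_local_seed(
        spec$seed,
        randomForest::randomForest(x = X, y = y, ntree = h$ntree, mtry = mtry)
      )
    },
    XGB = {
      params <- xgboost::xgb.params(
        objective = "reg:squarederror", eta = h$eta, max_depth = h$max_depth,
        subsample = h$subsample, colsample_bytree = h$colsample_bytree,
        lambda = h$lambda, nthread = 1L, seed = spec$seed
      )
      xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
        nrounds = h$nrounds, verbose = 0L
      )
    }
  )
  structure(list(family = spec$family, fit = fit, features = colnames(X)),
    class = "spad_fit"
  )
}

predict_spad_model <- function(fit, X) {
  stopifnot(inherits(fit, "spad_fit"))
  X <- as.matrix(X)[, fit$features, drop = FALSE]
  switch(fit$family,
    PLS = {
      p <- predict(fit$fit$model, X)$predict
      as.numeric(p[, 1L, fit$fit$ncomp])
    },
    SVR = as.numeric(predict(fit$fit, X)),
    RF = as.numeric(predict(fit$fit, X)),
    XGB = as.numeric(predict(fit$fit, xgboost::xgb.DMatrix(X, nthread = 1L)))
  )
}
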