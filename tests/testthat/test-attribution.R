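library(randomForest)

test_that("a balanced stump attributes prediction minus base to its single feature", {
  # tree: x <= 0 -> 0, x > 0 -> 1, with balanced cover
  fa <- list(
    child_left = c(1L, -1L, -1L), child_right = c(2L, -1L, -1L),
    feature = c(0L, -1L, -1L), split = c(0, 0, 0),
    value = c(NA_real_, 0, 1), cover = c(100, 50, 50), roots = 0L
  )
  sh <- spadgdd:::cpp_forest_shap(
    fa$child_left, fa$child_right, fa$feature, fa$split, fa$value,
    fa$cover, fa$roots, matrix(1), TRUE
  )
  expect_equal(sh[1, 1], 0.5) # phi = prediction 1 - base 0.5
  expect_equal(sh[1, 2], 0.5) # base = cover-weighted leaf mean
})

test_that("the TreeSHAP kernel matches brute-force subset enumeration on real forests", {
  set.seed(19)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- as.numeric(2 * X[, 1] + sin(2 * X[, 2]) + 0.5 * X[, 3] * X[, 4] + rnorm(n, 0, 0.1))
  rf <- randomForest(X, y, ntree = 12)
  fa <- spadgdd:::rf_forest_arrays(rf, X)
  for (tree in c(1L, 5L)) {
    sh <- spadgdd:::cpp_forest_shap(
      fa$child_left, fa$child_right, fa$feature, fa$split, fa$value,
      fa$cover, fa$roots[tree], X[1:6, , drop = FALSE], FALSE
    )
    for (i in 1:6) {
      oracle <- oracle_tree_shap(fa, fa$roots[tree], X[i, ], 4)
      expect_equal(unname(sh[i, 1:4]), oracle, tolerance = 1e-10)
    }
  }
})

test_that("the TreeSHAP kernel reproduces xgboost's own exact contributions", {
  set.seed(8)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- as.numeric(X %*% c(2, -1, 0.5, 0, 1) + rnorm(n, 0, 0.2))
  dtr <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "reg:squarederror", max_depth = 4, eta = 0.3, nthread = 1,
      base_score = 0.5
    ),
    data = dtr, nrounds = 10, verbose = 0
  )
  # evaluate on fresh points: training rows can sit exactly on float32 split
  # thresholds where xgboost's float32 routing and float64 routing diverge
  X_new <- matrix(rnorm(25 * 5), 25, 5)
  colnames(X_new) <- colnames(X)
  ref <- predict(bst, xgboost::xgb.DMatrix(X_new, nthread = 1), predcontrib = TRUE)

  # rebuild the boosted trees in the generic flat-array format (Cover is
  # xgboost's own training cover) and run the package kernel on them
  dt <- xgboost::xgb.model.dt.tree(model = bst)
  dt <- as.data.frame(dt)
  dt$row <- seq_len(nrow(dt)) - 1L
  id2row <- setNames(dt$row, dt$ID)
  leaf <- dt$Feature == "Leaf"
  fa <- list(
    child_left = ifelse(leaf, -1L, unname(id2row[dt$Yes])),
    child_right = ifelse(leaf, -1L, unname(id2row[dt$No])),
    feature = suppressWarnings(ifelse(leaf, -1L, as.integer(sub("^f", "", dt$Feature)) - 1L)),
    split = ifelse(leaf, 0, dt$Split),
    value = ifelse(leaf, dt$Gain, 0), # Gain column holds leaf values for leaves
    cover = dt$Cover,
    roots = dt$row[dt$Node == 0]
  )
  mine <- spadgdd:::cpp_forest_shap(
    as.integer(fa$child_left), as.integer(fa$child_right),
    as.integer(fa$feature), as.numeric(fa$split), as.numeric(fa$value),
    as.numeric(fa$cover), as.integer(fa$roots), X_new, FALSE
  )
  mine[, 6] <- mine[, 6] + 0.5 # add back xgboost's global base_score
  expect_lt(max(abs(mine - ref)), 1e-4) # float32 trees vs float64 kernel
})

test_that("duplicated feature columns share the attribution mass of the original", {
  set.seed(30)
  n <- 200
  x <- rnorm(n)
  z <- rnorm(n)
  y <- 2 * x + 0.5 * z + rnorm(n, 0, 0.1)
  X1 <- cbind(x = x, z = z)
  X2 <- cbind(x1 = x, x2 = x, z = z) # x duplicated
  set.seed(1)
  rf1 <- randomForest(X1, y, ntree = 80)
  set.seed(1)
  rf2 <- randomForest(X2, y, ntree = 80)
  fa1 <- spadgdd:::rf_forest_arrays(rf1, X1)
  fa2 <- spadgdd:::rf_forest_arrays(rf2, X2)
  s1 <- spadgdd:::cpp_forest_shap(
    fa1$child_left, fa1$child_right, fa1$feature, fa1$split, fa1$value,
    fa1$cover, fa1$roots, X1[1:40, ], TRUE
  )
  s2 <- spadgdd:::cpp_forest_shap(
    fa2$child_left, fa2$child_right, fa2$feature, fa2$split, fa2$value,
    fa2$cover, fa2$roots, X2[1:40, ], TRUE
  )
  mass1 <- mean(abs(s1[, 1]))
  mass2 <- mean(abs(s2[, 1] + s2[, 2])) # combined mass of the duplicates
  expect_lt(abs(mass2 - mass1) / mass1, 0.2) # sampling tolerance
})

test_that("out-of-fold attributions satisfy local accuracy and cover each row once", {
  obs <- make_small_obs(n_groups = 4, per_group = 25, noise_sd = 0.3)
  fm <- build_formulation(obs, "C", "PNC")
  plan <- plan_group_folds(fm$groups, k = 4)
  for (family in c("RF", "XGB")) {
    spec <- if (family == "RF") {
      model_spec(family, ntree = 60, seed = 11)
    } else {
      model_spec(family, nrounds = 50, seed = 11)
    }
    at <- oof_attributions(fm, spec, plan)
    expect_setequal(at$observation_id, fm$ids)

    # reconstruct each fold model's predictions and check base + sum = prediction
    fold_of <- unname(plan$assignment[fm$groups])
    for (f in sort(unique(fold_of))) {
      tr <- which(fold_of != f)
      va <- which(fold_of == f)
      prep <- spadgdd:::fit_fold_preprocessor(fm$features[tr, ], FALSE)
      X_tr <- spadgdd:::apply_preprocessor(fm$features[tr, ], prep)
      X_va <- spadgdd:::apply_preprocessor(fm$features[va, ], prep)
      fit <- spadgdd:::fit_spad_model(spec, X_tr, fm$target[tr])
      pred <- spadgdd:::predict_spad_model(fit, X_va)
      rows <- match(fm$ids[va], at$observation_id)
      contrib_sum <- at$base[rows] +
        rowSums(as.matrix(at[rows, attr(at, "feature_names")]))
      expect_lt(max(abs(contrib_sum - pred)), 1e-6)
    }
  }
  expect_error(
    oof_attributions(fm, model_spec("SVR"), plan),
    class = "spadgdd_error_unsupported_model"
  )
})

test_that("global importance rescales mean absolute contributions to 100%", {
  at <- tibble::tibble(
    observation_id = c("a", "b"), group = c("g1", "g2"), gdd = c(800, 900),
    fold = c(1L, 2L), base = c(0, 0),
    F1 = c(0.1, -0.1), F2 = c(0.3, 0.3), F3 = c(-0.6, 0.6)
  )
  attr(at, "feature_names") <- c("F1", "F2", "F3")
  gi <- global_importance(at)
  expect_equal(gi$importance_pct, c(10, 30, 60))
  expect_equal(sum(gi$importance_pct), 100, tolerance = 1e-9)

  single <- at
  attr(single, "feature_names") <- "F2"
  expect_equal(global_importance(single)$importance_pct, 100)

  zero <- at
  zero$F1 <- zero$F2 <- zero$F3 <- 0
  expect_error(global_importance(zero), class = "spadgdd_error_undefined_normalization")
})

test_that("mid-canopy shares normalise to 100% and drop zero-signal rows with a count", {
  at <- tibble::tibble(
    observation_id = c("a", "b", "c"), group = "g", gdd = c(700, 800, 900),
    fold = 1L, base = 0,
    LFT2 = c(0.2, 0, 1), LFT3 = c(-0.3, 0, 1), LFT4 = c(0.5, 0, 1)
  )
  sh <- midcanopy_shares(at)
  expect_equal(nrow(sh), 2L)
  expect_equal(attr(sh, "n_dropped"), 1L)
  expect_equal(unlist(sh[1, c("share_lft2", "share_lft3", "share_lft4")]),
    c(share_lft2 = 20, share_lft3 = 30, share_lft4 = 50)
  )
  expect_equal(unlist(sh[2, c("share_lft2", "share_lft3", "share_lft4")]),
    rep(100 / 3, 3),
    ignore_attr = TRUE
  )
  expect_equal(sh$share_lft2 + sh$share_lft3 + sh$share_lft4, rep(100, 2), tolerance = 1e-9)

  expect_error(midcanopy_shares(at[, -7]), class = "spadgdd_error_schema")
})
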