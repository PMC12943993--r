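test_that("fold planning is balanced, deterministic, and never splits a group", {
  groups <- rep(sprintf("G%02d", 1:20), each = 10)
  plan <- plan_group_folds(groups, k = 10)
  per_fold <- table(plan$assignment)
  expect_true(all(per_fold == 2)) # 20 equal groups over 10 folds
  expect_identical(plan, plan_group_folds(groups, k = 10))

  # hand-enumerated greedy steps: sizes {6,5,4,3}, k = 2 -> {6,3} and {5,4}
  g2 <- rep(c("a", "b", "c", "d"), times = c(6, 5, 4, 3))
  p2 <- plan_group_folds(g2, k = 2)
  expect_equal(unname(p2$assignment[c("a", "d")]), c(1L, 1L))
  expect_equal(unname(p2$assignment[c("b", "c")]), c(2L, 2L))

  expect_error(plan_group_folds(rep("only", 5)), class = "spadgdd_error_infeasible")
})

test_that("regression metrics follow the standard definitions, including negative r2", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(r2 = 1, rmse = 0, mae = 0))
  expect_equal(regression_metrics(c(1, 2, 3), c(2, 2, 2))$r2, 0) # mean predictor
  m <- regression_metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(m$r2, 0.97) # hand-evaluated
  expect_equal(m$rmse, 0.1414214, tolerance = 1e-6)
  expect_equal(m$mae, 0.1333333, tolerance = 1e-6)
  expect_lt(regression_metrics(c(1, 2, 3), c(30, -10, 15))$r2, 0)
  expect_error(regression_metrics(c(2, 2, 2), c(1, 2, 3)), class = "spadgdd_error_undefined_r2")
})

test_that("fold-wise median imputation uses the training split only", {
  obs <- make_small_obs(n_groups = 2, per_group = 4)
  fm <- build_formulation(obs, "A", "LNC")
  fm$features$LFT1 <- c(1, 2, 3, 100, NA, 5, 6, 7) # train = G01 rows
  prep <- fit_fold_preprocessor(fm$features[1:4, ], FALSE)
  filled <- impute_with(fm$features[5:8, ], prep$medians)
  expect_equal(filled$LFT1[1], 2.5) # median of {1,2,3,100}

  # a validation-only outlier never changes the imputation value
  with_outlier <- fm$features
  with_outlier$LFT2[6] <- 1e6
  expect_identical(
    fit_fold_preprocessor(fm$features[1:4, ], TRUE),
    fit_fold_preprocessor(with_outlier[1:4, ], TRUE)
  )
  # deleting validation rows entirely leaves preprocessing bit-identical
  expect_identical(
    fit_fold_preprocessor(fm$features[1:4, ], TRUE),
    fit_fold_preprocessor(rbind(fm$features[1:4, ]), TRUE)
  )
  # all-missing training column is a named error
  broken <- fm$features
  broken$LFT3[1:4] <- NA
  err <- expect_error(fit_fold_preprocessor(broken[1:4, ], FALSE),
    class = "spadgdd_error_imputation"
  )
  expect_match(conditionMessage(err), "LFT3")
})

test_that("grouped CV covers every row out-of-fold exactly once, by a foreign-group model", {
  obs <- make_small_obs(n_groups = 6, per_group = 25, noise_sd = 0.2)
  fm <- build_formulation(obs, "C", "LNC")
  plan <- plan_group_folds(fm$groups, k = 3)
  cv <- run_grouped_cv(fm, model_spec("RF", ntree = 60, seed = 9), plan)
  expect_setequal(cv$oof$observation_id, fm$ids)
  expect_equal(nrow(cv$oof), length(fm$ids))
  # each row was predicted in the fold its group maps to
  expect_equal(cv$oof$fold, unname(plan$assignment[cv$oof$group]))
  expect_equal(nrow(cv$fold_metrics), 3L)
  expect_true(all(cv$fold_metrics$rmse >= cv$fold_metrics$mae))
  expect_equal(cv$summary$mean[cv$summary$metric == "r2"], mean(cv$fold_metrics$r2))
})

test_that("tree CV on noiseless functional data recovers the target almost exactly", {
  obs <- make_small_obs(n_groups = 5, per_group = 40, noise_sd = 0)
  fm <- build_formulation(obs, "C", "LNC")
  cv <- run_grouped_cv(fm, model_spec("RF", ntree = 200, seed = 4),
    plan_group_folds(fm$groups, k = 5)
  )
  expect_gte(mean(cv$fold_metrics$r2), 0.99)
})

test_that("CV results are reproducible under fixed seeds for stochastic families", {
  obs <- make_small_obs(n_groups = 4, per_group = 20, noise_sd = 0.2)
  fm <- build_formulation(obs, "A", "PNC")
  plan <- plan_group_folds(fm$groups, k = 4)
  for (family in c("RF", "XGB")) {
    spec <- if (family == "RF") {
      model_spec(family, ntree = 50, seed = 7)
    } else {
      model_spec(family, nrounds = 40, seed = 7)
    }
    a <- run_grouped_cv(fm, spec, plan)
    b <- run_grouped_cv(fm, spec, plan)
    expect_identical(a$oof$predicted, b$oof$predicted)
  }
})

test_that("scale-sensitive families standardise within folds and all four families run", {
  obs <- make_small_obs(n_groups = 4, per_group = 25, noise_sd = 0.3)
  fm <- build_formulation(obs, "C", "LNC")
  plan <- plan_group_folds(fm$groups, k = 4)
  specs <- list(
    model_spec("PLS"), model_spec("SVR"),
    model_spec("RF", ntree = 50, seed = 2), model_spec("XGB", nrounds = 40, seed = 2)
  )
  for (spec in specs) {
    cv <- run_grouped_cv(fm, spec, plan)
    expect_true(all(is.finite(cv$oof$predicted)))
    expect_gt(mean(cv$fold_metrics$r2), 0.5) # strong signal, all families learn it
  }
})
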