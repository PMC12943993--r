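# A reduced panel keeps generator tests fast; the full default panel is
# exercised by the acceptance suite.
small_config <- function(...) {
  designs <- lapply(1:4, function(i) {
    experiment_design(
      experiment_id = sprintf("E%02d", i),
      sowing_day = 130 + 4 * i,
      n_rates = c(0, 150, 300), replicates = 2,
      sampling_gdds = c(750, 1100, 1450) + 20 * i
    )
  })
  generator_config(designs = designs, seed = 7L, ...)
}

test_that("simulated weather is sinusoidal, reproducible, and degenerate without noise", {
  quiet <- site_climate(20, 0, 10, daily_noise_sd = 0)
  w <- simulate_weather(quiet, year_span = 30, seed = 1)
  expect_equal(w$tmax_c, rep(25, 30)) # constant climate collapses to (25, 15)
  expect_equal(w$tmin_c, rep(15, 30))

  noisy <- site_climate(16, 12, 8, daily_noise_sd = 2)
  expect_identical(
    simulate_weather(noisy, 100, seed = 5),
    simulate_weather(noisy, 100, seed = 5)
  )
  expect_false(identical(
    simulate_weather(noisy, 100, seed = 5)$tmax_c,
    simulate_weather(noisy, 100, seed = 6)$tmax_c
  ))
})

test_that("noiseless sinusoidal weather integrates to the closed-form floored sum", {
  site <- site_climate(16, 12, 8, phase_day = 205, daily_noise_sd = 0)
  w <- simulate_weather(site, year_span = 365, seed = 1)
  doy <- as.integer(format(w$date, "%j"))
  closed_form <- sum(pmax(0, 16 + 12 * cos(2 * pi * (doy - 205) / 365.25) - 10))
  expect_equal(cumulative_gdd(w, w$date[1], w$date[365]), closed_form)
})

test_that("generation is deterministic and carries a well-formed group structure", {
  a <- generate_dataset(small_config())
  b <- generate_dataset(small_config())
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)

  obs <- a$observations
  # one row per experiment x rate x replicate x sampling
  expect_equal(nrow(obs), 4 * 3 * 2 * 3)
  expect_false(anyDuplicated(obs$observation_id) > 0)
  per_exp_gdd <- tapply(obs$gdd_cd, obs$experiment_id, function(g) length(unique(g)))
  expect_true(all(per_exp_gdd >= 2))
  # recorded truth matches the parameters actually used
  expect_equal(a$truth$crossover_gdd_true, 1100)
  expect_equal(nrow(a$truth$noiseless), nrow(obs))
})

test_that("zero noise collapses replicates onto the recorded noiseless truth", {
  cfg <- small_config(
    dm_noise_sdlog = 0, pnc_noise_sdlog = 0, lnc_noise_sd = 0,
    spad_noise_sd = rep(0, 5), leaf_idio_sd = 0, sampling_jitter_days = 0,
    lft5_emergence_gdd = 0, lft5_senescence_gdd = 1e6 # keep LFT5 deterministic
  )
  ds <- generate_dataset(cfg)
  obs <- ds$observations
  one_rate <- obs[obs$n_rate_kg_ha == 150 & obs$stage == 1, ]
  split_by_exp <- split(one_rate, one_rate$experiment_id)
  for (tab in split_by_exp) {
    expect_equal(length(unique(tab$lft2)), 1L) # replicates identical
    expect_equal(length(unique(tab$pnc_pct)), 1L)
  }
  truth <- ds$truth$noiseless[match(obs$observation_id, ds$truth$noiseless$observation_id), ]
  expect_equal(obs$lft3, truth$spad3_true)
  expect_equal(obs$pnc_pct, truth$pnc_true)

  # ground-truth crossover: the two sensitivity trajectories meet there exactly
  gam <- spadgdd:::gamma_trajectories(cfg$crossover_gdd_true, cfg)
  expect_equal(unname(gam[, "lft2"]), unname(gam[, "lft3"]))
})

test_that("LFT5 missingness is confined to early emergence and late senescence", {
  ds <- generate_dataset(generator_config(seed = 3))
  obs <- ds$observations
  frac_missing <- mean(is.na(obs$lft5))
  expect_gt(frac_missing, 0)
  cfg <- generator_config()
  early <- obs$gdd_cd < cfg$lft5_emergence_gdd
  late <- obs$gdd_cd > cfg$lft5_senescence_gdd
  expect_true(all(is.na(obs$lft5[early]))) # deterministic before emergence
  expect_true(all(!is.na(obs$lft5) | early | late)) # none missing mid-season
})

test_that("default panel reproduces the reference marginal structure", {
  obs <- generate_dataset(generator_config())$observations
  # reference means: LNC 3.02, PNC 2.02, NNI 0.95 (within 20%)
  expect_lt(abs(mean(obs$lnc_pct) / 3.02 - 1), 0.2)
  expect_lt(abs(mean(obs$pnc_pct) / 2.02 - 1), 0.2)
  expect_lt(abs(mean(obs$nni) / 0.95 - 1), 0.2)
  # dispersion grows toward lower leaves
  expect_gt(sd(obs$lft5, na.rm = TRUE), sd(obs$lft1))
  expect_equal(length(unique(obs$experiment_id)), 20L)
  expect_true(all(obs$n_rate_kg_ha >= 0 & obs$n_rate_kg_ha <= 300))
})

test_that("infeasible sampling schedules are rejected", {
  bad <- small_config()
  bad$designs[[1]]$sampling_gdds <- c(700, 9000)
  expect_error(generate_dataset(bad), class = "spadgdd_error_config")
})

test_that("datasets round-trip through write_dataset and read_observations", {
  ds <- generate_dataset(small_config())
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_observations(file.path(dir, "observations.csv"))
  expect_equal(back$pnc_pct, ds$observations$pnc_pct)
  expect_equal(back$lft5, ds$observations$lft5) # NA cells preserved
  expect_equal(back$nni, ds$observations$nni) # NNI recomputed, not read
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$crossover_gdd_true, 1100)
})
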