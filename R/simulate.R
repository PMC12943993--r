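# Synthetic multi-experiment rice trial generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: many independent field experiments (groups) with N-rate gradients,
# destructive samplings spread over thermal time, growth-linked N dilution,
# a leaf-position-stratified SPAD response to leaf N with dispersion
# increasing down the canopy, and a ground-truth GDD at which the N
# sensitivities of leaves 2 and 3 cross. All parameters live in
# `generator_config()` so tests can collapse noise or move the crossover.

#' Site climate description for the weather simulator
#'
#' @param mean_annual_temp Mean annual air temperature (degrees C).
#' @param seasonal_amplitude Half-range of the seasonal sinusoid (degrees C).
#' @param diurnal_range Daily tmax - tmin (degrees C).
#' @param phase_day Day of year of the warmest day.
#' @param daily_noise_sd SD of independent daily temperature noise (degrees C).
#' @return A `site_climate` list.
#' @export
site_climate <- function(mean_annual_temp = 16.5, seasonal_amplitude = 12,
                         diurnal_range = 8, phase_day = 205,
                         daily_noise_sd = 1.5) {
  stopifnot(
    is_number(mean_annual_temp), is_number(seasonal_amplitude),
    is_number(diurnal_range), is_number(phase_day), is_number(daily_noise_sd)
  )
  if (seasonal_amplitude < 0 || diurnal_range < 0 || daily_noise_sd < 0) {
    stop_spadgdd("climate amplitude, diurnal range and noise SD must be >= 0.", "config")
  }
  structure(
    list(
      mean_annual_temp = mean_annual_temp, seasonal_amplitude = seasonal_amplitude,
      diurnal_range = diurnal_range, phase_day = phase_day,
      daily_noise_sd = daily_noise_sd
    ),
    class = "site_climate"
  )
}

#' One synthetic field experiment
#'
#' @param experiment_id Label, e.g. `"E01"`.
#' @param site A [site_climate()].
#' @param sowing_day Day of year of nursery seeding.
#' @param n_rates Nitrogen rates (kg N/ha), each within 0-300.
#' @param replicates Number of field replicates per N rate.
#' @param sampling_gdds Strictly increasing schedule of target sampling
#'   thermal times (degree C days from sowing).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(experiment_id, site = site_climate(),
                              sowing_day = 135,
                              n_rates = c(0, 100, 200, 300),
                              replicates = 3,
                              sampling_gdds = c(700, 1000, 1300, 1600, 1900)) {
  if (any(n_rates < 0 | n_rates > 300)) {
    stop_spadgdd("N rates must lie within [0, 300] kg N/ha.", "config")
  }
  if (replicates < 1) stop_spadgdd("replicates must be >= 1.", "config")
  if (is.unsorted(sampling_gdds, strictly = TRUE)) {
    stop_spadgdd("sampling_gdds must be strictly increasing.", "config")
  }
  structure(
    list(
      experiment_id = as.character(experiment_id), site = site,
      sowing_day = sowing_day, n_rates = n_rates, replicates = replicates,
      sampling_gdds = sampling_gdds
    ),
    class = "experiment_design"
  )
}

#' Default panel of 20 synthetic experiments
#'
#' Twenty experiments across five climates (mean annual temperature
#' 15.1-17.5 degrees C), mid-May to late-June sowings, 2-4 nitrogen rates
#' spanning 0-300 kg N/ha, three replicates, and five samplings per plot
#' spread over roughly 650-2000 degree C days - about 1.1 thousand
#' observations in total.
#'
#' @return List of [experiment_design()] objects.
#' @export
default_designs <- function() {
  sites <- list(
    site_climate(15.1, 11.5, 8.5, 203), # cool site
    site_climate(15.8, 12.0, 8.0, 205),
    site_climate(16.4, 12.0, 8.0, 206),
    site_climate(16.9, 12.5, 7.5, 207),
    site_climate(17.5, 11.0, 7.0, 208) # warm site, late sowing
  )
  # number of N treatments per experiment (2-4) and site/sowing layout
  n_treat <- c(4, 4, 4, 4, 4, 4, 4, 3, 4, 4, 4, 4, 4, 4, 2, 4, 4, 4, 4, 4)
  site_of <- c(1, 1, 2, 2, 2, 2, 2, 3, 3, 3, 4, 3, 5, 1, 3, 5, 5, 5, 5, 5)
  sow_of <- c(134, 134, 136, 136, 132, 139, 143, 133, 130, 132, 145, 139, 176, 133, 135, 176, 176, 176, 176, 176)
  lapply(seq_len(20L), function(i) {
    # deterministic per-experiment jitter spreads sampling coverage over 650-2000
    jit <- ((i * 37) %% 11 - 5) * 10
    experiment_design(
      experiment_id = sprintf("E%02d", i),
      site = sites[[site_of[i]]],
      sowing_day = sow_of[i],
      n_rates = round(seq(0, 300, length.out = n_treat[i])),
      replicates = 3,
      sampling_gdds = c(700, 1000, 1300, 1600, 1900) + jit
    )
  })
}

#' Generator configuration
#'
#' Bundles the experiment panel with the generative model parameters. The
#' generative dilution coefficients (`a_gen`, `b_gen`) deliberately differ
#' from the analysis dilution curve (3.44, 0.44) so that NNI computed
#' downstream is not circular. `crossover_gdd_true` is the thermal time at
#' which the N sensitivities of leaf 2 and leaf 3 are equal - the ground
#' truth that the attribution-dynamics pipeline should recover.
#'
#' @param designs List of [experiment_design()]s, default [default_designs()].
#' @param dm_max Asymptotic aboveground dry matter (t/ha) at full N supply.
#' @param dm_steepness Logistic steepness of DM growth (per degree C day).
#' @param dm_midpoint_gdd Logistic midpoint of DM growth (degree C days).
#' @param dm_noise_sdlog Lognormal SD of plot-level DM noise.
#' @param supply_half_n Michaelis constant of the saturating N-supply factor
#'   (kg N/ha).
#' @param supply_min,supply_gain PNC supply factor is
#'   `supply_min + supply_gain * N/(N + supply_half_n)`.
#' @param a_gen,b_gen Generative dilution coefficients (PNC before supply
#'   scaling is `a_gen * DM^-b_gen`).
#' @param nni_span Length-2 clamp on the noiseless nitrogen nutrition index
#'   implied by the analysis dilution curve.
#' @param pnc_noise_sdlog Lognormal SD of PNC noise.
#' @param lnc_intercept,lnc_slope,lnc_noise_sd Linear link LNC =
#'   intercept + slope * PNC + noise; leaves are more N-rich than the whole
#'   plant, so the intercept is positive.
#' @param spad_baseline SPAD baseline per leaf (LFT1-LFT5) at 1250 degree C
#'   days; LFT2 and LFT3 share one value so that their importance crossover
#'   is driven by the sensitivity trajectories alone.
#' @param spad_baseline_slope Baseline drift per 1000 degree C days; lower
#'   leaves decline (senescence); equal for LFT2 and LFT3 (same reason).
#' @param spad_ref_supply Reference N-supply factor: the origin of the
#'   standardised plot N-status latent (plots at this supply have status 0).
#' @param supply_sd_ref Reference spread (SD) of the supply factor across
#'   the N-rate gradient, used to standardise the N-status latent. Dilution
#'   compresses absolute LNC differences over the season; working in
#'   standardised status units keeps the leaf-signal distribution stationary
#'   along GDD, so leaf positions differ only in sensitivity and the
#'   importance crossover stays identifiable.
#' @param leaf_idio_sd Canopy-stratification SD: each leaf position carries
#'   a partly idiosyncratic N status, `z_l = sqrt(1 - s^2) z + s eta_l`
#'   with `eta_l` standard normal per plot and leaf. Whole-plant N is the
#'   average over strata, so every leaf holds information about the target
#'   that no other leaf can substitute - without this, near-noiseless
#'   leaves become interchangeable proxies and tree models split credit
#'   among them arbitrarily.
#' @param sampling_jitter_days Per-plot sampling-date jitter (each plot is
#'   sampled up to this many days before/after the experiment's nominal
#'   stage date), spreading thermal-time support within a stage.
#' @param gamma_hi,gamma_lo,gamma_width Mirrored sigmoid sensitivity
#'   trajectories of the two key mid-canopy leaves (SPAD units per SD of
#'   leaf N status): LFT2 declines from `gamma_hi` to `gamma_lo` and LFT3
#'   rises from `gamma_lo` to `gamma_hi` as logistic functions of GDD with
#'   scale `gamma_width` (degree C days), crossing exactly at
#'   `crossover_gdd_true`. The sigmoid shape concentrates the importance
#'   redistribution in a window around the crossover - a sharp transition
#'   between two plateaus, the regime the crossover estimator is built
#'   for - rather than spreading it over the whole season.
#' @param gamma1,gamma5 Constant sensitivities of the newest and lowest leaf.
#' @param gamma4_start,gamma4_slope LFT4 sensitivity: `gamma4_start` at 650
#'   degree C days plus an optional linear ramp (flat by default).
#' @param gamma_floor Lower bound applied to every sensitivity trajectory.
#' @param spad_noise_sd Per-leaf SPAD noise SDs, non-decreasing from LFT1 to
#'   LFT5; LFT2 and LFT3 share one value so that their importance crossover
#'   reflects sensitivity rather than signal-to-noise.
#' @param crossover_gdd_true Ground-truth crossover (degree C days).
#' @param lft5_emergence_gdd LFT5 is deterministically absent before this.
#' @param lft5_senescence_gdd,lft5_senescence_ramp Beyond the senescence
#'   threshold LFT5 is missing with probability
#'   `min(1, (gdd - threshold)/ramp)`.
#' @param seed Master integer seed; per-stage substreams (weather, biomass,
#'   nitrogen, SPAD, missingness) are derived from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(designs = default_designs(),
                             dm_max = 18, dm_steepness = 0.004,
                             dm_midpoint_gdd = 1350, dm_noise_sdlog = 0.10,
                             supply_half_n = 110, supply_min = 0.45,
                             supply_gain = 0.78,
                             a_gen = 3.9, b_gen = 0.40,
                             nni_span = c(0.5, 1.3),
                             pnc_noise_sdlog = 0.06,
                             lnc_intercept = 1.0, lnc_slope = 1.0,
                             lnc_noise_sd = 0.25,
                             spad_baseline = c(39.1, 42.6, 42.6, 42.0, 40.5),
                             spad_baseline_slope = c(1.0, 0.5, 0.5, -1.5, -4.0),
                             spad_ref_supply = 0.85,
                             supply_sd_ref = 0.26,
                             leaf_idio_sd = 0.7,
                             sampling_jitter_days = 3L,
                             gamma_hi = 2.3, gamma_lo = 0.7,
                             gamma_width = 90,
                             gamma1 = 0.5, gamma5 = 0.4,
                             gamma4_start = 0.9, gamma4_slope = 0,
                             gamma_floor = 0.1,
                             spad_noise_sd = c(1.3, 1.7, 1.7, 2.1, 2.6),
                             crossover_gdd_true = 1100,
                             lft5_emergence_gdd = 800,
                             lft5_senescence_gdd = 1650,
                             lft5_senescence_ramp = 450,
                             seed = 20L) {
  cfg <- list(
    designs = designs, dm_max = dm_max, dm_steepness = dm_steepness,
    dm_midpoint_gdd = dm_midpoint_gdd, dm_noise_sdlog = dm_noise_sdlog,
    supply_half_n = supply_half_n, supply_min = supply_min,
    supply_gain = supply_gain, a_gen = a_gen, b_gen = b_gen,
    nni_span = nni_span, pnc_noise_sdlog = pnc_noise_sdlog,
    lnc_intercept = lnc_intercept, lnc_slope = lnc_slope,
    lnc_noise_sd = lnc_noise_sd, spad_baseline = spad_baseline,
    spad_baseline_slope = spad_baseline_slope,
    spad_ref_supply = spad_ref_supply, supply_sd_ref = supply_sd_ref,
    leaf_idio_sd = leaf_idio_sd,
    sampling_jitter_days = as.integer(sampling_jitter_days),
    gamma_hi = gamma_hi, gamma_lo = gamma_lo, gamma_width = gamma_width,
    gamma1 = gamma1, gamma5 = gamma5, gamma4_start = gamma4_start,
    gamma4_slope = gamma4_slope, gamma_floor = gamma_floor,
    spad_noise_sd = spad_noise_sd, crossover_gdd_true = crossover_gdd_true,
    lft5_emergence_gdd = lft5_emergence_gdd,
    lft5_senescence_gdd = lft5_senescence_gdd,
    lft5_senescence_ramp = lft5_senescence_ramp, seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (length(cfg$designs) < 1L || !all(vapply(cfg$designs, inherits, logical(1), "experiment_design"))) {
    stop_spadgdd("`designs` must be a non-empty list of experiment_design objects.", "config")
  }
  ids <- vapply(cfg$designs, `[[`, character(1), "experiment_id")
  if (anyDuplicated(ids)) stop_spadgdd("experiment ids must be unique.", "config")
  sds <- c(
    cfg$dm_noise_sdlog, cfg$pnc_noise_sdlog, cfg$lnc_noise_sd,
    cfg$spad_noise_sd, cfg$leaf_idio_sd
  )
  if (any(sds < 0)) stop_spadgdd("all noise SDs must be >= 0.", "config")
  if (cfg$leaf_idio_sd >= 1) {
    stop_spadgdd("leaf_idio_sd must lie in [0, 1).", "config")
  }
  if (cfg$sampling_jitter_days < 0) {
    stop_spadgdd("sampling_jitter_days must be >= 0.", "config")
  }
  if (cfg$gamma_hi <= cfg$gamma_lo || cfg$gamma_lo <= 0 || cfg$gamma_width <= 0) {
    stop_spadgdd("gamma trajectories need gamma_hi > gamma_lo > 0 and gamma_width > 0.", "config")
  }
  if (length(cfg$spad_noise_sd) != 5L || is.unsorted(cfg$spad_noise_sd)) {
    stop_spadgdd("spad_noise_sd must be 5 non-decreasing values (LFT1..LFT5).", "config")
  }
  if (length(cfg$spad_baseline) != 5L || length(cfg$spad_baseline_slope) != 5L) {
    stop_spadgdd("spad_baseline and spad_baseline_slope must have length 5.", "config")
  }
  if (length(cfg$nni_span) != 2L || cfg$nni_span[1] >= cfg$nni_span[2]) {
    stop_spadgdd("nni_span must be an increasing pair.", "config")
  }
  invisible(cfg)
}

# evaluate the expr under `seed` without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# per-stage substream seeds, so that e.g. adding replicates re-draws SPAD
# noise but leaves the simulated weather untouched
stage_seed <- function(seed, stage) {
  offsets <- c(
    weather = 101L, sampling = 151L, biomass = 211L, nitrogen = 307L,
    spad = 401L, missing = 503L
  )
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Simulate daily weather for a site
#'
#' Sinusoidal seasonal mean temperature plus independent Gaussian daily
#' noise; `tmax = mean + diurnal_range/2`, `tmin = mean - diurnal_range/2`
#' (so `tmax >= tmin` always holds). Reproducible for a fixed seed.
#'
#' @param site A [site_climate()].
#' @param year_span Number of days to simulate.
#' @param seed Integer seed.
#' @param start_date First simulated day (default Jan 1 of a nominal year).
#' @return A weather tibble (`date`, `tmax_c`, `tmin_c`).
#' @export
simulate_weather <- function(site, year_span = 730, seed = 1L,
                             start_date = as.Date("2019-01-01")) {
  if (!inherits(site, "site_climate")) stop_spadgdd("`site` must be a site_climate.", "config")
  if (year_span < 1) stop_spadgdd("`year_span` must be >= 1.", "config")
  dates <- as.Date(start_date) + seq_len(year_span) - 1L
  doy <- as.integer(format(dates, "%j"))
  mean_t <- site$mean_annual_temp +
    site$seasonal_amplitude * cos(2 * pi * (doy - site$phase_day) / 365.25)
  noise <- with_local_seed(seed, rnorm(year_span, 0, site$daily_noise_sd))
  mean_t <- mean_t + noise
  tibble(
    date = dates,
    tmax_c = mean_t + site$diurnal_range / 2,
    tmin_c = mean_t - site$diurnal_range / 2
  )
}

# sensitivity trajectories gamma_l(gdd): SPAD response per SD of leaf N
# status. LFT2 declines and LFT3 rises as mirrored sigmoids through the
# configured crossover (two plateaus, sharp local redistribution);
# LFT1/LFT4/LFT5 are flat by default.
gamma_trajectories <- function(gdd, cfg) {
  u <- (gdd - cfg$crossover_gdd_true) / cfg$gamma_width
  g2 <- cfg$gamma_lo + (cfg$gamma_hi - cfg$gamma_lo) / (1 + exp(u))
  g3 <- cfg$gamma_lo + (cfg$gamma_hi - cfg$gamma_lo) / (1 + exp(-u))
  g4 <- cfg$gamma4_start + cfg$gamma4_slope * (gdd - 650)
  out <- cbind(
    lft1 = rep(cfg$gamma1, length(gdd)), lft2 = g2, lft3 = g3,
    lft4 = g4, lft5 = rep(cfg$gamma5, length(gdd))
  )
  pmax(out, cfg$gamma_floor)
}

spad_baselines <- function(gdd, cfg) {
  outer(gdd - 1250, cfg$spad_baseline_slope / 1000) +
    matrix(cfg$spad_baseline, length(gdd), 5L, byrow = TRUE)
}

#' Generate a synthetic multi-experiment observation table
#'
#' Runs the full generative model: per-experiment weather and sowing-aligned
#' thermal time, logistic dry-matter growth scaled by a saturating N-supply
#' factor, growth-linked N dilution (`PNC = supply(N) * a_gen * DM^-b_gen`,
#' clamped so the implied NNI stays within `nni_span`), a linear PNC-to-LNC
#' link, leaf-position-stratified SPAD responses
#' `SPAD_l = baseline_l(GDD) + gamma_l(GDD) * (LNC - 3) + noise_l`, and
#' early/late LFT5 missingness. The NNI column is computed with the
#' *analysis* dilution curve via [nni()], never with the generative one.
#'
#' @param config A [generator_config()].
#' @return A list of class `spad_dataset` with elements
#'   `observations` (tibble; one row per experiment x N rate x replicate x
#'   sampling) and `truth` (list: crossover, generative coefficients, and a
#'   tibble of noiseless per-observation values).
#' @export
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  cfg <- config
  ids <- vapply(cfg$designs, `[[`, character(1), "experiment_id")

  # stage 1: weather + realised sampling thermal times per experiment
  per_exp <- lapply(seq_along(cfg$designs), function(i) {
    d <- cfg$designs[[i]]
    w <- simulate_weather(d$site,
      year_span = 730,
      seed = stage_seed(cfg$seed, "weather") + i
    )
    sow <- w$date[1] + d$sowing_day - 1L
    daily <- daily_gdd(w$tmax_c, w$tmin_c, t_base = 10)
    daily[w$date < sow] <- 0
    cum <- cumsum(daily)
    hit <- vapply(d$sampling_gdds, function(target) {
      j <- which(cum >= target)[1]
      if (is.na(j) || j + cfg$sampling_jitter_days > length(cum)) {
        stop_spadgdd(
          sprintf(
            "experiment %s: sampling GDD %g exceeds weather coverage (max %.0f).",
            d$experiment_id, target, max(cum)
          ),
          "config"
        )
      }
      j
    }, integer(1))
    list(design = d, hit = hit, cum = cum, date = w$date)
  })

  # expand the design grid; plots are sampled within a few days of the
  # nominal stage date, spreading thermal-time support within each stage
  rows <- dplyr::bind_rows(lapply(seq_along(per_exp), function(i) {
    d <- per_exp[[i]]$design
    grid <- expand.grid(
      stage = seq_along(d$sampling_gdds), replicate = seq_len(d$replicates),
      n_rate = d$n_rates, KEEP.OUT.ATTRS = FALSE
    )
    tibble(
      exp_index = i,
      experiment_id = d$experiment_id,
      n_rate_kg_ha = grid$n_rate,
      replicate = grid$replicate,
      stage = grid$stage
    )
  }))
  n <- nrow(rows)
  jit <- cfg$sampling_jitter_days
  day_offset <- if (jit > 0) {
    with_local_seed(
      stage_seed(cfg$seed, "sampling"),
      sample(seq.int(-jit, jit), n, replace = TRUE)
    )
  } else {
    integer(n)
  }
  day_index <- vapply(seq_len(n), function(r) {
    e <- per_exp[[rows$exp_index[r]]]
    max(1L, e$hit[rows$stage[r]] + day_offset[r])
  }, integer(1))
  rows$gdd_cd <- vapply(seq_len(n), function(r) {
    per_exp[[rows$exp_index[r]]]$cum[day_index[r]]
  }, numeric(1))
  rows$sampling_date <- as.Date(vapply(seq_len(n), function(r) {
    as.character(per_exp[[rows$exp_index[r]]]$date[day_index[r]])
  }, character(1)))
  rows$observation_id <- sprintf(
    "%s_N%03d_R%d_S%d", rows$experiment_id, rows$n_rate_kg_ha,
    rows$replicate, rows$stage
  )

  # stage 2: biomass (logistic in thermal time, scaled by N supply)
  dm_supply <- 0.55 + 0.45 * rows$n_rate_kg_ha / (rows$n_rate_kg_ha + 120)
  dm_true <- cfg$dm_max * dm_supply /
    (1 + exp(-cfg$dm_steepness * (rows$gdd_cd - cfg$dm_midpoint_gdd)))
  dm_noise <- with_local_seed(
    stage_seed(cfg$seed, "biomass"),
    rnorm(n, 0, cfg$dm_noise_sdlog)
  )
  dm <- dm_true * exp(dm_noise)

  # stage 3: nitrogen. Canopy stratification: the N-rate-driven plot status
  # z spawns leaf-stratum statuses z_l = sqrt(1 - s^2) z + s eta_l (unit
  # variance), so each leaf position carries information about whole-plant
  # N that no other leaf can substitute. Whole-plant N concentration follows
  # the generative dilution law at the stratum-average status, clamped so
  # the implied NNI stays within `nni_span`.
  supply <- cfg$supply_min + cfg$supply_gain * rows$n_rate_kg_ha /
    (rows$n_rate_kg_ha + cfg$supply_half_n)
  z_plot <- (supply - cfg$spad_ref_supply) / cfg$supply_sd_ref
  s <- cfg$leaf_idio_sd
  nitro_noise <- with_local_seed(stage_seed(cfg$seed, "nitrogen"), list(
    eta = matrix(rnorm(n * 5L), n, 5L),
    pnc = rnorm(n, 0, cfg$pnc_noise_sdlog),
    lnc = rnorm(n, 0, cfg$lnc_noise_sd)
  ))
  z_leaf <- sqrt(1 - s^2) * z_plot + s * nitro_noise$eta
  z_plant <- rowMeans(z_leaf) / sqrt(1 - s^2 + s^2 / 5) # unit variance
  supply_eff <- cfg$spad_ref_supply + cfg$supply_sd_ref * z_plant
  pnc_true <- pmax(supply_eff, 0.05) * cfg$a_gen * dm_true^(-cfg$b_gen)
  nc_analysis <- critical_n(dm_true)
  pnc_true <- pmin(pmax(pnc_true, cfg$nni_span[1] * nc_analysis), cfg$nni_span[2] * nc_analysis)
  pnc <- pnc_true * exp(nitro_noise$pnc)
  lnc_true <- cfg$lnc_intercept + cfg$lnc_slope * pnc_true
  lnc <- cfg$lnc_intercept + cfg$lnc_slope * pnc + nitro_noise$lnc

  # stage 4: SPAD per leaf position. The seasonal greenness trajectory lives
  # in the baseline; the nitrogen signal is the sensitivity-scaled leaf
  # status in standardised units (dilution compresses absolute LNC
  # differences, so stationary status units keep leaf positions free of
  # hidden phenology content - they differ only in sensitivity).
  gam <- gamma_trajectories(rows$gdd_cd, cfg)
  base <- spad_baselines(rows$gdd_cd, cfg)
  spad_true <- base + gam * z_leaf
  spad_noise <- with_local_seed(
    stage_seed(cfg$seed, "spad"),
    matrix(rnorm(n * 5L), n, 5L) %*% diag(cfg$spad_noise_sd)
  )
  spad <- spad_true + spad_noise

  # stage 5: LFT5 missingness (deterministic before emergence, stochastic
  # senescence ramp after)
  p_sen <- pmin(1, pmax(0, (rows$gdd_cd - cfg$lft5_senescence_gdd) / cfg$lft5_senescence_ramp))
  sen_draw <- with_local_seed(stage_seed(cfg$seed, "missing"), runif(n))
  lft5_missing <- rows$gdd_cd < cfg$lft5_emergence_gdd | sen_draw < p_sen
  spad[lft5_missing, 5L] <- NA_real_

  nni_tab <- nni(pnc, dm)

  observations <- tibble(
    observation_id = rows$observation_id,
    experiment_id = rows$experiment_id,
    n_rate_kg_ha = rows$n_rate_kg_ha,
    replicate = rows$replicate,
    stage = rows$stage,
    gdd_cd = rows$gdd_cd,
    lft1 = spad[, 1L], lft2 = spad[, 2L], lft3 = spad[, 3L],
    lft4 = spad[, 4L], lft5 = spad[, 5L],
    dm_t_ha = dm, lnc_pct = lnc, pnc_pct = pnc,
    nni = nni_tab$nni
  )

  truth_obs <- tibble(
    observation_id = rows$observation_id,
    gdd_cd = rows$gdd_cd,
    dm_true = dm_true, pnc_true = pnc_true, lnc_true = lnc_true,
    spad1_true = spad_true[, 1L], spad2_true = spad_true[, 2L],
    spad3_true = spad_true[, 3L], spad4_true = spad_true[, 4L],
    spad5_true = spad_true[, 5L],
    gamma2 = gam[, 2L], gamma3 = gam[, 3L], gamma4 = gam[, 4L]
  )

  structure(
    list(
      observations = observations,
      truth = list(
        crossover_gdd_true = cfg$crossover_gdd_true,
        a_gen = cfg$a_gen, b_gen = cfg$b_gen,
        seed = cfg$seed,
        noiseless = truth_obs
      )
    ),
    class = "spad_dataset"
  )
}

#' @export
print.spad_dataset <- function(x, ...) {
  obs <- x$observations
  cat(sprintf(
    "<spad_dataset> %d observations, %d experiments, GDD %.0f-%.0f C d\n",
    nrow(obs), dplyr::n_distinct(obs$experiment_id),
    min(obs$gdd_cd), max(obs$gdd_cd)
  ))
  cat(sprintf(
    "  true importance crossover at %.0f C d; LFT5 missing in %d rows\n",
    x$truth$crossover_gdd_true, sum(is.na(obs$lft5))
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `observations.csv` in the shared observation schema (NNI is always
#' recomputed on read, so it is not written) and `truth.json` with the
#' generative ground truth.
#'
#' @param dataset A `spad_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spad_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs_path <- file.path(dir, "observations.csv")
  truth_path <- file.path(dir, "truth.json")
  out <- dataset$observations[, setdiff(names(dataset$observations), "nni")]
  readr::write_csv(out, obs_path, progress = FALSE)
  truth <- dataset$truth
  truth$noiseless <- as.list(truth$noiseless)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(observations = obs_path, truth = truth_path))
}
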