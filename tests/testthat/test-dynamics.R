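test_that("LOWESS reproduces collinear data exactly and preserves constants", {
  x <- seq(600, 2000, length.out = 80)
  grid <- seq(650, 1950, length.out = 50)
  line <- lowess_smooth(x, 10 + 0.03 * x, grid)
  expect_equal(line$value, 10 + 0.03 * grid, tolerance = 1e-9)
  flat <- lowess_smooth(x, rep(50, 80), grid, dynamics_config(lowess_fraction = 0.6))
  expect_equal(flat$value, rep(50, 50))
})

test_that("LOWESS agrees with a naive per-grid-point WLS oracle on a noisy sine", {
  set.seed(21)
  n <- 500
  x <- runif(n, 0, 10)
  y <- sin(x) + rnorm(n, 0, 0.3)
  grid <- seq(min(x), max(x), length.out = 220)
  mine <- lowess_smooth(x, y, grid)$value
  theirs <- oracle_lowess(x, y, grid, fraction = 0.25)
  expect_lt(max(abs(mine - theirs)), 1e-6)
})

test_that("LOWESS enforces its sample-size precondition", {
  expect_error(
    lowess_smooth(c(1, 2), c(1, 2), seq(1, 2, length.out = 5)),
    class = "spadgdd_error_sample_size"
  )
})

test_that("crossover detection interpolates the first sign change", {
  grid <- seq(600, 1400, length.out = 81)
  a <- tibble::tibble(gdd = grid, value = 60 - 0.02 * grid)
  b <- tibble::tibble(gdd = grid, value = 20 + 0.02 * grid)
  expect_equal(find_crossover(a, b), 1000) # lines cross exactly at 1000

  expect_true(is.na(find_crossover(a, tibble::tibble(gdd = grid, value = a$value - 5))))

  # two sign changes: the first (lowest GDD) one is returned
  d <- ifelse(grid < 800, 1, ifelse(grid < 1200, -1, 1))
  a2 <- tibble::tibble(gdd = grid, value = d)
  b2 <- tibble::tibble(gdd = grid, value = 0)
  expect_lt(find_crossover(a2, b2), 810)

  expect_error(
    find_crossover(a, tibble::tibble(gdd = grid + 1, value = b$value)),
    class = "spadgdd_error_alignment"
  )
})

test_that("crossover CI takes percentiles over defined crossings and counts the rest", {
  est <- crossover_ci(rep(1000, 50), point = 1000)
  expect_equal(c(est$ci_low, est$ci_high), c(1000, 1000))

  crossings <- seq(900, 1100, length.out = 201) # uniform fixture
  est <- crossover_ci(crossings, point = 1000)
  expect_equal(est$ci_low, unname(quantile(crossings, 0.025)))
  expect_equal(est$ci_high, unname(quantile(crossings, 0.975)))
  expect_equal(round(est$ci_low), 905)
  expect_equal(round(est$ci_high), 1095)

  half <- c(seq(950, 1050, length.out = 100), rep(NA_real_, 100))
  est <- crossover_ci(half, point = 1000)
  expect_equal(est$replicates_with_crossover, 100L)
  expect_equal(est$replicates_total, 200L)

  expect_error(crossover_ci(rep(NA_real_, 10), point = 1000), class = "spadgdd_error_no_crossover")

  # widening the percentiles never narrows the interval
  wide <- crossover_ci(crossings, point = 1000, config = dynamics_config(ci_percentiles = c(0.5, 99.5)))
  expect_lte(wide$ci_low, est$ci_low)
  expect_gte(wide$ci_high, est$ci_high)
})

make_shares <- function(n_groups = 8, per_group = 40, seed = 5, noise = 4) {
  set.seed(seed)
  n <- n_groups * per_group
  gdd <- runif(n, 650, 1950)
  s2 <- pmin(90, pmax(5, 55 - 0.015 * (gdd - 650) + rnorm(n, 0, noise)))
  s3 <- pmin(90, pmax(5, 25 + 0.015 * (gdd - 650) + rnorm(n, 0, noise)))
  s4 <- pmax(0, 100 - s2 - s3)
  tibble::tibble(
    observation_id = sprintf("o%04d", 1:n),
    group = rep(sprintf("G%02d", 1:n_groups), each = per_group),
    gdd = gdd, share_lft2 = s2, share_lft3 = s3, share_lft4 = s4
  )
}

test_that("group bootstrap is deterministic, spans the grid contract, and covers the full curve", {
  sh <- make_shares()
  cfg <- dynamics_config(bootstrap_replicates = 60, seed = 14)
  a <- group_bootstrap(sh, cfg)
  b <- group_bootstrap(sh, cfg)
  expect_identical(a$bands, b$bands)
  expect_identical(a$crossover, b$crossover)

  expect_length(a$grid, 220L)
  expect_equal(a$grid[1], min(sh$gdd))
  expect_equal(a$grid[220], max(sh$gdd))
  expect_equal(diff(range(diff(a$grid))), 0, tolerance = 1e-9) # equally spaced
  expect_true(all(a$bands$lower <= a$bands$upper))

  # pointwise bands should contain the full-data curve almost everywhere
  lft2_band <- a$bands[a$bands$leaf == "lft2", ]
  inside <- mean(a$curves$lft2 >= lft2_band$lower & a$curves$lft2 <= lft2_band$upper)
  expect_gte(inside, 0.9)

  # the generating share curves cross at gdd where 55-0.015 d = 25+0.015 d -> d=1000
  expect_equal(a$crossover$point_estimate, 1650, tolerance = 60)
  expect_true(a$crossover$ci_low <= a$crossover$point_estimate + 1e-9)
  expect_true(a$crossover$ci_high >= a$crossover$point_estimate - 1e-9)
})

test_that("identical rows in every group give zero-width bands", {
  gdd <- seq(700, 1900, length.out = 30)
  one <- tibble::tibble(
    gdd = gdd,
    share_lft2 = 50 - 0.01 * (gdd - 650), share_lft3 = 30 + 0.01 * (gdd - 650)
  )
  one$share_lft4 <- 100 - one$share_lft2 - one$share_lft3
  sh <- dplyr::bind_rows(lapply(1:4, function(g) {
    dplyr::mutate(one,
      group = paste0("G", g),
      observation_id = paste0(g, "_", seq_len(nrow(one)))
    )
  }))
  res <- group_bootstrap(sh, dynamics_config(bootstrap_replicates = 25, seed = 3))
  expect_equal(res$bands$lower, res$bands$upper, tolerance = 1e-9)
})
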