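test_that("noise-free constant climate is exactly constant and seeded runs repeat", {
  cl <- simulate_climate(2000, 2000, mean = 7, amplitude = 0, ar_coef = 0,
                         sd = 0, seed = 1)
  expect_equal(nrow(cl), 12L)
  expect_true(all(cl$value == 7))

  a <- simulate_climate(1950, 1980, seed = 42)
  b <- simulate_climate(1950, 1980, seed = 42)
  expect_identical(a, b)

  expect_error(simulate_climate(1950, 1940), "start_year")
  expect_error(simulate_climate(1950, 1960, sd = -1), "sd")
  expect_error(simulate_climate(1950, 1960, ar_coef = 1.2), "ar_coef")
})

test_that("annual anomalies carry the generating lag-1 autocorrelation", {
  acfs <- sapply(1:10, function(s) {
    cl <- simulate_climate(1900, 2014, mean = 7, amplitude = 3,
                           ar_coef = 0.6, sd = 0.5, seed = 7 + s)
    ann <- tapply(cl$value, cl$year, mean)
    stats::acf(ann - mean(ann), plot = FALSE, lag.max = 1)$acf[2]
  })
  expect_lt(abs(mean(acfs) - 0.6), 0.15)
})

test_that("the roster respects the sampling design arithmetic", {
  r <- simulate_population(100, 2000L, age_at_catch_range = c(8, 8), seed = 1)
  expect_equal(nrow(r), 100L)
  expect_true(all(r$cohort == 1992L))

  r2 <- simulate_population(500, 1929:2015, c(8, 14), seed = 2)
  expect_true(all(r2$cohort >= 1915 & r2$cohort <= 2007))
  expect_error(simulate_population(10, integer()), "catch_years")
  expect_error(simulate_population(0, 2000), "n_fish")
})

test_that("the degenerate generator returns exp(alpha0) everywhere", {
  truth <- sim_truth(alpha0 = 5, beta_age = 0, beta_w = 0, beta_a = 0,
                     beta_age_w = 0, beta_n = 0, beta_age_n = 0,
                     var_fish = 0, var_year = 0, var_cohort = 0,
                     var_age_fish = 0, var_age_year = 0, var_age_cohort = 0,
                     rho_fish = 0, rho_year = 0, rho_cohort = 0,
                     var_slope_fish = 0, sigma2 = 0)
  cl <- constant_climate(1970, 2000)
  rost <- simulate_population(20, 1990:2000, seed = 3)
  tab <- simulate_increments(truth, rost, cl, seed = 4)
  expect_equal(tab$width_um, rep(exp(5), nrow(tab)), tolerance = 1e-12)
})

test_that("identical truth and seed reproduce the identical table", {
  cl <- simulate_climate(1970, 2005, seed = 5)
  rost <- simulate_population(50, 1990:2005, seed = 6)
  t1 <- simulate_increments(sim_truth(), rost, cl, seed = 9)
  t2 <- simulate_increments(sim_truth(), rost, cl, seed = 9)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("design conservation: consecutive ages and year = cohort + age", {
  cl <- simulate_climate(1970, 2005, seed = 5)
  rost <- simulate_population(80, 1990:2005, seed = 7)
  tab <- simulate_increments(sim_truth(), rost, cl, seed = 8)
  expect_true(all(tab$year == tab$cohort + tab$age))
  by_fish <- split(tab$age, tab$fish_id)
  expect_true(all(vapply(by_fish, function(a)
    identical(sort(a), seq(min(a), max(a))), logical(1))))
  expect_true(all(tab$age >= 2 & tab$age <= 10))
  expect_true(all(tab$width_um > 0))
})

test_that("with no residual noise the log width equals the linear predictor", {
  truth <- sim_truth(sigma2 = 0)
  cl <- simulate_climate(1970, 2005, seed = 5)
  rost <- simulate_population(40, 1990:2005, seed = 10)
  tab <- simulate_increments(truth, rost, cl, seed = 11)
  tr <- attr(tab, "truth_realized")
  expect_equal(log(tab$width_um), tr$lp, tolerance = 1e-12)
})

test_that("fish-level intercept variance raises between-fish spread", {
  cl <- simulate_climate(1970, 2005, seed = 5)
  spread <- function(var_fish, seed) {
    truth <- sim_truth(var_fish = var_fish, var_age_fish = 0, rho_fish = 0,
                       var_year = 0, var_cohort = 0, var_age_year = 0,
                       var_age_cohort = 0, rho_year = 0, rho_cohort = 0,
                       var_slope_fish = 0, sigma2 = 0.01)
    rost <- simulate_population(150, 1990:2005, seed = seed)
    tab <- simulate_increments(truth, rost, cl, seed = seed + 50L)
    stats::var(tapply(log(tab$width_um), tab$fish_id, mean))
  }
  with_var <- sapply(1:10, function(s) spread(0.02, s))
  without <- sapply(1:10, function(s) spread(0, s + 100L))
  expect_true(all(with_var > without))
})

test_that("among-individual temperature contrast back-transforms to +9.46%", {
  # two fish, identical ages, lifetime-mean temperatures 1.31 degC apart,
  # only the among effect active and no noise
  truth <- sim_truth(alpha0 = 5, beta_age = 0, beta_w = 0, beta_a = 0.069,
                     beta_age_w = 0, var_fish = 0, var_year = 0,
                     var_cohort = 0, var_age_fish = 0, var_age_year = 0,
                     var_age_cohort = 0, rho_fish = 0, rho_year = 0,
                     rho_cohort = 0, var_slope_fish = 0, sigma2 = 0)
  cl <- constant_climate(1970, 2001)
  # fish 2's whole life is 1.31 degC warmer
  cl2 <- cl
  warm_years <- 1991:2000
  cl2$value[cl2$year %in% warm_years] <- cl2$value[cl2$year %in% warm_years] + 1.31
  rost <- data.frame(fish_id = c("A", "B"), catch_year = c(2000, 2000),
                     age_at_catch = c(9, 9), cohort = c(1991, 1991),
                     sex = c("F", "F"))
  # fish A lives under cl (6.40-like), fish B under cl2 (7.71-like): emulate
  # by simulating each under its own series and pooling
  tA <- simulate_increments(truth, rost[1, ], cl, seed = 1)
  tB <- simulate_increments(truth, rost[2, ], cl2, seed = 1)
  # among effect is centered within each call, so compare through the model:
  # the width ratio between the two environments equals exp(beta_a * 1.31)
  lpA <- attr(tA, "truth_realized")
  lpB <- attr(tB, "truth_realized")
  ratio <- exp((lpB$lp + 0.069 * mean(lpB$among)) -
                 (lpA$lp + 0.069 * mean(lpA$among)))
  expect_equal(unique(round(100 * (ratio - 1), 2)), 9.46)
})

test_that("cohort-specific slope variance maps require complete coverage", {
  truth <- sim_truth(var_slope_fish = c("1992" = 0.01))
  cl <- constant_climate(1980, 2001)
  rost <- simulate_population(10, 2000:2001, seed = 1)
  expect_error(simulate_increments(truth, rost, cl, seed = 2), "cohort")
})

test_that("climate coverage gaps inside a fish's life are an error", {
  truth <- sim_truth()
  cl <- constant_climate(1995, 2005)
  rost <- simulate_population(10, 2004:2005, seed = 1)  # lives reach back < 1995
  expect_error(simulate_increments(truth, rost, cl, seed = 2), "cover")
})

test_that("written simulation files round-trip through the readers", {
  cl <- simulate_climate(1975, 2005, seed = 5)
  rost <- simulate_population(30, 1995:2005, seed = 6)
  stock <- simulate_stock(1975:2005, seed = 7)
  tab <- simulate_increments(sim_truth(), rost, cl, stock, seed = 8)
  dir <- withr_tempdir()
  paths <- write_simulation(tab, cl, stock, dir)
  back <- read_inputs(paths["increments"], paths["climate"],
                      paths["abundance"], paths["hr"])
  expect_equal(nrow(back$raw), nrow(tab))
  expect_equal(back$climate$value, cl$value)
  expect_true(file.exists(paths["truth"]))
  unlink(dir, recursive = TRUE)
})
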