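#' Simulation truth for the growth generator
#'
#' Bundles every parameter of the generative crossed random-effects growth
#' model: fixed effects on the log scale, random-effect (co)variances for the
#' fish, year and cohort grouping factors, the individual thermal-plasticity
#' slope variance, and the residual variance. Defaults are on the scale of
#' published estimates for a long-lived demersal stock: log-increment widths
#' around exp(5.3) um, a steep age decline, a small positive within-individual
#' temperature slope that reverses with age, and a larger among-individual
#' slope.
#'
#' @param alpha0 intercept, log-um.
#' @param beta_age slope on centered log-age.
#' @param beta_w within-individual temperature slope (per degree C).
#' @param beta_a among-individual temperature slope (per degree C).
#' @param beta_age_w age x within-temperature interaction.
#' @param beta_n,beta_age_n abundance-index main effect and age interaction.
#' @param var_fish,var_year,var_cohort random-intercept variances.
#' @param var_age_fish,var_age_year,var_age_cohort random age-slope variances.
#' @param rho_fish,rho_year,rho_cohort intercept-slope correlations.
#' @param var_slope_fish individual thermal-plasticity slope variance. Either
#'   a single number, a named numeric vector keyed by cohort, or a function of
#'   the cohort-mean windowed temperature returning a variance (used to
#'   emulate cohort-heterogeneous plasticity).
#' @param sigma2 residual variance on the log scale.
#' @param seed default seed for generator calls that do not pass one.
#' @return An object of class `sim_truth` (a validated list).
#' @export
sim_truth <- function(alpha0 = 5.32, beta_age = -0.645,
                      beta_w = 0.020, beta_a = 0.069, beta_age_w = -0.092,
                      beta_n = -0.002, beta_age_n = 0.017,
                      var_fish = 0.007, var_year = 0.002, var_cohort = 0.001,
                      var_age_fish = 0.012, var_age_year = 0.001,
                      var_age_cohort = 0.004,
                      rho_fish = 0.44, rho_year = -0.107, rho_cohort = 0.167,
                      var_slope_fish = 0.005, sigma2 = 0.056,
                      seed = 20141007L) {
  tr <- list(alpha0 = alpha0, beta_age = beta_age, beta_w = beta_w,
             beta_a = beta_a, beta_age_w = beta_age_w, beta_n = beta_n,
             beta_age_n = beta_age_n,
             var_fish = var_fish, var_year = var_year, var_cohort = var_cohort,
             var_age_fish = var_age_fish, var_age_year = var_age_year,
             var_age_cohort = var_age_cohort,
             rho_fish = rho_fish, rho_year = rho_year, rho_cohort = rho_cohort,
             var_slope_fish = var_slope_fish, sigma2 = sigma2,
             seed = as.integer(seed))
  vars <- unlist(tr[c("var_fish", "var_year", "var_cohort", "var_age_fish",
                      "var_age_year", "var_age_cohort")])
  if (any(vars < 0)) stop("all variances must be >= 0")
  if (is.numeric(tr$var_slope_fish) && any(tr$var_slope_fish < 0))
    stop("var_slope_fish must be >= 0")
  rhos <- unlist(tr[c("rho_fish", "rho_year", "rho_cohort")])
  if (any(abs(rhos) > 1)) stop("correlations must lie in [-1, 1]")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  class(tr) <- "sim_truth"
  tr
}

#' Simulate a monthly sea-temperature series
#'
#' Monthly values are a sinusoidal seasonal cycle (peaking in late summer)
#' around `mean`, plus a stationary AR(1) annual anomaly shared by all months
#' of a year, plus independent month-level anomalies. This emulates the
#' structure of a regional mean-monthly SST series: strong seasonality,
#' interannual autocorrelation, and month-to-month weather noise (without
#' which no single month could ever be distinguished from its calendar year,
#' and sliding-window month selection would be ill-posed).
#'
#' @param start_year,end_year inclusive calendar span.
#' @param mean long-term mean, degrees C.
#' @param amplitude seasonal half-range, degrees C.
#' @param ar_coef lag-1 autocorrelation of annual anomalies, |ar_coef| < 1.
#' @param sd innovation standard deviation of the annual anomaly.
#' @param month_sd standard deviation of independent month-level anomalies
#'   (default 60% of the annual-anomaly scale; zero when `sd` is zero).
#' @param seed integer seed.
#' @return A `climate_series` data.frame with columns `year`, `month`, `value`.
#' @export
simulate_climate <- function(start_year, end_year, mean = 7, amplitude = 3,
                             ar_coef = 0.6, sd = 0.5, month_sd = 0.6 * sd,
                             seed = 1L) {
  if (start_year > end_year) stop("start_year must be <= end_year")
  if (sd < 0 || month_sd < 0) stop("sd must be >= 0")
  if (abs(ar_coef) >= 1) stop("ar_coef must satisfy |ar_coef| < 1")
  years <- start_year:end_year
  ny <- length(years)
  withr_seed(seed, {
    innov <- stats::rnorm(ny, 0, sd)
    anom <- numeric(ny)
    anom[1] <- if (sd > 0) stats::rnorm(1, 0, sd / sqrt(1 - ar_coef^2)) else 0
    if (ny > 1) for (t in 2:ny) anom[t] <- ar_coef * anom[t - 1] + innov[t]
    m_anom <- if (month_sd > 0) stats::rnorm(12L * ny, 0, month_sd) else 0
    out <- data.frame(
      year = rep(years, each = 12L),
      month = rep(1:12, ny),
      value = mean +
        amplitude * cos(2 * pi * (rep(1:12, ny) - 8) / 12) +
        rep(anom, each = 12L) + m_anom
    )
  })
  structure(out, class = c("climate_series", "data.frame"))
}

#' Simulate a fish sampling roster
#'
#' Emulates an archival sampling design in which otoliths of mature fish
#' (age >= 8 at catch by default) are drawn from each catch year. Catch ages
#' are weighted toward the youngest mature age, mirroring selection of the
#' most abundant mature age group.
#'
#' @param n_fish number of fish.
#' @param catch_years integer vector of candidate catch years.
#' @param age_at_catch_range two-element range of catch ages.
#' @param seed integer seed.
#' @return A data.frame with `fish_id`, `catch_year`, `age_at_catch`,
#'   `cohort` (= catch_year - age_at_catch) and `sex`.
#' @export
simulate_population <- function(n_fish, catch_years,
                                age_at_catch_range = c(8L, 14L), seed = 1L) {
  if (n_fish <= 0) stop("n_fish must be > 0")
  if (length(catch_years) == 0) stop("catch_years must be nonempty")
  ages <- seq.int(age_at_catch_range[1], age_at_catch_range[2])
  withr_seed(seed, {
    roster <- data.frame(
      fish_id = sprintf("F%05d", seq_len(n_fish)),
      catch_year = catch_years[sample.int(length(catch_years), n_fish,
                                          replace = TRUE)],
      age_at_catch = ages[sample.int(length(ages), n_fish, replace = TRUE,
                                     prob = 0.5^(ages - ages[1]))],
      sex = sample(c("F", "M"), n_fish, replace = TRUE)
    )
  })
  roster$cohort <- roster$catch_year - roster$age_at_catch
  roster[c("fish_id", "catch_year", "age_at_catch", "cohort", "sex")]
}

#' Simulate stock abundance-at-age and harvest rate series
#'
#' Log-abundance follows, per age class, a declining age profile plus an AR(1)
#' year anomaly shared across ages (cohort strength propagates along ages);
#' harvest rate is a logistic transform of a slow AR(1) walk, kept in (0, 1).
#'
#' @param years calendar years to cover.
#' @param ages age classes to cover.
#' @param seed integer seed.
#' @return list with `abundance` (year, age, abundance) and `hr` (year, hr).
#' @export
simulate_stock <- function(years, ages = 2:10, seed = 1L) {
  ny <- length(years)
  withr_seed(seed, {
    yr_anom <- as.numeric(stats::arima.sim(list(ar = 0.7), ny, sd = 0.4))
    age_anom <- stats::rnorm(ny * length(ages), 0, 0.15)
    hr_walk <- as.numeric(stats::arima.sim(list(ar = 0.9), ny, sd = 0.1))
  })
  ab <- expand.grid(year = years, age = ages)
  ab <- ab[order(ab$age, ab$year), ]
  ab$abundance <- exp(12 - 0.45 * ab$age +
                        yr_anom[match(ab$year, years)] + age_anom)
  rownames(ab) <- NULL
  hr <- data.frame(year = years, hr = stats::plogis(-1.2 + hr_walk))
  list(abundance = ab, hr = hr)
}

## resolve the plasticity slope variance for one cohort
slope_var_for <- function(var_slope_fish, cohort, cohort_mean_env) {
  if (is.function(var_slope_fish)) {
    v <- var_slope_fish(cohort_mean_env)
  } else if (!is.null(names(var_slope_fish))) {
    v <- var_slope_fish[as.character(cohort)]
    if (any(is.na(v))) stop("var_slope_fish has no entry for cohort ",
                            paste(cohort[is.na(v)], collapse = ", "))
  } else {
    v <- rep_len(var_slope_fish, length(cohort))
  }
  v <- as.numeric(v)
  if (any(v < 0)) stop("var_slope_fish resolved to a negative variance")
  v
}

## draw (intercept, slope) pairs from N(0, Sigma(var0, var1, rho))
draw_int_slope <- function(n, var0, var1, rho) {
  z <- matrix(stats::rnorm(2 * n), n, 2)
  sd0 <- sqrt(var0); sd1 <- sqrt(var1)
  cov01 <- rho * sd0 * sd1
  S <- matrix(c(var0, cov01, cov01, var1), 2, 2)
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  z %*% L
}

#' Simulate an otolith increment table from a known truth
#'
#' Generates, for every fish in the roster, one increment per age from 2 up to
#' the year before catch (and at most age 10), i.e. directly on the support
#' that survives first/edge-increment and old-age exclusion. Widths are
#' `exp(linear predictor + eps)` where the linear predictor follows the
#' extended growth model: centered log-age with crossed random
#' intercepts/age-slopes for fish, year and cohort; the windowed temperature
#' split into the fish's lifetime mean (among) and annual deviations from it
#' (within); a fish-specific random thermal slope drawn with its cohort's
#' slope variance; and optional abundance effects.
#'
#' @param truth a [sim_truth()].
#' @param roster from [simulate_population()].
#' @param climate a `climate_series` covering every formation year plus the
#'   window look-back.
#' @param stock optional list as from [simulate_stock()]; when supplied the
#'   abundance index and harvest rate are attached and the abundance effects
#'   of `truth` enter the linear predictor.
#' @param window two-element `c(open, close)` months-back window (default
#'   April of the growth year) defining the true temperature signal.
#' @param seed integer seed; defaults to `truth$seed`.
#' @return A `growth_table` data.frame (fish_id, cohort, year, age, width_um,
#'   sex) with attribute `truth_realized`: the per-row linear predictor and
#'   covariates, the realized random effects, and the centering constants used.
#' @export
simulate_increments <- function(truth, roster, climate, stock = NULL,
                                window = c(8L, 8L), seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  ages_per_fish <- pmin(roster$age_at_catch - 1L, 10L)
  keep <- ages_per_fish >= 2L
  roster <- roster[keep, , drop = FALSE]
  ages_per_fish <- ages_per_fish[keep]
  n_per <- ages_per_fish - 1L
  idx <- rep.int(seq_len(nrow(roster)), n_per)
  tab <- data.frame(
    fish_id = roster$fish_id[idx],
    cohort = roster$cohort[idx],
    age = unlist(lapply(ages_per_fish, function(a) 2:a), use.names = FALSE),
    sex = roster$sex[idx]
  )
  tab$year <- tab$cohort + tab$age

  env <- window_aggregate(climate, window, tab$year)
  among_fish <- tapply(env, tab$fish_id, mean)
  among <- as.numeric(among_fish[tab$fish_id])
  within <- env - among
  among_c <- among - mean(among)

  c_age <- mean(log(tab$age))
  log_age_c <- log(tab$age) - c_age

  n_idx <- rep(0, nrow(tab)); hr <- rep(0, nrow(tab))
  if (!is.null(stock)) {
    nix <- build_n_index(stock$abundance)
    key <- paste(tab$year, tab$age)
    m <- match(key, paste(nix$year, nix$age))
    if (anyNA(m)) stop("stock abundance missing (year, age): ",
                       paste(unique(key[is.na(m)]), collapse = "; "))
    n_idx <- nix$n_index[m]
    mh <- match(tab$year, stock$hr$year)
    if (anyNA(mh)) stop("harvest rate missing years: ",
                        paste(unique(tab$year[is.na(mh)]), collapse = ", "))
    hr <- stock$hr$hr[mh]
  }

  fish_lev <- unique(tab$fish_id)
  year_lev <- sort(unique(tab$year))
  coh_lev <- sort(unique(tab$cohort))
  coh_env <- tapply(among, tab$cohort, mean)  # cohort-mean lifetime temperature

  withr_seed(seed, {
    re_f <- draw_int_slope(length(fish_lev), truth$var_fish,
                           truth$var_age_fish, truth$rho_fish)
    re_y <- draw_int_slope(length(year_lev), truth$var_year,
                           truth$var_age_year, truth$rho_year)
    re_c <- draw_int_slope(length(coh_lev), truth$var_cohort,
                           truth$var_age_cohort, truth$rho_cohort)
    fish_coh <- tab$cohort[match(fish_lev, tab$fish_id)]
    sv <- slope_var_for(truth$var_slope_fish, fish_coh,
                        as.numeric(coh_env[as.character(fish_coh)]))
    therm <- stats::rnorm(length(fish_lev), 0, sqrt(sv))
    eps <- if (truth$sigma2 > 0)
      stats::rnorm(nrow(tab), 0, sqrt(truth$sigma2)) else numeric(nrow(tab))
  })

  fi <- match(tab$fish_id, fish_lev)
  yi <- match(tab$year, year_lev)
  ci <- match(tab$cohort, coh_lev)
  lp <- truth$alpha0 +
    (truth$beta_age + re_f[fi, 2] + re_y[yi, 2] + re_c[ci, 2]) * log_age_c +
    re_f[fi, 1] + re_y[yi, 1] + re_c[ci, 1] +
    (truth$beta_w + therm[fi]) * within +
    truth$beta_age_w * log_age_c * within +
    truth$beta_a * among_c +
    truth$beta_n * n_idx + truth$beta_age_n * log_age_c * n_idx

  tab$width_um <- exp(lp + eps)
  tab <- tab[c("fish_id", "cohort", "year", "age", "width_um", "sex")]
  attr(tab, "truth_realized") <- list(
    truth = truth, window = window, seed = seed, c_age = c_age,
    lp = lp, env = env, within = within, among = among, among_c = among_c,
    n_index = n_idx, hr = hr,
    fish_effects = data.frame(fish_id = fish_lev, intercept = re_f[, 1],
                              age_slope = re_f[, 2], thermal_slope = therm,
                              cohort = fish_coh),
    year_effects = data.frame(year = year_lev, intercept = re_y[, 1],
                              age_slope = re_y[, 2]),
    cohort_effects = data.frame(cohort = coh_lev, intercept = re_c[, 1],
                                age_slope = re_c[, 2])
  )
  attr(tab, "filtered") <- TRUE  # generated directly on the retained support
  class(tab) <- c("growth_table", "data.frame")
  tab
}

#' Write a simulated dataset to plain-text files
#'
#' @param table a `growth_table`.
#' @param climate a `climate_series`.
#' @param stock list as from [simulate_stock()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(table, climate, stock, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(increments = file.path(dir, "increments.csv"),
             climate = file.path(dir, "climate.csv"),
             abundance = file.path(dir, "abundance.csv"),
             hr = file.path(dir, "hr.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(as.data.frame(table), paths["increments"], row.names = FALSE)
  utils::write.csv(as.data.frame(climate), paths["climate"], row.names = FALSE)
  utils::write.csv(stock$abundance, paths["abundance"], row.names = FALSE)
  utils::write.csv(stock$hr, paths["hr"], row.names = FALSE)
  tr <- attr(table, "truth_realized")
  if (!is.null(tr)) {
    keep <- tr$truth[!vapply(tr$truth, is.function, logical(1))]
    jsonlite::write_json(keep, paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

## run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}
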