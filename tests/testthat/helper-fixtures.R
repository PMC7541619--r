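# Fixture builders shared across the suite. Everything is generated in code;
# sizes are kept small so single tests run in seconds.

withr_tempdir <- function() {
  d <- tempfile("otochron")
  dir.create(d)
  d
}

# constant-value climate covering a span, handy for exact window arithmetic
constant_climate <- function(start, end, value = 7) {
  structure(data.frame(year = rep(start:end, each = 12L),
                       month = rep(1:12, end - start + 1L),
                       value = value),
            class = c("climate_series", "data.frame"))
}

# climate whose value encodes (year, month) uniquely: year * 100 + month
coded_climate <- function(start, end) {
  cl <- constant_climate(start, end)
  cl$value <- cl$year * 100 + cl$month
  cl
}

# a prepared modelling frame simulated from `truth`, with the windowed
# covariate attached and decomposed
sim_prepared_frame <- function(n_fish = 200, truth = sim_truth(),
                               catch_years = 1980:2005, seed = 1,
                               climate = NULL, window = c(8L, 8L)) {
  if (is.null(climate))
    climate <- simulate_climate(min(catch_years) - 16L, max(catch_years),
                                seed = seed + 1L)
  roster <- simulate_population(n_fish, catch_years, seed = seed + 2L)
  tab <- simulate_increments(truth, roster, climate, NULL, window = window,
                             seed = seed)
  fr <- growth_transform(apply_filters(tab))
  fr <- attach_covariates(fr, climate, window)
  fr <- decompose_within_among(fr, "sst_win")
  attr(fr, "climate") <- climate
  fr
}

# a reduced-complexity truth: crossed intercepts but no year/cohort age
# slopes, for fast fitting in recovery and selection tests
reduced_truth <- function(...) {
  sim_truth(var_age_year = 0, var_age_cohort = 0, rho_year = 0,
            rho_cohort = 0, ...)
}

# balanced one-way layout: m groups of size n_i
oneway_data <- function(m, n_i, mu = 0, tau = 1, sigma2 = 1, seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(m), each = n_i))
  a <- rnorm(m, 0, sqrt(tau))
  data.frame(y = mu + a[as.integer(g)] + rnorm(m * n_i, 0, sqrt(sigma2)),
             g = g)
}

# closed-form ANOVA variance components for a balanced one-way layout
oneway_anova_components <- function(d) {
  n_i <- as.integer(table(d$g)[1])
  gm <- tapply(d$y, d$g, mean)
  msb <- n_i * sum((gm - mean(d$y))^2) / (length(gm) - 1)
  msw <- sum((d$y - gm[as.integer(d$g)])^2) / (nrow(d) - length(gm))
  c(tau = (msb - msw) / n_i, sigma2 = msw)
}

# random small crossed design + matching spec, for oracle equivalence tests
random_crossed_instance <- function(seed) {
  set.seed(seed)
  n <- sample(80:300, 1)
  n_groups <- sample(1:3, 1)
  d <- data.frame(y = 0, x = rnorm(n), z = rnorm(n))
  random <- list()
  lp <- rnorm(n, 0, 0.5) + 0.4 * d$x
  for (k in seq_len(n_groups)) {
    gname <- paste0("g", k)
    m <- sample(c(5, 10, 25), 1)
    d[[gname]] <- factor(sample(seq_len(m), n, replace = TRUE))
    with_slope <- runif(1) < 0.5
    slopes <- if (with_slope) "x" else character()
    random[[k]] <- random_term(gname, TRUE, slopes,
                               correlated = runif(1) < 0.5)
    u <- rnorm(m, 0, 0.6)
    lp <- lp + u[as.integer(d[[gname]])]
    if (with_slope) {
      v <- rnorm(m, 0, 0.4)
      lp <- lp + v[as.integer(d[[gname]])] * d$x
    }
  }
  d$y <- lp + rnorm(n, 0, 0.7)
  spec <- model_spec("y", c("x", "z"), random,
                     method = sample(c("ML", "REML"), 1))
  list(spec = spec, frame = d)
}

# random positive-definite covariance of dimension q, on a given scale
random_cov <- function(q, scale = 0.5) {
  A <- matrix(rnorm(q * q, 0, scale), q, q)
  crossprod(A) + diag(1e-4, q)
}

# random oracle parameter point for a spec
random_params <- function(spec) {
  blocks <- otochron:::expand_random(spec)
  list(groups = lapply(blocks, function(b) random_cov(length(b$effects))),
       sigma2 = runif(1, 0.2, 2))
}
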