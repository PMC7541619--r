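# a minimal hand-made growth_fit, for operations that only read the
# variance-component interface
fake_fit <- function(groups, sigma2, beta = NULL, n_obs = 100, aicc = 0,
                     method = "ML", k = 2, fixed = "x") {
  structure(list(
    spec = model_spec("y", fixed, list(), method),
    beta = beta, varcomps = list(groups = groups, sigma2 = sigma2),
    n_obs = n_obs, n_params = k, aicc = aicc, converged = TRUE,
    singular = FALSE), class = "growth_fit")
}

int_group <- function(name, tau) {
  list(group = name, effects = "(Intercept)",
       cov = matrix(tau, dimnames = list("(Intercept)", "(Intercept)")),
       tau = c("(Intercept)" = tau), rho = matrix(1, 1, 1))
}

test_that("a spec without random terms degenerates to ordinary least squares", {
  set.seed(4)
  d <- data.frame(x = rnorm(40), z = rnorm(40))
  d$y <- 1 + 2 * d$x - 0.5 * d$z + rnorm(40, 0, 0.3)
  ft <- fit_growth(model_spec("y", c("x", "z"), list(), "REML"), d)
  ref <- stats::lm(y ~ x + z, d)
  expect_equal(ft$beta$estimate, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(ft$varcomps$sigma2, sum(residuals(ref)^2) / (40 - 3),
               tolerance = 1e-10)
  ft_ml <- fit_growth(model_spec("y", c("x", "z"), list(), "ML"), d)
  expect_equal(ft_ml$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(ft_ml$n_params, 4)  # 3 coefficients + residual variance
})

test_that("rank-deficient fixed designs are rejected by name", {
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  d$x2 <- d$x
  expect_error(fit_growth(model_spec("y", c("x", "x2"), list(), "ML"), d),
               "rank-deficient")
  expect_error(fit_growth(model_spec("y", "nope", list(), "ML"), d),
               "nope")
})

test_that("balanced one-way REML reproduces the ANOVA closed form", {
  d <- oneway_data(m = 30, n_i = 6, tau = 1.5, sigma2 = 0.8, seed = 2)
  cf <- oneway_anova_components(d)
  expect_gt(cf["tau"], 0)  # interior optimum, closed form applies
  ft <- fit_growth(model_spec("y", character(), list(random_term("g")),
                              "REML"), d)
  expect_equal(ft$varcomps$groups[[1]]$tau[["(Intercept)"]],
               unname(cf["tau"]), tolerance = 1e-5)
  expect_equal(ft$varcomps$sigma2, unname(cf["sigma2"]), tolerance = 1e-5)
})

test_that("AICc matches its closed form, limit, and guard", {
  expect_equal(aicc(-100, 5, 100), 210 + 2 * 5 * 6 / 94, tolerance = 1e-12)
  expect_equal(aicc(-100, 5, 1e9), 210, tolerance = 1e-6)
  expect_equal(aicc(0, 0, 10), 0)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("ICC is the intercept-variance share", {
  f <- fake_fit(list(int_group("g", 1)), sigma2 = 3)
  expect_equal(icc(f, "g"), 0.25)
  f0 <- fake_fit(list(int_group("g", 0)), sigma2 = 3)
  expect_equal(icc(f0, "g"), 0)
  expect_error(icc(f, "h"), "no random intercept")
})

test_that("single-factor ICC is recovered at the published-scale ratio", {
  target <- 0.134
  est <- sapply(1:10, function(s) {
    d <- oneway_data(m = 1000, n_i = 5, tau = target, sigma2 = 1 - target,
                     seed = 100 + s)
    ft <- fit_growth(model_spec("y", character(), list(random_term("g")),
                                "REML"), d)
    icc(ft, "g")
  })
  expect_lt(abs(mean(est) - target), 0.03)
  expect_true(all(abs(est - target) < 0.09))  # 3 x seed-level spread
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  d <- data.frame(x = as.numeric(scale(1:12)), g = factor(rep(1:4, 3)))
  d$y <- d$x
  f <- fake_fit(list(int_group("g", 1)), sigma2 = 2,
                beta = data.frame(term = c("(Intercept)", "x"),
                                  estimate = c(0, 1)))
  r2 <- r2_growth(f, d)
  expect_equal(unname(r2["marginal"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(r2["conditional"]), 0.5, tolerance = 1e-12)

  # no random terms, near-perfect fit: both tend to 1
  d2 <- data.frame(x = rnorm(30))
  d2$y <- 2 * d2$x + rnorm(30, 0, 1e-4)
  ft <- fit_growth(model_spec("y", "x", list(), "ML"), d2)
  r22 <- r2_growth(ft, d2)
  expect_gt(r22["marginal"], 0.999)
  expect_gt(r22["conditional"], 0.999)

  # intercept-only fixed part: marginal exactly zero
  d3 <- oneway_data(10, 4, tau = 1, sigma2 = 1, seed = 3)
  ft3 <- fit_growth(model_spec("y", character(), list(random_term("g")),
                               "REML"), d3)
  expect_equal(unname(r2_growth(ft3, d3)["marginal"]), 0)
  expect_lte(r2_growth(ft3, d3)["conditional"], 1)
})

test_that("BLUPs shrink group means by the one-way shrinkage factor", {
  d <- oneway_data(m = 25, n_i = 4, tau = 1, sigma2 = 1, seed = 5)
  ft <- fit_growth(model_spec("y", character(), list(random_term("g")),
                              "REML"), d)
  tau <- ft$varcomps$groups[[1]]$tau[["(Intercept)"]]
  s2 <- ft$varcomps$sigma2
  mu <- ft$beta$estimate[1]
  shrink <- tau / (tau + s2 / 4)
  bl <- blup_extract(ft, "g")
  gm <- tapply(d$y, d$g, mean)
  expect_equal(bl$blup, as.numeric(shrink * (gm[bl$level] - mu)),
               tolerance = 1e-6)
  expect_lt(abs(sum(bl$blup)), 1e-6 * stats::sd(d$y) * 25)  # balanced identity
})

test_that("zero between-group signal gives identically zero BLUPs", {
  d <- data.frame(g = factor(rep(1:6, each = 4)))
  d$y <- rep(c(-1.5, -0.5, 0.5, 1.5), 6)  # identical group means
  ft <- fit_growth(model_spec("y", character(), list(random_term("g")),
                              "REML"), d)
  expect_true(ft$singular)
  expect_true(all(abs(blup_extract(ft, "g")$blup) < 1e-8))
})

test_that("model ranking applies delta-AICc and the parsimony tie rule", {
  f1 <- fake_fit(list(), 1, aicc = 100, k = 4)
  f2 <- fake_fit(list(), 1, aicc = 105, k = 5)
  tab <- compare_fits(list(a = f1, b = f2))
  expect_equal(tab$model, c("a", "b"))
  expect_equal(tab$delta_aicc, c(0, 5))

  # within 2 units the simpler model wins despite higher AICc
  g1 <- fake_fit(list(), 1, aicc = 100, k = 8)
  g2 <- fake_fit(list(), 1, aicc = 101.5, k = 6)
  tab2 <- compare_fits(list(complex = g1, simple = g2))
  expect_equal(tab2$model[1], "simple")

  # REML fits with different fixed parts cannot be ranked
  h1 <- fake_fit(list(), 1, aicc = 10, method = "REML", fixed = "x")
  h2 <- fake_fit(list(), 1, aicc = 12, method = "REML", fixed = "z")
  expect_error(compare_fits(list(h1, h2)), "REML")
})

test_that("standardized refits are scale invariant with a centered intercept", {
  set.seed(6)
  d <- data.frame(x = rnorm(60, 10, 2), g = factor(rep(1:12, 5)))
  d$y <- 3 + 0.8 * d$x + rnorm(12)[as.integer(d$g)] + rnorm(60, 0, 0.5)
  sp <- model_spec("y", "x", list(random_term("g")), "ML")
  s1 <- standardized_refit(sp, d)
  d10 <- d; d10$x <- d10$x * 10
  s2 <- standardized_refit(sp, d10)
  i <- match("x", s1$beta$term)
  expect_equal(s1$beta$estimate[i], s2$beta$estimate[i], tolerance = 1e-6)
  expect_lt(abs(s1$beta$estimate[match("(Intercept)", s1$beta$term)]), 1e-6)
})

test_that("standardized coefficient order tracks the generating effect sizes", {
  hits <- sapply(1:10, function(s) {
    set.seed(200 + s)
    n <- 300
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 1.2 * d$x1 + 0.6 * d$x2 + 0.2 * d$x3 + rnorm(n, 0, 0.8)
    ft <- standardized_refit(model_spec("y", c("x1", "x2", "x3"), list(),
                                        "ML"), d)
    b <- abs(ft$beta$estimate[match(c("x1", "x2", "x3"), ft$beta$term)])
    all(diff(b) < 0)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("VIF scores match the auxiliary-regression formula", {
  n <- 50
  x1 <- as.numeric(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ x1))
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * as.numeric(scale(e, scale = TRUE))
  d <- data.frame(x1 = x1, x2 = as.numeric(x2))
  # empirical correlation is exactly 0.6 by construction
  expect_equal(cor(d$x1, d$x2), 0.6, tolerance = 1e-10)
  v <- vif_scores(d, c("x1", "x2"))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 1e-8)

  d$o <- as.numeric(scale(e))  # orthogonal to x1 by construction
  v2 <- vif_scores(d[c("x1", "o")], c("x1", "o"))
  expect_equal(unname(v2), c(1, 1), tolerance = 1e-8)

  d$dup <- d$x1
  v3 <- suppressWarnings(vif_scores(d, c("x1", "dup")))
  expect_true(all(is.infinite(v3)))
  expect_error(vif_scores(d, "x1"), "two terms")
})

test_that("REML objective is invariant to shifting a covariate", {
  set.seed(7)
  d <- data.frame(x = rnorm(80), g = factor(rep(1:16, 5)))
  d$y <- 0.5 * d$x + rnorm(16, 0, 0.7)[as.integer(d$g)] + rnorm(80, 0, 0.5)
  sp <- model_spec("y", "x", list(random_term("g")), "REML")
  f1 <- fit_growth(sp, d)
  d2 <- d; d2$x <- d2$x + 100
  f2 <- fit_growth(sp, d2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("fixed-effect recovery at the published age-slope scale", {
  cl <- simulate_climate(1964, 2005, seed = 2)
  est <- sapply(1:20, function(s) {
    truth <- reduced_truth(beta_age = -0.65, var_fish = 0.007,
                           sigma2 = 0.056, var_slope_fish = 0)
    rost <- simulate_population(500, 1980:2005, seed = s)
    tab <- simulate_increments(truth, rost, cl, seed = s + 500L)
    fr <- growth_transform(apply_filters(tab))
    sp <- model_spec("log_width", "log_age_c",
                     list(random_term("fish_id", TRUE, "log_age_c"),
                          random_term("year"), random_term("cohort")),
                     "REML")
    ft <- fit_growth(sp, fr)
    ft$beta$estimate[match("log_age_c", ft$beta$term)]
  })
  expect_lt(abs(mean(est) - (-0.65)), 0.02)
})
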