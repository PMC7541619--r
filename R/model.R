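#' Declare a linear mixed model for the growth frame
#'
#' A declarative model description: response, fixed-effect terms, and a list
#' of random terms created with [random_term()]. The model is fitted with
#' [fit_growth()] by maximum likelihood (`"ML"`, for fixed-effect
#' comparisons) or restricted maximum likelihood (`"REML"`, for
#' variance-component estimation and random-structure comparisons).
#'
#' @param response response column name.
#' @param fixed character vector of fixed terms, e.g.
#'   `c("log_age_c", "sst_win_c", "log_age_c:sst_win_c")`.
#' @param random list of [random_term()] objects; empty for a fixed-effects
#'   model.
#' @param method "ML" or "REML".
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(), random = list(),
                       method = c("REML", "ML")) {
  method <- match.arg(method)
  if (length(random)) {
    stopifnot(all(vapply(random, inherits, logical(1), "random_term")))
    pairs <- unlist(lapply(random, function(r)
      paste(r$group, c(if (r$intercept) "(Intercept)", r$slopes))))
    if (anyDuplicated(pairs))
      stop("duplicated random effect for a grouping factor: ",
           paste(unique(pairs[duplicated(pairs)]), collapse = ", "))
  }
  structure(list(response = response, fixed = fixed, random = random,
                 method = method), class = "model_spec")
}

#' Random-effect term of a model specification
#'
#' @param group grouping-factor column.
#' @param intercept include a random intercept?
#' @param slopes character vector of random-slope variables (may be empty).
#' @param correlated should intercept and slopes share a full covariance
#'   matrix (`TRUE`) or be independent (`FALSE`)?
#' @return An object of class `random_term`.
#' @export
random_term <- function(group, intercept = TRUE, slopes = character(),
                        correlated = TRUE) {
  if (!intercept && length(slopes) == 0)
    stop("a random term needs an intercept or at least one slope")
  structure(list(group = group, intercept = intercept, slopes = slopes,
                 correlated = correlated), class = "random_term")
}

## Expand a spec's random terms into elementary (group, effects) blocks that
## map 1:1 onto lme4 formula terms and onto the oracle's covariance blocks.
expand_random <- function(spec) {
  out <- list()
  for (rt in spec$random) {
    if (rt$correlated || (rt$intercept && length(rt$slopes) == 0) ||
        (!rt$intercept && length(rt$slopes) == 1)) {
      eff <- c(if (rt$intercept) "(Intercept)", rt$slopes)
      out[[length(out) + 1L]] <- list(group = rt$group, effects = eff)
    } else {
      if (rt$intercept)
        out[[length(out) + 1L]] <- list(group = rt$group,
                                        effects = "(Intercept)")
      for (s in rt$slopes)
        out[[length(out) + 1L]] <- list(group = rt$group, effects = s)
    }
  }
  out
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  for (bl in expand_random(spec)) {
    eff <- bl$effects
    inner <- if ("(Intercept)" %in% eff)
      paste(c("1", setdiff(eff, "(Intercept)")), collapse = " + ")
    else paste(c("0", eff), collapse = " + ")
    rhs <- paste0(rhs, " + (", inner, " | ", bl$group, ")")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

fixed_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit a growth model
#'
#' Fits the Gaussian linear mixed model described by `spec` on the modelling
#' frame. Models with random terms are estimated with `lme4::lmer`
#' (crossed random effects, profiled (RE)ML over relative-covariance Cholesky
#' factors); a spec with no random terms degenerates to ordinary least
#' squares. Boundary fits (a variance estimated at zero) are reported with a
#' `singular` flag rather than an error.
#'
#' @param spec a [model_spec()].
#' @param frame the modelling frame (a `growth_table` or any data.frame).
#' @param control optional `lme4::lmerControl`; the default skips the
#'   finite-difference derivative check for speed.
#' @return An object of class `growth_fit`: fixed-effect table with Wald 95%
#'   CIs, variance components per grouping factor (tau, rho, sigma2),
#'   log-likelihood of the fitting method, AICc, parameter count, BLUPs, and
#'   convergence flags.
#' @export
fit_growth <- function(spec, frame, control = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(frame) == 0) stop("empty modelling frame")
  used <- unique(c(spec$response,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   unlist(lapply(spec$random, function(r) c(r$group, r$slopes)))))
  missing_cols <- setdiff(used, names(frame))
  if (length(missing_cols))
    stop("columns not in frame: ", paste(missing_cols, collapse = ", "))

  X <- stats::model.matrix(fixed_formula(spec), frame)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effect design: ", paste(colnames(X), collapse = ", "))
  p <- ncol(X)
  n <- nrow(frame)
  reml <- spec$method == "REML"

  if (length(spec$random) == 0) {
    fm <- stats::lm(fixed_formula(spec), data = frame)
    rss <- sum(stats::residuals(fm)^2)
    sigma2 <- if (reml) rss / (n - p) else rss / n
    ll <- if (reml) lm_reml_loglik(X, stats::model.response(stats::model.frame(fm)), rss)
          else as.numeric(stats::logLik(fm))
    k <- p + 1L
    sm <- summary(fm)$coefficients
    beta <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                       row.names = NULL)
    obj <- fm
    varcomps <- list(groups = list(), sigma2 = sigma2)
    blups <- list()
    converged <- TRUE; singular <- FALSE
  } else {
    for (bl in expand_random(spec))
      frame[[bl$group]] <- factor(frame[[bl$group]])
    ctrl <- if (is.null(control))
      lme4::lmerControl(calc.derivs = FALSE,
                        check.conv.singular = "ignore",
                        check.nobs.vs.nlev = "ignore",
                        check.nobs.vs.nRE = "ignore") else control
    msgs <- character()
    obj <- withCallingHandlers(
      lme4::lmer(spec_formula(spec), data = frame, REML = reml, control = ctrl),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      })
    singular <- lme4::isSingular(obj, tol = 1e-5)
    opt_ok <- is.null(obj@optinfo$conv$opt) || obj@optinfo$conv$opt == 0
    converged <- opt_ok && !any(grepl("failed to converge", msgs))
    ll <- as.numeric(stats::logLik(obj))
    vc <- lme4::VarCorr(obj)
    groups <- extract_varcomps(vc, expand_random(spec))
    sigma2 <- stats::sigma(obj)^2
    varcomps <- list(groups = groups, sigma2 = sigma2)
    nth <- length(lme4::getME(obj, "theta"))
    k <- p + nth + 1L
    fe <- lme4::fixef(obj)
    ## boundary (singular) fits can make the curvature-based vcov warn;
    ## the singular flag already records the state
    se <- suppressWarnings(sqrt(Matrix::diag(stats::vcov(obj))))
    beta <- data.frame(term = names(fe), estimate = as.numeric(fe),
                       se = as.numeric(se), row.names = NULL)
    blups <- lme4::ranef(obj, condVar = FALSE)
  }
  z <- stats::qnorm(0.975)
  beta$ci_lo <- beta$estimate - z * beta$se
  beta$ci_hi <- beta$estimate + z * beta$se

  structure(list(
    spec = spec, formula = spec_formula(spec), object = obj, beta = beta,
    varcomps = varcomps, loglik = ll, n_obs = n, n_params = k,
    aicc = aicc(ll, k, n), blups = blups, converged = converged,
    singular = singular, centering = attr(frame, "centering")
  ), class = "growth_fit")
}

## REML log-likelihood of an ordinary linear model (V = sigma2 I profiled out)
lm_reml_loglik <- function(X, y, rss) {
  n <- nrow(X); p <- ncol(X)
  s2 <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + (n - p) +
                       determinant(crossprod(X), logarithm = TRUE)$modulus))
}

## map lme4 VarCorr entries back to the spec's expanded blocks
extract_varcomps <- function(vc, blocks) {
  ents <- lapply(vc, function(m) {
    list(cov = matrix(as.numeric(m), nrow(m), dimnames = dimnames(m)),
         eff = rownames(m))
  })
  base <- sub("\\.[0-9]+$", "", names(vc))
  out <- list()
  for (bl in blocks) {
    hit <- which(base == bl$group &
                   vapply(ents, function(e) setequal(e$eff, bl$effects),
                          logical(1)))
    if (length(hit) != 1)
      stop("cannot match variance components for group ", bl$group)
    cv <- ents[[hit]]$cov[bl$effects, bl$effects, drop = FALSE]
    sd <- sqrt(diag(cv))
    ## correlations undefined at a variance boundary: report NA, not noise
    den <- outer(sd, sd)
    rho <- ifelse(den > 0, cv / den, NA_real_)
    diag(rho) <- 1
    key <- paste0(bl$group, if (length(bl$effects) == 1 &&
                                  bl$effects != "(Intercept)")
      paste0(".", bl$effects) else "")
    out[[key]] <- list(group = bl$group, effects = bl$effects, cov = cv,
                       tau = stats::setNames(diag(cv), bl$effects), rho = rho)
    ents[hit] <- NULL; base <- base[-hit]
  }
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of estimated parameters k (fixed effects +
#'   variance/covariance parameters + residual variance).
#' @param n_obs number of observations.
#' @return The AICc value.
#' @export
aicc <- function(loglik, n_params, n_obs) {
  k <- n_params
  if (n_obs <= k + 1) stop("AICc undefined: n_obs must exceed n_params + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Intraclass correlation coefficient of an intercept-only mixed model
#'
#' The share of total variance attributed to one grouping factor:
#' tau00_g / (sum of all random-intercept variances + sigma2).
#'
#' @param fit a `growth_fit` containing a random intercept for `grouping`.
#' @param grouping grouping-factor name.
#' @return The ICC, in \[0, 1\].
#' @export
icc <- function(fit, grouping) {
  taus <- intercept_variances(fit)
  if (!grouping %in% names(taus))
    stop("no random intercept for grouping: ", grouping)
  as.numeric(taus[grouping] / (sum(taus) + fit$varcomps$sigma2))
}

intercept_variances <- function(fit) {
  out <- numeric()
  for (g in fit$varcomps$groups)
    if ("(Intercept)" %in% g$effects)
      out[g$group] <- sum(out[g$group], g$tau[["(Intercept)"]], na.rm = TRUE)
  out
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition R2 for Gaussian mixed models: the marginal value is
#' the share of variance explained by fixed effects, the conditional value
#' adds the random effects. Random-slope terms contribute their mean
#' observation-level variance (the row-wise quadratic form of the term's
#' covariance matrix).
#'
#' @param fit a converged `growth_fit`.
#' @param frame the frame used to fit (defaults to the model frame).
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
r2_growth <- function(fit, frame = NULL) {
  if (is.null(frame)) frame <- stats::model.frame(fit$object)
  X <- stats::model.matrix(fixed_formula(fit$spec), frame)
  var_fixed <- stats::var(as.vector(X %*% fit$beta$estimate))
  var_rand <- 0
  for (g in fit$varcomps$groups) {
    Zg <- effect_design(g$effects, frame)
    var_rand <- var_rand + mean(rowSums((Zg %*% g$cov) * Zg))
  }
  tot <- var_fixed + var_rand + fit$varcomps$sigma2
  c(marginal = var_fixed / tot, conditional = (var_fixed + var_rand) / tot)
}

## n x q design of a random block's effect columns
effect_design <- function(effects, frame) {
  cols <- lapply(effects, function(e) {
    if (e == "(Intercept)") rep(1, nrow(frame)) else frame[[e]]
  })
  matrix(unlist(cols), nrow(frame), length(effects),
         dimnames = list(NULL, effects))
}

#' Extract BLUPs of a random effect
#'
#' Conditional modes of the random effects at the estimated variance
#' components, with conditional standard errors; shrunk toward zero.
#'
#' @param fit a `growth_fit`.
#' @param grouping grouping-factor name.
#' @param effect effect name (`"(Intercept)"` or a slope variable).
#' @param se compute conditional standard errors (default `TRUE`). Computing
#'   them is expensive for models in which a grouping factor carries several
#'   independent random terms; pass `FALSE` when only the point predictions
#'   are needed.
#' @return data.frame with `level`, `blup`, and `se` (NA when `se = FALSE`).
#' @export
blup_extract <- function(fit, grouping, effect = "(Intercept)", se = TRUE) {
  if (length(fit$varcomps$groups) == 0) stop("fit has no random effects")
  blups <- if (se) lme4::ranef(fit$object, condVar = TRUE) else fit$blups
  base <- sub("\\.[0-9]+$", "", names(blups))
  for (i in seq_along(blups)) {
    re <- blups[[i]]
    if (base[i] == grouping && effect %in% colnames(re)) {
      j <- match(effect, colnames(re))
      if (!se)
        return(data.frame(level = rownames(re), blup = re[[j]],
                          se = NA_real_, row.names = NULL))
      pv <- attr(re, "postVar")
      if (is.list(pv)) {
        ## several terms share this factor: one array per term block
        se <- NULL
        for (block in pv) {
          eff_bl <- dimnames(block)[[1]]
          if (is.null(eff_bl)) next
          if (effect %in% eff_bl) {
            jj <- match(effect, eff_bl)
            se <- sqrt(block[jj, jj, ])
          }
        }
        if (is.null(se)) {
          ## block dimnames absent: locate by column offset
          sizes <- vapply(pv, function(b) dim(b)[1], integer(1))
          ends <- cumsum(sizes)
          bi <- which(j <= ends)[1]
          jj <- j - c(0, ends)[bi]
          se <- sqrt(pv[[bi]][jj, jj, ])
        }
      } else {
        se <- sqrt(pv[j, j, ])
      }
      return(data.frame(level = rownames(re), blup = re[[j]], se = se,
                        row.names = NULL))
    }
  }
  stop("effect ", effect, " for grouping ", grouping, " not in fit")
}

#' Rank fitted models by AICc
#'
#' Sorts models by AICc with Delta-AICc against the best; among models within
#' `tie` units of the minimum, the one with fewest parameters is preferred
#' (parsimony tie-break). REML fits may only be compared when their fixed
#' structures are identical.
#'
#' @param fits named list of `growth_fit` objects on the same observations.
#' @param tie AICc band treated as a tie (default 2).
#' @return data.frame sorted by rank: model, method, k, aicc, delta_aicc,
#'   converged.
#' @export
compare_fits <- function(fits, tie = 2) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits))) names(fits) <- paste0("m", seq_along(fits))
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1)
    stop("models fitted on different observation sets")
  methods <- vapply(fits, function(f) f$spec$method, character(1))
  if (any(methods == "REML")) {
    ff <- vapply(fits, function(f)
      paste(deparse(fixed_formula(f$spec)), collapse = ""), character(1))
    if (length(unique(ff[methods == "REML"])) > 1 || any(methods == "ML"))
      stop("REML fits are only comparable with identical fixed structures")
  }
  tab <- data.frame(
    model = names(fits), method = methods,
    k = vapply(fits, `[[`, numeric(1), "n_params"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  ok <- tab$converged
  best_aicc <- min(tab$aicc[ok])
  tab$delta_aicc <- tab$aicc - best_aicc
  near <- ok & tab$delta_aicc <= tie
  pref <- which(near)[order(tab$k[near], tab$aicc[near])][1]
  ord <- c(pref, setdiff(order(!ok, tab$aicc), pref))
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Refit with standardized response and predictors
#'
#' Z-scores the response and every continuous fixed-effect variable, then
#' refits, so that coefficient magnitudes are comparable across predictors.
#'
#' @param spec a [model_spec()].
#' @param frame the modelling frame.
#' @return A `growth_fit` on the standardized scale (with attribute
#'   `scaling`: the mean/sd used per column).
#' @export
standardized_refit <- function(spec, frame) {
  vars <- unique(c(spec$response,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE))))
  vars <- vars[vars %in% names(frame)]
  scaling <- list()
  for (v in vars) {
    x <- frame[[v]]
    if (is.numeric(x) && stats::sd(x) > 0) {
      scaling[[v]] <- c(mean = mean(x), sd = stats::sd(x))
      frame[[v]] <- (x - mean(x)) / stats::sd(x)
    }
  }
  out <- fit_growth(spec, frame)
  attr(out, "scaling") <- scaling
  out
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) from the auxiliary regression of predictor j on the
#' remaining predictors. Perfectly collinear predictors report `Inf`.
#'
#' @param frame data.frame holding the predictors.
#' @param terms character vector (>= 2) of predictor columns.
#' @return Named numeric vector of VIF scores (all >= 1).
#' @export
vif_scores <- function(frame, terms) {
  if (length(terms) < 2) stop("need at least two terms for VIF")
  X <- frame[terms]
  out <- stats::setNames(numeric(length(terms)), terms)
  for (j in seq_along(terms)) {
    fm <- stats::lm(stats::reformulate(terms[-j], terms[j]), data = X)
    r2 <- summary(fm)$r.squared
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth model fit (", x$spec$method, ")\n", sep = "")
  cat("  formula: ", paste(deparse(x$formula), collapse = " "), "\n", sep = "")
  cat("  n =", x$n_obs, " k =", x$n_params,
      " logLik =", format(x$loglik, digits = 6),
      " AICc =", format(x$aicc, digits = 6), "\n")
  if (x$singular) cat("  note: singular fit (a variance at the boundary)\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  cat("Fixed effects:\n")
  print(x$beta, digits = 4)
  cat("Random effects:\n")
  for (g in x$varcomps$groups) {
    cat("  ", g$group, ": tau = ",
        paste(sprintf("%s %.4g", names(g$tau), g$tau), collapse = ", "),
        if (length(g$tau) > 1)
          paste0("; rho = ", format(g$rho[1, 2], digits = 3)), "\n", sep = "")
  }
  cat("  residual sigma2 =", format(x$varcomps$sigma2, digits = 4), "\n")
  invisible(x)
}
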