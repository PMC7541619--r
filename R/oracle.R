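#' Dense brute-force log-likelihood of a mixed model
#'
#' Evaluates the exact Gaussian (or REML-adjusted) log-likelihood of the
#' model described by `spec` at supplied variance parameters by forming the
#' full n x n marginal covariance V = ZGZ' + sigma2 I and using dense linear
#' algebra. This code path is completely independent of the fitting engine
#' and exists to verify its objective on small instances.
#'
#' @param spec a [model_spec()]; its `method` selects ML or REML.
#' @param frame the modelling frame (n <= 2000).
#' @param params list with `groups` (one covariance matrix per expanded
#'   random block, in the order of the spec's random terms), `sigma2`, and
#'   optionally `beta` (fixed effects; when `NULL` the GLS estimate at V is
#'   profiled in, as the fitting engine does).
#' @return The log-likelihood (REML log-likelihood when the spec's method is
#'   REML).
#' @export
loglik_oracle <- function(spec, frame, params) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(frame)
  if (n > 2000) stop("oracle restricted to n <= 2000 (dense n x n algebra)")
  if (params$sigma2 <= 0) stop("sigma2 must be > 0")
  X <- stats::model.matrix(fixed_formula(spec), frame)
  y <- frame[[spec$response]]
  p <- ncol(X)
  blocks <- expand_random(spec)
  if (length(blocks) != length(params$groups))
    stop("params$groups must supply one covariance per random block (",
         length(blocks), " needed)")
  V <- diag(params$sigma2, n)
  for (i in seq_along(blocks)) {
    bl <- blocks[[i]]
    G <- as.matrix(params$groups[[i]])
    q <- length(bl$effects)
    if (!all(dim(G) == q))
      stop("covariance for group ", bl$group, " must be ", q, " x ", q)
    Eg <- effect_design(bl$effects, frame)
    g <- factor(frame[[bl$group]])
    ## V += Z (I (x) G) Z' accumulated level by level
    for (lev in levels(g)) {
      idx <- which(g == lev)
      Zi <- Eg[idx, , drop = FALSE]
      V[idx, idx] <- V[idx, idx] + Zi %*% G %*% t(Zi)
    }
  }
  ch <- tryCatch(chol(V), error = function(e)
    stop("marginal covariance V is not positive definite"))
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  beta <- if (is.null(params$beta)) solve(XtViX, crossprod(X, Vi_y))
          else matrix(params$beta, ncol = 1)
  r <- y - as.vector(X %*% beta)
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- sum(r * Vi_r)
  if (spec$method == "REML") {
    logdetXtViX <- determinant(XtViX, logarithm = TRUE)$modulus
    as.numeric(-0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXtViX + quad))
  } else {
    -0.5 * (n * log(2 * pi) + logdetV + quad)
  }
}

#' Variance parameters of a fit, in oracle form
#'
#' @param fit a `growth_fit`.
#' @param profile_beta if `TRUE` (default) the oracle re-profiles the fixed
#'   effects by GLS; otherwise the fit's estimates are fixed.
#' @return A `params` list for [loglik_oracle()].
#' @export
fit_params <- function(fit, profile_beta = TRUE) {
  list(groups = lapply(fit$varcomps$groups, `[[`, "cov"),
       sigma2 = fit$varcomps$sigma2,
       beta = if (profile_beta) NULL else fit$beta$estimate)
}
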