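#' Within/among-individual decomposition of a covariate
#'
#' Within-group centering: replaces a time-varying covariate by (1) each
#' fish's lifetime mean over its retained records (the among-individual
#' component) and (2) the per-record deviation from that mean (the
#' within-individual component). The sum of the two reconstructs the original
#' covariate exactly, and each fish's within values average to zero. The
#' among component is additionally mean-centered across records into
#' `<name>_among_c` (constant recorded in the `centering` attribute).
#'
#' @param frame the modelling frame with the covariate attached.
#' @param covariate covariate column name (default `"sst_win"`).
#' @return The frame with `<name>_within`, `<name>_among`, `<name>_among_c`
#'   columns; attribute `single_record_fish` lists fish with only one record
#'   (their within value is 0 by construction).
#' @export
decompose_within_among <- function(frame, covariate = "sst_win") {
  if (!covariate %in% names(frame))
    stop("covariate not attached to the frame: ", covariate)
  x <- frame[[covariate]]
  if (anyNA(x)) stop("covariate has missing values")
  among_fish <- tapply(x, frame$fish_id, mean)
  among <- as.numeric(among_fish[as.character(frame$fish_id)])
  counts <- table(frame$fish_id)
  singles <- names(counts)[counts == 1]
  frame[[paste0(covariate, "_within")]] <- x - among
  frame[[paste0(covariate, "_among")]] <- among
  cc <- attr(frame, "centering")
  cc[paste0(covariate, "_among")] <- mean(among)
  frame[[paste0(covariate, "_among_c")]] <- among - mean(among)
  attr(frame, "centering") <- cc
  attr(frame, "single_record_fish") <- singles
  class(frame) <- unique(c("growth_table", class(frame)))
  frame
}

#' Compare centered-covariate model variants against a baseline
#'
#' Fits (a) the within + among variant (the within component also in
#' interaction with age; the among component as a main effect only) and
#' (b) the original covariate + among variant, and ranks them against the
#' baseline extrinsic model by ML-AICc.
#'
#' @param frame frame after [decompose_within_among()].
#' @param base_spec the baseline extrinsic [model_spec()] whose fixed part
#'   contains the original (centered) covariate terms.
#' @param covariate the undecomposed covariate name.
#' @param cov_terms character vector of the baseline's fixed terms built from
#'   the original covariate (these are replaced in variant (a)).
#' @param age_var centered log-age column.
#' @return list with `fits` (baseline, within_among, original_among) and
#'   `comparison` (from [compare_fits()]).
#' @export
fit_centered_models <- function(frame, base_spec, covariate = "sst_win",
                                cov_terms = c("sst_win_c", "log_age_c:sst_win_c"),
                                age_var = "log_age_c") {
  w <- paste0(covariate, "_within")
  a <- paste0(covariate, "_among_c")
  if (!w %in% names(frame)) stop("run decompose_within_among() first")
  if (stats::sd(frame[[w]]) == 0) {
    warning("within component is identically zero; dropping the within term")
    w <- NULL
  }
  base_fit <- fit_growth(base_spec, frame)
  fixed_wa <- c(setdiff(base_spec$fixed, cov_terms),
                w, if (!is.null(w)) paste0(age_var, ":", w), a)
  spec_wa <- model_spec(base_spec$response, fixed_wa, base_spec$random, "ML")
  fixed_oa <- c(base_spec$fixed, a)
  spec_oa <- model_spec(base_spec$response, fixed_oa, base_spec$random, "ML")
  try_fit <- function(sp, label) tryCatch(fit_growth(sp, frame),
    error = function(e) {
      warning("variant `", label, "` could not be fitted: ",
              conditionMessage(e))
      NULL
    })
  fits <- list(baseline = base_fit,
               within_among = try_fit(spec_wa, "within_among"),
               original_among = try_fit(spec_oa, "original_among"))
  ok <- !vapply(fits, is.null, logical(1))
  list(fits = fits, comparison = compare_fits(fits[ok]))
}

#' Individual thermal reaction norms via random within-individual slopes
#'
#' Extends a model containing the within-individual temperature component by
#' a fish-specific random slope on that component (by default independent of
#' the fish random intercept), fits both models, and summarises the
#' individual reaction norms: per-fish slope BLUP deviations and total slopes
#' (population slope + deviation).
#'
#' @param frame frame after [decompose_within_among()].
#' @param spec [model_spec()] whose fixed part contains the within term.
#' @param within name of the within-component column.
#' @param fish_var grouping column for fish (default `"fish_id"`).
#' @param correlated should the random slope correlate with the fish random
#'   intercept (default `FALSE`)?
#' @return list with `fit` (random-slope model), `fit_null` (without the
#'   random slope), `comparison`, and `summary`: a `plasticity_summary`
#'   data.frame (fish_id, cohort, slope_blup, slope_se, slope_total) with the
#'   estimated slope variance as attribute `slope_variance`.
#' @export
fit_random_slopes <- function(frame, spec, within = "sst_win_within",
                              fish_var = "fish_id", correlated = FALSE) {
  if (!within %in% names(frame)) stop("within component missing: ", within)
  random_null <- spec$random
  fish_i <- which(vapply(random_null, `[[`, character(1), "group") == fish_var)
  if (length(fish_i) == 0)
    stop("spec has no random term for ", fish_var)
  random_slope <- random_null
  if (correlated) {
    rt <- random_slope[[fish_i[1]]]
    random_slope[[fish_i[1]]] <- random_term(rt$group, rt$intercept,
                                             c(rt$slopes, within),
                                             correlated = TRUE)
  } else {
    ## independent thermal-slope block alongside the existing fish term
    random_slope[[length(random_slope) + 1L]] <-
      random_term(fish_var, intercept = FALSE, slopes = within)
  }
  spec_slope <- model_spec(spec$response, spec$fixed, random_slope,
                           spec$method)
  spec_null <- model_spec(spec$response, spec$fixed, random_null, spec$method)
  fit_null <- fit_growth(spec_null, frame)
  fit_slope <- fit_growth(spec_slope, frame)
  comp <- compare_fits(list(no_random_slope = fit_null,
                            random_slope = fit_slope))
  summary <- plasticity_summary(fit_slope, frame, within, fish_var)
  list(fit = fit_slope, fit_null = fit_null, comparison = comp,
       summary = summary)
}

#' Summarise individual plasticity from a random-slope fit
#'
#' @param fit a `growth_fit` with a random slope of `within` for `fish_var`.
#' @param frame the fitted frame (for the fish-to-cohort lookup).
#' @param within,fish_var as in [fit_random_slopes()].
#' @param se also compute per-fish conditional standard errors (slow for
#'   large fish numbers; the cohort-variance analysis needs only the point
#'   predictions).
#' @return A `plasticity_summary` data.frame.
#' @export
plasticity_summary <- function(fit, frame, within = "sst_win_within",
                               fish_var = "fish_id", se = FALSE) {
  bl <- blup_extract(fit, fish_var, within, se = se)
  pop <- fit$beta$estimate[match(within, fit$beta$term)]
  coh <- tapply(frame$cohort, as.character(frame[[fish_var]]), `[`, 1)
  out <- data.frame(fish_id = bl$level,
                    cohort = as.numeric(coh[bl$level]),
                    slope_blup = bl$blup, slope_se = bl$se,
                    slope_total = pop + bl$blup, row.names = NULL)
  sv <- NA_real_
  for (g in fit$varcomps$groups)
    if (g$group == fish_var && within %in% g$effects)
      sv <- g$tau[[within]]
  attr(out, "slope_variance") <- sv
  attr(out, "singular") <- fit$singular
  class(out) <- c("plasticity_summary", "data.frame")
  out
}

#' Percent growth change over an environmental range
#'
#' Back-transforms log-scale coefficients to the percent change in increment
#' width across an environmental range:
#' `100 * (exp((beta_main + beta_age_interaction * centered_log_age) *
#' (high - low)) - 1)`.
#'
#' @param beta_main main-effect coefficient (per covariate unit, log scale).
#' @param beta_age_interaction age-interaction coefficient (0 if absent).
#' @param centered_log_age centered log-age value(s) at which to predict.
#' @param env_range `c(low, high)` covariate range.
#' @return Percent change (vectorized over `centered_log_age`).
#' @export
percent_change <- function(beta_main, beta_age_interaction = 0,
                           centered_log_age = 0, env_range) {
  span <- env_range[2] - env_range[1]
  100 * (exp((beta_main + beta_age_interaction * centered_log_age) * span) - 1)
}

#' Age-specific percent-change table for a fitted effect
#'
#' @param fit a `growth_fit`.
#' @param term main-effect term name.
#' @param interaction_term age-interaction term name (or `NULL`).
#' @param env_range `c(low, high)` covariate range.
#' @param ages integer ages to tabulate (default 2:10).
#' @param c_age log-age centering constant; defaults to the fit's stored
#'   constant.
#' @return data.frame with `age` and `pct_change`.
#' @export
percent_change_table <- function(fit, term, interaction_term = NULL,
                                 env_range, ages = 2:10, c_age = NULL) {
  if (is.null(c_age)) {
    cc <- fit$centering
    if (is.null(cc) || !"log_age" %in% names(cc))
      stop("no stored log-age centering constant; supply c_age")
    c_age <- cc[["log_age"]]
  }
  bm <- fit$beta$estimate[match(term, fit$beta$term)]
  if (is.na(bm)) stop("term not in fit: ", term)
  bi <- 0
  if (!is.null(interaction_term)) {
    bi <- fit$beta$estimate[match(interaction_term, fit$beta$term)]
    if (is.na(bi)) stop("interaction term not in fit: ", interaction_term)
  }
  data.frame(age = ages,
             pct_change = percent_change(bm, bi, log(ages) - c_age, env_range))
}

#' Cohort-level analysis of plasticity variance
#'
#' Computes the per-cohort sample variance of the individual thermal-slope
#' BLUPs (cohorts represented by more than `min_fish` fish only) and its
#' Pearson correlation with cohort-mean environmental conditions.
#'
#' @param summary a `plasticity_summary`.
#' @param env_by_cohort data.frame with a `cohort` column and one column per
#'   environmental variable (cohort means).
#' @param min_fish inclusion threshold: cohorts with more than this number of
#'   fish are kept (default 5).
#' @param use_total correlate using total slopes instead of BLUP deviations.
#' @return list with `cohort_variance` (cohort, n_fish, variance),
#'   `correlations` (variable, r, df, p), `n_excluded`.
#' @export
cohort_variance_analysis <- function(summary, env_by_cohort, min_fish = 5L,
                                     use_total = FALSE) {
  sl <- if (use_total) summary$slope_total else summary$slope_blup
  n_by <- table(summary$cohort)
  keep <- names(n_by)[n_by > min_fish]
  n_excluded <- sum(!summary$cohort %in% as.numeric(keep))
  if (length(keep) < 3)
    stop("fewer than 3 cohorts with more than ", min_fish, " fish")
  cv <- data.frame(
    cohort = as.numeric(keep),
    n_fish = as.integer(n_by[keep]),
    variance = vapply(keep, function(k)
      stats::var(sl[summary$cohort == as.numeric(k)]), numeric(1)),
    row.names = NULL)
  env_vars <- setdiff(names(env_by_cohort), "cohort")
  m <- match(cv$cohort, env_by_cohort$cohort)
  if (anyNA(m)) stop("env_by_cohort missing cohorts: ",
                     paste(cv$cohort[is.na(m)], collapse = ", "))
  cors <- do.call(rbind, lapply(env_vars, function(v) {
    ct <- stats::cor.test(cv$variance, env_by_cohort[[v]][m])
    data.frame(variable = v, r = unname(ct$estimate),
               df = unname(ct$parameter), p = ct$p.value)
  }))
  list(cohort_variance = cv, correlations = cors, n_excluded = n_excluded)
}

#' Cohort-mean environmental conditions
#'
#' Mean of each environmental column over the records of every cohort — the
#' average conditions experienced by the cohort's fish over their retained
#' growth years.
#'
#' @param frame the modelling frame.
#' @param vars environmental columns to average.
#' @return data.frame with `cohort` and one mean column per variable.
#' @export
cohort_env_means <- function(frame, vars) {
  out <- data.frame(cohort = sort(unique(frame$cohort)))
  for (v in vars) {
    if (!v %in% names(frame)) stop("no such column: ", v)
    m <- tapply(frame[[v]], frame$cohort, mean)
    out[[v]] <- as.numeric(m[as.character(out$cohort)])
  }
  out
}
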