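#' Default pipeline configuration
#'
#' Builds a validated configuration list for [run_pipeline()], either from a
#' YAML file or from arguments. Exactly one of a `data` block (paths to
#' increments/climate/abundance/hr CSVs) or a `simulation` block (arguments
#' for the synthetic-data generator) must be present.
#'
#' @param path optional YAML file; entries override the defaults.
#' @param ... named overrides applied after the file.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    data = NULL,
    simulation = list(n_fish = 300L, catch_years = 1960:2010,
                      truth = list(), seed = 20141007L),
    filter = list(max_age = 10L),
    window = list(max_back = 23L, interaction = "both"),
    randomization = list(enabled = FALSE, n_rand = 199L, unit = "fish"),
    extrinsic = list(candidates = c("n_index", "hr")),
    plasticity = list(correlated = FALSE, min_fish = 5L),
    chronology = list(min_obs = 10L),
    random_structure = list(select = FALSE),
    seed = 1L,
    out_dir = NULL)
  given <- character()
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, y)
    given <- c(given, names(y))
  }
  dots <- list(...)
  if (length(dots)) {
    cfg <- utils::modifyList(cfg, dots)
    given <- c(given, names(dots))
  }
  ## a configured data block replaces the default simulation block
  if ("data" %in% given && !"simulation" %in% given) cfg["simulation"] <- list(NULL)
  has_data <- !is.null(cfg$data)
  has_sim <- !is.null(cfg$simulation)
  if (has_data == has_sim)
    stop("exactly one of `data` and `simulation` must be configured")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the four-step growth-analysis protocol end to end
#'
#' Executes, on real or simulated inputs: data preparation (filtering,
#' transformation); optional REML-AICc selection of the random structure;
#' the intrinsic baseline fit; the sliding-window climate scan (with optional
#' randomization test); extrinsic covariate selection (abundance index and
#' harvest rate, each with and without the age interaction, by ML-AICc);
#' within/among decomposition of the selected climate signal and the
#' centered-model comparison; the random-slope plasticity model and cohort
#' variance analysis; the final REML refit and standardized refit; and the
#' year/cohort BLUP chronologies. Artifacts are written to `out_dir` when
#' configured.
#'
#' @param config a [pipeline_config()].
#' @return A result bundle (list) with every stage's output.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
  }

  ## ---- inputs -------------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$data)) {
      d <- config$data
      read_inputs(d$increments, d$climate, d$abundance, d$hr)
    } else {
      s <- config$simulation
      truth <- do.call(sim_truth, s$truth)
      first_year <- min(s$catch_years) - 16L
      climate <- simulate_climate(first_year, max(s$catch_years),
                                  seed = s$seed + 1L)
      roster <- simulate_population(s$n_fish, s$catch_years, seed = s$seed + 2L)
      stock <- simulate_stock(first_year:max(s$catch_years), seed = s$seed + 3L)
      tab <- simulate_increments(truth, roster, climate, stock,
                                 seed = s$seed)
      list(raw = tab, climate = climate, stock = stock, truth = truth)
    }
  })
  note("inputs: ", nrow(inputs$raw), " raw rows")

  ## ---- prep ---------------------------------------------------------------
  frame <- stage("prep", {
    f <- apply_filters(inputs$raw, config$filter$max_age)
    f <- growth_transform(f)
    f
  })
  note("prep: ", nrow(frame), " rows retained")

  ## ---- random structure / intrinsic baseline ------------------------------
  intrinsic_random <- list(random_term("fish_id", TRUE, "log_age_c"),
                           random_term("year", TRUE, "log_age_c"),
                           random_term("cohort", TRUE, "log_age_c"))
  random_sel <- NULL
  if (isTRUE(config$random_structure$select)) {
    random_sel <- stage("random_structure", {
      cands <- random_structure_candidates()
      fits <- lapply(cands, function(rs)
        fit_growth(model_spec("log_width", "log_age_c", rs, "REML"), frame))
      names(fits) <- names(cands)
      cmp <- compare_fits(fits)
      list(comparison = cmp, selected = cmp$model[1],
           random = cands[[cmp$model[1]]])
    })
    intrinsic_random <- random_sel$random
    note("random structure selected: ", random_sel$selected)
  }
  base_spec <- model_spec("log_width", "log_age_c", intrinsic_random, "ML")
  intrinsic_fit <- stage("intrinsic", fit_growth(base_spec, frame))
  note("intrinsic AICc: ", format(intrinsic_fit$aicc))

  ## ICCs from the intercept-only random structure (the fixed age effect is
  ## retained: age = year - cohort, so without it the crossed year and
  ## cohort intercepts would jointly absorb the age trend)
  iccs <- stage("icc", {
    f0 <- fit_growth(model_spec("log_width", "log_age_c",
                                list(random_term("fish_id"),
                                     random_term("year"),
                                     random_term("cohort")), "REML"), frame)
    c(fish_id = icc(f0, "fish_id"), year = icc(f0, "year"),
      cohort = icc(f0, "cohort"))
  })

  ## ---- window scan --------------------------------------------------------
  scan <- stage("window_scan",
                scan_windows(frame, inputs$climate, base_spec,
                             config$window$max_back,
                             config$window$interaction))
  note("best window: back ", scan$best$open, "-", scan$best$close,
       " interaction=", scan$best$interaction,
       " dAICc=", format(scan$best$delta_aicc))
  rand <- NULL
  if (isTRUE(config$randomization$enabled)) {
    rand <- stage("randomization",
                  randomization_test(frame, inputs$climate, base_spec,
                                     config$randomization$n_rand,
                                     seed = config$seed,
                                     max_back = config$window$max_back,
                                     interaction = config$window$interaction,
                                     unit = config$randomization$unit))
    note("randomization percentile: ", format(rand$percentile))
  }

  ## attach the selected window covariate (centered) and stock covariates
  frame <- stage("covariates", {
    f <- attach_covariates(frame, inputs$climate,
                           c(scan$best$open, scan$best$close),
                           stock = inputs$stock)
    growth_transform(f, center = "sst_win")
  })

  ## ---- extrinsic selection ------------------------------------------------
  climate_terms <- c("sst_win_c",
                     if (isTRUE(scan$best$interaction)) "log_age_c:sst_win_c")
  extrinsic <- stage("extrinsic", {
    keep_if_better <- function(fixed, cand_terms) {
      f0 <- fit_growth(model_spec("log_width", fixed, intrinsic_random, "ML"),
                       frame)
      fits <- list(without = f0)
      for (nm in names(cand_terms))
        fits[[nm]] <- fit_growth(
          model_spec("log_width", c(fixed, cand_terms[[nm]]),
                     intrinsic_random, "ML"), frame)
      cmp <- compare_fits(fits)
      sel <- cmp$model[1]
      list(fixed = if (sel == "without") fixed
           else c(fixed, cand_terms[[sel]]), comparison = cmp)
    }
    fixed <- c("log_age_c", climate_terms)
    comps <- list()
    for (v in config$extrinsic$candidates) {
      if (!v %in% names(frame)) next
      step <- keep_if_better(fixed, list(
        main = v, with_age = c(v, paste0("log_age_c:", v))))
      fixed <- step$fixed
      comps[[v]] <- step$comparison
    }
    list(fixed = fixed, comparisons = comps)
  })
  extrinsic_spec <- model_spec("log_width", extrinsic$fixed,
                               intrinsic_random, "ML")
  extrinsic_fit <- stage("extrinsic_fit", fit_growth(extrinsic_spec, frame))
  note("extrinsic fixed terms: ", paste(extrinsic$fixed, collapse = ", "))

  ## ---- centering decomposition --------------------------------------------
  frame <- stage("decompose", decompose_within_among(frame, "sst_win"))
  centered <- stage("centered_models",
                    fit_centered_models(frame, extrinsic_spec))
  wa_spec <- centered$fits$within_among$spec

  ## ---- random-slope plasticity --------------------------------------------
  plast <- stage("plasticity",
                 fit_random_slopes(frame, wa_spec,
                                   correlated = config$plasticity$correlated))
  env_means <- stage("cohort_env", {
    vars <- c("sst_win", intersect(c("n_index", "hr"), names(frame)))
    cohort_env_means(frame, vars)
  })
  cohort_var <- stage("cohort_variance", tryCatch(
    cohort_variance_analysis(plast$summary, env_means,
                             config$plasticity$min_fish),
    error = function(e) {
      note("cohort variance analysis skipped: ", conditionMessage(e))
      NULL
    }))

  ## ---- final refits -------------------------------------------------------
  final_spec <- model_spec(wa_spec$response, wa_spec$fixed,
                           plast$fit$spec$random, "REML")
  final_fit <- stage("final_reml", fit_growth(final_spec, frame))
  std_fit <- stage("standardized", standardized_refit(
    model_spec(wa_spec$response, wa_spec$fixed, plast$fit$spec$random, "ML"),
    frame))
  r2 <- r2_growth(final_fit, frame)
  note("final model R2: marginal ", format(r2[["marginal"]], digits = 3),
       ", conditional ", format(r2[["conditional"]], digits = 3))

  ## ---- chronology (from the intrinsic fit, no year/cohort age slopes) -----
  chron_spec <- model_spec("log_width", "log_age_c",
                           list(random_term("fish_id", TRUE, "log_age_c"),
                                random_term("year"), random_term("cohort")),
                           "REML")
  chron_fit <- stage("chronology_fit", fit_growth(chron_spec, frame))
  chronology <- stage("chronology",
                      export_chronology(chron_fit, frame,
                                        min_obs = config$chronology$min_obs))

  bundle <- list(config = config, inputs = inputs, frame = frame,
                 random_structure = random_sel,
                 intrinsic = intrinsic_fit, icc = iccs,
                 scan = scan, randomization = rand,
                 extrinsic = extrinsic, extrinsic_fit = extrinsic_fit,
                 centered = centered, plasticity = plast,
                 cohort_env = env_means, cohort_variance = cohort_var,
                 final = final_fit, standardized = std_fit, r2 = r2,
                 chronology = chronology, log = log_lines)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

## candidate random structures: fish always present (repeated measures),
## year/cohort absent, intercept-only, or intercept + age slope
random_structure_candidates <- function() {
  fish <- list(fi = list(random_term("fish_id")),
               fs = list(random_term("fish_id", TRUE, "log_age_c")))
  opt <- function(g) list(none = NULL, i = list(random_term(g)),
                          s = list(random_term(g, TRUE, "log_age_c")))
  out <- list()
  for (fn in names(fish)) for (yn in names(opt("year")))
    for (cn in names(opt("cohort"))) {
      out[[paste(fn, yn, cn, sep = "_")]] <-
        c(fish[[fn]], opt("year")[[yn]], opt("cohort")[[cn]])
    }
  out
}

#' Export year and cohort growth chronologies from a fit
#'
#' BLUPs of the year and cohort random intercepts with standard errors,
#' joined to observation counts; rows supported by fewer than `min_obs`
#' observations are flagged.
#'
#' @param fit a `growth_fit` with year and cohort random intercepts.
#' @param frame the fitted frame.
#' @param min_obs flagging threshold (default 10).
#' @return list of two data.frames (`year`, `cohort`) with columns level,
#'   blup, se, n_obs, flagged.
#' @export
export_chronology <- function(fit, frame, min_obs = 10L) {
  out <- list()
  for (g in c("year", "cohort")) {
    bl <- tryCatch(blup_extract(fit, g, "(Intercept)"),
                   error = function(e) stop("fit lacks a random intercept for ",
                                            g, call. = FALSE))
    counts <- table(frame[[g]])
    bl$n_obs <- as.integer(counts[bl$level])
    bl$flagged <- bl$n_obs < min_obs
    names(bl)[1] <- g
    bl[[g]] <- as.numeric(bl[[g]])
    out[[g]] <- bl[order(bl[[g]]), ]
    rownames(out[[g]]) <- NULL
  }
  out
}

## write the result bundle as JSON/TSV artifacts
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  fit_json <- function(fit) list(
    formula = paste(deparse(fit$formula), collapse = " "),
    method = fit$spec$method, beta = fit$beta,
    sigma2 = fit$varcomps$sigma2,
    tau = lapply(fit$varcomps$groups, function(g) as.list(g$tau)),
    loglik = fit$loglik, aicc = fit$aicc, n_obs = fit$n_obs,
    n_params = fit$n_params, converged = fit$converged,
    singular = fit$singular,
    centering = as.list(fit$centering))
  seeds <- list(seed = bundle$config$seed,
                simulation_seed = bundle$config$simulation$seed)
  js <- list(seeds = seeds,
             icc = as.list(bundle$icc),
             intrinsic = fit_json(bundle$intrinsic),
             extrinsic = fit_json(bundle$extrinsic_fit),
             final = fit_json(bundle$final),
             r2 = as.list(bundle$r2),
             best_window = as.list(bundle$scan$best),
             randomization = if (!is.null(bundle$randomization))
               list(observed_delta = bundle$randomization$observed_delta,
                    percentile = bundle$randomization$percentile),
             cohort_correlations = bundle$cohort_variance$correlations)
  jsonlite::write_json(js, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  tsv(bundle$scan$table, "window_scan.tsv")
  tsv(bundle$chronology$year, "chronology_year.tsv")
  tsv(bundle$chronology$cohort, "chronology_cohort.tsv")
  tsv(as.data.frame(bundle$plasticity$summary), "plasticity_summary.tsv")
  if (!is.null(bundle$cohort_variance))
    tsv(bundle$cohort_variance$cohort_variance, "cohort_variance.tsv")
  if (!is.null(bundle$randomization))
    tsv(data.frame(null_delta = bundle$randomization$null_deltas),
        "randomization_null.tsv")
  writeLines(bundle$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}
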