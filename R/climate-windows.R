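#' Enumerate candidate climate windows
#'
#' All (open, close) month pairs with 0 <= close <= open <= max_back, counted
#' back from the reference month (December of the growth year). With the
#' default 24-month look-back this yields 300 windows.
#'
#' @param max_back furthest month back (default 23).
#' @return data.frame with columns `open`, `close`.
#' @export
enumerate_windows <- function(max_back = 23L) {
  if (max_back < 0) stop("max_back must be >= 0")
  grid <- expand.grid(close = 0:max_back, open = 0:max_back)
  grid <- grid[grid$close <= grid$open, c("open", "close")]
  rownames(grid) <- NULL
  grid
}

#' Aggregate a monthly climate series over a months-back window
#'
#' The window runs from `open` months back through `close` months back from
#' December of the growth year, inclusive; the aggregate is the arithmetic
#' mean of the monthly values. `open = close = 8` is April of the growth
#' year; `open = 23, close = 0` spans the full 24 months.
#'
#' @param climate a `climate_series` (year, month, value).
#' @param window `c(open, close)` months back, `0 <= close <= open`.
#' @param years vector of growth years (recycled against nothing; one
#'   aggregate per element).
#' @return Numeric vector of window means, one per growth year.
#' @export
window_aggregate <- function(climate, window, years) {
  open <- as.integer(window[1]); close <- as.integer(window[2])
  if (close < 0 || close > open) stop("window must satisfy 0 <= close <= open")
  key <- climate$year * 12L + climate$month          # absolute month index
  if (anyDuplicated(key)) stop("duplicate (year, month) in climate series")
  lut <- stats::setNames(climate$value, key)
  dec <- years * 12L + 12L
  backs <- close:open
  vals <- matrix(NA_real_, length(years), length(backs))
  for (j in seq_along(backs)) {
    v <- lut[as.character(dec - backs[j])]
    vals[, j] <- v
  }
  if (anyNA(vals)) {
    miss <- unique(as.vector(outer(dec, backs, `-`))[is.na(as.vector(vals))])
    miss_lab <- sprintf("%d-%02d", (miss - 1L) %/% 12L, (miss - 1L) %% 12L + 1L)
    stop("climate series does not cover months: ",
         paste(sort(miss_lab), collapse = ", "))
  }
  rowMeans(vals)
}

#' Sliding-window scan of a climate signal against an intrinsic baseline
#'
#' For every candidate window (and, optionally, with and without an
#' interaction of the windowed temperature with centered log-age), attaches
#' the window mean as a mean-centered covariate, fits the model by the
#' baseline's method (ML for these fixed-effect comparisons), and records the
#' AICc against the baseline model treated as a null hypothesis. The random
#' structure of the baseline is used unchanged for every candidate.
#'
#' @param frame the modelling frame (filtered, transformed).
#' @param climate a `climate_series`.
#' @param base_spec intrinsic baseline [model_spec()] (method "ML").
#' @param max_back furthest month back to scan (default 23).
#' @param interaction `"both"` (default) scans each window with and without
#'   the age interaction; `"none"`/`"only"` restrict to one variant.
#' @param age_var name of the centered log-age column for the interaction.
#' @return A `window_scan` list: `table` (open, close, interaction, aicc,
#'   delta_aicc, coef, converged), `best` (minimal-AICc row, parsimony
#'   tie-break toward the simpler variant), `baseline_aicc`, `baseline_fit`.
#' @export
scan_windows <- function(frame, climate, base_spec, max_back = 23L,
                         interaction = c("both", "none", "only"),
                         age_var = "log_age_c") {
  interaction <- match.arg(interaction)
  base_fit <- fit_growth(base_spec, frame)
  if (!base_fit$converged) stop("baseline model did not converge")
  wins <- enumerate_windows(max_back)
  variants <- switch(interaction, both = c(FALSE, TRUE), none = FALSE,
                     only = TRUE)
  rows <- vector("list", nrow(wins) * length(variants))
  r <- 0L
  for (w in seq_len(nrow(wins))) {
    env <- window_aggregate(climate, c(wins$open[w], wins$close[w]),
                            frame$year)
    frame$.win <- env - mean(env)
    for (ia in variants) {
      fixed <- c(base_spec$fixed, ".win", if (ia) paste0(age_var, ":.win"))
      sp <- model_spec(base_spec$response, fixed, base_spec$random,
                       method = base_spec$method)
      ft <- tryCatch(fit_growth(sp, frame), error = function(e) NULL)
      r <- r + 1L
      rows[[r]] <- data.frame(
        open = wins$open[w], close = wins$close[w], interaction = ia,
        aicc = if (is.null(ft)) NA_real_ else ft$aicc,
        coef = if (is.null(ft)) NA_real_
               else ft$beta$estimate[match(".win", ft$beta$term)],
        converged = !is.null(ft) && ft$converged)
    }
  }
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- tab$aicc - base_fit$aicc
  ok <- which(tab$converged)
  best <- ok[order(tab$aicc[ok], tab$interaction[ok])][1]  # tie: simpler first
  structure(list(table = tab, best = tab[best, ],
                 baseline_aicc = base_fit$aicc, baseline_fit = base_fit),
            class = "window_scan")
}

#' Randomization test for the window-scan support
#'
#' Re-runs the scan on data in which the link between growth and calendar
#' time has been destroyed: the year sequences are reshuffled across fish
#' (each fish's whole series is reassigned the cohort of another fish with
#' the same age span, preserving the repeated-measures age structure), or
#' optionally year labels are permuted across observations. The observed best
#' Delta-AICc is ranked within the null distribution of best Delta-AICc
#' values.
#'
#' @param frame,climate,base_spec,max_back,interaction as [scan_windows()].
#' @param n_rand number of randomized iterations (999 for full runs; reduce
#'   for test work).
#' @param seed integer seed.
#' @param unit `"fish"` (default) or `"observation"` permutation.
#' @return A `randomization_result` list: `observed_delta`, `null_deltas`,
#'   `percentile` = (1 + #\{null <= observed\}) / (1 + n_rand).
#' @export
randomization_test <- function(frame, climate, base_spec, n_rand = 999L,
                               seed = 1L, max_back = 23L,
                               interaction = "both", unit = c("fish", "observation")) {
  unit <- match.arg(unit)
  if (n_rand < 1) stop("n_rand must be >= 1")
  obs <- scan_windows(frame, climate, base_spec, max_back, interaction)
  null_deltas <- numeric(n_rand)
  withr_seed(seed, {
    for (b in seq_len(n_rand)) {
      pf <- permute_years(frame, unit)
      sc <- scan_windows(pf, climate, base_spec, max_back, interaction)
      null_deltas[b] <- sc$best$delta_aicc
    }
  })
  observed <- obs$best$delta_aicc
  structure(list(observed_delta = observed, null_deltas = null_deltas,
                 percentile = (1 + sum(null_deltas <= observed)) / (1 + n_rand),
                 scan = obs),
            class = "randomization_result")
}

## permute the growth-year labels under the null of no climate dependence
permute_years <- function(frame, unit = "fish") {
  if (unit == "observation") {
    frame$year <- sample(frame$year)
    return(frame)
  }
  ## fish-level: reshuffle cohorts among fish with identical age sets, so the
  ## multiset of year labels and each fish's age structure are preserved
  sig <- tapply(frame$age, frame$fish_id,
                function(a) paste(sort(a), collapse = ","))
  coh <- tapply(frame$cohort, frame$fish_id, `[`, 1)
  new_coh <- coh
  for (s in unique(sig)) {
    i <- which(sig == s)
    new_coh[i] <- coh[i][sample(length(i))]
  }
  frame$cohort <- as.numeric(new_coh[as.character(frame$fish_id)])
  frame$year <- frame$cohort + frame$age
  frame
}
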