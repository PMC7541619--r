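#' Filter a raw increment table
#'
#' Applies the standard biochronology exclusions, per fish and in this order:
#' (1) the first and last (edge) increments are dropped because they do not
#' represent complete growth through a year; (2) increments formed after the
#' 10th year of life are dropped. Fish whose whole series is removed (fewer
#' than 3 raw increments) are counted and a warning is issued.
#'
#' A table that has already been filtered (attribute `filtered`) is returned
#' unchanged, so the operation is idempotent.
#'
#' @param raw data.frame with at least `fish_id`, `age`, `width_um`; `year`
#'   or `cohort` and `sex` are carried through. Ages within a fish must be
#'   unique.
#' @param max_age oldest retained age (default 10).
#' @return A `growth_table` with attribute `filter_report`: counts of rows
#'   removed by each rule and of fish dropped entirely.
#' @export
apply_filters <- function(raw, max_age = 10L) {
  if (isTRUE(attr(raw, "filtered"))) return(raw)
  need <- c("fish_id", "age", "width_um")
  if (!all(need %in% names(raw)))
    stop("raw table must have columns: ", paste(need, collapse = ", "))
  if (nrow(raw) > 0 && any(raw$width_um <= 0))
    stop("non-positive increment widths found")
  rep0 <- list(n_input = nrow(raw), removed_edge = 0L, removed_age = 0L,
               fish_dropped = 0L, n_output = 0L)
  if (nrow(raw) == 0) {
    out <- raw
    attr(out, "filter_report") <- rep0
    attr(out, "filtered") <- TRUE
    class(out) <- unique(c("growth_table", class(out)))
    return(out)
  }
  if (anyDuplicated(raw[c("fish_id", "age")]))
    stop("duplicated (fish_id, age) rows")
  amin <- stats::ave(raw$age, raw$fish_id, FUN = min)
  amax <- stats::ave(raw$age, raw$fish_id, FUN = max)
  edge <- raw$age == amin | raw$age == amax
  kept <- raw[!edge, , drop = FALSE]
  old <- kept$age > max_age
  out <- kept[!old, , drop = FALSE]
  n_fish_in <- length(unique(raw$fish_id))
  n_fish_out <- length(unique(out$fish_id))
  report <- list(n_input = nrow(raw), removed_edge = sum(edge),
                 removed_age = sum(old), fish_dropped = n_fish_in - n_fish_out,
                 n_output = nrow(out))
  if (report$fish_dropped > 0)
    warning(report$fish_dropped, " fish had no retained increments")
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  attr(out, "filtered") <- TRUE
  class(out) <- unique(c("growth_table", class(out)))
  out
}

#' Log-transform and center the modelling frame
#'
#' Adds `log_width = ln(width_um)` and `log_age_c = ln(age) - c_age`, and
#' mean-centers any continuous covariates named in `center` into `<name>_c`
#' columns. Centering constants are either estimated from the data or
#' supplied (e.g. from a previous fit, so that predictions on new data reuse
#' them); they are stored in the `centering` attribute.
#'
#' @param table a filtered `growth_table`.
#' @param center character vector of covariate columns to mean-center.
#' @param constants optional named numeric vector of fixed centering
#'   constants (must include `log_age` and every entry of `center`).
#' @return The table with transformed columns and a `centering` attribute.
#' @export
growth_transform <- function(table, center = character(), constants = NULL) {
  if (nrow(table) == 0) stop("cannot transform an empty table")
  if (any(table$width_um <= 0)) stop("non-positive widths")
  if (!is.null(constants)) {
    need <- c("log_age", center)
    if (!all(need %in% names(constants)))
      stop("fixed constants missing for: ",
           paste(setdiff(need, names(constants)), collapse = ", "))
  }
  cc <- c(log_age = if (is.null(constants)) mean(log(table$age))
          else unname(constants["log_age"]))
  table$log_width <- log(table$width_um)
  table$log_age_c <- log(table$age) - cc[["log_age"]]
  for (v in center) {
    if (!v %in% names(table)) stop("no such covariate column: ", v)
    cv <- if (is.null(constants)) mean(table[[v]]) else unname(constants[v])
    table[[paste0(v, "_c")]] <- table[[v]] - cv
    cc[v] <- cv
  }
  attr(table, "centering") <- cc
  class(table) <- unique(c("growth_table", class(table)))
  table
}

#' Build the abundance index from abundance-at-age
#'
#' Within each age class, the index is the z-score across years of
#' log abundance, so that it has mean 0 and (sample) sd 1 within every age
#' class — a density-dependence index comparable across ages.
#'
#' @param abundance data.frame with `year`, `age`, `abundance` (> 0).
#' @return data.frame with `year`, `age`, `n_index`.
#' @export
build_n_index <- function(abundance) {
  stopifnot(all(c("year", "age", "abundance") %in% names(abundance)))
  if (any(abundance$abundance <= 0)) stop("abundances must be > 0")
  la <- log(abundance$abundance)
  out <- abundance[c("year", "age")]
  out$n_index <- NA_real_
  for (a in unique(abundance$age)) {
    i <- abundance$age == a
    if (sum(i) < 2) stop("age class ", a, " has a single year; sd undefined")
    s <- stats::sd(la[i])
    if (s == 0) stop("age class ", a, " has constant abundance; sd is zero")
    out$n_index[i] <- (la[i] - mean(la[i])) / s
  }
  out
}

#' Attach windowed climate and stock covariates to the frame
#'
#' @param table a `growth_table` with formation `year` (and `age` if stock
#'   covariates are attached).
#' @param climate a `climate_series`.
#' @param window `c(open, close)` months-back window (see
#'   [window_aggregate()]).
#' @param stock optional list with `abundance` (raw abundance-at-age, passed
#'   through [build_n_index()]) and `hr` (year, hr).
#' @param name column name for the windowed climate covariate.
#' @return The table with new columns `name`, and `n_index`/`hr` when stock
#'   is given.
#' @export
attach_covariates <- function(table, climate, window = c(8L, 8L),
                              stock = NULL, name = "sst_win") {
  table[[name]] <- window_aggregate(climate, window, table$year)
  if (!is.null(stock)) {
    nix <- build_n_index(stock$abundance)
    m <- match(paste(table$year, table$age), paste(nix$year, nix$age))
    if (anyNA(m)) {
      bad <- unique(paste0("(", table$year, ", ", table$age, ")")[is.na(m)])
      stop("stock abundance missing for (year, age): ",
           paste(bad, collapse = "; "))
    }
    table$n_index <- nix$n_index[m]
    mh <- match(table$year, stock$hr$year)
    if (anyNA(mh))
      stop("harvest rate missing for years: ",
           paste(sort(unique(table$year[is.na(mh)])), collapse = ", "))
    table$hr <- stock$hr$hr[mh]
  }
  class(table) <- unique(c("growth_table", class(table)))
  table
}

#' Read raw inputs from CSV files
#'
#' @param increments,climate,abundance,hr file paths; `abundance` and `hr`
#'   may be `NULL`.
#' @return list with elements `raw`, `climate`, `stock`.
#' @export
read_inputs <- function(increments, climate, abundance = NULL, hr = NULL) {
  raw <- utils::read.csv(increments, stringsAsFactors = FALSE)
  cl <- utils::read.csv(climate, stringsAsFactors = FALSE)
  class(cl) <- c("climate_series", "data.frame")
  stock <- NULL
  if (!is.null(abundance)) {
    stock <- list(abundance = utils::read.csv(abundance),
                  hr = if (!is.null(hr)) utils::read.csv(hr))
  }
  list(raw = raw, climate = cl, stock = stock)
}
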