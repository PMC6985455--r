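#' @title Per-well growth summaries from confluency time series
#' @description Helpers that reduce a well's confluency-vs-time trace to the
#'   screen's summary statistics: AUC, exponential-phase cutoff, slopes, and
#'   control-relative versions.
#' @name growth_metrics
NULL

validate_well_series <- function(series) {
  if (!all(c("time_h", "confluency_pct") %in% names(series))) {
    abort("a well series needs `time_h` and `confluency_pct` columns",
          class = "cin_invalid_series")
  }
  t <- series$time_h
  y <- series$confluency_pct
  if (length(t) < 2) abort("a well series needs at least 2 time points",
                           class = "cin_invalid_series")
  if (any(diff(t) <= 0)) abort("times must be strictly increasing",
                               class = "cin_invalid_series")
  if (any(!is.finite(y)) || any(y < 0)) {
    abort("confluency must be finite and non-negative", class = "cin_invalid_series")
  }
  invisible(series)
}

#' Area under a confluency curve
#'
#' The screen's default AUC convention is the plain sum of the confluency
#' values across time points, which is only comparable between wells sharing
#' an identical time grid; the trapezoid rule (percent x hours) is provided
#' for unequal grids.
#'
#' @param series A well series (tibble with `time_h`, `confluency_pct`).
#' @param method `"sum"` (default) or `"trapezoid"`.
#' @return A non-negative scalar.
#' @export
#' @examples
#' s <- tibble::tibble(time_h = 0:4 * 2, confluency_pct = rep(10, 5))
#' compute_auc(s) # 50
compute_auc <- function(series, method = c("sum", "trapezoid")) {
  method <- match.arg(method)
  validate_well_series(series)
  switch(method,
         sum = sum(series$confluency_pct),
         trapezoid = pracma::trapz(series$time_h, series$confluency_pct))
}

# R^2 of the least-squares line over every expanding window [1..k] of (x, y),
# via cumulative sums. Values clamped to [0, 1] and rounded to 12 digits so
# exact linear data survives floating point.
expanding_r2 <- function(x, y) {
  n <- length(x)
  k <- seq_len(n)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x^2); syy <- cumsum(y^2); sxy <- cumsum(x * y)
  sxy_c <- sxy - sx * sy / k
  sxx_c <- sxx - sx^2 / k
  syy_c <- syy - sy^2 / k
  r2 <- ifelse(syy_c <= 0 | sxx_c <= 0, 1, sxy_c^2 / (sxx_c * syy_c))
  round(pmin(pmax(r2, 0), 1), 12)
}

#' Detect the end of exponential (logarithmic) growth
#'
#' Fits least-squares lines to (time, ln confluency) over expanding windows
#' starting at the first positive observation, and returns the largest time
#' `t*` whose window still achieves `R^2 >= r2_min`. On a logistic curve this
#' marks where growth departs from log-linearity. If no window of at least
#' `min_points` points qualifies, the time after `min_points` observations is
#' returned and flagged low quality.
#'
#' @param series A well series.
#' @param r2_min Minimum R-squared for a window to count as log-linear
#'   (default 0.99).
#' @param min_points Minimum window size (default 4).
#' @return A list with `cutoff_time` (hours), `confluency_at_cutoff` (percent),
#'   `r2` (of the selected window), and `low_quality` (logical).
#' @export
detect_exponential_cutoff <- function(series, r2_min = 0.99, min_points = 4) {
  validate_well_series(series)
  pos <- which(series$confluency_pct > 0)
  if (!length(pos)) {
    abort("insufficient data: no positive confluency observations",
          class = "cin_insufficient_data")
  }
  start <- pos[1]
  run <- series[start:nrow(series), ]
  end_pos <- which(run$confluency_pct <= 0)
  if (length(end_pos)) run <- run[seq_len(end_pos[1] - 1), ]
  if (nrow(run) < min_points) {
    abort(sprintf("insufficient data: %d positive observations, need >= %d",
                  nrow(run), min_points),
          class = "cin_insufficient_data")
  }
  r2 <- expanding_r2(run$time_h, log(run$confluency_pct))
  eligible <- seq_len(nrow(run)) >= min_points
  ok <- which(eligible & r2 >= r2_min)
  if (length(ok)) {
    k <- max(ok)
    low <- FALSE
  } else {
    k <- min_points
    low <- TRUE
  }
  list(cutoff_time = run$time_h[k],
       confluency_at_cutoff = run$confluency_pct[k],
       r2 = r2[k],
       low_quality = low)
}

nearest_time_index <- function(times, target) {
  # ties resolve toward the earlier time (which.min keeps the first minimum)
  which.min(abs(times - target))
}

#' Control-relative slope at a shared cutoff time
#'
#' With the cutoff time fixed across a drug/control pair, the slope of
#' log-growth is proportional to the confluency at the cutoff, so the relative
#' slope reduces to the drug well's confluency at `t*` divided by the mean
#' control confluency there.
#'
#' @param series Drug-treated well series.
#' @param control_series A well series or list of well series for the same
#'   cell line's vehicle controls.
#' @param cutoff_time Shared cutoff time in hours; matched to the nearest
#'   sampled time on each grid (ties toward earlier).
#' @return Dimensionless relative slope.
#' @export
compute_relative_slope <- function(series, control_series, cutoff_time) {
  validate_well_series(series)
  if (is.data.frame(control_series)) control_series <- list(control_series)
  if (!length(control_series)) {
    abort("control set is empty", class = "cin_normalization_error")
  }
  ctrl_vals <- vapply(control_series, function(cs) {
    validate_well_series(cs)
    cs$confluency_pct[nearest_time_index(cs$time_h, cutoff_time)]
  }, numeric(1))
  m <- mean(ctrl_vals)
  if (m <= 0) abort("control mean confluency at cutoff is zero",
                    class = "cin_normalization_error")
  series$confluency_pct[nearest_time_index(series$time_h, cutoff_time)] / m
}

#' Manual log-slope of a growth curve
#'
#' The manually-estimated slope convention for daily-imaging curves: the
#' negative natural log of the confluency fraction at the cutoff, divided by
#' the cutoff time in days, i.e. `-ln(C(t*)/100) / (t*/24)`. Note this
#' quantity *decreases* as confluency rises; it is implemented literally as
#' defined for the daily-imaging analysis and is only used control-relative.
#'
#' @param series A well series.
#' @param cutoff_time Cutoff time in hours (must be > 0); matched to the
#'   nearest sampled time.
#' @return Slope in per-day units.
#' @export
compute_manual_slope <- function(series, cutoff_time) {
  validate_well_series(series)
  if (cutoff_time <= 0) abort("cutoff time must be > 0", class = "cin_invalid_series")
  cfrac <- series$confluency_pct[nearest_time_index(series$time_h, cutoff_time)] / 100
  if (cfrac <= 0) abort("log-domain error: zero confluency at cutoff",
                        class = "cin_log_domain_error")
  -log(cfrac) / (cutoff_time / 24)
}

#' Normalize per-well AUCs to the cell-line vehicle control
#'
#' Each AUC is divided by the mean AUC of the same cell line's vehicle wells,
#' so that genotype-level proliferation differences (e.g. the ~25% penalty of
#' a checkpoint-knockdown line) cancel before drugs are compared across lines.
#' Control wells themselves get relative values with mean exactly 1.
#'
#' @param records Per-well metric records with at least `cell_line`, `drug`,
#'   and `auc` columns.
#' @param vehicle Vehicle drug label (default `"DMSO"`).
#' @return `records` with a `relative_auc` column added.
#' @export
normalize_to_control <- function(records, vehicle = "DMSO") {
  missing_ctrl <- setdiff(unique(records$cell_line),
                          records$cell_line[records$drug == vehicle])
  if (length(missing_ctrl)) {
    abort(sprintf("normalization error: no %s control for cell line(s): %s",
                  vehicle, paste(missing_ctrl, collapse = ", ")),
          class = "cin_normalization_error")
  }
  records %>%
    group_by(.data$cell_line) %>%
    mutate(relative_auc = .data$auc / mean(.data$auc[.data$drug == vehicle])) %>%
    ungroup()
}

select_window <- function(times, start_h, end_h, boundary = c("shared", "left"),
                          is_last = FALSE) {
  boundary <- match.arg(boundary)
  if (boundary == "shared" || is_last) {
    times >= start_h & times <= end_h
  } else {
    times >= start_h & times < end_h
  }
}

#' Split a screen table into analysis time windows
#'
#' Partitions every series at the given day boundaries (e.g. `4` for a
#' days 0-4 / days 4-8 split), preserving all label columns. With the default
#' `boundary = "shared"`, a boundary that coincides with a sampled time point
#' belongs to both adjacent windows, which makes trapezoid AUCs additive
#' across windows; `boundary = "left"` gives a strict half-open partition
#' instead. Empty windows are dropped with a warning.
#'
#' @param table A screen table or well series with a `time_h` column.
#' @param boundaries Numeric vector of interior boundaries, in days.
#' @param boundary `"shared"` (default) or `"left"`; see Details.
#' @return A named list of tables, one per window, each with a `window` label
#'   column added (e.g. `"d0-4"`).
#' @export
split_time_windows <- function(table, boundaries, boundary = c("shared", "left")) {
  boundary <- match.arg(boundary)
  t <- table$time_h
  edges_h <- sort(unique(c(min(t), boundaries * 24, max(t))))
  edges_h <- edges_h[edges_h >= min(t) & edges_h <= max(t)]
  if (length(edges_h) < 2) edges_h <- range(t)
  out <- list()
  for (i in seq_len(length(edges_h) - 1)) {
    lab <- sprintf("d%g-%g", edges_h[i] / 24, edges_h[i + 1] / 24)
    keep <- select_window(t, edges_h[i], edges_h[i + 1], boundary,
                          is_last = i == length(edges_h) - 1)
    piece <- table[keep, , drop = FALSE]
    if (!nrow(piece)) {
      warn(sprintf("window %s contains no observations; dropped", lab))
      next
    }
    piece$window <- lab
    out[[lab]] <- piece
  }
  out
}

#' Per-well growth metrics for a whole screen
#'
#' Computes every well's AUC, the cell line's shared exponential-phase cutoff
#' (detected on the mean vehicle-control curve so drug/control pairs share a
#' cutoff time), the confluency at that cutoff, the manual log-slope, and all
#' control-relative versions.
#'
#' @param screen Long-format screen table (see [simulate_screen()] /
#'   [read_screen_table()]).
#' @param auc_method `"sum"` (default) or `"trapezoid"`. The sum convention
#'   requires all wells to share one time grid.
#' @param r2_min,min_points Cutoff-detection parameters, see
#'   [detect_exponential_cutoff()].
#' @param vehicle Vehicle drug label.
#' @param slopes If `FALSE`, skip cutoff/slope computation (AUC only).
#' @return A per-well tibble with columns `plate`, `well`, `cell_line`,
#'   `drug`, `dose_uM`, `bio_rep`, `tech_rep`, `auc`, `relative_auc`, and when
#'   `slopes = TRUE` also `cutoff_time`, `confluency_at_cutoff`,
#'   `slope_relative`, `slope_manual`, `slope_manual_relative`.
#' @export
screen_metrics <- function(screen, auc_method = c("sum", "trapezoid"),
                           r2_min = 0.99, min_points = 4,
                           vehicle = "DMSO", slopes = TRUE) {
  auc_method <- match.arg(auc_method)
  keys <- intersect(c("plate", "well", "cell_line", "drug", "dose_uM",
                      "bio_rep", "tech_rep", "window"), names(screen))
  if (auc_method == "sum") {
    grids <- screen %>%
      group_by(across(all_of(keys))) %>%
      summarise(g = paste(.data$time_h, collapse = ","), .groups = "drop")
    if (length(unique(grids$g)) > 1) {
      abort("grid error: sum-convention AUC requires an identical time grid in every well",
            class = "cin_grid_error")
    }
  }
  auc_fun <- if (auc_method == "sum") {
    function(t, y) sum(y)
  } else {
    function(t, y) pracma::trapz(t, y)
  }
  metrics <- screen %>%
    group_by(across(all_of(keys))) %>%
    summarise(auc = auc_fun(.data$time_h, .data$confluency_pct),
              .groups = "drop") %>%
    normalize_to_control(vehicle = vehicle)

  if (!slopes) return(metrics)

  # shared cutoff per cell line, detected on the mean vehicle-control curve
  cutoffs <- screen %>%
    filter(.data$drug == vehicle) %>%
    group_by(.data$cell_line, .data$time_h) %>%
    summarise(confluency_pct = mean(.data$confluency_pct), .groups = "drop") %>%
    group_by(.data$cell_line) %>%
    summarise(cutoff_time = detect_exponential_cutoff(
      dplyr::pick("time_h", "confluency_pct"),
      r2_min = r2_min, min_points = min_points)$cutoff_time,
      .groups = "drop")

  at_cutoff <- screen %>%
    left_join(cutoffs, by = "cell_line") %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      cutoff_time = .data$cutoff_time[1],
      confluency_at_cutoff =
        .data$confluency_pct[nearest_time_index(.data$time_h, .data$cutoff_time[1])],
      .groups = "drop"
    ) %>%
    mutate(slope_manual = ifelse(
      .data$confluency_at_cutoff > 0,
      -log(.data$confluency_at_cutoff / 100) / (.data$cutoff_time / 24),
      NA_real_))

  metrics <- metrics %>%
    left_join(at_cutoff, by = keys) %>%
    group_by(.data$cell_line) %>%
    mutate(
      slope_relative = .data$confluency_at_cutoff /
        mean(.data$confluency_at_cutoff[.data$drug == vehicle]),
      slope_manual_relative = .data$slope_manual /
        mean(.data$slope_manual[.data$drug == vehicle])
    ) %>%
    ungroup()
  metrics
}
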