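#' Compare a control-relative metric between two cell lines
#'
#' Effect size is the log2 ratio of group means of the control-relative metric
#' (so 0 means the drug hits both lines equally once each line's baseline
#' growth is divided out); the p-value comes from a two-sample t test,
#' Student's pooled-variance version by default. With the screen's typical
#' three biological replicates per group, Welch's Satterthwaite degrees of
#' freedom are too unstable and make the test noticeably conservative, so the
#' pooled test (reasonable under a shared measurement protocol) is the
#' default; set `var_equal = FALSE` for Welch.
#'
#' @param values_a,values_b Numeric samples of the control-relative metric for
#'   the two cell lines (at least 2 finite values each).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (one-sided, direction refers to `values_a` vs `values_b`).
#' @param var_equal Pooled-variance Student t test (default `TRUE`); set
#'   `FALSE` for Welch's unequal-variance test.
#' @return A list with `effect` (log2 mean ratio), `p_value`, `statistic`,
#'   `df`, `n_a`, `n_b`, and `degenerate` (TRUE when both groups have zero
#'   variance; then `p_value` is 1 for equal means and 0 otherwise, by
#'   convention).
#' @export
#' @examples
#' compare_cell_lines(c(1.0, 1.1, 0.9), c(0.50, 0.55, 0.45))$effect # ~1
compare_cell_lines <- function(values_a, values_b,
                               alternative = c("two.sided", "greater", "less"),
                               var_equal = TRUE) {
  alternative <- match.arg(alternative)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("need at least 2 finite values per group", class = "cin_insufficient_data")
  }
  ma <- mean(values_a); mb <- mean(values_b)
  if (ma <= 0 || mb <= 0) {
    abort("effect undefined: group means must be positive for a log2 ratio",
          class = "cin_effect_undefined")
  }
  effect <- log2(ma / mb)
  if (var(values_a) == 0 && var(values_b) == 0) {
    return(list(effect = effect, p_value = if (ma == mb) 1 else 0,
                statistic = NA_real_, df = NA_real_,
                n_a = length(values_a), n_b = length(values_b),
                degenerate = TRUE))
  }
  tt <- t.test(values_a, values_b, alternative = alternative,
               var.equal = var_equal)
  list(effect = effect, p_value = unname(tt$p.value),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       n_a = length(values_a), n_b = length(values_b), degenerate = FALSE)
}

#' Bonferroni multiple-testing adjustment
#'
#' `p_adj = min(1, m * p)`, preserving order. `m` may exceed the number of
#' p-values supplied (e.g. when only a subset of a screened family is being
#' adjusted).
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1) abort("family size `m` must be >= 1", class = "cin_parameter_error")
  if (m < length(p_values)) {
    abort("family size `m` must be at least the number of tests",
          class = "cin_parameter_error")
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Per-drug differential sensitivity between two cell lines
#'
#' For each non-vehicle drug, compares the control-relative metric between the
#' two lines with [compare_cell_lines()] and applies Bonferroni correction
#' across the drug family. By default the biological replicate is the unit of
#' analysis: technical replicates are averaged within each biological
#' replicate, and each biological replicate's drug AUC is normalized by the
#' *same replicate's* vehicle-control mean (every plate carries its own
#' control), which keeps replicate values independent of one another. Set
#' `replicate_unit = "well"` to treat all wells as independent instead; wells
#' are then compared on the line-level `relative_auc` (or whichever metric
#' column is requested).
#'
#' @param metrics Per-well metrics from [screen_metrics()].
#' @param line_a,line_b The two cell lines to compare.
#' @param metric Column to compare, e.g. `"relative_auc"` (default) or
#'   `"slope_relative"`.
#' @param replicate_unit `"bio"` (default) or `"well"`.
#' @param alternative,var_equal Passed to [compare_cell_lines()].
#' @param family_size Bonferroni family size; defaults to the number of drugs
#'   tested.
#' @param vehicle Vehicle drug label (excluded from testing).
#' @return A tibble with one row per drug: `drug`, `dose_uM`, `metric`,
#'   `effect`, `p_raw`, `p_bonferroni`, `n_a`, `n_b`.
#' @export
differential_screen <- function(metrics, line_a, line_b,
                                metric = "relative_auc",
                                replicate_unit = c("bio", "well"),
                                alternative = "two.sided",
                                var_equal = TRUE,
                                family_size = NULL,
                                vehicle = "DMSO") {
  replicate_unit <- match.arg(replicate_unit)
  stopifnot(metric %in% names(metrics))
  dat <- metrics %>%
    filter(.data$drug != vehicle, .data$cell_line %in% c(line_a, line_b))
  if (!nrow(dat)) abort("no drug wells for the requested cell lines",
                        class = "cin_insufficient_data")
  if (replicate_unit == "bio" && metric == "relative_auc") {
    # renormalize within each biological replicate against its own control
    ctrl <- metrics %>%
      filter(.data$drug == vehicle, .data$cell_line %in% c(line_a, line_b)) %>%
      group_by(.data$cell_line, .data$bio_rep) %>%
      summarise(ctrl_auc = mean(.data$auc), .groups = "drop")
    dat <- dat %>%
      group_by(.data$cell_line, .data$drug, .data$dose_uM, .data$bio_rep) %>%
      summarise(auc = mean(.data$auc), .groups = "drop") %>%
      left_join(ctrl, by = c("cell_line", "bio_rep")) %>%
      mutate(value = .data$auc / .data$ctrl_auc)
  } else if (replicate_unit == "bio") {
    dat <- dat %>%
      group_by(.data$cell_line, .data$drug, .data$dose_uM, .data$bio_rep) %>%
      summarise(value = mean(.data[[metric]]), .groups = "drop")
  } else {
    dat <- dat %>% rename(value = all_of(metric))
  }
  drugs <- dat %>% dplyr::distinct(.data$drug, .data$dose_uM)
  res <- purrr::pmap_dfr(drugs, function(drug, dose_uM) {
    va <- dat$value[dat$drug == drug & dat$dose_uM == dose_uM &
                      dat$cell_line == line_a]
    vb <- dat$value[dat$drug == drug & dat$dose_uM == dose_uM &
                      dat$cell_line == line_b]
    cmp <- compare_cell_lines(va, vb, alternative = alternative,
                              var_equal = var_equal)
    tibble(drug = drug, dose_uM = dose_uM, metric = metric,
           effect = cmp$effect, p_raw = cmp$p_value,
           n_a = cmp$n_a, n_b = cmp$n_b)
  })
  m <- if (is.null(family_size)) nrow(res) else family_size
  res$p_bonferroni <- bonferroni_adjust(res$p_raw, m = m)
  res
}

#' Annotate a differential table for volcano plotting
#'
#' Flags hits where `|effect| >= effect_min` and the Bonferroni-adjusted
#' p-value is below `alpha`, and adds a `-log10(p_raw)` column for plotting.
#'
#' @param records Differential records from [differential_screen()].
#' @param effect_min Minimum absolute log2 effect for a hit (default 1).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return `records` with `neg_log10_p` and logical `hit` columns.
#' @export
build_volcano_table <- function(records, effect_min = 1, alpha = 0.05) {
  stopifnot(all(c("effect", "p_raw", "p_bonferroni") %in% names(records)))
  records %>%
    mutate(
      neg_log10_p = -log10(pmax(.data$p_raw, .Machine$double.xmin)),
      hit = abs(.data$effect) >= effect_min & .data$p_bonferroni < alpha
    )
}

#' Volcano plot of a differential screen
#'
#' @param volcano Table from [build_volcano_table()].
#' @param label_hits Label hit points with the drug id.
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, label_hits = TRUE) {
  p <- ggplot2::ggplot(volcano,
                       ggplot2::aes(x = .data$effect, y = .data$neg_log10_p,
                                    colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "blue"),
                                 guide = "none") +
    ggplot2::labs(x = expression(log[2] ~ "effect (line A / line B)"),
                  y = expression(-log[10] ~ italic(P))) +
    ggplot2::theme_minimal()
  if (label_hits && any(volcano$hit)) {
    p <- p + ggplot2::geom_text(
      data = volcano[volcano$hit, , drop = FALSE],
      ggplot2::aes(label = .data$drug), vjust = -0.8, size = 3, colour = "blue")
  }
  p
}
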