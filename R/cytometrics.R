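#' Chi-squared test on a phenotype-by-condition count table
#'
#' Pearson chi-squared test of homogeneity on a contingency table of phenotype
#' counts (e.g. normal / misaligned / lagging / micronucleated cells per
#' condition), without continuity correction by default.
#'
#' @param counts Numeric matrix or data frame of non-negative counts;
#'   conditions in rows, phenotype categories in columns.
#' @param correct Apply Yates continuity correction (2x2 tables only;
#'   default `FALSE`).
#' @return A list with `statistic`, `df`, `p_value`, `expected`, `n`.
#' @export
#' @examples
#' chi_squared_test(rbind(c(46, 54), c(1, 99)))
chi_squared_test <- function(counts, correct = FALSE) {
  m <- as.matrix(counts)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("need at least 2 conditions and 2 categories", class = "cin_degenerate_table")
  }
  if (any(m < 0) || any(!is.finite(m))) {
    abort("counts must be finite and non-negative", class = "cin_degenerate_table")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate table: a row or column marginal is zero",
          class = "cin_degenerate_table")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    warn("some expected counts are below 5; the chi-squared approximation may be poor")
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = expected, n = sum(m))
}

#' Proportion with Wilson confidence interval
#'
#' Summarizes a count out of a total as a percentage (e.g. the fraction of
#' aneuploid cells among cells sequenced) with a Wilson score 95% interval.
#'
#' @param k Count of events (0 <= k <= n).
#' @param n Total (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `pct` (exact percentage), `pct_display` (rounded to
#'   the nearest integer), `ci_low_pct`, `ci_high_pct`, `k`, `n`.
#' @export
#' @examples
#' proportion_summary(76, 169)$pct_display # 45
proportion_summary <- function(k, n, conf_level = 0.95) {
  if (n <= 0) abort("total `n` must be > 0", class = "cin_parameter_error")
  if (k < 0 || k > n) abort("`k` must lie in [0, n]", class = "cin_parameter_error")
  ci <- suppressWarnings(
    prop.test(k, n, conf.level = conf_level, correct = FALSE)$conf.int)
  list(pct = 100 * k / n, pct_display = round(100 * k / n),
       ci_low_pct = 100 * ci[1], ci_high_pct = 100 * ci[2], k = k, n = n)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test as used for per-track cell speeds and relative
#' AUC comparisons. The exact null distribution is enumerated when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction (and continuity correction) is
#' used. If every value across both samples is identical, p = 1 by
#' convention, flagged.
#'
#' @param sample_a,sample_b Numeric samples (>= 1 value each).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @param exact_max Largest combined n for which the exact distribution is
#'   used (default 12).
#' @return A list with `statistic` (Mann-Whitney U for sample_a), `p_value`,
#'   `exact` (logical), `tied` (logical).
#' @export
rank_sum_test <- function(sample_a, sample_b,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max = 12) {
  alternative <- match.arg(alternative)
  if (!length(sample_a) || !length(sample_b)) {
    abort("need at least one value per sample", class = "cin_insufficient_data")
  }
  pooled <- c(sample_a, sample_b)
  tied <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(sample_a) * length(sample_b) / 2,
                p_value = 1, exact = FALSE, tied = TRUE))
  }
  exact <- (length(pooled) <= exact_max) && !tied
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = alternative,
                exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = unname(wt$p.value),
       exact = exact, tied = tied)
}

#' Per-cell microtubule assembly-rate comparison
#'
#' Each cell contributes the mean of its per-microtubule plus-end assembly
#' rates (um/min); the cell, never the individual microtubule, is the unit of
#' analysis. Conditions are compared with an unpaired two-sided t test on the
#' per-cell means.
#'
#' @param rates Long table with columns `cell_id`, `condition`, `rate`
#'   (one row per microtubule measurement).
#' @param condition_a,condition_b Conditions to compare.
#' @param expected_mts Expected measurements per cell (default 20); cells
#'   deviating from it trigger a warning, cells with none are dropped.
#' @param var_equal Pooled-variance t test (default `FALSE`, Welch).
#' @return A list with `cell_means` (tibble `cell_id`, `condition`, `n_mt`,
#'   `mean_rate`), `difference` (mean B - mean A), `statistic`, `df`,
#'   `p_value`, `degenerate`.
#' @export
mt_rate_comparison <- function(rates, condition_a, condition_b,
                               expected_mts = 20, var_equal = FALSE) {
  stopifnot(all(c("cell_id", "condition", "rate") %in% names(rates)))
  if (any(rates$rate < 0)) abort("assembly rates must be >= 0",
                                 class = "cin_parameter_error")
  dat <- rates %>% filter(.data$condition %in% c(condition_a, condition_b))
  cell_means <- dat %>%
    group_by(.data$condition, .data$cell_id) %>%
    summarise(n_mt = dplyr::n(), mean_rate = mean(.data$rate), .groups = "drop")
  if (any(cell_means$n_mt != expected_mts)) {
    warn(sprintf("some cells do not have exactly %d microtubule measurements",
                 expected_mts))
  }
  va <- cell_means$mean_rate[cell_means$condition == condition_a]
  vb <- cell_means$mean_rate[cell_means$condition == condition_b]
  if (length(va) < 2 || length(vb) < 2) {
    abort("need >= 2 cells per condition", class = "cin_insufficient_data")
  }
  diff_ab <- mean(vb) - mean(va)
  if (sd(va) == 0 && sd(vb) == 0) {
    return(list(cell_means = cell_means, difference = diff_ab,
                statistic = NA_real_, df = NA_real_,
                p_value = if (diff_ab == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(vb, va, var.equal = var_equal)
  list(cell_means = cell_means, difference = diff_ab,
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value), degenerate = FALSE)
}

#' Mitotic timing durations and group comparison
#'
#' From per-cell ordered timestamps (first DNA condensation, last point
#' before anaphase, complete de-condensation), computes the
#' prophase-to-metaphase and anaphase-to-decondensation durations, group
#' medians, and a rank-sum comparison between two groups (a t test is
#' available as an option). Cells with unordered timestamps are rejected with
#' a reason.
#'
#' @param events Tibble with columns `cell_id`, `group`, `t_condensation`,
#'   `t_pre_anaphase`, `t_decondensation` (minutes).
#' @param test `"ranksum"` (default) or `"t"`.
#' @param duration Which duration the group comparison uses:
#'   `"mitotic"` (condensation to pre-anaphase, default) or `"exit"`.
#' @return A list with `durations` (per accepted cell), `rejected` (with
#'   `reason`), `summary` (group medians and n), and `comparison`
#'   (`p_value`, `method`) when exactly two groups are present.
#' @export
mitotic_timing_summary <- function(events, test = c("ranksum", "t"),
                                   duration = c("mitotic", "exit")) {
  test <- match.arg(test)
  duration <- match.arg(duration)
  need <- c("cell_id", "group", "t_condensation", "t_pre_anaphase",
            "t_decondensation")
  stopifnot(all(need %in% names(events)))
  bad <- events$t_condensation > events$t_pre_anaphase |
    events$t_pre_anaphase > events$t_decondensation
  rejected <- events[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "unordered timestamps"
  ok <- events[!bad, , drop = FALSE]
  durations <- ok %>%
    mutate(mitotic_min = .data$t_pre_anaphase - .data$t_condensation,
           exit_min = .data$t_decondensation - .data$t_pre_anaphase) %>%
    select("cell_id", "group", "mitotic_min", "exit_min")
  summary <- durations %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(),
              median_mitotic_min = median(.data$mitotic_min),
              median_exit_min = median(.data$exit_min), .groups = "drop")
  comparison <- NULL
  groups <- unique(durations$group)
  if (length(groups) == 2) {
    col <- if (duration == "mitotic") "mitotic_min" else "exit_min"
    va <- durations[[col]][durations$group == groups[1]]
    vb <- durations[[col]][durations$group == groups[2]]
    comparison <- if (test == "ranksum") {
      rs <- rank_sum_test(va, vb)
      list(p_value = rs$p_value, method = "rank-sum")
    } else {
      list(p_value = unname(t.test(va, vb)$p.value), method = "t")
    }
  }
  list(durations = durations, rejected = rejected,
       summary = summary, comparison = comparison)
}
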