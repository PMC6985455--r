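# Monte-Carlo calibration of the screen's tests under the additive null.
# These helpers re-use the generator's noiseless curve and noise model but
# work on AUC matrices directly, so thousands of null screens fit in seconds;
# the statistics themselves are computed by the same functions the pipeline
# uses (compare_cell_lines, synergy_test) or by t_vec, which is pinned
# to compare_cell_lines by a unit test.

null_aucs <- function(curve, n_wells, cv) {
  n_t <- length(curve)
  eps <- matrix(lognormal_noise(n_t * n_wells, cv), nrow = n_t)
  as.vector(crossprod(curve, eps))
}

# Vectorized two-sided two-sample t-test p-values from two value matrices
# (replicates in rows, tests in columns); pooled variance by default to match
# compare_cell_lines().
t_vec <- function(a, b, var_equal = TRUE) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  2 * pt(-abs(t_stat), df)
}

#' Null p-values of the differential or synergy test
#'
#' Simulates screens under the additive null (all genotype penalties and drug
#' effects equal, zero interaction) and returns the p-value of the configured
#' test in each simulation, for empirical type-I error calibration.
#'
#' For `"differential"`, each simulation draws two cell lines x (vehicle +
#' one drug) x `n_bio` x `n_tech` wells, averages technical replicates within
#' biological replicates, normalizes each biological replicate's drug AUC by
#' the same replicate's vehicle mean (as [differential_screen()] does), and
#' applies [compare_cell_lines()]. For `"synergy"`, each simulation draws the
#' four Bliss groups and applies [synergy_test()] to the paired per-replicate
#' excesses (the default convention of [bliss_excess()]).
#'
#' @param n_sims Number of null simulations.
#' @param test `"differential"` or `"synergy"`.
#' @param config A [sim_config()]; only its growth/noise/replicate settings
#'   are used (effects are forced to the null).
#' @param seed Integer seed.
#' @return Numeric vector of `n_sims` p-values.
#' @export
simulate_null_pvalues <- function(n_sims,
                                  test = c("differential", "synergy"),
                                  config = sim_config(duration_h = 48,
                                                      passage_day = NULL),
                                  seed = 1L) {
  test <- match.arg(test)
  times <- time_grid(config)
  passage_h <- if (is.null(config$passage_day)) NULL else config$passage_day * 24
  curve <- noiseless_confluency(times, config$c0, config$K, config$r_base,
                                passage_h, config$split_ratio)
  n_rep <- config$n_bio * config$n_tech
  cv <- config$noise_cv
  bio_idx <- rep(seq_len(config$n_bio), each = config$n_tech)

  withr::with_seed(seed, vapply(seq_len(n_sims), function(i) {
    if (test == "differential") {
      ctrl_a <- null_aucs(curve, n_rep, cv)
      drug_a <- null_aucs(curve, n_rep, cv)
      ctrl_b <- null_aucs(curve, n_rep, cv)
      drug_b <- null_aucs(curve, n_rep, cv)
      rel_a <- tapply(drug_a, bio_idx, mean) / tapply(ctrl_a, bio_idx, mean)
      rel_b <- tapply(drug_b, bio_idx, mean) / tapply(ctrl_b, bio_idx, mean)
      compare_cell_lines(as.vector(rel_a), as.vector(rel_b))$p_value
    } else {
      ref <- null_aucs(curve, n_rep, cv)
      a <- null_aucs(curve, n_rep, cv)
      b <- null_aucs(curve, n_rep, cv)
      ab <- null_aucs(curve, n_rep, cv)
      Fa_i <- fractional_inhibition(a, ref, warn = FALSE)
      Fb_i <- fractional_inhibition(b, ref, warn = FALSE)
      obs <- fractional_inhibition(ab, ref, warn = FALSE)
      synergy_test(obs - (Fa_i + Fb_i - Fa_i * Fb_i), 0)$p_value
    }
  }, numeric(1)))
}

#' Family-wise error of the Bonferroni-corrected screen under the full null
#'
#' Simulates all-null screens of `n_drugs` drugs against a vehicle control in
#' two cell lines, runs the per-drug t test on bio-replicate means of
#' control-relative AUCs, applies [bonferroni_adjust()] with family size
#' `n_drugs`, and reports the fraction of simulated screens with at least one
#' (false) hit at level `alpha`.
#'
#' @param n_sims Number of simulated screens.
#' @param n_drugs Drugs per screen (default 95).
#' @param config A [sim_config()] providing growth, noise and replicate
#'   settings.
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return Empirical family-wise error rate (scalar).
#' @export
estimate_fwer <- function(n_sims, n_drugs = 95,
                          config = sim_config(duration_h = 48,
                                              passage_day = NULL),
                          alpha = 0.05, seed = 1L) {
  times <- time_grid(config)
  passage_h <- if (is.null(config$passage_day)) NULL else config$passage_day * 24
  curve <- noiseless_confluency(times, config$c0, config$K, config$r_base,
                                passage_h, config$split_ratio)
  n_bio <- config$n_bio; n_tech <- config$n_tech
  n_rep <- n_bio * n_tech
  cv <- config$noise_cv

  line_values <- function() {
    # wells ordered: condition (vehicle first, then drugs) x bio x tech
    aucs <- null_aucs(curve, (n_drugs + 1) * n_rep, cv)
    arr <- array(aucs, dim = c(n_tech, n_bio, n_drugs + 1))
    bio_means <- apply(arr, c(2, 3), mean)          # n_bio x (n_drugs + 1)
    rel <- bio_means / bio_means[, 1]               # vs own replicate's control
    rel[, -1, drop = FALSE]                         # drugs only
  }
  hits <- withr::with_seed(seed, vapply(seq_len(n_sims), function(i) {
    p <- t_vec(line_values(), line_values())
    any(bonferroni_adjust(p, m = n_drugs) < alpha)
  }, logical(1)))
  mean(hits)
}
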