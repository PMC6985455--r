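#' Fractional growth inhibition
#'
#' `1 - AUC(treated) / AUC(reference)`: the inhibition scale on which the
#' Bliss independence model operates. Negative values (growth stimulation)
#' are permitted and flagged with a warning.
#'
#' @param auc_treated AUC of the treated condition (vectorized).
#' @param auc_reference Reference AUC (must be > 0).
#' @param warn Warn when an inhibition is negative.
#' @return Fractional inhibition in `(-Inf, 1]`.
#' @export
#' @examples
#' fractional_inhibition(50, 100) # 0.5
fractional_inhibition <- function(auc_treated, auc_reference, warn = TRUE) {
  if (any(auc_reference <= 0)) {
    abort("reference AUC must be > 0", class = "cin_division_error")
  }
  f <- 1 - auc_treated / auc_reference
  if (warn && any(f < 0)) {
    warn("negative fractional inhibition (growth stimulation) observed")
  }
  f
}

#' Bliss-independence expected combined inhibition
#'
#' `Fa + Fb - Fa * Fb`: the combined inhibition expected if the two
#' perturbations act independently. Inputs are clipped to \[0, 1\] inside the
#' formula (raw values should be retained for reporting).
#'
#' @param Fa,Fb Fractional inhibitions of the two single perturbations.
#' @return Expected combined inhibition in \[0, 1\].
#' @export
#' @examples
#' expected_inhibition(0.5, 0.5) # 0.75
expected_inhibition <- function(Fa, Fb) {
  Fa <- pmin(pmax(Fa, 0), 1)
  Fb <- pmin(pmax(Fb, 0), 1)
  Fa + Fb - Fa * Fb
}

#' One-sample test of observed combined inhibition against the Bliss expectation
#'
#' Replicate-level observed inhibitions are tested against the (fixed)
#' expected inhibition with a one-sample t test. If the replicates have zero
#' variance the result is degenerate: p is 1 when they all equal the
#' expectation and 0 otherwise, flagged.
#'
#' @param observed Replicate-level observed combined inhibitions (>= 2).
#' @param expected Scalar Bliss expected inhibition.
#' @param alternative `"two.sided"` (default), `"greater"` (synergy only) or
#'   `"less"`.
#' @return A list with `p_value`, `statistic`, `df`, `degenerate`.
#' @export
synergy_test <- function(observed, expected,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(observed) < 2) {
    abort("need >= 2 replicate-level observed inhibitions",
          class = "cin_insufficient_data")
  }
  if (sd(observed) == 0) {
    return(list(p_value = if (isTRUE(all.equal(mean(observed), expected))) 1 else 0,
                statistic = NA_real_, df = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(observed, mu = expected, alternative = alternative)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), degenerate = FALSE)
}

bliss_groups <- function(metrics, drug, perturbation_line, reference_line,
                         vehicle) {
  pick <- function(line, d, label) {
    v <- metrics$auc[metrics$cell_line == line & metrics$drug == d]
    if (!length(v)) {
      abort(sprintf("design error: missing group '%s' (%s + %s)", label, line, d),
            class = "cin_design_error")
    }
    v
  }
  list(
    ref  = pick(reference_line, vehicle, "reference"),
    a    = pick(reference_line, drug, "drug-alone"),
    b    = pick(perturbation_line, vehicle, "perturbation-alone"),
    ab   = pick(perturbation_line, drug, "combination")
  )
}

#' Bliss excess of a drug x perturbation combination
#'
#' Computes, from per-well AUCs taken over one consistent grid and window:
#' `Fa` (drug alone vs the wild-type vehicle reference), `Fb` (perturbation
#' alone vs reference), the Bliss expected combined inhibition, the observed
#' combined inhibition, and the excess `observed - expected` (positive =
#' synergy). Each combination well yields a replicate-level observed
#' inhibition (its AUC against the mean reference AUC); the reported
#' `expected` is computed from the mean `Fa` and `Fb`.
#'
#' Significance: with the default `replicate_mode = "paired"`, replicate `i`'s
#' excess is computed from its own quartet of wells (same replicate index in
#' all four groups, including the reference):
#' `e_i = obs_i - (Fa_i + Fb_i - Fa_i * Fb_i)` with all inhibitions taken
#' against reference well `i`, and [synergy_test()] tests the `e_i` against
#' zero. The quartet excesses are then independent across replicates, which
#' keeps the test calibrated. `replicate_mode = "mean_expected"` instead tests the
#' per-well observed inhibitions against the expectation built from the mean
#' `Fa` and `Fb`, treated as fixed; that convention is anti-conservative under
#' measurement noise (the expectation's own sampling error is ignored) and is
#' provided for comparison. With `method = "bootstrap"`, a paired bootstrap
#' resampling wells of all four groups replaces the t test.
#'
#' Both the absolute excess (fraction of inhibition) and the relative excess
#' (`excess / expected`) are reported, since "X% stronger than additive" can
#' refer to either scale.
#'
#' @param metrics Per-well metrics (needs `cell_line`, `drug`, `auc`).
#' @param drug Drug id.
#' @param perturbation_line Cell line carrying the genotype/second
#'   perturbation.
#' @param reference_line Wild-type reference line.
#' @param vehicle Vehicle drug label.
#' @param alternative Sidedness of the significance test.
#' @param method `"t"` (default) or `"bootstrap"`.
#' @param replicate_mode `"paired"` (default) or `"mean_expected"`; see
#'   Details. Pairing requires equal group sizes and falls back to
#'   `"mean_expected"` with a warning otherwise.
#' @param n_boot Bootstrap resamples (when `method = "bootstrap"`).
#' @param window Optional window label carried into the output.
#' @return A one-row tibble: `drug`, `perturbation`, `window`, `Fa`, `Fb`,
#'   `expected`, `observed`, `excess`, `excess_relative`, `p_value`, `n_comb`,
#'   `degenerate`.
#' @export
bliss_excess <- function(metrics, drug, perturbation_line, reference_line,
                         vehicle = "DMSO",
                         alternative = c("two.sided", "greater", "less"),
                         method = c("t", "bootstrap"),
                         replicate_mode = c("paired", "mean_expected"),
                         n_boot = 2000,
                         window = NA_character_) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  replicate_mode <- match.arg(replicate_mode)
  g <- bliss_groups(metrics, drug, perturbation_line, reference_line, vehicle)
  ref_mean <- mean(g$ref)
  Fa <- fractional_inhibition(mean(g$a), ref_mean, warn = FALSE)
  Fb <- fractional_inhibition(mean(g$b), ref_mean, warn = FALSE)
  expected <- expected_inhibition(Fa, Fb)
  obs_rep <- fractional_inhibition(g$ab, ref_mean, warn = FALSE)
  observed <- mean(obs_rep)
  if (replicate_mode == "paired" && length(unique(lengths(g))) != 1L) {
    warn("unequal group sizes: falling back to replicate_mode = 'mean_expected'")
    replicate_mode <- "mean_expected"
  }

  if (method == "t") {
    ts <- if (replicate_mode == "paired") {
      # full quartet pairing: replicate i's excess uses its own reference
      # well, and the raw (unclipped) Bliss formula -- clipping per-replicate
      # inhibitions at 0 would bias the excesses under the null
      Fa_i <- fractional_inhibition(g$a, g$ref, warn = FALSE)
      Fb_i <- fractional_inhibition(g$b, g$ref, warn = FALSE)
      obs_i <- fractional_inhibition(g$ab, g$ref, warn = FALSE)
      synergy_test(obs_i - (Fa_i + Fb_i - Fa_i * Fb_i), 0,
                   alternative = alternative)
    } else {
      synergy_test(obs_rep, expected, alternative = alternative)
    }
    p <- ts$p_value
    degenerate <- ts$degenerate
  } else {
    boot_excess <- replicate(n_boot, {
      rm <- mean(sample(g$ref, replace = TRUE))
      fa <- expected_inhibition(
        fractional_inhibition(mean(sample(g$a, replace = TRUE)), rm, warn = FALSE),
        fractional_inhibition(mean(sample(g$b, replace = TRUE)), rm, warn = FALSE))
      mean(fractional_inhibition(sample(g$ab, replace = TRUE), rm, warn = FALSE)) - fa
    })
    p_low <- mean(boot_excess <= 0)
    p_high <- mean(boot_excess >= 0)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_low, p_high)),
                greater = p_low,
                less = p_high)
    degenerate <- FALSE
  }
  tibble(
    drug = drug, perturbation = perturbation_line, window = window,
    Fa = Fa, Fb = Fb, expected = expected, observed = observed,
    excess = observed - expected,
    excess_relative = if (expected > 0) (observed - expected) / expected else NA_real_,
    p_value = p, n_comb = length(obs_rep), degenerate = degenerate
  )
}

#' Bliss synergy across all drugs of a screen, optionally per time window
#'
#' Runs [bliss_excess()] for every non-vehicle drug against the perturbation
#' line. When `window_boundaries` is given, the screen is first split with
#' [split_time_windows()] and each window is analyzed with its own reference
#' AUCs (per-window metrics recomputed from scratch).
#'
#' @param screen Long-format screen table.
#' @param perturbation_line,reference_line,vehicle Condition labels.
#' @param window_boundaries Optional numeric day boundaries, e.g. `4` to get
#'   days 0-4 and days 4-8 windows; `NULL` analyzes the full run only.
#' @param auc_method AUC convention, see [compute_auc()].
#' @param ... Passed to [bliss_excess()].
#' @return A tibble with one row per drug x window.
#' @export
synergy_screen <- function(screen, perturbation_line, reference_line,
                           vehicle = "DMSO", window_boundaries = NULL,
                           auc_method = "sum", ...) {
  run_one <- function(tbl, window_label) {
    metrics <- screen_metrics(tbl, auc_method = auc_method,
                              vehicle = vehicle, slopes = FALSE)
    drugs <- setdiff(unique(metrics$drug), vehicle)
    bind_rows(lapply(drugs, function(d) {
      bliss_excess(metrics, d, perturbation_line, reference_line,
                   vehicle = vehicle, window = window_label, ...)
    }))
  }
  if (is.null(window_boundaries)) {
    return(run_one(screen, "full"))
  }
  windows <- split_time_windows(screen, window_boundaries)
  bind_rows(lapply(names(windows), function(w) run_one(windows[[w]], w)))
}
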