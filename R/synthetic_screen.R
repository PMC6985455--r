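#' Configuration for a synthetic confluency screen
#'
#' Bundles the generative parameters of the synthetic screen: logistic growth
#' toward a carrying capacity, per-genotype proliferation penalties, per-drug
#' multiplicative growth-rate inhibition, an optional greater-than-additive
#' interaction applied only in combination wells, a passage (split) event, and
#' multiplicative lognormal measurement noise.
#'
#' The defaults emulate an 8-day live-cell imaging screen: cells seeded at low
#' confluency in a 96-well plate, imaged every 2 h, passaged 1:8 on day 4, with
#' three technical replicates in each of three biological replicates. The CIN
#' (spindle-checkpoint knockdown) line carries a ~25% proliferation penalty and
#' the trisomic line a modest one.
#'
#' @param r_base Baseline exponential growth rate of the reference line
#'   (per hour). The default 0.04/h corresponds to a doubling time of ~17 h.
#' @param K Carrying capacity, in percent confluency (default 100).
#' @param c0 Seeding confluency in percent; must satisfy `0 < c0 < K`.
#' @param genotype_penalty Named numeric vector of multiplicative factors on
#'   `r_base`, one per cell line, each in \[0, 1\]. The first name is taken as
#'   the reference (wild-type) line unless `reference_line` is given.
#' @param drug_effect Named numeric vector of multiplicative factors on the
#'   growth rate, one per drug, each in \[0, 1\]. The vehicle always has
#'   effect 1 and need not be listed.
#' @param bliss_excess_rate Extra multiplicative rate reduction, applied only
#'   in combination wells (non-reference line and non-vehicle drug): the
#'   effective rate there is multiplied by `1 - bliss_excess_rate`. Either a
#'   scalar or a named per-drug vector; values in \[0, 1).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise applied to every observation (dimensionless).
#' @param bio_cv Coefficient of variation of the latent growth-rate multiplier
#'   shared by all technical replicates of one biological replicate (default 0:
#'   biological replicates are exact copies).
#' @param cadence_h Sampling interval in hours (2 h emulates an IncuCyte run,
#'   24 h emulates daily microscope images).
#' @param duration_h Total duration in hours.
#' @param passage_day Day of the 1:`split_ratio` passage, or `NULL` for no
#'   passage. Must fall strictly inside the observed duration.
#' @param split_ratio Dilution factor at passage (default 8, i.e. a 1:8 split).
#' @param n_bio,n_tech Numbers of biological and technical replicates.
#' @param seed Integer seed from which all randomness of the generator flows.
#' @param vehicle Drug label of the vehicle control (default `"DMSO"`).
#' @param reference_line Cell line used as the wild-type reference; defaults to
#'   the first name of `genotype_penalty`.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(duration_h = 96, n_bio = 2, n_tech = 2)
#' cfg$passage_day
sim_config <- function(r_base = 0.04,
                       K = 100,
                       c0 = 2,
                       genotype_penalty = c(RPE1 = 1, Mad2cKD = 0.75),
                       drug_effect = c(DMSO = 1),
                       bliss_excess_rate = 0,
                       noise_cv = 0.05,
                       bio_cv = 0,
                       cadence_h = 2,
                       duration_h = 192,
                       passage_day = 4,
                       split_ratio = 8,
                       n_bio = 3,
                       n_tech = 3,
                       seed = 1L,
                       vehicle = "DMSO",
                       reference_line = NULL) {
  if (!is.numeric(c0) || !is.numeric(K) || c0 <= 0 || c0 >= K) {
    abort("invalid config: seeding confluency `c0` must satisfy 0 < c0 < K",
          class = "cin_invalid_config")
  }
  if (r_base <= 0) abort("invalid config: `r_base` must be > 0",
                         class = "cin_invalid_config")
  if (is.null(names(genotype_penalty)) || any(names(genotype_penalty) == "")) {
    abort("`genotype_penalty` must be a fully named vector (one entry per cell line)",
          class = "cin_invalid_config")
  }
  stopifnot(all(genotype_penalty >= 0), all(genotype_penalty <= 1))
  if (length(drug_effect)) {
    if (is.null(names(drug_effect)) || any(names(drug_effect) == "")) {
      abort("`drug_effect` must be a fully named vector (one entry per drug)",
            class = "cin_invalid_config")
    }
    stopifnot(all(drug_effect >= 0), all(drug_effect <= 1))
  }
  if (any(bliss_excess_rate < 0) || any(bliss_excess_rate >= 1)) {
    abort("`bliss_excess_rate` must lie in [0, 1)", class = "cin_invalid_config")
  }
  if (cadence_h <= 0 || duration_h <= 0) {
    abort("`cadence_h` and `duration_h` must be > 0", class = "cin_invalid_config")
  }
  if (n_bio < 1 || n_tech < 1) {
    abort("`n_bio` and `n_tech` must be >= 1", class = "cin_invalid_config")
  }
  if (noise_cv < 0 || bio_cv < 0) {
    abort("noise coefficients of variation must be >= 0", class = "cin_invalid_config")
  }
  if (!is.null(passage_day)) {
    if (split_ratio < 1) abort("`split_ratio` must be >= 1", class = "cin_invalid_config")
    if (passage_day * 24 <= 0 || passage_day * 24 >= duration_h) {
      abort("invalid config: passage time falls outside the observed duration",
            class = "cin_invalid_config")
    }
  }
  if (is.null(reference_line)) reference_line <- names(genotype_penalty)[1]
  if (!reference_line %in% names(genotype_penalty)) {
    abort("`reference_line` must be one of the cell lines in `genotype_penalty`",
          class = "cin_invalid_config")
  }
  structure(
    list(r_base = r_base, K = K, c0 = c0,
         genotype_penalty = genotype_penalty, drug_effect = drug_effect,
         bliss_excess_rate = bliss_excess_rate,
         noise_cv = noise_cv, bio_cv = bio_cv,
         cadence_h = cadence_h, duration_h = duration_h,
         passage_day = passage_day, split_ratio = split_ratio,
         n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
         seed = as.integer(seed),
         vehicle = vehicle, reference_line = reference_line),
    class = "sim_config"
  )
}

time_grid <- function(config) seq(0, config$duration_h, by = config$cadence_h)

logistic_at <- function(t, c0, K, r) {
  K / (1 + ((K - c0) / c0) * exp(-r * t))
}

# Closed-form logistic with an optional instantaneous 1:split dilution of the
# state at passage_h; samples at t <= passage_h show the pre-split state.
noiseless_confluency <- function(times, c0, K, r, passage_h = NULL, split_ratio = 1) {
  if (is.null(passage_h) || split_ratio == 1) {
    return(logistic_at(times, c0, K, r))
  }
  out <- numeric(length(times))
  pre <- times <= passage_h
  out[pre] <- logistic_at(times[pre], c0, K, r)
  c_split <- logistic_at(passage_h, c0, K, r) / split_ratio
  out[!pre] <- logistic_at(times[!pre] - passage_h, c_split, K, r)
  out
}

lookup_named <- function(x, key, what) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!key %in% names(x)) {
    abort(sprintf("no %s entry for '%s'", what, key), class = "cin_invalid_config")
  }
  unname(x[[key]])
}

# Effective growth rate for one condition: r_base x genotype penalty x drug
# effect, further multiplied by (1 - bliss_excess_rate) in combination wells.
resolve_rate <- function(config, cell_line, drug) {
  gp <- lookup_named(config$genotype_penalty, cell_line, "genotype_penalty")
  de <- if (drug == config$vehicle) 1 else
    lookup_named(config$drug_effect, drug, "drug_effect")
  r <- config$r_base * gp * de
  if (cell_line != config$reference_line && drug != config$vehicle) {
    ber <- if (length(config$bliss_excess_rate) == 1L && is.null(names(config$bliss_excess_rate)))
      config$bliss_excess_rate
    else if (drug %in% names(config$bliss_excess_rate))
      unname(config$bliss_excess_rate[[drug]])
    else 0
    r <- r * (1 - ber)
  }
  r
}

#' Simulate one noiseless logistic confluency curve
#'
#' Samples the logistic closed form
#' \deqn{C(t) = K / (1 + ((K - c_0)/c_0)\,e^{-r_{\mathrm{eff}} t})}
#' at the configured cadence, where the effective rate resolves the condition's
#' genotype penalty, drug effect, and (in combination wells) the injected
#' interaction. No passage and no noise are applied here; see
#' [apply_noise_and_passage()].
#'
#' @param config A [sim_config()].
#' @param cell_line,drug Condition labels; must resolve against the config's
#'   `genotype_penalty` and `drug_effect`.
#' @param dose_uM Dose label carried through to the output (not used in the
#'   rate model; dose enters via `drug_effect`).
#' @return A tibble (one well's series) with columns `cell_line`, `drug`,
#'   `dose_uM`, `time_h`, `confluency_pct`, carrying the effective rate as
#'   attribute `"r_eff"`.
#' @export
#' @examples
#' cfg <- sim_config(duration_h = 48, passage_day = NULL)
#' head(simulate_logistic_curve(cfg, "RPE1", "DMSO"))
simulate_logistic_curve <- function(config, cell_line, drug, dose_uM = 0) {
  stopifnot(inherits(config, "sim_config"))
  r_eff <- resolve_rate(config, cell_line, drug)
  times <- time_grid(config)
  out <- tibble(
    cell_line = cell_line, drug = drug, dose_uM = dose_uM,
    time_h = times,
    confluency_pct = logistic_at(times, config$c0, config$K, r_eff)
  )
  attr(out, "r_eff") <- r_eff
  out
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Apply the passage event and measurement noise to a noiseless curve
#'
#' At the passage time the logistic state is divided by the split ratio and
#' growth continues from the diluted state (an instantaneous 1:`split_ratio`
#' split of adherent cells). Each observation is then multiplied by lognormal
#' noise with unit mean and coefficient of variation `noise_cv`, and clipped
#' to `[0, K]`. Deterministic given `seed`.
#'
#' @param series A noiseless well series from [simulate_logistic_curve()].
#' @param config The [sim_config()] used to generate it.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return The series with passage and noise applied.
#' @export
apply_noise_and_passage <- function(series, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  r_eff <- attr(series, "r_eff")
  if (is.null(r_eff)) {
    r_eff <- resolve_rate(config, series$cell_line[1], series$drug[1])
  }
  times <- series$time_h
  if (!is.null(config$passage_day)) {
    passage_h <- config$passage_day * 24
    if (passage_h >= max(times)) {
      abort("passage time falls outside the observed duration",
            class = "cin_invalid_config")
    }
    series$confluency_pct <- noiseless_confluency(
      times, config$c0, config$K, r_eff,
      passage_h = passage_h, split_ratio = config$split_ratio
    )
  }
  draw <- function() {
    eps <- lognormal_noise(length(times), config$noise_cv)
    series$confluency_pct <- pmin(pmax(series$confluency_pct * eps, 0), config$K)
    series
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Build a screen design table
#'
#' @param cell_lines Character vector of cell lines.
#' @param drugs Character vector of drugs (the vehicle is added if missing).
#' @param doses Optional named numeric vector of doses per drug (uM).
#' @param vehicle Vehicle drug label.
#' @return A tibble with columns `cell_line`, `drug`, `dose_uM`: the full
#'   crossing, every cell line carrying a vehicle control.
#' @export
screen_design <- function(cell_lines, drugs, doses = NULL, vehicle = "DMSO") {
  drugs <- union(vehicle, drugs)
  design <- tidyr::expand_grid(cell_line = cell_lines, drug = drugs)
  design$dose_uM <- ifelse(design$drug == vehicle, 0,
                           if (is.null(doses)) 1 else unname(doses[design$drug]))
  design
}

#' Simulate a full confluency screen with known ground truth
#'
#' Expands a condition design into `n_bio x n_tech` wells per condition,
#' simulates each well's logistic curve (with the configured passage event and
#' multiplicative noise), and returns both the long-format screen table and
#' the ground truth computed from the noiseless curves. Technical replicates
#' share their biological replicate's latent growth rate, which is drawn with
#' between-replicate coefficient of variation `bio_cv` (default 0).
#'
#' Ground-truth fractional inhibitions use the same sum-over-timepoints AUC
#' convention as [compute_auc()], so recovery tests compare like with like.
#'
#' @param design A tibble with columns `cell_line`, `drug` and optionally
#'   `dose_uM` (see [screen_design()]). Every cell line must include a vehicle
#'   control condition.
#' @param config A [sim_config()].
#' @return A list of class `cin_sim` with elements `screen` (tidy well-level
#'   table: plate, well, cell_line, drug, dose_uM, bio_rep, tech_rep, time_h,
#'   confluency_pct), `truth` (list with `conditions` and `synergy` tibbles),
#'   `config`, and `design`.
#' @export
#' @examples
#' cfg <- sim_config(duration_h = 96, passage_day = NULL, seed = 7)
#' sim <- simulate_screen(screen_design("RPE1", "drugA"), cfg)
#' nrow(sim$screen)
simulate_screen <- function(design, config) {
  stopifnot(inherits(config, "sim_config"))
  design <- as_tibble(design)
  if (!all(c("cell_line", "drug") %in% names(design))) {
    abort("design needs columns `cell_line` and `drug`", class = "cin_design_error")
  }
  if (!"dose_uM" %in% names(design)) design$dose_uM <- 0
  missing_ctrl <- setdiff(unique(design$cell_line),
                          design$cell_line[design$drug == config$vehicle])
  if (length(missing_ctrl)) {
    abort(sprintf("design error: no %s control for cell line(s): %s",
                  config$vehicle, paste(missing_ctrl, collapse = ", ")),
          class = "cin_design_error")
  }

  times <- time_grid(config)
  n_t <- length(times)
  passage_h <- if (is.null(config$passage_day)) NULL else config$passage_day * 24

  pieces <- withr::with_seed(config$seed, {
    lapply(seq_len(nrow(design)), function(i) {
      r0 <- resolve_rate(config, design$cell_line[i], design$drug[i])
      bio_mult <- lognormal_noise(config$n_bio, config$bio_cv)
      per_bio <- lapply(seq_len(config$n_bio), function(b) {
        base_curve <- noiseless_confluency(times, config$c0, config$K,
                                           r0 * bio_mult[b],
                                           passage_h, config$split_ratio)
        eps <- matrix(lognormal_noise(n_t * config$n_tech, config$noise_cv),
                      nrow = n_t, ncol = config$n_tech)
        conf <- pmin(pmax(base_curve * eps, 0), config$K)
        tibble(
          plate = sprintf("B%d", b),
          well = rep(sprintf("W%03d", (i - 1L) * config$n_tech + seq_len(config$n_tech)),
                     each = n_t),
          cell_line = design$cell_line[i],
          drug = design$drug[i],
          dose_uM = design$dose_uM[i],
          bio_rep = b,
          tech_rep = rep(seq_len(config$n_tech), each = n_t),
          time_h = rep(times, config$n_tech),
          confluency_pct = as.vector(conf)
        )
      })
      bind_rows(per_bio)
    })
  })
  screen <- bind_rows(pieces)
  truth <- ground_truth(design, config)
  structure(list(screen = screen, truth = truth, config = config, design = design),
            class = "cin_sim")
}

noiseless_auc <- function(config, cell_line, drug, window_days = NULL,
                          boundary = "shared") {
  times <- time_grid(config)
  passage_h <- if (is.null(config$passage_day)) NULL else config$passage_day * 24
  r <- resolve_rate(config, cell_line, drug)
  conf <- noiseless_confluency(times, config$c0, config$K, r,
                               passage_h, config$split_ratio)
  if (!is.null(window_days)) {
    keep <- select_window(times, window_days[1] * 24, window_days[2] * 24,
                          boundary = boundary,
                          is_last = window_days[2] * 24 >= max(times))
    conf <- conf[keep]
  }
  sum(conf)
}

#' Ground truth for a simulated screen
#'
#' Computes, from the noiseless curves, each condition's effective rate and
#' AUC (sum convention), and for every drug x non-reference line pair present
#' with all four Bliss groups, the true fractional inhibitions, expected and
#' observed combined inhibition, and Bliss excess.
#'
#' @param design,config As in [simulate_screen()].
#' @param window_days Optional `c(start, end)` window in days over which AUCs
#'   are taken (both endpoints' samples included); default is the full run.
#' @return A list with tibbles `conditions` and `synergy`.
#' @export
ground_truth <- function(design, config, window_days = NULL) {
  design <- as_tibble(design)
  if (!"dose_uM" %in% names(design)) design$dose_uM <- 0
  conditions <- design %>%
    mutate(
      r_eff = purrr::map2_dbl(.data$cell_line, .data$drug,
                              ~ resolve_rate(config, .x, .y)),
      auc_noiseless = purrr::map2_dbl(.data$cell_line, .data$drug,
                                      ~ noiseless_auc(config, .x, .y, window_days))
    )
  ref <- config$reference_line
  veh <- config$vehicle
  auc_of <- function(line, drug) {
    hit <- conditions$cell_line == line & conditions$drug == drug
    if (!any(hit)) return(NA_real_)
    conditions$auc_noiseless[which(hit)[1]]
  }
  auc_ref <- auc_of(ref, veh)
  pairs <- conditions %>%
    filter(.data$cell_line != ref, .data$drug != veh) %>%
    select("cell_line", "drug", "dose_uM")
  synergy <- pairs %>%
    mutate(
      Fa = 1 - purrr::map_dbl(.data$drug, ~ auc_of(ref, .x)) / auc_ref,
      Fb = 1 - purrr::map_dbl(.data$cell_line, ~ auc_of(.x, veh)) / auc_ref,
      observed = 1 - purrr::map2_dbl(.data$cell_line, .data$drug, auc_of) / auc_ref,
      expected = expected_inhibition(.data$Fa, .data$Fb),
      excess = .data$observed - .data$expected,
      excess_relative = ifelse(.data$expected > 0,
                               .data$excess / .data$expected, NA_real_)
    ) %>%
    filter(!is.na(.data$observed), !is.na(.data$Fa), !is.na(.data$Fb))
  list(conditions = conditions, synergy = synergy)
}

#' Solve for the interaction rate giving a target AUC-scale Bliss excess
#'
#' The generator injects interaction on the growth rate; the AUC-scale excess
#' it induces is a monotone function of that rate. This helper inverts the
#' relation numerically so simulations can be parameterized by the true
#' AUC-scale excess.
#'
#' @param config A [sim_config()]; its `bliss_excess_rate` is overridden.
#' @param cell_line,drug Combination condition to calibrate on.
#' @param target_excess Desired true Bliss excess: a fraction of inhibition
#'   when `scale = "absolute"` (observed - expected), or a fraction *of the
#'   expected inhibition* when `scale = "relative"`
#'   ((observed - expected) / expected, the "X% stronger than additive"
#'   reading).
#' @param window_days Optional analysis window in days (see [ground_truth()]).
#' @param scale `"absolute"` (default) or `"relative"`.
#' @return The `bliss_excess_rate` value (scalar) achieving the target.
#' @export
calibrate_excess_rate <- function(config, cell_line, drug, target_excess,
                                  window_days = NULL,
                                  scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  stopifnot(target_excess >= 0)
  if (target_excess == 0) return(0)
  design <- tibble(cell_line = c(config$reference_line, config$reference_line,
                                 cell_line, cell_line),
                   drug = c(config$vehicle, drug, config$vehicle, drug))
  excess_at <- function(rate) {
    cfg <- config
    cfg$bliss_excess_rate <- rate
    truth <- ground_truth(design, cfg, window_days)$synergy
    val <- if (scale == "absolute") truth$excess[1] else truth$excess_relative[1]
    val - target_excess
  }
  uniroot(excess_at, c(0, 0.9999), tol = 1e-8)$root
}
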