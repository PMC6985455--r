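# shared fixtures: small configurations and screens built in code

quiet_config <- function(...) {
  args <- list(...)
  defaults <- list(duration_h = 96, cadence_h = 2, passage_day = NULL,
                   noise_cv = 0, n_bio = 2, n_tech = 2, seed = 1L)
  do.call(sim_config, modifyList(defaults, args))
}

# noiseless two-line, one-drug screen with configurable effects
two_line_screen <- function(penalty = 0.75, effect = 0.8, excess_rate = 0,
                            noise_cv = 0, seed = 1L, n_bio = 3, n_tech = 3,
                            duration_h = 96, passage_day = NULL) {
  cfg <- sim_config(duration_h = duration_h, passage_day = passage_day,
                    noise_cv = noise_cv, n_bio = n_bio, n_tech = n_tech,
                    seed = seed,
                    genotype_penalty = c(RPE1 = 1, Mad2cKD = penalty),
                    drug_effect = c(DMSO = 1, drugA = effect),
                    bliss_excess_rate = excess_rate)
  simulate_screen(screen_design(c("RPE1", "Mad2cKD"), "drugA"), cfg)
}

# a single well series from the logistic closed form (independent of the
# generator's internals)
logistic_series <- function(times, c0, K, r) {
  tibble::tibble(time_h = times,
                 confluency_pct = K / (1 + ((K - c0) / c0) * exp(-r * times)))
}
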