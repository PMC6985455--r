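#!/usr/bin/env Rscript

# Simulate the two synthetic compound screens the rest of the workflow
# analyzes: an "aneuploidy" screen (reference RPE1 line vs a stable trisomic
# line with a modest growth penalty) and a "CIN" screen (RPE1 vs an inducible
# spindle-checkpoint-knockdown line with a ~25% penalty). Both run 8 days
# with a 1:8 passage on day 4, sampled every 2 h, 3 biological x 3 technical
# replicates, 5% multiplicative measurement noise. A handful of drugs carry
# an injected greater-than-additive interaction with the perturbed genotype;
# the rest are additive on the growth rate.

library(cinsynergy)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

seed <- 20260924L

drugs <- sprintf("drug%02d", 1:20)
effects <- setNames(rep(c(1, 0.95, 0.9, 0.85, 0.8), 4), drugs)

message("simulating aneuploidy screen (RPE1 vs Ts12Ts5, 20 drugs) ...")
cfg_aneu <- sim_config(
  duration_h = 192, passage_day = 4, noise_cv = 0.05, seed = seed,
  genotype_penalty = c(RPE1 = 1, Ts12Ts5 = 0.9),
  drug_effect = c(DMSO = 1, effects),
  bliss_excess_rate = c(drug07 = 0.35))   # one synergistic compound
sim_aneu <- simulate_screen(screen_design(c("RPE1", "Ts12Ts5"), drugs),
                            cfg_aneu)

message("simulating CIN screen (RPE1 vs Mad2cKD, 20 drugs) ...")
cfg_cin <- sim_config(
  duration_h = 192, passage_day = 4, noise_cv = 0.05, seed = seed + 1L,
  genotype_penalty = c(RPE1 = 1, Mad2cKD = 0.75),
  drug_effect = c(DMSO = 1, effects),
  bliss_excess_rate = c(drug03 = 0.45, drug12 = 0.3))
sim_cin <- simulate_screen(screen_design(c("RPE1", "Mad2cKD"), drugs),
                           cfg_cin)

write_stage_csv(sim_aneu$screen, "scratch/screen_aneuploidy.csv",
                "simulate", cfg_aneu)
write_stage_csv(sim_cin$screen, "scratch/screen_cin.csv",
                "simulate", cfg_cin)
write_stage_csv(sim_aneu$truth$synergy, "results/truth_aneuploidy.csv",
                "simulate", cfg_aneu)
write_stage_csv(sim_cin$truth$synergy, "results/truth_cin.csv",
                "simulate", cfg_cin)

message(sprintf("aneuploidy screen: %d rows; CIN screen: %d rows",
                nrow(sim_aneu$screen), nrow(sim_cin$screen)))
message("true non-additive combinations (|excess| > 0.02):")
for (sim in list(sim_aneu, sim_cin)) {
  tr <- sim$truth$synergy
  hit <- tr[abs(tr$excess) > 0.02, c("drug", "cell_line", "excess")]
  print(as.data.frame(hit), row.names = FALSE)
}
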