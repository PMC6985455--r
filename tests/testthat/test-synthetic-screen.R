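test_that("logistic curve hits its closed-form boundaries", {
  cfg <- quiet_config(c0 = 5)
  s <- simulate_logistic_curve(cfg, "RPE1", "DMSO")
  expect_equal(s$confluency_pct[s$time_h == 0], 5)

  # zero effective rate: constant series at the seeding confluency
  cfg0 <- quiet_config(c0 = 5, drug_effect = c(DMSO = 1, dead = 0))
  s0 <- simulate_logistic_curve(cfg0, "RPE1", "dead")
  expect_equal(s0$confluency_pct, rep(5, nrow(s0)))
})

test_that("logistic samples match an independent ODE integration", {
  skip_if_not_installed("deSolve")
  cfg <- quiet_config(c0 = 5, r_base = 0.05, duration_h = 48)
  s <- simulate_logistic_curve(cfg, "RPE1", "DMSO")
  ode_out <- deSolve::ode(
    y = c(C = 5), times = seq(0, 48, by = 2),
    func = function(t, y, p) list(0.05 * y * (1 - y / 100)),
    rtol = 1e-10, atol = 1e-10)
  expect_equal(s$confluency_pct, unname(ode_out[, "C"]), tolerance = 1e-7)
  expect_equal(s$confluency_pct[s$time_h == 48],
               unname(ode_out[ode_out[, "time"] == 48, "C"]),
               tolerance = 1e-7)
})

test_that("invalid seeding confluency is rejected", {
  expect_error(sim_config(c0 = 0), class = "cin_invalid_config")
  expect_error(sim_config(c0 = -3), class = "cin_invalid_config")
  expect_error(sim_config(c0 = 120, K = 100), class = "cin_invalid_config")
  expect_error(sim_config(duration_h = 96, passage_day = 10),
               class = "cin_invalid_config")
})

test_that("noise-free, passage-free transformation is the identity", {
  cfg <- quiet_config()
  s <- simulate_logistic_curve(cfg, "RPE1", "DMSO")
  expect_identical(apply_noise_and_passage(s, cfg, seed = 1), s)
})

test_that("passage divides the logistic state by the split ratio", {
  cfg <- sim_config(duration_h = 192, cadence_h = 2, passage_day = 4,
                    split_ratio = 8, noise_cv = 0)
  s <- simulate_logistic_curve(cfg, "RPE1", "DMSO")
  out <- apply_noise_and_passage(s, cfg, seed = 1)
  pre <- out$confluency_pct[out$time_h == 96]
  # the state just after the split is the pre-split value / 8
  post_limit <- cinsynergy:::noiseless_confluency(
    96 + 1e-9, cfg$c0, cfg$K, attr(s, "r_eff"),
    passage_h = 96, split_ratio = 8)
  expect_equal(post_limit, pre / 8, tolerance = 1e-6)
  # later samples follow a logistic restarted from the diluted state
  expected_98 <- 100 / (1 + ((100 - pre / 8) / (pre / 8)) *
                          exp(-attr(s, "r_eff") * 2))
  expect_equal(out$confluency_pct[out$time_h == 98], expected_98,
               tolerance = 1e-10)
})

test_that("multiplicative noise has the configured CV and unit mean", {
  draws <- withr::with_seed(5, cinsynergy:::lognormal_noise(10000, 0.05))
  expect_lt(abs(sd(draws) / mean(draws) - 0.05) / 0.05, 0.1)
  expect_lt(abs(mean(draws) - 1), 0.005)
})

test_that("screen expansion produces the expected rows with full labels", {
  cfg <- sim_config(duration_h = 96, cadence_h = 2, passage_day = NULL,
                    n_bio = 3, n_tech = 3, seed = 2,
                    drug_effect = c(DMSO = 1, drugA = 0.8))
  sim <- simulate_screen(screen_design(c("RPE1", "Mad2cKD"), "drugA"), cfg)
  # 4 conditions x 9 wells x 49 time points
  expect_equal(nrow(sim$screen), 4 * 9 * 49)
  expect_false(any(is.na(sim$screen)))
  expect_equal(dplyr::n_distinct(sim$screen[c("plate", "well")]), 4 * 9)
})

test_that("a missing vehicle control is a design error", {
  cfg <- quiet_config(drug_effect = c(DMSO = 1, drugA = 0.8))
  bad <- tibble::tibble(cell_line = c("RPE1", "RPE1", "Mad2cKD"),
                        drug = c("DMSO", "drugA", "drugA"))
  expect_error(simulate_screen(bad, cfg), class = "cin_design_error")
})

test_that("ground truth is exactly null when either factor is absent", {
  # all-null: no penalty, no drug effect, no interaction
  sim <- two_line_screen(penalty = 1, effect = 1, excess_rate = 0)
  expect_equal(sim$truth$synergy$Fa, 0, tolerance = 1e-12)
  expect_equal(sim$truth$synergy$Fb, 0, tolerance = 1e-12)
  expect_equal(sim$truth$synergy$excess, 0, tolerance = 1e-12)
  # no genotype penalty: combination equals drug-alone, excess exactly 0
  sim2 <- two_line_screen(penalty = 1, effect = 0.7, excess_rate = 0)
  expect_equal(sim2$truth$synergy$excess, 0, tolerance = 1e-12)
})

test_that("rate-level independence maps to near-zero AUC-scale excess", {
  # Bliss additivity on AUC-derived inhibitions is not an identity for
  # rate-multiplicative effects; the residual must stay small
  sim <- two_line_screen(penalty = 0.75, effect = 0.8, excess_rate = 0,
                         duration_h = 192, passage_day = 4)
  expect_lt(abs(sim$truth$synergy$excess), 0.01)
})

test_that("ground-truth excess equals a brute-force re-simulation", {
  cfg <- sim_config(duration_h = 120, cadence_h = 2, passage_day = 4,
                    split_ratio = 8, noise_cv = 0, seed = 9,
                    genotype_penalty = c(RPE1 = 1, Mad2cKD = 0.8),
                    drug_effect = c(DMSO = 1, drugA = 0.7),
                    bliss_excess_rate = 0.25)
  sim <- simulate_screen(screen_design(c("RPE1", "Mad2cKD"), "drugA"), cfg)

  # independent oracle: closed-form curves with a manual split, summed
  curve <- function(r) {
    t <- seq(0, 120, by = 2)
    pre <- 100 / (1 + ((100 - 2) / 2) * exp(-r * t))
    c96 <- (100 / (1 + ((100 - 2) / 2) * exp(-r * 96))) / 8
    post <- 100 / (1 + ((100 - c96) / c96) * exp(-r * (t - 96)))
    sum(ifelse(t <= 96, pre, post))
  }
  r <- 0.04
  auc_ref <- curve(r)
  Fa <- 1 - curve(r * 0.7) / auc_ref
  Fb <- 1 - curve(r * 0.8) / auc_ref
  observed <- 1 - curve(r * 0.8 * 0.7 * (1 - 0.25)) / auc_ref
  excess <- observed - (Fa + Fb - Fa * Fb)
  expect_equal(sim$truth$synergy$excess, excess, tolerance = 1e-12)
  expect_equal(sim$truth$synergy$Fa, Fa, tolerance = 1e-12)
})

test_that("fixed seeds reproduce the screen bit for bit", {
  a <- two_line_screen(noise_cv = 0.05, seed = 7)
  b <- two_line_screen(noise_cv = 0.05, seed = 7)
  c <- two_line_screen(noise_cv = 0.05, seed = 8)
  expect_identical(a$screen, b$screen)
  expect_false(identical(a$screen, c$screen))
})

test_that("noiseless curves are monotone between passages and bounded by K", {
  for (r in c(0.01, 0.04, 0.1)) {
    cfg <- quiet_config(r_base = r)
    s <- simulate_logistic_curve(cfg, "RPE1", "DMSO")
    expect_true(all(diff(s$confluency_pct) >= 0))
    expect_true(all(s$confluency_pct <= cfg$K))
    # with a passage: monotone within each segment
    cfg2 <- sim_config(r_base = r, duration_h = 192, passage_day = 4,
                       noise_cv = 0)
    s2 <- apply_noise_and_passage(
      simulate_logistic_curve(cfg2, "RPE1", "DMSO"), cfg2, seed = 1)
    seg1 <- s2$confluency_pct[s2$time_h <= 96]
    seg2 <- s2$confluency_pct[s2$time_h > 96]
    expect_true(all(diff(seg1) >= 0))
    expect_true(all(diff(seg2) >= 0))
    expect_true(all(s2$confluency_pct <= cfg2$K))
  }
})

test_that("excess-rate calibration inverts the truth relation", {
  cfg <- sim_config(duration_h = 96, passage_day = NULL, noise_cv = 0,
                    genotype_penalty = c(RPE1 = 1, Mad2cKD = 0.75),
                    drug_effect = c(DMSO = 1, drugA = 0.8))
  for (tgt in c(0.05, 0.2)) {
    rate <- calibrate_excess_rate(cfg, "Mad2cKD", "drugA", tgt)
    cfg2 <- cfg
    cfg2$bliss_excess_rate <- rate
    sim <- simulate_screen(screen_design(c("RPE1", "Mad2cKD"), "drugA"), cfg2)
    expect_equal(sim$truth$synergy$excess, tgt, tolerance = 1e-6)
  }
  expect_equal(calibrate_excess_rate(cfg, "Mad2cKD", "drugA", 0), 0)
})
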