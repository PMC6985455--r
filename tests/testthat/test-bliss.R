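test_that("fractional inhibition follows its definition and flags edge cases", {
  expect_equal(fractional_inhibition(100, 100, warn = FALSE), 0)
  expect_equal(fractional_inhibition(0, 100, warn = FALSE), 1)
  expect_equal(fractional_inhibition(c(50, 25), 100, warn = FALSE),
               c(0.5, 0.75))
  expect_error(fractional_inhibition(50, 0), class = "cin_division_error")
  expect_warning(fractional_inhibition(120, 100), "stimulation")
})

test_that("Bliss expectation is exact, symmetric, and monotone", {
  expect_equal(expected_inhibition(0, 0.3), 0.3)
  expect_equal(expected_inhibition(0.5, 0.5), 0.75)
  for (x in c(0, 0.2, 0.7, 1)) expect_equal(expected_inhibition(1, x), 1)
  grid <- seq(0, 1, by = 0.1)
  for (fa in grid) {
    expect_equal(expected_inhibition(fa, grid), expected_inhibition(grid, fa))
    expect_true(all(diff(expected_inhibition(fa, grid)) >= -1e-12))
    expect_true(all(expected_inhibition(fa, grid) >= pmax(fa, grid) - 1e-12))
  }
})

test_that("synergy test conventions on degenerate replicates", {
  expect_equal(synergy_test(rep(0.4, 5), 0.4)$p_value, 1)
  expect_true(synergy_test(rep(0.4, 5), 0.4)$degenerate)
  expect_equal(synergy_test(rep(0.5, 5), 0.4)$p_value, 0)
  expect_error(synergy_test(0.4, 0.4), class = "cin_insufficient_data")
})

test_that("synergy test detects a 3-SD shift with high power", {
  sd0 <- 0.01
  rejections <- withr::with_seed(61, vapply(1:200, function(i) {
    obs <- rnorm(9, mean = 0.4 + 3 * sd0, sd = sd0)
    synergy_test(obs, 0.4)$p_value < 0.05
  }, logical(1)))
  expect_gte(mean(rejections), 0.9)
})

test_that("excess is invariant to rescaling all AUCs", {
  sim <- two_line_screen(penalty = 0.8, effect = 0.7, excess_rate = 0.3,
                         noise_cv = 0.03, seed = 13)
  m <- screen_metrics(sim$screen, slopes = FALSE)
  r1 <- bliss_excess(m, "drugA", "Mad2cKD", "RPE1")
  m2 <- m
  m2$auc <- m2$auc * 7.3
  r2 <- bliss_excess(m2, "drugA", "Mad2cKD", "RPE1")
  expect_equal(r2$excess, r1$excess, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
})

test_that("a missing Bliss group is a design error naming the group", {
  sim <- two_line_screen(seed = 2)
  m <- screen_metrics(sim$screen, slopes = FALSE)
  err <- tryCatch(
    bliss_excess(m[m$drug == "DMSO" | m$cell_line == "RPE1", ],
                 "drugA", "Mad2cKD", "RPE1"),
    error = function(e) e)
  expect_s3_class(err, "cin_design_error")
  expect_match(conditionMessage(err), "combination")
})

test_that("additive-null screens give near-zero estimated excess", {
  # under the study conditions (8 d, 1:8 passage on day 4) the rate-level
  # null leaves only a small AUC-scale Bliss residual
  sim <- two_line_screen(penalty = 0.75, effect = 0.8, excess_rate = 0,
                         noise_cv = 0.05, seed = 41,
                         duration_h = 192, passage_day = 4)
  m <- screen_metrics(sim$screen, slopes = FALSE)
  est <- bliss_excess(m, "drugA", "Mad2cKD", "RPE1")
  expect_lt(abs(est$excess), 0.02)
  expect_lt(abs(est$excess - sim$truth$synergy$excess), 0.02)
})

test_that("an injected excess of 0.15 is recovered within 0.03", {
  cfg0 <- sim_config(duration_h = 96, passage_day = NULL, noise_cv = 0.05,
                     seed = 43,
                     genotype_penalty = c(RPE1 = 1, Mad2cKD = 0.75),
                     drug_effect = c(DMSO = 1, drugA = 0.8))
  rate <- calibrate_excess_rate(cfg0, "Mad2cKD", "drugA", 0.15)
  cfg0$bliss_excess_rate <- rate
  sim <- simulate_screen(screen_design(c("RPE1", "Mad2cKD"), "drugA"), cfg0)
  m <- screen_metrics(sim$screen, slopes = FALSE)
  est <- bliss_excess(m, "drugA", "Mad2cKD", "RPE1")
  expect_lt(abs(est$excess - sim$truth$synergy$excess), 0.03)
  expect_lt(est$p_value, 0.05)
})

test_that("the paired bootstrap agrees with the t test on a clear synergy", {
  sim <- two_line_screen(penalty = 0.8, effect = 0.8, excess_rate = 0.5,
                         noise_cv = 0.05, seed = 47)
  m <- screen_metrics(sim$screen, slopes = FALSE)
  pt_ <- bliss_excess(m, "drugA", "Mad2cKD", "RPE1")
  pb <- withr::with_seed(48,
    bliss_excess(m, "drugA", "Mad2cKD", "RPE1", method = "bootstrap",
                 n_boot = 500))
  expect_lt(pt_$p_value, 0.01)
  expect_lt(pb$p_value, 0.05)
  expect_equal(pb$excess, pt_$excess)
})

test_that("the mean-expected replicate convention is available", {
  sim <- two_line_screen(penalty = 0.8, effect = 0.8, excess_rate = 0.4,
                         noise_cv = 0.05, seed = 53)
  m <- screen_metrics(sim$screen, slopes = FALSE)
  a <- bliss_excess(m, "drugA", "Mad2cKD", "RPE1",
                    replicate_mode = "mean_expected")
  b <- bliss_excess(m, "drugA", "Mad2cKD", "RPE1")
  expect_equal(a$excess, b$excess)  # point estimate unaffected by the mode
  expect_lt(a$p_value, 0.05)
})

test_that("windowed synergy re-references each window", {
  cfg <- sim_config(duration_h = 192, passage_day = 4, noise_cv = 0.03,
                    seed = 59,
                    genotype_penalty = c(RPE1 = 1, Mad2cKD = 0.75),
                    drug_effect = c(DMSO = 1, drugA = 0.85),
                    bliss_excess_rate = 0.3)
  sim <- simulate_screen(screen_design(c("RPE1", "Mad2cKD"), "drugA"), cfg)
  syn <- synergy_screen(sim$screen, "Mad2cKD", "RPE1", window_boundaries = 4)
  expect_setequal(syn$window, c("d0-4", "d4-8"))
  for (w in c("d0-4", "d4-8")) {
    truth_w <- ground_truth(sim$design, cfg,
                            window_days = if (w == "d0-4") c(0, 4) else c(4, 8))
    expect_equal(syn$excess[syn$window == w],
                 truth_w$synergy$excess, tolerance = 0.03)
  }
})

test_that("large-replicate additive-null excess is unbiased", {
  cfg <- sim_config(duration_h = 96, passage_day = NULL, noise_cv = 0.05,
                    n_bio = 5, n_tech = 5,
                    genotype_penalty = c(RPE1 = 1, Mad2cKD = 0.75),
                    drug_effect = c(DMSO = 1, drugA = 0.8))
  des <- screen_design(c("RPE1", "Mad2cKD"), "drugA")
  errs <- vapply(1:12, function(i) {
    cfg$seed <- 700L + i
    sim <- simulate_screen(des, cfg)
    m <- screen_metrics(sim$screen, slopes = FALSE)
    bliss_excess(m, "drugA", "Mad2cKD", "RPE1")$excess -
      sim$truth$synergy$excess
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.005)
})
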