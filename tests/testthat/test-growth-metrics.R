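test_that("AUC conventions agree with arithmetic and quadrature", {
  flat <- tibble::tibble(time_h = seq(0, 8, by = 2),
                         confluency_pct = rep(10, 5))
  expect_equal(compute_auc(flat, "sum"), 50)
  zero <- tibble::tibble(time_h = 0:4, confluency_pct = rep(0, 5))
  expect_equal(compute_auc(zero, "sum"), 0)
  expect_equal(compute_auc(zero, "trapezoid"), 0)

  # trapezoid on 2-h samples of a logistic vs adaptive quadrature
  f <- function(t) 100 / (1 + ((100 - 2) / 2) * exp(-0.05 * t))
  s <- logistic_series(seq(0, 96, by = 2), 2, 100, 0.05)
  exact <- integrate(f, 0, 96, rel.tol = 1e-10)$value
  expect_lt(abs(compute_auc(s, "trapezoid") - exact) / exact, 0.005)
})

test_that("series validation rejects malformed input", {
  expect_error(compute_auc(tibble::tibble(time_h = 1, confluency_pct = 5)),
               class = "cin_invalid_series")
  expect_error(
    compute_auc(tibble::tibble(time_h = c(0, 0, 2),
                               confluency_pct = c(1, 2, 3))),
    class = "cin_invalid_series")
  expect_error(
    compute_auc(tibble::tibble(time_h = 0:2, confluency_pct = c(1, -2, 3))),
    class = "cin_invalid_series")
})

test_that("a noiseless exponential stays log-linear to the last point", {
  s <- tibble::tibble(time_h = seq(0, 48, by = 2),
                      confluency_pct = 5 * exp(0.05 * seq(0, 48, by = 2)))
  for (r2 in c(0.9, 0.99, 0.999, 1)) {
    expect_equal(detect_exponential_cutoff(s, r2_min = r2)$cutoff_time, 48)
  }
})

test_that("cutoff detection equals exhaustive expanding-window search", {
  s <- logistic_series(seq(0, 120, by = 2), 1, 100, 0.1)
  # oracle: fit every expanding window with lm and take the largest
  # qualifying endpoint
  oracle <- function(series, r2_min, min_points) {
    y <- log(series$confluency_pct)
    t <- series$time_h
    best <- NA_real_
    for (k in min_points:length(t)) {
      fit <- lm(y[1:k] ~ t[1:k])
      r2 <- summary(fit)$r.squared
      if (r2 >= r2_min) best <- t[k]
    }
    best
  }
  for (r2_min in c(0.95, 0.99, 0.999)) {
    expect_equal(detect_exponential_cutoff(s, r2_min = r2_min)$cutoff_time,
                 oracle(s, r2_min, 4))
  }
})

test_that("too few positive points is an insufficient-data error", {
  s <- tibble::tibble(time_h = c(0, 2, 4), confluency_pct = c(1, 2, 4))
  expect_error(detect_exponential_cutoff(s, min_points = 4),
               class = "cin_insufficient_data")
})

test_that("relative slope reduces to a confluency ratio at the cutoff", {
  s <- logistic_series(seq(0, 48, by = 2), 5, 100, 0.05)
  expect_equal(compute_relative_slope(s, list(s, s), 24), 1.0)
  half <- s
  half$confluency_pct <- half$confluency_pct / 2
  expect_equal(compute_relative_slope(half, s, 24), 0.5)
})

test_that("relative slope decreases with drug strength", {
  ctrl <- logistic_series(seq(0, 96, by = 2), 2, 100, 0.04)
  vals <- vapply(c(1, 0.9, 0.8, 0.7, 0.6), function(e) {
    drug <- logistic_series(seq(0, 96, by = 2), 2, 100, 0.04 * e)
    compute_relative_slope(drug, ctrl, 48)
  }, numeric(1))
  expect_equal(vals[1], 1.0, tolerance = 1e-12)
  expect_true(all(diff(vals) < 0))
})

test_that("manual slope follows its defining formula", {
  s <- tibble::tibble(time_h = c(0, 120), confluency_pct = c(5, 50))
  expect_equal(compute_manual_slope(s, 120), -log(0.5) / 5)
  s100 <- tibble::tibble(time_h = c(0, 120), confluency_pct = c(5, 100))
  expect_equal(compute_manual_slope(s100, 120), 0)
  s0 <- tibble::tibble(time_h = c(0, 120), confluency_pct = c(5, 0))
  expect_error(compute_manual_slope(s0, 120), class = "cin_log_domain_error")

  # control-relative manual slope equals direct evaluation on both curves
  ctrl <- logistic_series(seq(0, 120, by = 24), 2, 100, 0.04)
  drug <- logistic_series(seq(0, 120, by = 24), 2, 100, 0.028)
  rel <- compute_manual_slope(drug, 96) / compute_manual_slope(ctrl, 96)
  direct <- log(drug$confluency_pct[drug$time_h == 96] / 100) /
    log(ctrl$confluency_pct[ctrl$time_h == 96] / 100)
  expect_equal(rel, direct, tolerance = 1e-12)
})

test_that("control normalization centres controls at exactly 1", {
  rec <- tibble::tibble(cell_line = "RPE1", drug = "DMSO",
                        auc = c(90, 100, 110))
  out <- normalize_to_control(rec)
  expect_equal(mean(out$relative_auc), 1)
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(cell_line = "RPE1",
                                               drug = "drugA", auc = 100))
  out2 <- normalize_to_control(rec2)
  expect_equal(out2$relative_auc[out2$drug == "drugA"], 1.0)
  rec3 <- tibble::tibble(cell_line = c("RPE1", "Mad2cKD"),
                         drug = c("DMSO", "drugA"), auc = c(100, 50))
  err <- tryCatch(normalize_to_control(rec3), error = function(e) e)
  expect_s3_class(err, "cin_normalization_error")
  expect_match(conditionMessage(err), "Mad2cKD")
})

test_that("screen metrics recover the ground-truth relative AUC", {
  sim <- two_line_screen(penalty = 0.75, effect = 0.8, noise_cv = 0.02,
                         seed = 21)
  m <- screen_metrics(sim$screen, slopes = FALSE)
  truth <- sim$truth$conditions
  truth_rel <- truth$auc_noiseless /
    truth$auc_noiseless[truth$cell_line == "Mad2cKD" & truth$drug == "DMSO"]
  est <- mean(m$relative_auc[m$cell_line == "Mad2cKD" & m$drug == "drugA"])
  expect_equal(
    est,
    truth_rel[truth$cell_line == "Mad2cKD" & truth$drug == "drugA"],
    tolerance = 0.02)
})

test_that("mixed time grids are a grid error under the sum convention", {
  sim <- two_line_screen(seed = 3)
  shifted <- sim$screen
  shifted$time_h[shifted$well == "W001"] <-
    shifted$time_h[shifted$well == "W001"] + 1
  expect_error(screen_metrics(shifted, auc_method = "sum", slopes = FALSE),
               class = "cin_grid_error")
  expect_silent(screen_metrics(shifted, auc_method = "trapezoid",
                               slopes = FALSE))
})

test_that("time windows split, label, and stay additive", {
  s <- logistic_series(seq(0, 192, by = 24), 2, 100, 0.04)
  w <- split_time_windows(s, 4)
  expect_named(w, c("d0-4", "d4-8"))
  expect_equal(diff(range(w[[1]]$time_h)), diff(range(w[[2]]$time_h)))
  # boundary beyond the data: single window identical to the input
  w2 <- split_time_windows(s, 20)
  expect_length(w2, 1)
  expect_equal(w2[[1]]$time_h, s$time_h)
  # trapezoid additivity when the boundary is a sampled point
  total <- compute_auc(s, "trapezoid")
  parts <- sum(vapply(w, compute_auc, numeric(1), method = "trapezoid"))
  expect_equal(parts, total, tolerance = 1e-12)
  # strict partition drops the boundary sample from the left window
  w3 <- split_time_windows(s, 4, boundary = "left")
  expect_equal(sum(vapply(w3, nrow, integer(1))), nrow(s))
})

test_that("AUC is monotone under pointwise dominance and relative metrics
           are scale-invariant", {
  withr::with_seed(17, {
    for (i in 1:5) {
      t <- seq(0, 48, by = 4)
      lo <- tibble::tibble(time_h = t, confluency_pct = runif(length(t), 1, 40))
      hi <- lo
      hi$confluency_pct <- hi$confluency_pct + runif(length(t), 0, 10)
      expect_gte(compute_auc(hi, "sum"), compute_auc(lo, "sum"))
      expect_gte(compute_auc(hi, "trapezoid"), compute_auc(lo, "trapezoid"))
    }
  })
  sim <- two_line_screen(noise_cv = 0.03, seed = 31)
  m1 <- screen_metrics(sim$screen, slopes = FALSE)
  scaled <- sim$screen
  scaled$confluency_pct <- ifelse(scaled$cell_line == "Mad2cKD",
                                  scaled$confluency_pct * 0.5,
                                  scaled$confluency_pct)
  m2 <- screen_metrics(scaled, slopes = FALSE)
  expect_equal(m2$relative_auc, m1$relative_auc, tolerance = 1e-12)
})
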