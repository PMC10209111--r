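make_outcomes <- function(forces, withdrawals, n = 5) {
  do.call(rbind, lapply(seq_along(forces), function(i) {
    data.frame(force_g = forces[i], trial = seq_len(n),
               withdrawal = rep(c(1, 0), c(withdrawals[i],
                                           n - withdrawals[i])),
               censored = FALSE)
  }))
}

test_that("withdrawal curves apply the ascending stop rule", {
  forces <- c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0)
  out <- make_outcomes(forces, c(0, 1, 2, 5, 0, 0, 0, 0))
  cv <- withdrawal_curve(out)
  expect_equal(cv$prob[cv$force_g == 0.16], 0.4)
  expect_true(all(cv$censored[cv$force_g > 0.4]))
  expect_true(all(cv$prob[cv$force_g > 0.4] == 1.0))
  expect_false(any(cv$censored[cv$force_g <= 0.4]))

  flat <- withdrawal_curve(make_outcomes(forces, rep(0, 8)))
  expect_true(all(flat$prob == 0))
  expect_false(any(flat$censored))
  expect_equal(withdrawal_curve(make_outcomes(0.4, 3))$prob, 0.6)
})

test_that("threshold interpolation runs on the log10 force axis", {
  forces <- c(0.04, 0.16, 0.4)
  cv <- withdrawal_curve(make_outcomes(forces, c(0, 3, 4)))
  expect_equal(threshold_at(cv, 0.6), 0.16)  # exactly 0.6 there
  cv2 <- withdrawal_curve(make_outcomes(forces, c(0, 2, 4)))
  expect_equal(threshold_at(cv2, 0.6),
               10^(log10(0.16) + 0.5 * (log10(0.4) - log10(0.16))),
               tolerance = 1e-12)
  expect_equal(round(threshold_at(cv2, 0.6), 3), 0.253)
  low <- withdrawal_curve(make_outcomes(forces, c(0, 1, 2)))
  th <- threshold_at(low, 0.6)
  expect_true(is.na(th))
  expect_true(attr(th, "censored_above_max"))
  # first filament already above the level -> its force
  hi <- withdrawal_curve(make_outcomes(forces, c(4, 4, 4)))
  expect_equal(threshold_at(hi, 0.6), 0.04)
})

test_that("raising the curve never raises the threshold", {
  forces <- c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0)
  set.seed(90)
  for (i in 1:10) {
    w <- sort(sample(0:4, 8, TRUE))
    cv <- withdrawal_curve(make_outcomes(forces, w))
    up <- cv
    up$prob <- pmin(1, up$prob + 0.2)
    t1 <- threshold_at(cv, 0.6)
    t2 <- threshold_at(up, 0.6)
    if (!is.na(t1) && !is.na(t2)) expect_lte(t2, t1 + 1e-12)
    if (is.na(t2)) expect_true(is.na(t1))
  }
})

test_that("sensitivity AUC is the trapezoid over the force axis", {
  forces <- c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0)
  full <- withdrawal_curve(make_outcomes(forces, rep(5, 8)))
  # stop rule censors everything above 0.04 but imputes 1.0 throughout
  expect_equal(sensitivity_auc(full), 1.96)
  half <- withdrawal_curve(make_outcomes(forces, rep(0, 8)))
  half$prob <- rep(0.5, 8)
  expect_equal(sensitivity_auc(half), 0.98)
  expect_equal(sensitivity_auc(half, normalize = TRUE), 0.5)

  # step curve vs brute-force fine-grid integration of the same polyline
  step <- withdrawal_curve(make_outcomes(forces, c(0, 0, 0, 0, 5, 5, 5, 5)))
  f <- approxfun(step$force_g, step$prob)
  grid <- seq(0.04, 2.0, length.out = 2e5 + 1)
  brute <- sum((f(grid[-1]) + f(grid[-length(grid)])) / 2 * diff(grid))
  expect_equal(sensitivity_auc(step), brute, tolerance = 1e-10)
})

test_that("preference index matches its formula and is antisymmetric", {
  expect_equal(preference_index(1200, 0), 1)
  expect_equal(preference_index(600, 600), 0)
  expect_equal(preference_index(300, 900), -0.5)
  expect_true(is.na(preference_index(0, 0)))
  set.seed(91)
  for (i in 1:10) {
    a <- runif(1, 0, 1200); b <- runif(1, 0, 1200)
    expect_equal(preference_index(a, b), -preference_index(b, a))
  }
})

test_that("occupancy accounting splits samples across chambers", {
  inp <- data.frame(x_cm = rep(7, 100), y_cm = rep(7, 100))
  occ <- occupancy_times(inp, dt_s = 1)
  expect_equal(occ$paired_s, 100)
  expect_equal(occ$unpaired_s, 0)
  alt <- data.frame(x_cm = rep(c(7, 30), 50), y_cm = 7)
  occ2 <- occupancy_times(alt, dt_s = 1)
  expect_equal(occ2$paired_s, 50)
  expect_equal(occ2$unpaired_s, 50)
  out <- data.frame(x_cm = c(7, 50), y_cm = c(7, 7))
  expect_warning(occ3 <- occupancy_times(out, dt_s = 1), "outside")
  expect_equal(occ3$neutral_s, 1)
})

test_that("Markov occupancy approaches the chain's stationary fraction", {
  a <- 0.95; b <- 0.90
  # pi_P : pi_N : pi_U = 0.5/(1-a) : 1 : 0.5/(1-b)
  wp <- 0.5 / (1 - a); wu <- 0.5 / (1 - b)
  frac_paired <- wp / (wp + wu + 1)
  fr <- vapply(1:20, function(s) {
    trj <- simulate_place_session(a, b, duration_s = 1200, dt_s = 1,
                                  seed = 200 + s)
    occ <- occupancy_times(trj, dt_s = 1)
    occ$paired_s / 1200
  }, numeric(1))
  expect_lt(abs(mean(fr) - frac_paired),
            3 * sd(fr) / sqrt(length(fr)) + 0.01)
})

test_that("paw-lift threshold is the highest intensity with no lifts", {
  expect_equal(paw_lift_threshold(c(0, 2, 4, 6, 8), c(0, 0, 1, 3, 5)), 2)
  all_l <- paw_lift_threshold(c(2, 4), c(3, 5))
  expect_equal(as.numeric(all_l), 2)
  expect_true(attr(all_l, "all_lifting"))
  expect_equal(paw_lift_threshold(c(2, 4, 8), c(0, 0, 0)), 8)
  expect_error(paw_lift_threshold(numeric(0), numeric(0)), "empty")
})

test_that("Hargreaves latencies are capped at the cutoff before averaging", {
  expect_equal(hargreaves_latency(c(5, 10, 30)), mean(c(5, 10, 20)))
})

test_that("laser hypersensitivity raises the AUC in nearly all replicates", {
  psy <- list(threshold_g = 0.6, slope = 8, laser_shift = 4)
  hits <- vapply(1:200, function(s) {
    sess <- simulate_vonfrey(psy, n_per_filament = 10, seed = 300 + s)
    auc_off <- sensitivity_auc(withdrawal_curve(sess[!sess$laser, ]))
    auc_on <- sensitivity_auc(withdrawal_curve(sess[sess$laser, ]))
    auc_on > auc_off
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
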