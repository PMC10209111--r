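test_that("window alignment uses half-open intervals around onset", {
  units <- data.frame(unit_id = "u1", depth_um = 600, channel = 30)
  # spikes: exactly at onset (10), in delay gap, at onset+0.5, in baseline
  spikes <- list(u1 = c(9.0, 10.0, 10.25, 10.5, 11.9))
  tr <- spike_train_set(units, spikes, 100)
  ev <- event_table("L", 10, 5)
  al <- align_spikes(tr, ev, "u1", "L")
  base <- optoephys:::trial_window_spikes(al, "baseline")
  resp <- optoephys:::trial_window_spikes(al, "response")
  expect_equal(base[[1]], -1.0)              # onset spike excluded
  expect_equal(resp[[1]], c(0.5, 1.9))       # onset+0.5 included
  expect_error(align_spikes(tr, ev, "u1", "ML"), "no events")
})

test_that("every spike in the trial span lands in exactly one window", {
  w <- window_spec()
  set.seed(11)
  for (i in 1:20) {
    t <- runif(50, -w$baseline_dur_s,
               w$response_delay_s + w$response_dur_s)
    in_base <- t >= -w$baseline_dur_s & t < 0
    in_gap <- t >= 0 & t < w$response_delay_s
    in_resp <- t >= w$response_delay_s &
      t < w$response_delay_s + w$response_dur_s
    expect_true(all(in_base + in_gap + in_resp == 1))
  }
})

test_that("silent units give empty trial arrays", {
  units <- data.frame(unit_id = "u1", depth_um = 600, channel = 30)
  tr <- spike_train_set(units, list(u1 = numeric(0)), 5000)
  ev <- event_table(rep("M", 40), seq(10, by = 100, length.out = 40),
                    rep(5, 40))
  al <- align_spikes(tr, ev, "u1", "M")
  expect_length(al$trials, 40)
  expect_true(all(lengths(al$trials) == 0))
  expect_equal(mean_rate(al, "response"), 0)
  expect_equal(response_probability(al), 0)
})

test_that("mean rate is count per trial over window duration", {
  al <- make_aligned(list(c(0.6, 0.7, 1.0), c(0.9, 1.2, 1.5),
                          c(0.55, 1.1, 1.99)))
  expect_equal(mean_rate(al, "response"), 2.0)   # 3 spikes / 1.5 s
  al_poisson <- make_null_unit(21, rate_hz = 5, n_trials = 200)
  lambda <- 5 * 1.5
  tol <- 3 * sqrt(lambda / 200) / 1.5
  expect_lt(abs(mean_rate(al_poisson, "response") - 5), tol)
})

test_that("modulation index follows its formula with antisymmetry", {
  expect_equal(modulation_index(6, 2), 0.5)
  expect_equal(modulation_index(0, 2), -1)
  expect_equal(modulation_index(2, 0), 1)
  expect_true(is.na(modulation_index(0, 0)))
  expect_error(modulation_index(-1, 2), "non-negative")
  set.seed(5)
  a <- runif(50, 0, 20); b <- runif(50, 0, 20)
  expect_equal(modulation_index(a, b), -modulation_index(b, a))
})

test_that("response probability matches its definition and closed form", {
  trials <- c(lapply(1:7, function(i) 0.6), lapply(1:3, function(i)
    numeric(0)))
  expect_equal(response_probability(make_aligned(trials)), 0.7)
  # Poisson(lambda) response-window counts: RP -> 1 - exp(-lambda)
  lambda <- 1.2
  al <- make_null_unit(31, rate_hz = lambda / 1.5, n_trials = 500)
  rp <- response_probability(al)
  expected <- 1 - exp(-lambda)
  expect_lt(abs(rp - expected),
            3 * sqrt(expected * (1 - expected) / 500))
})

test_that("burst parsing matches hand enumeration and the brute-force oracle", {
  times <- c(0, 2, 4, 104, 107, 307) / 1000
  ev <- parse_burst_events(times)
  expect_equal(ev$type, c("burst", "burst", "single"))
  expect_equal(ev$n_spikes, c(3L, 2L, 1L))
  expect_equal(nrow(parse_burst_events(0.5)), 1L)
  expect_equal(parse_burst_events(0.5)$type, "single")
  allburst <- parse_burst_events(seq(0, 0.009, by = 0.001))
  expect_equal(nrow(allburst), 1L)
  expect_equal(allburst$type, "burst")
  expect_error(parse_burst_events(c(2, 1)), "sorted")

  set.seed(7)
  for (i in 1:30) {
    t <- sort(runif(sample(0:30, 1), 0, 0.2))
    mine <- parse_burst_events(t)
    ref <- reference_burst_parser(t)
    expect_equal(mine$type, ref$type)
    expect_equal(mine$n_spikes, ref$n_spikes)
  }
})

test_that("burst probability pools events across trials", {
  al <- make_aligned(list(c(0.5, 0.502, 0.504, 0.604, 0.607, 0.807)))
  expect_equal(burst_probability(al), 2 / 3)
  # tonic Poisson at 5 Hz: expected ISI 200 ms >> 5 ms cutoff
  al5 <- make_null_unit(41, rate_hz = 5, n_trials = 500)
  expect_lt(burst_probability(al5), 0.05)
})

test_that("planted burst probability is recovered from the generator", {
  spec <- unit_spec("b1", baseline_rate_hz = 4, burst_prob = 0.5,
                    burst_size_mean = 2, intra_burst_isi_ms = 3)
  ev <- event_table(rep("L", 500), seq(10, by = 10, length.out = 500),
                    rep(5, 500))
  sim <- simulate_session(list(spec), ev, seed = 77)
  al <- align_spikes(sim$train, sim$events, "b1", "L")
  expect_lt(abs(burst_probability(al) - 0.5), 0.05)
})

test_that("burst regime classification uses a strict 0.1 cutoff", {
  expect_equal(classify_burst_regime(0.11), "bursty")
  expect_equal(classify_burst_regime(0.1), "tonic")
  expect_equal(classify_burst_regime(0), "tonic")
  expect_error(classify_burst_regime(NA_real_), "undefined")
})

test_that("ISI CDFs behave on degenerate and analytic inputs", {
  # all ISIs exactly 10 ms
  al <- make_aligned(list(seq(0.5, 0.6, by = 0.01)))
  cdf <- isi_cdf(al)
  expect_true(all(cdf$cdf[cdf$isi_ms < 10] == 0))
  expect_true(all(cdf$cdf[cdf$isi_ms >= 10] == 1))
  # two identical units: median equals either
  pop <- population_median_cdf(list(cdf, cdf))
  expect_equal(pop$cdf_median, cdf$cdf)
  # no-ISI unit excluded with warning
  expect_warning(res <- isi_cdf(make_aligned(list(0.7))), "excluded")
  expect_null(res)
  # exponential ISIs within the DKW band of 1 - exp(-lambda t); a single
  # long trial carries all n ISIs inside a widened response window
  set.seed(13)
  lambda <- 50  # per second
  isis <- rexp(1e4, lambda)
  train <- 0.5 + c(0, cumsum(isis))
  w_long <- window_spec(response_dur_s = max(train) + 1)
  cdf_exp <- isi_cdf(make_aligned(list(train), window = w_long),
                     max_ms = 60)
  n <- 1e4
  eps <- sqrt(log(2 / 0.01) / (2 * n))
  theo <- 1 - exp(-lambda * cdf_exp$isi_ms / 1000)
  expect_true(all(abs(cdf_exp$cdf - theo) < eps + 0.01))
})

test_that("pressure derivative is exact on polynomials and O(dt^2) on sine", {
  expect_equal(pressure_derivative(rep(3, 10), 0.1), rep(0, 10))
  ramp <- seq(0, 9) * 2.5
  expect_equal(pressure_derivative(ramp, 1), rep(2.5, 10))
  dt <- 0.001
  t <- seq(0, 1, by = dt)
  d <- pressure_derivative(sin(2 * pi * t), dt)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(d[interior] - 2 * pi * cos(2 * pi * t[interior]))),
            (2 * pi)^3 * dt^2)
  expect_error(pressure_derivative(1), "2 samples")
})

test_that("response probability is monotone in planted rate", {
  rates <- c(0.5, 1, 2, 4, 8)
  rps <- vapply(seq_along(rates), function(i) {
    response_probability(make_null_unit(100 + i, rate_hz = rates[i],
                                        n_trials = 300))
  }, numeric(1))
  expect_true(all(diff(rps) >= 0))
})
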