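#' Specification of one synthetic unit
#'
#' Ground-truth parameters for a simulated single unit: lognormally
#' distributed baseline rate, multiplicative per-condition gain (gain > 1
#' enhancement, gain < 1 suppression), Poisson-cluster burst structure, an
#' optional optotagged low-latency/low-jitter pulse response, and the
#' metadata (depth, channel, waveform metric) the classifier consumes.
#'
#' @param unit_id Unit identifier (integer-like string).
#' @param baseline_rate_hz Baseline event rate (Hz), `>= 0`.
#' @param gain Named numeric, multiplicative rate gain for conditions
#'   `L`, `M`, `ML` (all `>= 0`).
#' @param burst_prob Probability an emitted event expands into a burst.
#' @param burst_size_mean Mean number of extra spikes per burst (geometric,
#'   at least one extra spike).
#' @param intra_burst_isi_ms Spacing of intra-burst spikes (ms).
#' @param refractory_ms Absolute refractory period (ms): spikes closer
#'   than this to their predecessor are suppressed. Must stay below the
#'   intra-burst ISI so burst structure is preserved.
#' @param tagged Logical: optotagged unit.
#' @param tag_latency_mean_ms,tag_latency_sd_ms,tag_reliability Pulse
#'   response parameters (used when `tagged`).
#' @param depth_um,channel,trough_peak_us Cluster metadata.
#' @return list of class `unit_spec`.
#' @export
unit_spec <- function(unit_id, baseline_rate_hz,
                      gain = c(L = 1, M = 1, ML = 1),
                      burst_prob = 0, burst_size_mean = 2,
                      intra_burst_isi_ms = 3, refractory_ms = 1.5,
                      tagged = FALSE,
                      tag_latency_mean_ms = 5, tag_latency_sd_ms = 1,
                      tag_reliability = 0.9, depth_um = NA_real_,
                      channel = NA_real_, trough_peak_us = 400) {
  stopifnot(baseline_rate_hz >= 0, all(gain >= 0),
            burst_prob >= 0, burst_prob <= 1, burst_size_mean >= 1,
            intra_burst_isi_ms > 0, refractory_ms > 0,
            refractory_ms < intra_burst_isi_ms,
            tag_reliability >= 0, tag_reliability <= 1)
  if (tagged && tag_latency_sd_ms <= 0) {
    stop("tag_latency_sd_ms must be positive for tagged units",
         call. = FALSE)
  }
  structure(list(unit_id = as.character(unit_id),
                 baseline_rate_hz = baseline_rate_hz,
                 gain = gain[c("L", "M", "ML")],
                 burst_prob = burst_prob,
                 burst_size_mean = burst_size_mean,
                 intra_burst_isi_ms = intra_burst_isi_ms,
                 refractory_ms = refractory_ms,
                 tagged = tagged,
                 tag_latency_mean_ms = tag_latency_mean_ms,
                 tag_latency_sd_ms = tag_latency_sd_ms,
                 tag_reliability = tag_reliability,
                 depth_um = depth_um, channel = channel,
                 trough_peak_us = trough_peak_us),
            class = "unit_spec")
}

#' Sample a synthetic unit population
#'
#' Draws `n` unit specs with lognormal baseline rates, a mixture of
#' enhanced / suppressed / unmodulated ML gains (L gain follows ML for
#' enhanced units at reduced strength; M gain is intermediate),
#' heterogeneous per-unit burst probabilities (the population spans tonic
#' to strongly bursty regimes), a tagged subpopulation, and depths spread
#' over the cortical axis (channel = depth / 20 micrometres).
#'
#' @param n Number of units.
#' @param seed Integer seed.
#' @param config Generator parameters (the `simulate` entry of
#'   [default_config()]).
#' @return list of [unit_spec()] objects.
#' @export
sample_unit_specs <- function(n, seed, config = default_config()$simulate) {
  with_seed(seed, {
    cls <- sample(c("enhanced", "suppressed", "none"), n, replace = TRUE,
                  prob = c(config$p_enhanced, config$p_suppressed,
                           1 - config$p_enhanced - config$p_suppressed))
    rates <- stats::rlnorm(n, config$baseline_meanlog,
                           config$baseline_sdlog)
    depths <- stats::runif(n, 100, 1300)
    tagged <- stats::runif(n) < config$tagged_fraction
    bursty <- stats::runif(n, config$burst_prob_range[1],
                           config$burst_prob_range[2])
    lapply(seq_len(n), function(i) {
      g_ml <- switch(cls[i],
        enhanced = sample(config$gain_enhanced, 1),
        suppressed = sample(config$gain_suppressed, 1),
        none = 1)
      g_l <- if (cls[i] == "none") 1 else exp(0.5 * log(g_ml))
      g_m <- if (cls[i] == "none") 1 else exp(0.75 * log(g_ml))
      unit_spec(unit_id = i, baseline_rate_hz = rates[i],
                gain = c(L = g_l, M = g_m, ML = g_ml),
                burst_prob = bursty[i],
                burst_size_mean = config$burst_size_mean,
                intra_burst_isi_ms = config$intra_burst_isi_ms,
                tagged = tagged[i],
                tag_latency_mean_ms = stats::runif(1,
                  config$tag_latency_ms[1], config$tag_latency_ms[2]),
                tag_latency_sd_ms = stats::runif(1,
                  config$tag_jitter_ms[1], config$tag_jitter_ms[2]),
                tag_reliability = config$tag_reliability,
                depth_um = depths[i], channel = floor(depths[i] / 20),
                trough_peak_us = stats::runif(1, 300, 600))
    })
  })
}

#' Default stimulation protocol
#'
#' Cycles of the three 5 s stimulus conditions with the study spacing
#' (mechanical to mechanical+laser 60 s, otherwise 30 s), preceded by a
#' block of brief optotagging light pulses.
#'
#' @param n_trials Trials per condition.
#' @param n_pulses Number of 10 ms optotagging pulses (1 s apart).
#' @param stim_s Stimulus duration (s).
#' @param gap_m_ml_s Interval from M onset to ML onset (s).
#' @param gap_other_s Interval between the other condition onsets (s).
#' @return An [event_table()].
#' @export
default_protocol <- function(n_trials = 40, n_pulses = 40, stim_s = 5,
                             gap_m_ml_s = 60, gap_other_s = 30) {
  pulse_on <- seq(5, by = 1, length.out = n_pulses)
  t0 <- if (n_pulses > 0) max(pulse_on) + 30 else 5
  cycle <- gap_m_ml_s + 2 * gap_other_s
  m_on <- t0 + cycle * (seq_len(n_trials) - 1)
  ml_on <- m_on + gap_m_ml_s
  l_on <- ml_on + gap_other_s
  ev <- rbind(
    if (n_pulses > 0)
      data.frame(condition = "PULSE", onset_s = pulse_on,
                 duration_s = 0.01),
    data.frame(condition = "M", onset_s = m_on, duration_s = stim_s),
    data.frame(condition = "ML", onset_s = ml_on, duration_s = stim_s),
    data.frame(condition = "L", onset_s = l_on, duration_s = stim_s))
  ev <- ev[order(ev$onset_s), ]
  event_table(ev$condition, ev$onset_s, ev$duration_s)
}

simulate_unit_train <- function(spec, events, duration) {
  rate <- spec$baseline_rate_hz
  # baseline homogeneous Poisson event process over the whole recording
  n_base <- stats::rpois(1, rate * duration)
  ev_times <- stats::runif(n_base, 0, duration)
  # per-condition gain inside [onset + 0.5, onset + duration_s)
  stim <- events[events$condition %in% c("L", "M", "ML"), , drop = FALSE]
  if (nrow(stim) && rate > 0) {
    for (i in seq_len(nrow(stim))) {
      g <- spec$gain[[stim$condition[i]]]
      lo <- stim$onset_s[i] + 0.5
      hi <- stim$onset_s[i] + stim$duration_s[i]
      if (hi <= lo) next
      inwin <- ev_times >= lo & ev_times < hi
      if (g < 1) {                       # thin baseline events
        drop <- inwin & stats::runif(length(ev_times)) > g
        ev_times <- ev_times[!drop]
      } else if (g > 1) {                # superpose extra events
        n_extra <- stats::rpois(1, (g - 1) * rate * (hi - lo))
        ev_times <- c(ev_times, stats::runif(n_extra, lo, hi))
      }
    }
  }
  # burst expansion: Poisson cluster process
  spikes <- ev_times
  if (spec$burst_prob > 0 && length(ev_times)) {
    is_burst <- stats::runif(length(ev_times)) < spec$burst_prob
    if (any(is_burst)) {
      extra_n <- 1 + stats::rgeom(sum(is_burst),
                                  prob = 1 / spec$burst_size_mean)
      isi <- spec$intra_burst_isi_ms / 1000
      extras <- unlist(mapply(function(t0, k) t0 + isi * seq_len(k),
                              ev_times[is_burst], extra_n,
                              SIMPLIFY = FALSE))
      spikes <- c(spikes, extras)
    }
  }
  # optotagged pulse response
  pulses <- events$onset_s[events$condition == "PULSE"]
  if (spec$tagged && length(pulses)) {
    respond <- stats::runif(length(pulses)) < spec$tag_reliability
    lat <- stats::rnorm(sum(respond), spec$tag_latency_mean_ms,
                        spec$tag_latency_sd_ms) / 1000
    lat <- pmax(lat, 0)
    spikes <- c(spikes, pulses[respond] + lat)
  }
  spikes <- sort(spikes[spikes >= 0 & spikes <= duration])
  # absolute refractory period: drop spikes too close to their
  # predecessor (intra-burst spacing exceeds it by construction)
  dead <- spec$refractory_ms / 1000
  while (length(spikes) >= 2) {
    bad <- which(diff(spikes) < dead) + 1L
    if (!length(bad)) break
    bad <- bad[c(TRUE, diff(bad) > 1L)]
    spikes <- spikes[-bad]
  }
  spikes
}

#' Simulate a full recording session
#'
#' Generates a spike train for every unit spec against a stimulation
#' protocol. Event onsets follow a Poisson process at
#' `baseline_rate x gain(condition)` inside the stimulus window (after the
#' 0.5 s onset delay) and at the baseline rate elsewhere; each event
#' expands into a burst with probability `burst_prob` (extra spikes at the
#' intra-burst ISI); tagged units additionally emit one spike per pulse
#' with probability `tag_reliability` at a truncated-normal latency.
#'
#' @param specs Non-empty list of [unit_spec()] objects.
#' @param protocol An [event_table()] (see [default_protocol()]).
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @return list: `train` ([spike_train_set()]), `events`, `manifest`
#'   (specs + protocol + seed).
#' @export
simulate_session <- function(specs, protocol = default_protocol(),
                             seed = 1) {
  if (!length(specs)) stop("empty spec list", call. = FALSE)
  duration <- max(protocol$onset_s + protocol$duration_s) + 30
  spikes <- with_seed(seed, {
    lapply(specs, simulate_unit_train, events = protocol,
           duration = duration)
  })
  names(spikes) <- vapply(specs, `[[`, character(1), "unit_id")
  units <- data.frame(
    unit_id = names(spikes),
    depth_um = vapply(specs, `[[`, numeric(1), "depth_um"),
    channel = vapply(specs, `[[`, numeric(1), "channel"),
    trough_peak_us = vapply(specs, `[[`, numeric(1), "trough_peak_us"))
  train <- spike_train_set(units, spikes, duration)
  manifest <- list(seed = seed, n_units = length(specs),
                   duration_s = duration, specs = specs)
  list(train = train, events = protocol, manifest = manifest)
}

#' Simulate a von Frey session
#'
#' Per-trial Bernoulli withdrawal with probability
#' `plogis(slope * (log10(force) - log10(threshold)))`; on laser-on trials
#' the threshold is divided by `laser_shift` (shift > 1 models
#' hypersensitivity). The ascending stop rule is applied: once a filament
#' yields withdrawals on all its trials, higher filaments are emitted as
#' censored (untested).
#'
#' @param psychometric list with `threshold_g`, `slope` (per decade of
#'   force), `laser_shift`.
#' @param filaments Ascending filament forces (g).
#' @param n_per_filament Trials per filament.
#' @param seed Integer seed.
#' @param laser Logical vector of laser states to simulate (both by
#'   default).
#' @return data.frame: `laser`, `force_g`, `trial`, `withdrawal`,
#'   `censored`.
#' @export
simulate_vonfrey <- function(psychometric, filaments =
                               c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0),
                             n_per_filament = 5, seed = 1,
                             laser = c(FALSE, TRUE)) {
  if (is.unsorted(filaments, strictly = TRUE)) {
    stop("filaments must be strictly ascending", call. = FALSE)
  }
  stopifnot(n_per_filament >= 1)
  with_seed(seed, {
    out <- lapply(laser, function(on) {
      thr <- psychometric$threshold_g /
        (if (on) psychometric$laser_shift else 1)
      stopped <- FALSE
      rows <- lapply(filaments, function(f) {
        if (stopped) {
          return(data.frame(laser = on, force_g = f,
                            trial = seq_len(n_per_filament),
                            withdrawal = NA, censored = TRUE))
        }
        p <- stats::plogis(psychometric$slope * (log10(f) - log10(thr)))
        w <- stats::rbinom(n_per_filament, 1, p)
        if (all(w == 1)) stopped <<- TRUE
        data.frame(laser = on, force_g = f,
                   trial = seq_len(n_per_filament),
                   withdrawal = w, censored = FALSE)
      })
      do.call(rbind, rows)
    })
    do.call(rbind, out)
  })
}

#' Simulate a two-chamber place session
#'
#' Three-state Markov occupancy (paired chamber, neutral transit zone,
#' unpaired chamber) sampled at `dt_s`. From a chamber the animal stays
#' with the given probability or moves to the neutral zone; from the
#' neutral zone it enters either chamber with equal probability. Positions
#' are drawn uniformly inside the current chamber rectangle (paired
#' `[0,15] x [0,15]`, neutral `[15,23] x [0,8]`, unpaired
#' `[23,38] x [0,15]` cm).
#'
#' @param p_stay_paired,p_stay_unpaired Per-step stay probabilities, in
#'   (0, 1].
#' @param duration_s Session duration (s).
#' @param dt_s Sample interval (s), `< duration_s`.
#' @param seed Integer seed.
#' @return data.frame: `t_s`, `state` (`"paired"`/`"neutral"`/`"unpaired"`),
#'   `x_cm`, `y_cm`.
#' @export
simulate_place_session <- function(p_stay_paired, p_stay_unpaired,
                                   duration_s = 1200, dt_s = 1, seed = 1) {
  stopifnot(p_stay_paired > 0, p_stay_paired <= 1,
            p_stay_unpaired > 0, p_stay_unpaired <= 1)
  if (dt_s >= duration_s) stop("dt_s must be smaller than duration_s",
                               call. = FALSE)
  n <- floor(duration_s / dt_s)
  with_seed(seed, {
    states <- character(n)
    s <- "neutral"
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      s <- switch(s,
        paired = if (u[i] < p_stay_paired) "paired" else "neutral",
        unpaired = if (u[i] < p_stay_unpaired) "unpaired" else "neutral",
        neutral = if (u[i] < 0.5) "paired" else "unpaired")
      states[i] <- s
    }
    x <- stats::runif(n); y <- stats::runif(n)
    pos <- cbind(
      ifelse(states == "paired", x * 15,
             ifelse(states == "neutral", 15 + x * 8, 23 + x * 15)),
      ifelse(states == "neutral", y * 8, y * 15))
    data.frame(t_s = (seq_len(n) - 1) * dt_s, state = states,
               x_cm = pos[, 1], y_cm = pos[, 2])
  })
}
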