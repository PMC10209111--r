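#' Unit quality control
#'
#' A sorted single unit is accepted when its refractory-period violation
#' rate (fraction of ISIs shorter than 1 ms) is below 0.5% and its overall
#' firing rate exceeds 0.1 Hz.
#'
#' @param spike_times Sorted spike times (s) over the whole recording.
#' @param recording_duration Recording length (s).
#' @param refractory_ms Refractory period (ms).
#' @param max_violation_rate Maximum tolerated violation fraction.
#' @param min_rate_hz Minimum overall rate (Hz).
#' @return list: `pass` (logical), `reasons` (character), `violation_rate`,
#'   `rate_hz`.
#' @export
qc_unit <- function(spike_times, recording_duration, refractory_ms = 1,
                    max_violation_rate = 0.005, min_rate_hz = 0.1) {
  if (recording_duration <= 0) stop("recording_duration must be positive",
                                    call. = FALSE)
  n <- length(spike_times)
  rate <- n / recording_duration
  viol <- if (n >= 2) mean(diff(spike_times) < refractory_ms / 1000) else 0
  reasons <- character(0)
  if (viol >= max_violation_rate) reasons <- c(reasons, "refractory")
  if (rate <= min_rate_hz) reasons <- c(reasons, "rate")
  list(pass = length(reasons) == 0L, reasons = reasons,
       violation_rate = viol, rate_hz = rate)
}

#' First-spike latency statistics over light pulses
#'
#' For each pulse, the latency (ms) of the first spike within the search
#' window after pulse onset. Returns the mean and sample SD (n - 1) over
#' responsive pulses and the fraction of pulses that were responsive.
#'
#' @param spike_times Sorted spike times (s).
#' @param pulse_onsets Pulse onset times (s); at least 10 expected.
#' @param search_window_ms First-spike search window after onset (ms).
#' @return list: `mean_ms`, `sd_ms` (both `NA` when no pulse was
#'   responsive), `responsive_fraction`, `n_pulses`.
#' @export
first_spike_latency_stats <- function(spike_times, pulse_onsets,
                                      search_window_ms = 25) {
  if (length(pulse_onsets) < 1L) stop("no pulse events", call. = FALSE)
  w <- search_window_ms / 1000
  lat <- vapply(pulse_onsets, function(on) {
    s <- spike_times[spike_times >= on & spike_times < on + w]
    if (length(s)) (s[1] - on) * 1000 else NA_real_
  }, numeric(1))
  resp <- lat[!is.na(lat)]
  list(mean_ms = if (length(resp)) mean(resp) else NA_real_,
       sd_ms = if (length(resp) >= 2) stats::sd(resp) else
         if (length(resp) == 1) 0 else NA_real_,
       responsive_fraction = length(resp) / length(pulse_onsets),
       n_pulses = length(pulse_onsets))
}

#' Optotagging decision from latency statistics
#'
#' A unit is tagged when its mean first-spike latency is below 9.5 ms and
#' its latency SD (jitter) is below the population-specific bound (3 ms for
#' L5, 2 ms for L6-CT), provided enough pulses evoked a response.
#'
#' @param stats A [first_spike_latency_stats()] result.
#' @param population `"L5"` or `"L6CT"`.
#' @param latency_max_ms Mean-latency bound (ms).
#' @param jitter_max_ms Jitter bound; defaults to 3 (L5) / 2 (L6CT).
#' @param min_responsive_fraction Minimum fraction of responsive pulses.
#' @return logical flag.
#' @export
classify_optotagged <- function(stats, population = c("L5", "L6CT"),
                                latency_max_ms = 9.5, jitter_max_ms = NULL,
                                min_responsive_fraction = 0.5) {
  population <- match.arg(population)
  if (is.null(jitter_max_ms)) {
    jitter_max_ms <- if (population == "L5") 3 else 2
  }
  if (is.na(stats$mean_ms) || is.na(stats$sd_ms)) return(FALSE)
  if (stats$responsive_fraction < min_responsive_fraction) return(FALSE)
  stats$mean_ms < latency_max_ms && stats$sd_ms < jitter_max_ms
}

#' Fast-spiking waveform flag
#'
#' Putative fast-spiking (interneuron-like) units have a peak-to-second
#' trough latency below 215 microseconds (strict). A missing metric keeps
#' the unit with an `NA` flag.
#'
#' @param trough_peak_us Waveform metric (microseconds); vectorized.
#' @return logical vector (`NA` where the metric is missing).
#' @export
is_fast_spiking <- function(trough_peak_us) {
  ifelse(is.na(trough_peak_us), NA, trough_peak_us < 215)
}

#' Assign a cortical layer from recording depth
#'
#' Depths are registered to histologically derived layer borders; the
#' default table (L2/3 `[100, 350)`, L4 `[350, 500)`, L5 `[500, 900)`,
#' L6 `[900, 1300)` micrometres) is a configuration default only -- real use
#' requires histology-derived boundaries per animal.
#'
#' @param depth_um Depth(s) below pia in micrometres.
#' @param boundaries data.frame `layer`, `upper_um`, `lower_um` with
#'   half-open intervals `[upper, lower)`.
#' @return character vector of layer labels (`"unassigned"` outside all
#'   intervals).
#' @export
assign_layer <- function(depth_um, boundaries = default_config()$layers) {
  if (any(depth_um < 0, na.rm = TRUE)) {
    stop("depth must be non-negative", call. = FALSE)
  }
  vapply(depth_um, function(d) {
    if (is.na(d)) return("unassigned")
    hit <- which(d >= boundaries$upper_um & d < boundaries$lower_um)
    if (length(hit)) boundaries$layer[hit[1]] else "unassigned"
  }, character(1))
}

#' Dorsolateral VPL channel range from modulation significance
#'
#' Identifies the contiguous probe channel interval spanning the first to
#' the last channel that hosts a unit with a significant response to the
#' mechanical (M) or mechanical+laser (ML) condition; every unit on a
#' channel inside the interval is assigned to VPL.
#'
#' @param channels Integer channel per unit.
#' @param significant Logical per unit: significant M or ML modulation.
#' @return list: `range` (length-2 integer interval or `NULL`), `in_vpl`
#'   logical per unit.
#' @export
select_vpl_channel_range <- function(channels, significant) {
  stopifnot(length(channels) == length(significant))
  sig_ch <- channels[significant %in% TRUE]
  if (!length(sig_ch)) {
    warning("no significant units; empty VPL channel range", call. = FALSE)
    return(list(range = NULL, in_vpl = rep(FALSE, length(channels))))
  }
  rng <- range(sig_ch)
  list(range = rng, in_vpl = channels >= rng[1] & channels <= rng[2])
}

#' Classify every unit of a spike train set
#'
#' Runs QC, optotagging against pulse trials, fast-spiking flagging and
#' layer assignment; FS units are removed from the optotagged set.
#'
#' @param train A [spike_train_set()].
#' @param events An [event_table()] (used for `PULSE` trials; optotag
#'   columns are `NA` when absent).
#' @param population Optotagged population to test for (`"L5"`/`"L6CT"`).
#' @param config A [default_config()]-style list.
#' @return data.frame, one row per unit: qc, layer, latency stats, fs and
#'   optotag flags.
#' @export
classify_units <- function(train, events, population = "L6CT",
                           config = default_config()) {
  pulses <- events$onset_s[events$condition == "PULSE"]
  rows <- lapply(seq_len(nrow(train$units)), function(i) {
    uid <- train$units$unit_id[i]
    st <- train$spikes[[uid]]
    qc <- qc_unit(st, train$recording_duration,
                  refractory_ms = config$qc$refractory_ms,
                  max_violation_rate = config$qc$max_violation_rate,
                  min_rate_hz = config$qc$min_rate_hz)
    fs <- is_fast_spiking(train$units$trough_peak_us[i])
    if (length(pulses)) {
      ls <- first_spike_latency_stats(st, pulses,
        search_window_ms = config$optotag$search_window_ms)
      tagged <- qc$pass && !isTRUE(fs) &&
        classify_optotagged(ls, population,
          latency_max_ms = config$optotag$latency_max_ms,
          jitter_max_ms = if (population == "L5")
            config$optotag$jitter_max_ms_L5 else
            config$optotag$jitter_max_ms_L6CT,
          min_responsive_fraction = config$optotag$min_responsive_fraction)
    } else {
      ls <- list(mean_ms = NA_real_, sd_ms = NA_real_,
                 responsive_fraction = NA_real_)
      tagged <- NA
    }
    data.frame(unit_id = uid, qc_pass = qc$pass,
               qc_reasons = paste(qc$reasons, collapse = ";"),
               rate_hz = qc$rate_hz, violation_rate = qc$violation_rate,
               depth_um = train$units$depth_um[i],
               channel = train$units$channel[i],
               layer = assign_layer(train$units$depth_um[i], config$layers),
               fs = fs, latency_mean_ms = ls$mean_ms,
               latency_sd_ms = ls$sd_ms,
               responsive_fraction = ls$responsive_fraction,
               optotagged = tagged)
  })
  do.call(rbind, rows)
}
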