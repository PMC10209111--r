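#' Response window specification
#'
#' Spike counts and timing are evaluated in a 1.5 s window starting 0.5 s
#' after stimulus onset (the delay discards transient effects at onset and
#' the mechanical actuator's lag); baseline activity is the 1.5 s before
#' onset. Laser-only trials use the same windows so conditions remain
#' comparable.
#'
#' @param response_delay_s Delay after onset before the response window
#'   opens (s).
#' @param response_dur_s Response window duration (s).
#' @param baseline_dur_s Baseline window duration before onset (s).
#' @return list of class `window_spec`.
#' @export
window_spec <- function(response_delay_s = 0.5, response_dur_s = 1.5,
                        baseline_dur_s = 1.5) {
  stopifnot(response_delay_s >= 0, response_dur_s > 0, baseline_dur_s > 0)
  structure(list(response_delay_s = response_delay_s,
                 response_dur_s = response_dur_s,
                 baseline_dur_s = baseline_dur_s),
            class = "window_spec")
}

#' Align a unit's spikes to stimulus onsets of one condition
#'
#' For each trial of the requested condition, collects spikes in
#' `[onset - baseline_dur, onset + response_delay + response_dur)` as times
#' relative to onset. Windows are half-open so every spike in the trial span
#' lands in exactly one of baseline `[-baseline_dur, 0)`, delay gap
#' `[0, response_delay)` or response `[response_delay,
#' response_delay + response_dur)`.
#'
#' @param train A [spike_train_set()].
#' @param events An [event_table()].
#' @param unit_id Unit to align.
#' @param condition One of `"L"`, `"M"`, `"ML"`, `"PULSE"`.
#' @param window A [window_spec()].
#' @return list of class `aligned_responses` with per-trial relative-time
#'   vectors.
#' @export
align_spikes <- function(train, events, unit_id, condition,
                         window = window_spec()) {
  onsets <- events$onset_s[events$condition == condition]
  if (!length(onsets)) {
    stop("no events of condition '", condition, "'", call. = FALSE)
  }
  st <- train$spikes[[as.character(unit_id)]]
  if (is.null(st)) stop("unknown unit_id: ", unit_id, call. = FALSE)
  lo <- -window$baseline_dur_s
  hi <- window$response_delay_s + window$response_dur_s
  trials <- lapply(onsets, function(on) {
    st[st >= on + lo & st < on + hi] - on
  })
  structure(list(unit_id = as.character(unit_id), condition = condition,
                 trials = trials, window = window, onsets = onsets),
            class = "aligned_responses")
}

trial_window_spikes <- function(aligned, which = c("response", "baseline")) {
  which <- match.arg(which)
  w <- aligned$window
  if (which == "response") {
    lo <- w$response_delay_s
    hi <- w$response_delay_s + w$response_dur_s
  } else {
    lo <- -w$baseline_dur_s
    hi <- 0
  }
  lapply(aligned$trials, function(t) t[t >= lo & t < hi])
}

#' Mean spiking rate over trials
#'
#' Mean spike count per trial divided by the window duration (1.5 s by
#' default), for either the response or the baseline window.
#'
#' @param aligned An [align_spikes()] result.
#' @param which `"response"` or `"baseline"`.
#' @return Rate in Hz.
#' @export
mean_rate <- function(aligned, which = c("response", "baseline")) {
  which <- match.arg(which)
  sp <- trial_window_spikes(aligned, which)
  if (!length(sp)) stop("zero trials", call. = FALSE)
  dur <- if (which == "response") aligned$window$response_dur_s
         else aligned$window$baseline_dur_s
  mean(vapply(sp, length, numeric(1))) / dur
}

#' Modulation index
#'
#' `MI = (r_stim - r_base) / (r_stim + r_base)`, bounded in `[-1, 1]`;
#' `NA` when both rates are zero (undefined).
#'
#' @param r_stim,r_base Non-negative rates (Hz); vectorized.
#' @return MI value(s).
#' @export
modulation_index <- function(r_stim, r_base) {
  if (any(r_stim < 0) || any(r_base < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  ifelse(r_stim + r_base == 0, NA_real_,
         (r_stim - r_base) / (r_stim + r_base))
}

#' Response probability
#'
#' Fraction of trials with at least one spike in the response window.
#'
#' @param aligned An [align_spikes()] result.
#' @return RP in `[0, 1]`.
#' @export
response_probability <- function(aligned) {
  sp <- trial_window_spikes(aligned, "response")
  if (!length(sp)) stop("zero trials", call. = FALSE)
  mean(vapply(sp, length, numeric(1)) > 0)
}

#' Parse a spike train into burst and single-spike events
#'
#' Consecutive spikes separated by less than `isi_cutoff_ms` are merged into
#' one burst event; an isolated spike is a single event. The first spike of
#' a window always opens a new event (it has no preceding ISI).
#'
#' @param spike_times Sorted spike times in **seconds**.
#' @param isi_cutoff_ms Burst ISI cutoff (default 5 ms).
#' @return data.frame with one row per event: `type` (`"burst"`/`"single"`),
#'   `n_spikes`, `start_s`.
#' @export
parse_burst_events <- function(spike_times, isi_cutoff_ms = 5) {
  if (is.unsorted(spike_times)) {
    stop("spike times must be sorted", call. = FALSE)
  }
  n <- length(spike_times)
  if (n == 0L) {
    return(data.frame(type = character(0), n_spikes = integer(0),
                      start_s = numeric(0)))
  }
  cutoff_s <- isi_cutoff_ms / 1000
  new_event <- c(TRUE, diff(spike_times) >= cutoff_s)
  event_id <- cumsum(new_event)
  sizes <- tabulate(event_id)
  data.frame(type = ifelse(sizes > 1L, "burst", "single"),
             n_spikes = sizes,
             start_s = spike_times[new_event])
}

#' Burst probability
#'
#' `BP = burst events / (burst events + single-spike events)`, computed
#' over response-window spikes pooled across trials (ISIs never bridge
#' trials). `NA` when no events occurred.
#'
#' @param aligned An [align_spikes()] result.
#' @param isi_cutoff_ms Burst ISI cutoff in ms.
#' @return BP in `[0, 1]` or `NA`.
#' @export
burst_probability <- function(aligned, isi_cutoff_ms = 5) {
  sp <- trial_window_spikes(aligned, "response")
  ev <- lapply(sp, parse_burst_events, isi_cutoff_ms = isi_cutoff_ms)
  types <- unlist(lapply(ev, `[[`, "type"))
  if (!length(types)) return(NA_real_)
  mean(types == "burst")
}

#' Classify a unit's firing regime from its burst probability
#'
#' Bursty iff `BP > 0.1` (strict); `BP <= 0.1` is tonic.
#'
#' @param bp Burst probability.
#' @return `"bursty"` or `"tonic"`.
#' @export
classify_burst_regime <- function(bp) {
  if (is.na(bp)) stop("BP undefined", call. = FALSE)
  if (bp > 0.1) "bursty" else "tonic"
}

#' Per-unit ISI cumulative distribution
#'
#' Empirical CDF of within-trial response-window ISIs evaluated on a 1 ms
#' grid. Units without any ISI yield `NULL` with a warning.
#'
#' @param aligned An [align_spikes()] result.
#' @param bin_ms Bin width in ms.
#' @param max_ms Upper edge of the grid in ms.
#' @return data.frame `isi_ms`, `cdf`, or `NULL` when the unit has no ISIs.
#' @export
isi_cdf <- function(aligned, bin_ms = 1, max_ms = 100) {
  sp <- trial_window_spikes(aligned, "response")
  isis <- unlist(lapply(sp, function(t) if (length(t) >= 2) diff(t)
                        else numeric(0)))
  if (!length(isis)) {
    warning("unit ", aligned$unit_id, " has no within-trial ISIs; excluded",
            call. = FALSE)
    return(NULL)
  }
  grid <- seq(bin_ms, max_ms, by = bin_ms)
  isis_ms <- isis * 1000
  data.frame(isi_ms = grid,
             cdf = vapply(grid, function(g)
               mean(isis_ms <= g + 1e-9), numeric(1)))
}

#' Population median ISI CDF
#'
#' Median across units, per 1 ms bin, of the per-unit ISI CDFs.
#'
#' @param cdfs List of [isi_cdf()] results (`NULL` entries dropped).
#' @return data.frame `isi_ms`, `cdf_median`.
#' @export
population_median_cdf <- function(cdfs) {
  cdfs <- Filter(Negate(is.null), cdfs)
  if (!length(cdfs)) stop("no units with defined ISI CDFs", call. = FALSE)
  grid <- cdfs[[1]]$isi_ms
  mat <- vapply(cdfs, function(d) d$cdf, numeric(length(grid)))
  data.frame(isi_ms = grid,
             cdf_median = apply(as.matrix(mat), 1, stats::median))
}

#' First temporal derivative of a pressure trace
#'
#' Central differences in the interior, one-sided differences at the edges.
#'
#' @param trace Uniformly sampled pressure values.
#' @param dt_s Sample interval (s).
#' @return dP/dt series, same length as `trace`.
#' @export
pressure_derivative <- function(trace, dt_s = 1) {
  n <- length(trace)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  d <- numeric(n)
  d[1] <- (trace[2] - trace[1]) / dt_s
  d[n] <- (trace[n] - trace[n - 1]) / dt_s
  if (n > 2L) {
    d[2:(n - 1)] <- (trace[3:n] - trace[1:(n - 2)]) / (2 * dt_s)
  }
  d
}

#' Per-unit, per-condition response metrics
#'
#' Computes the full metric bundle for one aligned unit/condition:
#' baseline and stimulus-evoked mean rates, modulation index, response
#' probability, burst probability and trial count.
#'
#' @param aligned An [align_spikes()] result.
#' @param isi_cutoff_ms Burst ISI cutoff in ms.
#' @return One-row data.frame: `unit_id`, `condition`, `r_base_hz`,
#'   `r_stim_hz`, `mi`, `rp`, `bp`, `n_trials`.
#' @export
unit_condition_metrics <- function(aligned, isi_cutoff_ms = 5) {
  rb <- mean_rate(aligned, "baseline")
  rs <- mean_rate(aligned, "response")
  data.frame(unit_id = aligned$unit_id, condition = aligned$condition,
             r_base_hz = rb, r_stim_hz = rs,
             mi = modulation_index(rs, rb),
             rp = response_probability(aligned),
             bp = burst_probability(aligned, isi_cutoff_ms),
             n_trials = length(aligned$trials))
}
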