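#' Default pipeline configuration
#'
#' A nested list holding every tunable parameter of the analysis with its
#' default: response windows (0.5 s onset delay, 1.5 s response window,
#' 1.5 s baseline), unit QC (refractory 1 ms, <0.5% violations, >0.1 Hz),
#' optotagging (latency < 9.5 ms; jitter < 3 ms for L5, < 2 ms for L6-CT;
#' responsive fraction >= 0.5 within a 25 ms search window), fast-spiking
#' waveform cutoff (215 microseconds), burst ISI cutoff (5 ms), the cortical
#' layer boundary table, timing-test resampling count, alpha, and the
#' synthetic-session / behavior generator parameters.
#'
#' @param ... Named overrides, e.g. `default_config(alpha = 0.01)`. Nested
#'   fields can be replaced by passing the whole sub-list.
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    alpha = 0.05,
    window = list(response_delay_s = 0.5, response_dur_s = 1.5,
                  baseline_dur_s = 1.5),
    qc = list(refractory_ms = 1, max_violation_rate = 0.005,
              min_rate_hz = 0.1),
    optotag = list(latency_max_ms = 9.5, jitter_max_ms_L5 = 3,
                   jitter_max_ms_L6CT = 2, min_responsive_fraction = 0.5,
                   search_window_ms = 25),
    fs_cutoff_us = 215,
    burst = list(isi_cutoff_ms = 5),
    layers = data.frame(
      layer = c("L2/3", "L4", "L5", "L6"),
      upper_um = c(100, 350, 500, 900),
      lower_um = c(350, 500, 900, 1300)),
    timing_test = list(n_resamples = 250L, method = "permutation"),
    simulate = list(
      n_units = 200L, n_trials = 40L, n_pulses = 40L,
      baseline_meanlog = 0, baseline_sdlog = 0.85,
      p_enhanced = 0.4, p_suppressed = 0.25,
      gain_enhanced = c(2, 3, 5), gain_suppressed = c(0.5, 1/3, 0.2),
      burst_prob_range = c(0, 0.6), burst_size_mean = 2,
      intra_burst_isi_ms = 3,
      tagged_fraction = 0.15, tag_latency_ms = c(4, 8),
      tag_jitter_ms = c(0.5, 1.5), tag_reliability = 0.9,
      stim_s = 5, gap_m_ml_s = 60, gap_other_s = 30),
    behavior = list(
      n_animals = 10L, threshold_g = 0.6, slope = 8, laser_shift = 4,
      filaments_g = c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0),
      n_per_filament = 5L,
      place = list(p_stay_paired = 0.95, p_stay_unpaired = 0.98,
                   duration_s = 1200, dt_s = 1)),
    optics = list(power_mW = 10, core_radius_mm = 0.1, NA_fiber = 0.39,
                  tissue_n = 1.36, scatter_per_mm = 11.2)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Validate a pipeline configuration
#'
#' Checks layer boundaries are ordered and non-overlapping and that all
#' thresholds are positive.
#'
#' @param cfg A configuration list.
#' @return `cfg` invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  lb <- cfg$layers
  if (!is.null(lb)) {
    lb <- as.data.frame(lb)
    if (any(lb$lower_um <= lb$upper_um)) {
      stop("layer intervals must have lower_um > upper_um", call. = FALSE)
    }
    if (is.unsorted(lb$upper_um, strictly = TRUE) ||
        any(utils::head(lb$lower_um, -1) > utils::tail(lb$upper_um, -1))) {
      stop("layer boundaries must be ordered by depth and non-overlapping",
           call. = FALSE)
    }
  }
  pos <- c(cfg$qc$refractory_ms, cfg$qc$max_violation_rate,
           cfg$qc$min_rate_hz, cfg$optotag$latency_max_ms,
           cfg$fs_cutoff_us, cfg$burst$isi_cutoff_ms, cfg$alpha)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults from
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.data.frame(base[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else if (is.data.frame(base[[nm]])) {
        base[[nm]] <- as.data.frame(over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write a pipeline configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$layers <- as.list(as.data.frame(cfg$layers))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
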