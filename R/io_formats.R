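#' @keywords internal
"_PACKAGE"

CONDITION_LEVELS <- c("L", "M", "ML", "PULSE")

#' Construct a spike train set
#'
#' Container for a population of sorted single units: per-unit spike times
#' (seconds, ascending) together with the cluster metadata needed downstream
#' (depth below pia, probe channel, waveform trough-to-peak metric).
#'
#' @param units data.frame with columns `unit_id`, `depth_um`, `channel`
#'   and optionally `trough_peak_us`.
#' @param spikes named list of numeric vectors (seconds), names matching
#'   `unit_id`.
#' @param recording_duration Recording length in seconds.
#' @param sampling_rate Acquisition sampling rate in Hz.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(units, spikes, recording_duration,
                            sampling_rate = 30030) {
  units <- as.data.frame(units)
  stopifnot(all(c("unit_id", "depth_um", "channel") %in% names(units)))
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) {
    stop("unit_id values must be unique", call. = FALSE)
  }
  if (!("trough_peak_us" %in% names(units))) units$trough_peak_us <- NA_real_
  if (!is.list(spikes) || is.null(names(spikes))) {
    stop("spikes must be a named list of numeric vectors", call. = FALSE)
  }
  missing <- setdiff(units$unit_id, names(spikes))
  for (m in missing) spikes[[m]] <- numeric(0)
  spikes <- spikes[units$unit_id]
  for (u in units$unit_id) {
    st <- spikes[[u]]
    if (is.unsorted(st)) stop("spike times for unit ", u,
                              " are not ascending", call. = FALSE)
    if (length(st) && (min(st) < 0 || max(st) > recording_duration)) {
      stop("spike times for unit ", u,
           " fall outside [0, recording_duration]", call. = FALSE)
    }
  }
  units$n_spikes <- vapply(spikes, length, integer(1))
  structure(list(units = units, spikes = spikes,
                 recording_duration = as.numeric(recording_duration),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("<spike_train_set> ", nrow(x$units), " units, ",
      sum(x$units$n_spikes), " spikes, ",
      format(x$recording_duration, digits = 6), " s @ ",
      x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Construct a trial event table
#'
#' Per-trial stimulus records: condition (`L` laser-only, `M` mechanical,
#' `ML` mechanical + laser, `PULSE` brief optotagging light pulse), onset
#' and duration in seconds, and optional laser power / mechanical force.
#'
#' @param condition character vector from the closed vocabulary.
#' @param onset_s,duration_s numeric vectors (seconds).
#' @param laser_power_mW,force_g optional numeric vectors.
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(condition, onset_s, duration_s,
                        laser_power_mW = NA_real_, force_g = NA_real_) {
  condition <- toupper(as.character(condition))
  bad <- which(!condition %in% CONDITION_LEVELS)
  if (length(bad)) {
    stop("unknown condition value(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(condition[bad]), collapse = ", "),
         " (expected L, M, ML or PULSE)", call. = FALSE)
  }
  if (any(duration_s <= 0)) {
    stop("duration_s must be positive (row(s) ",
         paste(which(duration_s <= 0), collapse = ", "), ")", call. = FALSE)
  }
  if (is.unsorted(onset_s)) {
    stop("trial onsets must be non-decreasing", call. = FALSE)
  }
  out <- data.frame(condition = condition, onset_s = as.numeric(onset_s),
                    duration_s = as.numeric(duration_s),
                    laser_power_mW = as.numeric(laser_power_mW),
                    force_g = as.numeric(force_g))
  class(out) <- c("event_table", "data.frame")
  out
}

#' Read a Phy/Kilosort-style sorted spike directory
#'
#' Expects `spike_times.npy` (per-spike sample indices), `spike_clusters.npy`
#' (per-spike cluster labels) and a tab-separated cluster metadata table
#' (`cluster_info.tsv`) with columns `unit_id` (or `cluster_id`), `group`,
#' `depth_um`, `channel` and optionally `trough_peak_us`. Only clusters
#' curated as `"good"` are returned; sample indices are converted to seconds
#' via `sampling_rate`.
#'
#' @param path Directory containing the three files.
#' @param sampling_rate Sampling rate in Hz used for the index-to-seconds
#'   conversion (acquisition default 30030 Hz).
#' @param recording_duration Optional recording length (seconds); defaults
#'   to the last spike time rounded up.
#' @return A [spike_train_set()].
#' @export
read_sorted_spikes <- function(path, sampling_rate = 30030,
                               recording_duration = NULL) {
  req <- c("spike_times.npy", "spike_clusters.npy", "cluster_info.tsv")
  for (f in req) {
    if (!file.exists(file.path(path, f))) {
      stop("missing required file '", f, "' in ", path, call. = FALSE)
    }
  }
  samples <- read_npy(file.path(path, "spike_times.npy"))
  clusters <- read_npy(file.path(path, "spike_clusters.npy"))
  if (length(samples) != length(clusters)) {
    stop("format error: spike_times.npy (", length(samples),
         ") and spike_clusters.npy (", length(clusters),
         ") have different lengths", call. = FALSE)
  }
  info <- utils::read.delim(file.path(path, "cluster_info.tsv"),
                            stringsAsFactors = FALSE)
  if ("cluster_id" %in% names(info) && !"unit_id" %in% names(info)) {
    names(info)[names(info) == "cluster_id"] <- "unit_id"
  }
  stopifnot(all(c("unit_id", "group", "depth_um", "channel") %in% names(info)))
  good <- info[info$group == "good", , drop = FALSE]
  times_s <- samples / sampling_rate
  spikes <- list()
  for (i in seq_len(nrow(good))) {
    uid <- good$unit_id[i]
    st <- sort(times_s[clusters == as.numeric(uid)])
    if (!length(st)) {
      warning("unit ", uid, " listed in cluster_info.tsv has no spikes ",
              "in spike_clusters.npy", call. = FALSE)
    }
    spikes[[as.character(uid)]] <- st
  }
  if (is.null(recording_duration)) {
    recording_duration <- if (length(times_s)) ceiling(max(times_s)) else 0
  }
  good$unit_id <- as.character(good$unit_id)
  spike_train_set(good[, intersect(c("unit_id", "depth_um", "channel",
                                     "trough_peak_us"), names(good))],
                  spikes, recording_duration, sampling_rate)
}

#' Read spike times from a plain CSV fallback
#'
#' Portable alternative to the Phy directory layout: a delimited file with
#' columns `unit_id` and `spike_time_s` (plus optional `depth_um`,
#' `channel`, `trough_peak_us`, constant within unit).
#'
#' @inheritParams read_sorted_spikes
#' @param path CSV/TSV file path.
#' @return A [spike_train_set()].
#' @export
read_spikes_csv <- function(path, recording_duration = NULL,
                            sampling_rate = 30030) {
  df <- read_delim_auto(path)
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(df)))
  df$unit_id <- as.character(df$unit_id)
  ids <- unique(df$unit_id)
  spikes <- lapply(ids, function(u) sort(df$spike_time_s[df$unit_id == u]))
  names(spikes) <- ids
  meta <- function(col, default) {
    if (col %in% names(df)) {
      vapply(ids, function(u) df[[col]][df$unit_id == u][1], numeric(1))
    } else rep(default, length(ids))
  }
  units <- data.frame(unit_id = ids,
                      depth_um = meta("depth_um", NA_real_),
                      channel = meta("channel", NA_real_),
                      trough_peak_us = meta("trough_peak_us", NA_real_))
  if (is.null(recording_duration)) {
    recording_duration <- ceiling(max(df$spike_time_s))
  }
  spike_train_set(units, spikes, recording_duration, sampling_rate)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' Read a trial event table from delimited text
#'
#' Requires a header with `condition`, `onset_s`, `duration_s`; optional
#' `laser_power_mW` and `force_g` columns are attached to trials. Unknown
#' condition strings and non-positive durations are rejected with the
#' offending row number.
#'
#' @param path CSV or TSV file.
#' @return An [event_table()].
#' @export
read_event_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("condition", "onset_s", "duration_s")
  if (!all(need %in% names(df))) {
    stop("event table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  event_table(df$condition, df$onset_s, df$duration_s,
              laser_power_mW = if ("laser_power_mW" %in% names(df))
                df$laser_power_mW else NA_real_,
              force_g = if ("force_g" %in% names(df)) df$force_g
                else NA_real_)
}

#' Write a results table as TSV
#'
#' Stable column order, floating-point columns at 6 significant digits;
#' round-trips through [read_results_table()].
#'
#' @param records data.frame of homogeneous records (may have zero rows).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"),
    error = function(e) stop("cannot write results table to ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an event table as TSV
#' @param events An [event_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  write_results_table(as.data.frame(events), path)
}

#' Write a spike train set as a Phy-style directory
#'
#' Emits `spike_times.npy` (sample indices, unsigned 64-bit),
#' `spike_clusters.npy` (32-bit ints) and `cluster_info.tsv`, the layout
#' [read_sorted_spikes()] consumes. Unit ids must be coercible to integers.
#'
#' @param train A [spike_train_set()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_sorted_spikes <- function(train, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- suppressWarnings(as.integer(train$units$unit_id))
  if (anyNA(ids)) stop("unit ids must be integer-like for the Phy layout",
                       call. = FALSE)
  samples <- unlist(lapply(train$spikes, function(s)
    round(s * train$sampling_rate)), use.names = FALSE)
  clusters <- rep(ids, times = train$units$n_spikes)
  ord <- order(samples)
  write_npy(samples[ord], file.path(path, "spike_times.npy"), "<u8")
  write_npy(clusters[ord], file.path(path, "spike_clusters.npy"), "<i4")
  info <- data.frame(unit_id = ids, group = "good",
                     depth_um = train$units$depth_um,
                     channel = train$units$channel,
                     trough_peak_us = train$units$trough_peak_us)
  utils::write.table(info, file.path(path, "cluster_info.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
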