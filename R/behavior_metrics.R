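#' Psychometric withdrawal curve from von Frey trial outcomes
#'
#' Withdrawal probability per filament. Filaments after an all-withdrawal
#' filament (the ascending stop rule) or already marked censored are
#' imputed at probability 1.0 and flagged -- the stop rule only fires after
#' a 100% filament, so 1.0 is the conservative continuation.
#'
#' @param outcomes data.frame with `force_g`, `withdrawal` (0/1, `NA` on
#'   untested trials) and optionally `censored`.
#' @return data.frame of class `psychometric_curve`: `force_g`, `prob`,
#'   `n_trials`, `censored`.
#' @export
withdrawal_curve <- function(outcomes) {
  if (!nrow(outcomes)) stop("no trials", call. = FALSE)
  forces <- sort(unique(outcomes$force_g))
  rows <- lapply(forces, function(f) {
    sub <- outcomes[outcomes$force_g == f, ]
    cens <- ("censored" %in% names(outcomes) && all(sub$censored)) ||
      all(is.na(sub$withdrawal))
    data.frame(force_g = f,
               prob = if (cens) 1.0 else mean(sub$withdrawal),
               n_trials = if (cens) 0L else sum(!is.na(sub$withdrawal)),
               censored = cens)
  })
  curve <- do.call(rbind, rows)
  # stop rule: everything above the first all-withdrawal filament is
  # censored even if trials were (erroneously) recorded
  full <- which(!curve$censored & curve$prob == 1)
  if (length(full)) {
    above <- seq_along(curve$force_g) > min(full)
    curve$censored[above] <- TRUE
    curve$prob[above] <- 1.0
  }
  class(curve) <- c("psychometric_curve", "data.frame")
  curve
}

#' Withdrawal threshold at a probability level
#'
#' Smallest force at which the curve reaches `level` (default 60%
#' withdrawal). Between bracketing filaments the crossing is interpolated
#' linearly on log10(force) -- the filament series is approximately
#' geometric. If the first filament already reaches the level its force is
#' returned; if the level is never reached the result is `NA` with
#' attribute `censored_above_max = TRUE`.
#'
#' @param curve A [withdrawal_curve()] result.
#' @param level Probability level in (0, 1].
#' @return Force in grams (possibly `NA`, see above).
#' @export
threshold_at <- function(curve, level = 0.6) {
  if (!nrow(curve)) stop("empty curve", call. = FALSE)
  at <- which(curve$prob >= level)
  if (!length(at)) {
    return(structure(NA_real_, censored_above_max = TRUE))
  }
  i <- min(at)
  if (i == 1L || curve$prob[i] == level) return(curve$force_g[i])
  p0 <- curve$prob[i - 1]; p1 <- curve$prob[i]
  f0 <- log10(curve$force_g[i - 1]); f1 <- log10(curve$force_g[i])
  10^(f0 + (level - p0) / (p1 - p0) * (f1 - f0))
}

#' Area under the sensitivity curve
#'
#' Trapezoidal area of withdrawal probability over the force axis
#' (units probability x grams), including imputed censored points. With
#' `normalize = TRUE` the area is divided by the force range; with
#' `axis = "log10"` the abscissa is log10(force).
#'
#' @param curve A [withdrawal_curve()] result with `>= 2` forces.
#' @param normalize Divide by the abscissa range.
#' @param axis `"linear"` (default) or `"log10"`.
#' @return AUC value.
#' @export
sensitivity_auc <- function(curve, normalize = FALSE,
                            axis = c("linear", "log10")) {
  axis <- match.arg(axis)
  if (nrow(curve) < 2) stop("need at least 2 forces", call. = FALSE)
  if (all(curve$censored)) stop("curve is entirely censored", call. = FALSE)
  x <- if (axis == "linear") curve$force_g else log10(curve$force_g)
  y <- curve$prob
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (normalize) auc <- auc / (max(x) - min(x))
  auc
}

#' Place preference index
#'
#' `PI = (time paired - time unpaired) / (time paired + time unpaired)`;
#' 1 is full preference for, -1 full avoidance of the paired chamber.
#'
#' @param time_paired_s,time_unpaired_s Dwell times (s), both `>= 0`.
#' @return PI in `[-1, 1]` (`NA` when both are zero).
#' @export
preference_index <- function(time_paired_s, time_unpaired_s) {
  stopifnot(time_paired_s >= 0, time_unpaired_s >= 0)
  tot <- time_paired_s + time_unpaired_s
  if (tot == 0) return(NA_real_)
  (time_paired_s - time_unpaired_s) / tot
}

#' Chamber occupancy times from a position trace
#'
#' Dwell seconds per chamber from uniformly sampled positions; samples in
#' neither rectangle (including out-of-arena positions, which trigger a
#' warning) count as neutral.
#'
#' @param positions data.frame with `x_cm`, `y_cm`, uniformly sampled.
#' @param dt_s Sample interval (s).
#' @param chambers named list `paired`, `unpaired` of rectangles
#'   `c(xmin, xmax, ymin, ymax)`; defaults match
#'   [simulate_place_session()].
#' @param arena Optional arena rectangle for the out-of-bounds warning.
#' @return list of class `place_session`: `paired_s`, `unpaired_s`,
#'   `neutral_s`.
#' @export
occupancy_times <- function(positions, dt_s = 1,
                            chambers = list(paired = c(0, 15, 0, 15),
                                            unpaired = c(23, 38, 0, 15)),
                            arena = c(0, 38, 0, 15)) {
  inside <- function(r) positions$x_cm >= r[1] & positions$x_cm <= r[2] &
    positions$y_cm >= r[3] & positions$y_cm <= r[4]
  in_p <- inside(chambers$paired)
  in_u <- inside(chambers$unpaired) & !in_p
  if (!is.null(arena) && any(!inside(arena))) {
    warning(sum(!inside(arena)), " sample(s) outside the arena counted as ",
            "neutral", call. = FALSE)
  }
  n <- nrow(positions)
  structure(list(paired_s = sum(in_p) * dt_s,
                 unpaired_s = sum(in_u) * dt_s,
                 neutral_s = (n - sum(in_p) - sum(in_u)) * dt_s),
            class = "place_session")
}

#' Paw-lift laser intensity threshold
#'
#' The highest tested intensity whose trials produced no paw lift -- the
#' per-animal stimulation intensity used for sensitivity measurements. If
#' every intensity produced lifts, the lowest intensity is returned with
#' attribute `all_lifting = TRUE`.
#'
#' @param intensities Ascending tested intensities (mW or mW/mm^2).
#' @param lifts Lift counts per intensity.
#' @param n_trials Trials per intensity (default 5).
#' @return Threshold intensity (with attribute flag in the degenerate
#'   case).
#' @export
paw_lift_threshold <- function(intensities, lifts, n_trials = 5) {
  if (!length(intensities)) stop("empty input", call. = FALSE)
  stopifnot(length(lifts) == length(intensities), !is.unsorted(intensities))
  ok <- which(lifts == 0)
  if (!length(ok)) {
    return(structure(intensities[1], all_lifting = TRUE))
  }
  intensities[max(ok)]
}

#' Mean Hargreaves withdrawal latency
#'
#' Plain mean of the per-trial thermal withdrawal latencies (bookkeeping
#' only; trials are capped at the apparatus cutoff).
#'
#' @param latencies_s Per-trial latencies (s).
#' @param cutoff_s Apparatus cutoff (s).
#' @return Mean latency (s).
#' @export
hargreaves_latency <- function(latencies_s, cutoff_s = 20) {
  stopifnot(length(latencies_s) >= 1)
  mean(pmin(latencies_s, cutoff_s))
}
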