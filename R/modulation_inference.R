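with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Paired spike-count modulation test
#'
#' Two-sided Wilcoxon signed-rank test on paired baseline vs
#' stimulus-evoked spike counts per trial (see [wilcoxon_signed_rank()]
#' for the exact/approximate branching).
#'
#' @param baseline_counts,response_counts Equal-length per-trial counts.
#' @return list: `p`, `statistic`, `n`, `method`, `delta_count` (mean
#'   response minus baseline count per trial), `all_zero` flag.
#' @export
paired_count_test <- function(baseline_counts, response_counts) {
  stopifnot(length(baseline_counts) == length(response_counts))
  res <- wilcoxon_signed_rank(response_counts, baseline_counts)
  res$delta_count <- mean(response_counts - baseline_counts)
  res
}

timing_stat <- function(sorted_times, span) {
  n <- length(sorted_times)
  d <- seq_len(n) / n - sorted_times / span
  max(abs(d - mean(d)))
}

#' Time-locked deviation (ZETA-style) spike-timing test
#'
#' Tests whether spike timing within the response window deviates from
#' temporal uniformity, pooling trials. The statistic is the maximal
#' absolute value of the mean-centered difference between the empirical CDF
#' of pooled relative spike times and the uniform CDF, evaluated at the
#' spike times. The null distribution is built by circularly shifting each
#' trial's spike times by independent uniform offsets; the p-value is the
#' empirical tail probability with add-one correction, or a Gumbel tail
#' approximation fitted to the null maxima.
#'
#' @param aligned An [align_spikes()] result.
#' @param n_resamples Number of resamples for the null.
#' @param seed Optional integer seed (restores the global RNG state).
#' @param method `"permutation"` (default, assumption-free) or `"gumbel"`.
#' @return list: `statistic`, `p`, `testable`, `method`, `n_spikes`.
#' @export
timing_deviation_test <- function(aligned, n_resamples = 250, seed = NULL,
                                  method = c("permutation", "gumbel")) {
  method <- match.arg(method)
  w <- aligned$window
  span <- w$response_dur_s
  trials <- trial_window_spikes(aligned, "response")
  rel <- lapply(trials, function(t) t - w$response_delay_s)
  times <- unlist(rel)
  n <- length(times)
  if (n == 0L) {
    return(list(statistic = NA_real_, p = NA_real_, testable = FALSE,
                method = method, n_spikes = 0L))
  }
  stat <- timing_stat(sort(times), span)
  trial_idx <- rep(seq_along(rel), times = vapply(rel, length, integer(1)))
  null_max <- with_seed(seed, {
    offsets <- matrix(stats::runif(length(rel) * n_resamples, 0, span),
                      nrow = length(rel))
    shifted <- (times + offsets[trial_idx, , drop = FALSE]) %% span
    shifted <- apply(shifted, 2, sort.int, method = "quick")
    if (!is.matrix(shifted)) shifted <- matrix(shifted, nrow = n)
    d <- seq_len(n) / n - shifted / span
    d <- sweep(d, 2, colMeans(d))
    apply(abs(d), 2, max)
  })
  if (method == "permutation") {
    p <- (1 + sum(null_max >= stat)) / (1 + n_resamples)
  } else {
    beta <- sqrt(6 * stats::var(null_max)) / pi
    mu <- mean(null_max) - 0.5772156649 * beta
    p <- 1 - exp(-exp(-(stat - mu) / beta))
  }
  list(statistic = stat, p = p, testable = TRUE, method = method,
       n_spikes = n)
}

#' Classify a unit's modulation from the two tests
#'
#' A unit is modulated in a condition when either the paired count test or
#' the timing test is significant at `alpha`. Direction: `enhanced` /
#' `suppressed` when the count test is significant with positive / negative
#' mean count change; `timing_only` when only the timing test is
#' significant (plotted at zero count change); `none` otherwise.
#'
#' @param p_count,p_timing P-values (`NA` when untestable).
#' @param delta_count Mean response-minus-baseline count per trial.
#' @param alpha Significance level.
#' @return list: `significant`, `direction`, `p_count`, `p_timing`,
#'   `delta_count`.
#' @export
classify_modulation <- function(p_count, p_timing, delta_count,
                                alpha = 0.05) {
  if (is.na(p_count) && is.na(p_timing)) {
    stop("both p-values undefined", call. = FALSE)
  }
  count_sig <- !is.na(p_count) && p_count <= alpha
  timing_sig <- !is.na(p_timing) && p_timing <= alpha
  direction <- if (count_sig && delta_count > 0) "enhanced"
    else if (count_sig && delta_count < 0) "suppressed"
    else if (timing_sig) "timing_only"
    else "none"
  list(significant = count_sig || timing_sig, direction = direction,
       p_count = p_count, p_timing = p_timing, delta_count = delta_count)
}

#' Modulated-unit proportions per group and condition
#'
#' Tabulates enhanced / suppressed / timing-only / unmodulated fractions
#' (summing to 1) per group (layer or region) and stimulation condition.
#'
#' @param calls data.frame with columns `group`, `condition`, `direction`.
#' @return data.frame, one row per group x condition present in `calls`.
#' @export
condition_proportions <- function(calls) {
  stopifnot(all(c("group", "condition", "direction") %in% names(calls)))
  keys <- unique(calls[, c("group", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- calls[calls$group == keys$group[i] &
                 calls$condition == keys$condition[i], ]
    n <- nrow(sub)
    data.frame(group = keys$group[i], condition = keys$condition[i],
               n = n,
               n_enhanced = sum(sub$direction == "enhanced"),
               n_suppressed = sum(sub$direction == "suppressed"),
               n_timing_only = sum(sub$direction == "timing_only"),
               n_none = sum(sub$direction == "none"),
               frac_enhanced = mean(sub$direction == "enhanced"),
               frac_suppressed = mean(sub$direction == "suppressed"),
               frac_timing_only = mean(sub$direction == "timing_only"),
               frac_none = mean(sub$direction == "none"))
  })
  do.call(rbind, rows)
}
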