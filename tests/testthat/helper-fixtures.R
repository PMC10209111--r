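# Shared fixtures and independent reference implementations (oracles).

# Build an aligned_responses object directly from per-trial relative times.
make_aligned <- function(trials, window = window_spec(), unit_id = "u1",
                         condition = "L") {
  structure(list(unit_id = unit_id, condition = condition, trials = trials,
                 window = window, onsets = seq_along(trials)),
            class = "aligned_responses")
}

# Homogeneous-Poisson null unit: spikes iid uniform over the aligned span.
make_null_unit <- function(seed, rate_hz = 5, n_trials = 40,
                           window = window_spec()) {
  set.seed(seed)
  span <- window$baseline_dur_s + window$response_delay_s +
    window$response_dur_s
  trials <- lapply(seq_len(n_trials), function(i) {
    sort(stats::runif(stats::rpois(1, rate_hz * span),
                      -window$baseline_dur_s,
                      window$response_delay_s + window$response_dur_s))
  })
  make_aligned(trials, window)
}

# Brute-force burst parser: walk the train spike by spike.
reference_burst_parser <- function(times_s, isi_cutoff_ms = 5) {
  if (!length(times_s)) {
    return(data.frame(type = character(0), n_spikes = integer(0)))
  }
  cutoff <- isi_cutoff_ms / 1000
  sizes <- c()
  cur <- 1L
  for (i in seq_along(times_s)[-1]) {
    if (times_s[i] - times_s[i - 1] < cutoff) {
      cur <- cur + 1L
    } else {
      sizes <- c(sizes, cur)
      cur <- 1L
    }
  }
  sizes <- c(sizes, cur)
  data.frame(type = ifelse(sizes > 1, "burst", "single"), n_spikes = sizes)
}

# Exact signed-rank p by enumeration of all 2^n sign patterns.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  ple <- mean(v_all <= v_obs + 1e-9)
  pge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(ple, pge))
}

# Exact rank-sum p by enumeration of all C(m+n, m) labelings.
enumerate_rank_sum_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(r), m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  ple <- mean(w_all <= w_obs + 1e-9)
  pge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(ple, pge))
}

# Exact McNemar p as a direct binomial tail sum via choose().
enumerate_mcnemar_p <- function(b, c) {
  n <- b + c
  pmf <- choose(n, 0:n) / 2^n
  min(1, 2 * sum(pmf[seq_len(min(b, c) + 1)]))
}

# Exact Friedman permutation p by full enumeration of within-block
# orderings, with the tie-corrected statistic taken from stats::friedman.test.
enumerate_friedman_p <- function(mat) {
  k <- ncol(mat)
  n <- nrow(mat)
  q_of <- function(m) unname(stats::friedman.test(m)$statistic)
  q_obs <- q_of(mat)
  perms <- matrix(unlist(combinat_perms(seq_len(k))), ncol = k,
                  byrow = TRUE)
  idx <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), n))
  q_all <- apply(idx, 1, function(row) {
    pm <- mat
    for (i in seq_len(n)) pm[i, ] <- mat[i, perms[row[i], ]]
    q_of(pm)
  })
  mean(q_all >= q_obs - 1e-9)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Small Phy-style directory fixture on disk.
write_phy_fixture <- function(dir, groups = c("good", "good", "noise"),
                              rate_hz = 30030) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # cluster 1: spikes at samples 30030, 60060; cluster 2: 15015;
  # cluster 3 (noise): 100
  samples <- c(100, 15015, 30030, 60060)
  clusters <- c(3, 2, 1, 1)
  ord <- order(samples)
  write_npy(samples[ord], file.path(dir, "spike_times.npy"), "<u8")
  write_npy(clusters[ord], file.path(dir, "spike_clusters.npy"), "<i4")
  info <- data.frame(unit_id = 1:3, group = groups,
                     depth_um = c(1205, 589, 300), channel = c(60, 29, 15),
                     trough_peak_us = c(400, 500, 200))
  utils::write.table(info, file.path(dir, "cluster_info.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
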