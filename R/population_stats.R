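#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired differences `x - y`. Zero
#' differences are dropped; absolute differences are ranked with midranks
#' for ties. For `n <= exact_max` the null distribution of the positive-rank
#' sum is computed exactly by convolution over the observed (possibly tied)
#' ranks; above that a normal approximation with tie correction and
#' continuity correction is used. The exact branch covers typical trial
#' counts (it is O(n * sum(ranks)) and handles ties), which keeps the test
#' at or below its nominal level on discrete count data where the normal
#' approximation is slightly anticonservative.
#'
#' @param x,y Equal-length numeric vectors.
#' @param exact_max Largest `n` for the exact branch.
#' @return list: `statistic` (positive-rank sum V), `p`, `n` (pairs after
#'   zero removal), `method`, `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 60) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate",
                all_zero = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    s <- as.integer(round(2 * r))      # midranks doubled -> integers
    total <- sum(s)
    # dp[w+1] = number of sign assignments with doubled rank-sum w
    dp <- numeric(total + 1)
    dp[1] <- 1
    for (si in s) {
      shifted <- c(numeric(si), dp[seq_len(total + 1 - si)])
      dp <- dp + shifted
    }
    dp <- dp / sum(dp)
    w2 <- as.integer(round(2 * v))
    ple <- sum(dp[seq_len(w2 + 1)])
    pge <- sum(dp[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(ple, pge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = v, p = p, n = n, method = method, all_zero = FALSE)
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. For `m + n <= exact_max`
#' the null distribution of the rank sum of `x` is computed exactly by
#' dynamic programming over the observed pooled ranks; otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Largest pooled size for the exact branch.
#' @return list: `statistic` (rank sum W of `x`), `p`, `method`.
#' @export
rank_sum <- function(x, y, exact_max = 20) {
  m <- length(x); n <- length(y)
  stopifnot(m > 0, n > 0)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(m)])
  N <- m + n
  if (N <= exact_max) {
    s <- as.integer(round(2 * r))
    total <- sum(s)
    # dp[[k]][w+1] = number of k-subsets of the doubled ranks with sum w
    dp <- vector("list", m + 1)
    dp[[1]] <- c(1, numeric(total))
    for (k in seq_len(m)) dp[[k + 1]] <- numeric(total + 1)
    for (si in s) {
      for (k in rev(seq_len(m))) {
        shifted <- c(numeric(si), dp[[k]][seq_len(total + 1 - si)])
        dp[[k + 1]] <- dp[[k + 1]] + shifted
      }
    }
    dist <- dp[[m + 1]] / sum(dp[[m + 1]])
    w2 <- as.integer(round(2 * w))
    ple <- sum(dist[seq_len(w2 + 1)])
    pge <- sum(dist[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(ple, pge))
    method <- "exact"
  } else {
    mu <- m * (N + 1) / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p = p, method = method)
}

#' McNemar's test for paired proportions
#'
#' Exact two-sided binomial test on the discordant-pair counts for
#' `b + c < exact_min_chisq`; chi-square with continuity correction above.
#'
#' @param b,c Discordant pair counts.
#' @param exact_min_chisq Switch point to the asymptotic branch.
#' @return list: `p`, `method`, `degenerate` flag (`b + c == 0`).
#' @export
mcnemar <- function(b, c, exact_min_chisq = 25) {
  stopifnot(b >= 0, c >= 0)
  nd <- b + c
  if (nd == 0) return(list(p = 1, method = "degenerate", degenerate = TRUE))
  if (nd < exact_min_chisq) {
    p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
    method <- "exact"
  } else {
    x2 <- (abs(b - c) - 1)^2 / nd
    p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
    method <- "chisq_cc"
  }
  list(p = p, method = method, degenerate = FALSE)
}

#' Chi-square homogeneity test for k proportions
#'
#' Pearson chi-square on the k x 2 (success, failure) table against the
#' pooled proportion; `df = k - 1`. `correct = TRUE` applies the Yates
#' continuity correction (two groups only).
#'
#' @param successes,n Integer vectors, one entry per group.
#' @param correct Apply the Yates continuity correction (`k == 2`).
#' @return list: `statistic`, `df`, `p`.
#' @export
chisq_homogeneity <- function(successes, n, correct = FALSE) {
  k <- length(successes)
  stopifnot(k >= 2, length(n) == k, all(successes >= 0), all(successes <= n),
            all(n > 0))
  p_pool <- sum(successes) / sum(n)
  if (p_pool %in% c(0, 1)) {
    stop("an expected count is zero; use an exact test", call. = FALSE)
  }
  exp_s <- n * p_pool
  exp_f <- n * (1 - p_pool)
  cc <- if (correct && k == 2) pmin(0.5, abs(successes - exp_s)) else 0
  stat <- sum((abs(successes - exp_s) - cc)^2 / exp_s +
              (abs((n - successes) - exp_f) - cc)^2 / exp_f)
  df <- k - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Marascuillo procedure for pairwise proportion comparisons
#'
#' After a significant k-proportion chi-square test, pair `(i, j)` is
#' declared different when `|p_i - p_j|` exceeds the critical range
#' `sqrt(chi^2_{1-alpha, k-1}) * sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)`.
#'
#' @param successes,n Integer vectors (k >= 3 groups).
#' @param labels Optional group labels.
#' @param alpha Family-wise level.
#' @return data.frame, one row per pair: `group_i`, `group_j`, `diff`,
#'   `critical_range`, `significant`.
#' @export
marascuillo <- function(successes, n, labels = NULL, alpha = 0.05) {
  k <- length(successes)
  if (k < 3) stop("need k >= 3 groups; use a two-proportion test",
                  call. = FALSE)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  p <- successes / n
  crit_mult <- sqrt(stats::qchisq(1 - alpha, df = k - 1))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    rng <- crit_mult * sqrt(p[i] * (1 - p[i]) / n[i] +
                            p[j] * (1 - p[j]) / n[j])
    c(diff = abs(p[i] - p[j]), critical_range = rng)
  })
  data.frame(group_i = labels[pairs[1, ]], group_j = labels[pairs[2, ]],
             diff = res["diff", ], critical_range = res["critical_range", ],
             significant = res["diff", ] > res["critical_range", ],
             row.names = NULL)
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Friedman test for repeated measures across conditions
#'
#' Within-block midranks; tie-corrected statistic
#' `Q = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` with
#' `A = sum r_ij^2`, `C = n k (k+1)^2 / 4`, which reduces to the classic
#' statistic without ties. P-value from the chi-square reference with
#' `k - 1` df, or from exact enumeration of all within-block rank
#' permutations when requested and feasible.
#'
#' @param mat Numeric matrix, blocks (subjects) in rows, conditions in
#'   columns; `>= 2` rows and `>= 3` columns.
#' @param exact Use the exact permutation null (feasible for small
#'   `(k!)^n`; enforced limit 2e5 arrangements).
#' @return list: `statistic` (Q), `df`, `p`, `method`.
#' @export
friedman <- function(mat, exact = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 2, k >= 3)
  ranks <- t(apply(mat, 1, rank))
  Rj <- colSums(ranks)
  A <- sum(ranks^2)
  C <- n * k * (k + 1)^2 / 4
  Q <- if (A == C) 0 else (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  df <- k - 1
  if (exact) {
    n_arr <- factorial(k)^n
    if (n_arr > 2e5) stop("exact Friedman infeasible for (k!)^n = ", n_arr,
                          call. = FALSE)
    # cross-product of within-block rank permutations, accumulating the
    # column rank sums; A and C are permutation-invariant
    acc <- matrix(0, nrow = 1, ncol = k)
    for (i in seq_len(n)) {
      perms <- permutations_of(ranks[i, ])
      a_rep <- acc[rep(seq_len(nrow(acc)), times = nrow(perms)), ,
                   drop = FALSE]
      p_rep <- perms[rep(seq_len(nrow(perms)), each = nrow(acc)), ,
                     drop = FALSE]
      acc <- a_rep + p_rep
    }
    if (A == C) {
      Qs <- rep(0, nrow(acc))
    } else {
      Qs <- (k - 1) * rowSums((acc - n * (k + 1) / 2)^2) / (A - C)
    }
    p <- mean(Qs >= Q - 1e-12)
    return(list(statistic = Q, df = df, p = p, method = "exact"))
  }
  p <- stats::pchisq(Q, df, lower.tail = FALSE)
  list(statistic = Q, df = df, p = p, method = "chisq")
}
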