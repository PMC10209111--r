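test_that("signed-rank exact branch matches full sign enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p, 0.0625)
  expect_equal(wilcoxon_signed_rank(rep(2, 8), rep(2, 8))$p, 1)
  expect_true(wilcoxon_signed_rank(rep(2, 8), rep(2, 8))$all_zero)

  set.seed(1)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, sd = 2), if (i %% 2) 2 else 0)  # ties when rounded
    d <- d[d != 0]
    if (length(d) < 3) next
    expect_equal(wilcoxon_signed_rank(d)$p, enumerate_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with wilcox.test and its own approximation", {
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # exact vs normal approximation at n = 25 within 0.01
  for (i in 1:10) {
    z <- rnorm(25)
    pe <- wilcoxon_signed_rank(z, exact_max = 25)$p
    pa <- wilcoxon_signed_rank(z, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("rank-sum exact branch matches labeling enumeration", {
  expect_equal(rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(rank_sum(c(1, 1, 1), c(1, 1, 1))$p, 1)

  set.seed(3)
  for (i in 1:25) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- round(rnorm(m, sd = 2), if (i %% 2) 2 else 0)
    y <- round(rnorm(n, sd = 2), if (i %% 2) 2 else 0)
    expect_equal(rank_sum(x, y)$p, enumerate_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum agrees with wilcox.test and is symmetric", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(rank_sum(x, y)$p, wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(rank_sum(x, y)$p, rank_sum(y, x)$p)
  # exact vs normal approximation at m = n = 10 within 0.01
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    pe <- rank_sum(a, b, exact_max = 20)$p
    pa <- rank_sum(a, b, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("McNemar exact p is the binomial tail and matches the oracle", {
  expect_equal(mcnemar(8, 2)$p, 112 / 1024)
  expect_equal(mcnemar(5, 5)$p, 1)
  expect_true(mcnemar(0, 0)$degenerate)
  for (b in 0:12) {
    for (cc in 0:(12 - b)) {
      if (b + cc == 0) next
      expect_equal(mcnemar(b, cc)$p, enumerate_mcnemar_p(b, cc),
                   tolerance = 1e-12)
    }
  }
  # exact vs continuity-corrected chi-square near the switch point
  p_ex <- min(1, 2 * pbinom(9, 25, 0.5))
  p_cc <- mcnemar(16, 9)$p
  expect_lt(abs(p_ex - p_cc), 0.02)
})

test_that("chi-square homogeneity matches hand computation and base R", {
  z <- chisq_homogeneity(c(30, 30), c(100, 100))
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)

  h <- chisq_homogeneity(c(90, 50), c(100, 100))
  # expected successes 70 each: 2 * (400/70 + 400/30)
  expect_equal(h$statistic, 2 * (400 / 70 + 400 / 30))
  expect_equal(h$df, 1)
  ref <- chisq.test(rbind(c(90, 10), c(50, 50)), correct = FALSE)
  expect_equal(h$statistic, unname(ref$statistic))
  expect_equal(h$p, ref$p.value)
  hc <- chisq_homogeneity(c(90, 50), c(100, 100), correct = TRUE)
  refc <- prop.test(c(90, 50), c(100, 100))
  expect_equal(hc$statistic, unname(refc$statistic))
  expect_error(chisq_homogeneity(c(0, 0), c(10, 10)), "expected")
})

test_that("chi-square p agrees with a Monte-Carlo permutation oracle", {
  succ <- c(18, 9, 30)
  n <- c(40, 40, 45)
  obs <- chisq_homogeneity(succ, n)
  set.seed(10)
  pool <- rep(c(1, 0), c(sum(succ), sum(n) - sum(succ)))
  grp <- rep(seq_along(n), n)
  stats_mc <- replicate(1e4, {
    s <- tapply(sample(pool), grp, sum)
    chisq_homogeneity(as.numeric(s), n)$statistic
  })
  p_mc <- mean(stats_mc >= obs$statistic - 1e-9)
  expect_lt(abs(obs$p - p_mc), 0.01)
})

test_that("Marascuillo critical ranges follow the k-1 df formula", {
  m <- marascuillo(c(50, 50, 90), c(100, 100, 100))
  r13 <- m[m$group_i == "g1" & m$group_j == "g3", ]
  expect_equal(r13$critical_range,
               sqrt(qchisq(0.95, 2)) * sqrt(0.25 / 100 + 0.09 / 100))
  expect_equal(r13$critical_range, 0.143, tolerance = 0.005)
  expect_true(r13$significant)
  expect_false(m$significant[m$group_i == "g1" & m$group_j == "g2"])
  expect_false(any(marascuillo(c(40, 40, 40),
                               c(100, 100, 100))$significant))
  expect_error(marascuillo(c(1, 2), c(10, 10)), "two-proportion")
})

test_that("Marascuillo family-wise error stays near alpha under the null", {
  set.seed(20)
  reps <- 2000
  any_sig <- replicate(reps, {
    s <- rbinom(3, 100, 0.5)
    any(marascuillo(s, rep(100, 3))$significant)
  })
  expect_lte(mean(any_sig), 0.05 + 0.02)
})

test_that("Friedman statistic and exact permutation p match the oracles", {
  m <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))  # identical ordering
  fr <- friedman(m, exact = TRUE)
  expect_equal(fr$statistic, 6)
  expect_equal(fr$p, 6 / 216)

  set.seed(30)
  for (i in 1:5) {
    mm <- matrix(rnorm(12), 4, 3)
    if (i > 3) mm[1, 2] <- mm[1, 1]  # force a within-block tie
    expect_equal(friedman(mm)$statistic,
                 unname(friedman.test(mm)$statistic), tolerance = 1e-12)
    expect_equal(friedman(mm, exact = TRUE)$p, enumerate_friedman_p(mm),
                 tolerance = 1e-12)
  }
  const <- matrix(5, 4, 3)
  expect_equal(friedman(const)$statistic, 0)
})

test_that("Friedman exact null rejection rate is at most nominal", {
  set.seed(40)
  rej <- replicate(400, {
    friedman(matrix(rnorm(12), 4, 3), exact = TRUE)$p <= 0.05
  })
  # discrete exact null is conservative
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("all tests return p-values in [0, 1] on random inputs", {
  set.seed(50)
  for (i in 1:20) {
    p1 <- wilcoxon_signed_rank(rnorm(sample(3:30, 1)))$p
    p2 <- rank_sum(rnorm(sample(2:15, 1)), rnorm(sample(2:15, 1)))$p
    p3 <- mcnemar(sample(0:30, 1), sample(1:30, 1))$p
    p4 <- friedman(matrix(rnorm(15), 5, 3))$p
    expect_true(all(c(p1, p2, p3, p4) >= 0 & c(p1, p2, p3, p4) <= 1))
  }
})
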