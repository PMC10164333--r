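test_that("normality screen flags normal and skewed samples correctly", {
  set.seed(71)
  # 100 seeded replicates of 50 standard-normal draws: rarely rejected
  p_norm <- replicate(100, stats::shapiro.test(rnorm(50))$p.value)
  expect_gte(mean(p_norm > 0.01), 0.95)
  # heavily skewed exponential samples: usually rejected
  p_exp <- replicate(100, stats::shapiro.test(rexp(50))$p.value)
  expect_gte(mean(p_exp < 0.05), 0.90)
  # the screen itself: per-condition p, degenerate columns skipped
  tab <- cbind(a = rnorm(20), b = rexp(20), c = rep(1, 20))
  expect_message(p <- normality_screen(tab), "constant")
  expect_true(is.na(p["c"]))
  expect_equal(p[["a"]], stats::shapiro.test(tab[, "a"])$p.value)
  expect_message(normality_screen(cbind(x = c(1, 2))), "fewer than 3")
})

test_that("Friedman test matches the rank-sum formula", {
  # identical values in every cell: statistic 0
  m <- matrix(5, nrow = 6, ncol = 3)
  m <- m + matrix(rep(c(0, 1, 2), each = 6), ncol = 3) * 0  # keep ties
  expect_equal(friedman_rm(matrix(rep(1:6, 3), ncol = 3))$statistic, 0)
  # 3 conditions ordered identically for all 6 participants, no ties:
  # chi^2 = 12/(n k (k+1)) sum R^2 - 3 n (k+1) with R = {6, 12, 18} -> 12
  base <- matrix(rnorm(6), nrow = 6, ncol = 3)
  ordered <- base + matrix(rep(c(0, 10, 20), each = 6), ncol = 3)
  fr <- friedman_rm(ordered)
  expect_equal(fr$statistic, 12)
  expect_equal(fr$df, 2)
  expect_equal(fr$p_value, stats::pchisq(12, 2, lower.tail = FALSE))
  # independent oracle: explicit rank formula on a random tie-free table
  set.seed(72)
  tab <- matrix(rnorm(24), nrow = 8, ncol = 3)
  ranks <- t(apply(tab, 1, rank))
  R <- colSums(ranks)
  n <- nrow(tab); k <- ncol(tab)
  chi <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  expect_equal(friedman_rm(tab)$statistic, chi)
  # listwise deletion of incomplete participants
  tab_na <- rbind(tab, c(1, NA, 2))
  expect_equal(friedman_rm(tab_na)$n_complete, 8L)
  expect_equal(friedman_rm(tab_na)$statistic, chi)
  expect_error(friedman_rm(tab[, 1, drop = FALSE]), "2 conditions")
  expect_error(friedman_rm(matrix(c(1, NA, NA, 1), 2)), "complete")
})

test_that("Wilcoxon-Pratt agrees with classical Wilcoxon when zero-free", {
  d <- c(1, 2, 3, 4, 5)
  wp <- wilcoxon_pratt(d)
  wt <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(wp$statistic, unname(wt$statistic))
  expect_equal(wp$p_value, wt$p.value)
  d2 <- c(-2, 1, 3, -4, 5, 6, -1.5)
  wp2 <- wilcoxon_pratt(d2)
  wt2 <- stats::wilcox.test(d2, exact = TRUE)
  expect_equal(wp2$statistic, unname(wt2$statistic))
  expect_equal(wp2$p_value, wt2$p.value)
})

test_that("Pratt zero handling matches exhaustive enumeration", {
  # zeros are ranked but dropped from the signed sums
  d <- c(0, 1, 2, -1, 3)
  wp <- wilcoxon_pratt(d)
  oracle <- wilcoxon_pratt_oracle(d)
  expect_equal(wp$statistic, oracle$statistic)
  expect_equal(wp$p_value, oracle$p_value)
  # all differences zero: p = 1 with notice
  expect_message(w0 <- wilcoxon_pratt(c(0, 0, 0)), "zero")
  expect_equal(w0$p_value, 1)
  # property sweep: every n <= 8 case (zeros, ties, signs) matches the
  # independent brute-force oracle
  set.seed(73)
  for (k in 1:40) {
    n <- sample(3:8, 1)
    d <- sample(c(-3L:3L), n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1L
    wp <- wilcoxon_pratt(d)
    oracle <- wilcoxon_pratt_oracle(d)
    expect_equal(wp$statistic, oracle$statistic, info = paste(d, collapse = ","))
    expect_equal(wp$p_value, oracle$p_value, info = paste(d, collapse = ","))
  }
})

test_that("the normal approximation tracks the exact Pratt p-value", {
  set.seed(74)
  d <- rnorm(13) + 0.4          # forces the approximation branch
  approx <- wilcoxon_pratt(d)
  exact <- wilcoxon_pratt(d, exact_max = 20L)
  expect_equal(approx$method, "normal approximation")
  expect_equal(exact$method, "exact")
  expect_equal(approx$p_value, exact$p_value, tolerance = 0.06)
})

test_that("Holm-Bonferroni step-down matches hand-computed rejections", {
  h <- holm_bonferroni(c(0.01, 0.04), 0.05)
  expect_equal(h$rejected, c(TRUE, TRUE))       # 0.01<0.025, then 0.04<0.05
  h2 <- holm_bonferroni(c(0.03, 0.04), 0.05)
  expect_equal(h2$rejected, c(FALSE, FALSE))    # 0.03>0.025 stops step-down
  h3 <- holm_bonferroni(0.049, 0.05)
  expect_true(h3$rejected)
  expect_error(holm_bonferroni(numeric(0)), "empty")
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
  # adjusted p-values are monotone in rank order
  set.seed(75)
  p <- runif(7)
  adj <- holm_bonferroni(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("Holm sits between Bonferroni and unadjusted rejection sets", {
  set.seed(76)
  for (k in 1:20) {
    p <- runif(sample(2:8, 1))^2
    holm <- holm_bonferroni(p)$rejected
    bonf <- stats::p.adjust(p, "bonferroni") < 0.05
    raw <- p < 0.05
    expect_true(all(holm[bonf]))   # superset of Bonferroni rejections
    expect_true(all(raw[holm]))    # subset of unadjusted rejections
  }
})

test_that("the gated pipeline controls the family-wise error rate", {
  # null simulation: all conditions exchangeable; Friedman followed by
  # Holm-corrected Wilcoxon pairs should reject anything in <= 7% of runs
  set.seed(77)
  n_rej <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    tab <- matrix(rnorm(9 * 4), nrow = 9, ncol = 4)
    fr <- friedman_rm(tab)
    if (fr$p_value >= 0.05) next
    pw <- utils::combn(4, 2)
    praw <- vapply(seq_len(ncol(pw)), function(j)
      wilcoxon_pratt(tab[, pw[1, j]], tab[, pw[2, j]])$p_value, numeric(1))
    if (any(holm_bonferroni(praw)$rejected)) n_rej <- n_rej + 1L
  }
  expect_lte(n_rej / n_rep, 0.07)
})

test_that("the assembled pipeline reports all stages coherently", {
  set.seed(78)
  tab <- cbind(exoskeleton.synchronous = rnorm(9, 1.3, 0.4),
               exoskeleton.asynchronous = rnorm(9, 1.1, 0.4),
               manipulator.synchronous = rnorm(9, 1.9, 0.4),
               manipulator.asynchronous = rnorm(9, 1.5, 0.4))
  tab[1, 4] <- NA   # a lost session
  rep <- stats_pipeline(tab)
  expect_s3_class(rep, "stats_report")
  expect_length(rep$normality, 4L)
  expect_equal(rep$friedman$n_complete, 8L)
  expect_equal(nrow(rep$pairwise), 6L)
  # pairwise deletion: the pair not involving the NA column keeps n = 9
  expect_equal(rep$pairwise$n[rep$pairwise$comparison ==
                                "exoskeleton.synchronous vs manipulator.synchronous"], 9L)
  expect_true(all(rep$pairwise$p_holm >= rep$pairwise$p_raw - 1e-12))
})
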