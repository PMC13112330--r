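test_that("signed-rank exact p-values match closed forms on tiny inputs", {
  # all-positive differences: p = 1 / 2^n
  r <- signed_rank_test(c(3, 5, 7), alternative = "greater")
  expect_equal(r$p_value, 1 / 8)
  expect_true(r$exact)
  expect_equal(unname(r$statistic), 6)
  # zeros are dropped before ranking
  r2 <- signed_rank_test(c(0, 2, 4), alternative = "greater")
  expect_equal(r2$n_effective, 2L)
  expect_equal(r2$p_value, 1 / 4)
  expect_error(signed_rank_test(c(0, 0)), "undefined")
})

test_that("exact signed-rank equals brute-force enumeration under ties", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:9, 1)
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)  # tie-rich, no zeros
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(signed_rank_test(d, alternative = alt)$p_value,
                   brute_signed_rank_p(d, alt),
                   info = paste(alt, paste(d, collapse = ",")))
    }
  }
})

test_that("signed-rank large-sample branch agrees with stats::wilcox.test", {
  set.seed(31)
  d <- rnorm(40)
  mine <- signed_rank_test(d, alternative = "greater", exact_limit = 30)
  ref <- stats::wilcox.test(d, alternative = "greater", exact = FALSE,
                            correct = TRUE)
  expect_false(mine$exact)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("rank-sum exact p-values match closed forms and brute force", {
  r <- rank_sum_test(1:3, 4:6, alternative = "less")
  expect_equal(r$p_value, 1 / 20)
  expect_true(r$exact)
  ident <- rank_sum_test(c(1, 2, 3), c(1, 2, 3), alternative = "two_sided")
  expect_equal(ident$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")

  set.seed(22)
  for (rep in 1:25) {
    n_a <- sample(2:5, 1); n_b <- sample(2:5, 1)
    a <- sample(1:4, n_a, replace = TRUE)
    b <- sample(1:4, n_b, replace = TRUE)
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(rank_sum_test(a, b, alternative = alt)$p_value,
                   brute_rank_sum_p(a, b, alt),
                   info = paste(alt, paste(a, collapse = ","), "|",
                                paste(b, collapse = ",")))
    }
  }
})

test_that("rank-sum large-sample branch agrees with stats::wilcox.test", {
  set.seed(32)
  a <- rnorm(20); b <- rnorm(25, 0.3)
  mine <- rank_sum_test(a, b, alternative = "two_sided", exact_limit = 30)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches the direct rank formula", {
  r <- kruskal_wallis(list(a = 1:3, b = 4:6))
  expect_equal(unname(r$statistic), 3.857, tolerance = 1e-3)
  expect_equal(r$df, 1)
  # degenerate: everything tied
  dg <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(unname(dg$statistic), 0)
  expect_equal(dg$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), "two groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis H is invariant to monotone transformation", {
  set.seed(33)
  g <- list(a = runif(8), b = runif(6) + 0.2, c = runif(7))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x)))$statistic
  expect_equal(h1, h2)
})

test_that("small-sample Kruskal-Wallis p is consistent with a permutation oracle", {
  set.seed(34)
  g <- list(a = c(1, 5, 2), b = c(8, 9, 4), c = c(3, 3, 7))
  obs <- kruskal_wallis(g)
  pooled <- unlist(g)
  n <- length(pooled)
  sizes <- lengths(g)
  idx <- rep(seq_along(g), sizes)
  r <- rank(pooled)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  fast_h <- function(rr) {
    (12 / (n * (n + 1)) * sum(tapply(rr, idx, sum)^2 / sizes) -
       3 * (n + 1)) / tie_corr
  }
  expect_equal(fast_h(r), unname(obs$statistic))  # oracle sanity
  n_perm <- 20000
  h_obs <- unname(obs$statistic)
  hits <- replicate(n_perm, fast_h(sample(r)) >= h_obs - 1e-9)
  p_perm <- mean(hits)
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  # chi-square approximation should sit within a few MC errors + approx slack
  expect_lt(abs(obs$p_value - p_perm), 4 * se + 0.03)
})

test_that("Dunn's z follows the tie-corrected mean-rank formula", {
  d <- dunn_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # mean ranks 2 and 5; sigma2 = 6*7/12 = 3.5; se = sqrt(3.5 * 2/3)
  expect_equal(d$z, (2 - 5) / sqrt(3.5 * (2 / 3)))
  expect_equal(d$p_value, 2 * pnorm(-abs(d$z)))

  same <- dunn_posthoc(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  three <- dunn_posthoc(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(nrow(three), 3)

  # tie-rich hand check
  g <- list(a = c(1, 1, 2), b = c(2, 3, 3))
  got <- dunn_posthoc(g)
  r <- rank(unlist(g))
  ties <- table(r)
  n <- 6
  sigma2 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  z_hand <- (mean(r[1:3]) - mean(r[4:6])) / sqrt(sigma2 * (2 / 3))
  expect_equal(got$z, z_hand)
})

test_that("p-value adjustment matches hand-computed Bonferroni and Holm", {
  expect_equal(adjust_pvalues(0.001, "bonferroni", m = 2), 0.002)
  expect_equal(adjust_pvalues(c(0.6, 0.7), "bonferroni"), c(1, 1))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # bonferroni dominates holm; both dominate the raw p-values
  set.seed(35)
  p <- runif(10)
  bf <- adjust_pvalues(p, "bonferroni")
  hm <- adjust_pvalues(p, "holm")
  expect_true(all(bf >= hm))
  expect_true(all(hm >= p))
})

test_that("tidy and glance return one-row broom-style summaries", {
  r <- signed_rank_test(c(1, 2, 3), alternative = "greater")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("method", "statistic", "statistic_name", "n", "df",
                     "alternative", "p_value", "p_adjusted", "adjustment",
                     "exact"))
  expect_equal(glance(r), td)
  dd <- tidy(dunn_posthoc(list(a = 1:3, b = 4:6)))
  expect_true("adjustment" %in% names(dd))
})
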