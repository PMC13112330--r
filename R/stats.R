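# Exact and large-sample nonparametric tests. Midrank-based exact
# distributions are enumerated with a generating-function (shift) recursion:
# doubling midranks makes them integers, so the null distribution of a rank
# sum is a convolution over an integer grid. The large-sample branch uses the
# tie-corrected normal approximation with continuity correction.

rank_test_result <- function(method, statistic, n_effective, alternative,
                             p_value, exact, df = NA_real_) {
  out <- list(
    method = method,
    statistic = statistic,
    n_effective = as.integer(n_effective),
    alternative = alternative,
    p_value = p_value,
    p_adjusted = NA_real_,
    exact = exact,
    adjustment = NA_character_,
    df = df
  )
  class(out) <- "rank_test"
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, if (x$exact) "(exact)" else "(normal approximation)", "\n")
  cat(sprintf("%s = %g, n = %d, alternative = %s, p = %.5g\n",
              names(x$statistic) %||% "statistic", unname(x$statistic),
              x$n_effective, x$alternative, x$p_value))
  if (!is.na(x$p_adjusted)) {
    cat(sprintf("adjusted p (%s) = %.5g\n", x$adjustment, x$p_adjusted))
  }
  invisible(x)
}

# Null distribution of the signed-rank statistic over doubled midranks:
# counts of each achievable doubled sum, 0 .. sum(ir), totalling 2^n.
signed_rank_counts <- function(ir) {
  S <- sum(ir)
  f <- numeric(S + 1)
  f[1] <- 1
  for (r in ir) {
    shifted <- c(numeric(r), f[seq_len(S + 1 - r)])
    f <- f + shifted
  }
  f
}

# Counts of doubled rank sums over all size-k subsets of the doubled midranks.
rank_sum_counts <- function(ir, k) {
  S <- sum(ir)
  dp <- vector("list", k + 1)
  dp[[1]] <- c(1, numeric(S))
  for (j in 2:(k + 1)) dp[[j]] <- numeric(S + 1)
  for (r in ir) {
    for (kk in seq(min(k, length(ir)), 1)) {
      shifted <- c(numeric(r), dp[[kk]][seq_len(S + 1 - r)])
      dp[[kk + 1]] <- dp[[kk + 1]] + shifted
    }
  }
  dp[[k + 1]]
}

tail_p <- function(counts, doubled_obs, total) {
  sums <- seq_along(counts) - 1
  eps <- 1e-7
  list(
    ge = sum(counts[sums >= doubled_obs - eps]) / total,
    le = sum(counts[sums <= doubled_obs + eps]) / total
  )
}

one_sided_to_p <- function(tails, alternative) {
  switch(alternative,
    greater = tails$ge,
    less = tails$le,
    two_sided = min(1, 2 * min(tails$ge, tails$le))
  )
}

#' Paired Wilcoxon signed-rank test (exact with ties)
#'
#' Tests whether paired differences are centred above (or below) zero. Zero
#' differences are dropped before ranking; absolute differences receive
#' midranks under ties. For `n <= exact_limit` the p-value is exact, from the
#' full signed-rank null distribution enumerated by a shift recursion over
#' midranks; otherwise a tie-corrected normal approximation with continuity
#' correction is used. `alternative = "greater"` asks whether the first
#' measurement is stochastically larger (differences tend positive) — the
#' form used to test whether baseline abundance and condition exceed the
#' revisit values.
#'
#' @param x Paired differences, or the first sample if `y` is given.
#' @param y Optional second sample; differences are `x - y`.
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @param exact_limit Largest post-zero-drop `n` for which the exact
#'   distribution is enumerated (default 30).
#' @return A `rank_test` object (see [tidy.rank_test()]).
#' @examples
#' signed_rank_test(c(3, 5, 7), alternative = "greater")  # p = 1/8
#' @export
signed_rank_test <- function(x, y = NULL,
                             alternative = c("greater", "less", "two_sided"),
                             exact_limit = 30) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("Signed-rank test undefined: all differences are zero.")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    ir <- as.integer(round(2 * r))
    counts <- signed_rank_counts(ir)
    p <- one_sided_to_p(tail_p(counts, 2 * V, 2^n), alternative)
    exact <- TRUE
  } else {
    ties <- table(r)
    e_v <- n * (n + 1) / 4
    var_v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_ge <- (V - e_v - 0.5) / sqrt(var_v)
    z_le <- (V - e_v + 0.5) / sqrt(var_v)
    p <- switch(alternative,
      greater = pnorm(z_ge, lower.tail = FALSE),
      less = pnorm(z_le),
      two_sided = min(1, 2 * min(pnorm(z_ge, lower.tail = FALSE), pnorm(z_le)))
    )
    exact <- FALSE
  }
  rank_test_result("Wilcoxon signed-rank test", c(V = V), n, alternative, p, exact)
}

#' Two-sample Wilcoxon rank-sum test (exact with ties)
#'
#' Compares two independent samples by the rank sum of the first. Pooled
#' values receive midranks under ties. For `length(a) + length(b) <=
#' exact_limit` the p-value is exact, from the distribution of the rank sum
#' over all subsets enumerated by a shift recursion; otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param a,b Numeric samples. `alternative = "less"` asks whether `a` is
#'   stochastically smaller than `b`.
#' @inheritParams signed_rank_test
#' @return A `rank_test` object.
#' @examples
#' rank_sum_test(1:3, 4:6, alternative = "less")  # p = 1/20
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two_sided", "greater", "less"),
                          exact_limit = 30) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty.")
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n_a)])
  if (n <= exact_limit) {
    ir <- as.integer(round(2 * r))
    counts <- rank_sum_counts(ir, n_a)
    p <- one_sided_to_p(tail_p(counts, 2 * W, choose(n, n_a)), alternative)
    exact <- TRUE
  } else {
    ties <- table(r)
    e_w <- n_a * (n + 1) / 2
    var_w <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z_ge <- (W - e_w - 0.5) / sqrt(var_w)
    z_le <- (W - e_w + 0.5) / sqrt(var_w)
    p <- switch(alternative,
      greater = pnorm(z_ge, lower.tail = FALSE),
      less = pnorm(z_le),
      two_sided = min(1, 2 * min(pnorm(z_ge, lower.tail = FALSE), pnorm(z_le)))
    )
    exact <- FALSE
  }
  rank_test_result("Wilcoxon rank-sum test", c(W = W), n, alternative, p, exact)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) abort("groups must be a (named) list of numeric vectors.")
  if (!is.list(groups)) abort("groups must be a list of numeric vectors.")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0)) abort("Every group must be non-empty.")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

#' Kruskal-Wallis rank test across factor levels
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]). The fully
#' degenerate case — every pooled value identical — is reported as H = 0,
#' p = 1 rather than NaN.
#'
#' @param groups A named list of numeric vectors, one per factor level
#'   (at least two).
#' @return A `rank_test` object with `df` set.
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6))
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) abort("Need at least two groups.")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  df <- length(groups) - 1
  if (length(unique(values)) == 1) {
    return(rank_test_result("Kruskal-Wallis rank sum test", c(H = 0),
                            length(values), "two_sided", 1, FALSE, df = df))
  }
  kt <- stats::kruskal.test(values, g)
  rank_test_result("Kruskal-Wallis rank sum test",
                   c(H = unname(kt$statistic)), length(values), "two_sided",
                   kt$p.value, FALSE, df = unname(kt$parameter))
}

#' Dunn's post hoc test for pairwise level comparisons
#'
#' Follows a significant Kruskal-Wallis result with all pairwise mean-rank
#' comparisons. For levels i and j,
#' `z = (mean_rank_i - mean_rank_j) / SE` with the tie-corrected standard
#' error `SE = sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j))`.
#' Two-sided normal p-values are adjusted for the k(k-1)/2 comparisons.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment Multiplicity adjustment: `"holm"` (default) or
#'   `"bonferroni"`.
#' @return A tibble of class `dunn_test`: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`, with the adjustment recorded as an attribute.
#' @export
dunn_posthoc <- function(groups, adjustment = c("holm", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  groups <- as_group_list(groups)
  if (length(groups) < 2) abort("Need at least two groups.")
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n_tot <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(r)
  sigma2 <- n_tot * (n_tot + 1) / 12 - sum(ties^3 - ties) / (12 * (n_tot - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- vapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(sigma2 * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    if (se == 0) return(0)
    (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  out <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = z, p_value = p,
    p_adjusted = adjust_pvalues(p, adjustment)
  )
  attr(out, "adjustment") <- adjustment
  class(out) <- c("dunn_test", class(out))
  out
}

#' Adjust p-values for multiple comparisons
#'
#' Bonferroni (`min(1, m * p)`) or Holm step-down adjustment, preserving the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"holm"`.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values in the input order.
#' @examples
#' adjust_pvalues(c(0.01, 0.04, 0.03), "holm")
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "holm"), m = length(p)) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = method, n = m)
}
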