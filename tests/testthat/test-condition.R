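test_that("metric counts tally nonzero scores with the per-metric denominator", {
  ann <- make_annotations(6, timepoint = "T1", growth = c(0, 0, 1, 1, 2, 3))
  got <- tabulate_metric_counts(ann, "growth")
  expect_equal(got$score, c(1L, 2L, 3L))
  expect_equal(got$n, c(2L, 1L, 1L))
  expect_equal(unique(got$n_total), 4L)
  # scores never observed have no key
  expect_false(4 %in% got$score)
  expect_error(tabulate_metric_counts(make_annotations(3, timepoint = "T1"),
                                      "growth"),
               "No condition changes")
})

test_that("the any-change denominator counts individuals changed in any metric", {
  ann <- make_annotations(4, timepoint = "T1",
                          growth = c(1, 0, 0, 0), tissue_loss = c(0, 2, 2, 0))
  got <- tabulate_metric_counts(ann, "growth", denominator = "any_change")
  expect_equal(unique(got$n_total), 3L)  # three individuals changed somewhere
})

test_that("frequency weights are cumulative proportions with carry-forward", {
  w <- frequency_weights(c("1" = 2, "2" = 1, "3" = 1), n_total = 4)
  expect_equal(w$score, 0:3)
  expect_equal(w$weight, c(0, 0.5, 0.75, 1))
  # single observed level at the maximum
  w4 <- frequency_weights(c("4" = 7), n_total = 7)
  expect_equal(w4$weight[w4$score == 4], 1)
  # empty middle level carries the cumulative value forward
  w2 <- frequency_weights(c("1" = 1, "3" = 1), n_total = 2)
  expect_equal(w2$weight[w2$score == 2], w2$weight[w2$score == 1])
  expect_equal(w2$weight[w2$score == 2], 0.5)
  expect_error(frequency_weights(c("1" = 1), n_total = 0), "n_total")
})

test_that("severity scaling multiplies the weight by s / s_max", {
  expect_equal(severity_scaled_score(1, 4, 4), 1)
  expect_equal(severity_scaled_score(1, 2, 2), 1)
  expect_equal(severity_scaled_score(0.5, 1, 4), 0.125)
  expect_error(severity_scaled_score(1, 5, 4), "s_max")
})

test_that("individual condition sums signed components and hits the extremes", {
  ann <- make_annotations(3, timepoint = "T1",
                          growth = c(3, 0, 0), tissue_loss = c(0, 4, 0))
  sc <- condition_scores(ann)
  # growth max observed is 3, weight 1 -> +0.75; tissue loss 4 -> -1
  expect_equal(sc$value[1], 0.75)
  expect_equal(sc$value[2], -1)
  expect_equal(sc$value[3], 0)
  expect_false(any(sc$clamped))
  expect_equal(sc$changed, c(TRUE, TRUE, FALSE))
})

test_that("the overall score is clamped to [-1, 1] with components pre-clamp", {
  ann <- make_annotations(2, timepoint = "T1",
                          tissue_loss = c(4, 4), biofouling = c(4, 4),
                          orientation = c(2, 2))
  sc <- condition_scores(ann)
  expect_equal(sc$value, c(-1, -1))
  expect_true(all(sc$clamped))
  expect_equal(sc$tissue_loss_component, c(-1, -1))
  expect_equal(sc$orientation_component, c(-1, -1))
})

test_that("weights are monotone, bounded and permutation invariant", {
  set.seed(3)
  for (rep in 1:10) {
    scores <- sample(0:4, 30, replace = TRUE)
    if (all(scores == 0)) scores[1] <- 1
    ann <- make_annotations(30, timepoint = "T1", growth = scores)
    w <- frequency_weights(tabulate_metric_counts(ann, "growth"))
    expect_true(all(diff(w$weight) >= 0))
    expect_equal(w$weight[1], 0)
    expect_equal(max(w$weight), 1)  # per-metric denominator: top score weighs 1
    # strict monotonicity of severity-scaled scores between occupied levels
    occ <- sort(unique(scores[scores > 0]))
    if (length(occ) > 1) {
      ss <- severity_scaled_score(w$weight[match(occ, w$score)], occ, 4)
      expect_true(all(diff(ss) > 0))
    }
    perm <- sample(30)
    w2 <- frequency_weights(tabulate_metric_counts(ann[perm, ], "growth"))
    expect_equal(w2, w)
  }
})

test_that("a single nonzero metric never triggers the clamp", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    s <- sample(0:4, n, replace = TRUE)
    if (all(s == 0)) s[1] <- 2
    ann <- make_annotations(n, timepoint = "T1", tissue_loss = s)
    sc <- condition_scores(ann)
    expect_true(all(abs(sc$value) <= 1))
    expect_false(any(sc$clamped))
  }
})

test_that("factor summaries pool individuals, not OTUs", {
  sc <- tibble::tibble(
    individual_id = as.character(1:4), site_id = "S1",
    phylum = c("Porifera", "Porifera", "Cnidaria", "Cnidaria"),
    otu = c("a", "a", "b", "c"),
    value = c(-1, 0, 0, 0), changed = c(TRUE, FALSE, FALSE, FALSE)
  )
  got <- condition_summary(sc, by = "site_id")
  expect_equal(got$mean, -0.25)
  expect_equal(got$se, 0.25)
  expect_equal(got$n, 4L)

  one <- condition_summary(sc[1, ], by = "site_id")
  expect_equal(one$mean, -1)
  expect_true(is.na(one$se))

  sym <- condition_summary(
    tibble::tibble(site_id = "S1", value = c(0.2, -0.2),
                   changed = c(TRUE, TRUE)), by = "site_id")
  expect_equal(sym$mean, 0)

  chg <- condition_summary(sc, by = "site_id", changed_only = TRUE)
  expect_equal(chg$n, 1L)
  expect_equal(chg$mean, -1)
})

test_that("per-site weight pooling scores each site against its own cohort", {
  ann <- dplyr::bind_rows(
    make_annotations(4, site_id = "A", timepoint = "T1",
                     growth = c(3, 0, 0, 0)),
    make_annotations(4, site_id = "B", timepoint = "T1",
                     growth = c(1, 1, 2, 0))
  )
  glob <- condition_scores(ann, pooling = "global")
  per <- condition_scores(ann, pooling = "per_site")
  # site A's lone grower carries weight 1 within its site
  expect_equal(per$value[per$site_id == "A" & per$changed], 0.75)
  # global weights: growth scores {1,1,2,3}, so w(1) = 0.5, w(3) = 1
  expect_equal(glob$value[glob$site_id == "A" & glob$changed], 1 * 3 / 4)
  expect_equal(sort(glob$value[glob$site_id == "B" & glob$changed]),
               c(0.5 * 1 / 4, 0.5 * 1 / 4, 0.75 * 2 / 4))
  # site B's own cohort: scores {1,1,2}, w(1) = 2/3, w(2) = 1
  expect_equal(sort(per$value[per$site_id == "B" & per$changed]),
               c((2 / 3) / 4, (2 / 3) / 4, 1 * 2 / 4))
})
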