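one_otu <- function(n) {
  tibble::tibble(otu = "sp1", phylum = "Porifera", n_t0 = n)
}

test_that("full survival, no recruits, no jitter reproduces T0 exactly", {
  cfg <- site_sim_config("S1", otu_abundances = one_otu(15),
                         survival_prob = c(Porifera = 1),
                         position_jitter_sd = 0,
                         metric_distributions = zero_change_distributions())
  s <- generate_site_survey(cfg, seed = 5)
  expect_equal(nrow(s$t1), 15)
  expect_equal(s$t1$x_m, s$t0$x_m)
  expect_equal(s$t1$y_m, s$t0$y_m)
  expect_true(all(s$truth$fate == "survived"))
})

test_that("zero survival loses everything; T1 holds only recruits", {
  cfg <- site_sim_config("S1", otu_abundances = one_otu(20),
                         survival_prob = c(Porifera = 0),
                         recruit_rate = c(sp1 = 3))
  s <- generate_site_survey(cfg, seed = 5)
  t0_truth <- s$truth[s$truth$fate != "recruit", ]
  expect_true(all(t0_truth$fate == "lost"))
  expect_true(all(grepl("-R-", s$t1$individual_id)))
})

test_that("identical config and seed give identical output; seeds differ", {
  cfg <- site_sim_config("S1", otu_abundances = one_otu(30),
                         recruit_rate = c(sp1 = 2))
  a <- generate_site_survey(cfg, seed = 9)
  b <- generate_site_survey(cfg, seed = 9)
  expect_identical(a, b)
  c <- generate_site_survey(cfg, seed = 10)
  expect_false(identical(a$t0$x_m, c$t0$x_m))
  # truth structure (columns, fate domain) is invariant to the seed
  expect_identical(names(a$truth), names(c$truth))

  bundle1 <- generate_study(list(cfg), seed = 3)
  bundle2 <- generate_study(list(cfg), seed = 3)
  expect_identical(bundle1, bundle2)
  expect_error(generate_study(list(cfg, cfg), seed = 1), "Duplicate site_id")
})

test_that("partial coverage truncates T1 and clipping restores conservation", {
  cfg <- site_sim_config("S1", otu_abundances = one_otu(60),
                         area_m2 = 3600, min_spacing = 2,
                         position_jitter_sd = 0.01,
                         t1_coverage_fraction = 0.5,
                         recruit_rate = c(sp1 = 2))
  s <- generate_site_survey(cfg, seed = 13)
  side <- sqrt(cfg$area_m2)
  expect_true(all(s$t1$x_m <= side * 0.5))
  # individuals outside the window are never emitted at T1
  out_ids <- s$truth$t1_id[!s$truth$observed_t1 & !is.na(s$truth$t1_id)]
  expect_false(any(out_ids %in% s$t1$individual_id))

  t0_clip <- clip_to_overlap(s$t0, s$overlap_polygon)
  m <- match_individuals(t0_clip, s$t1, tolerance = 0.5)
  expect_equal(sum(m$fate != "recruit"), nrow(t0_clip))
  expect_equal(sum(m$fate != "lost"), nrow(s$t1))
})

test_that("the matcher recovers every true fate when jitter << tolerance << spacing", {
  cfg <- site_sim_config("S1", otu_abundances = one_otu(40),
                         area_m2 = 3600, min_spacing = 2,
                         position_jitter_sd = 0.05,
                         survival_prob = c(Porifera = 0.8),
                         recruit_rate = c(sp1 = 2))
  s <- generate_site_survey(cfg, seed = 17)
  m <- match_individuals(s$t0, s$t1, tolerance = 0.5)
  truth_surv <- s$truth[s$truth$fate == "survived", ]
  got_surv <- m[m$fate == "survived", ]
  expect_equal(sort(got_surv$t0_id), sort(truth_surv$individual_id))
  expect_equal(got_surv$t1_id[order(got_surv$t0_id)],
               truth_surv$t1_id[order(truth_surv$individual_id)])
  expect_setequal(m$t0_id[m$fate == "lost"],
                  s$truth$individual_id[s$truth$fate == "lost"])
  expect_setequal(m$t1_id[m$fate == "recruit"],
                  s$truth$individual_id[s$truth$fate == "recruit"])
})

test_that("realized loss fractions track the configured survival probability", {
  cfg <- site_sim_config("S1", otu_abundances = one_otu(500),
                         survival_prob = c(Porifera = 0.8))
  fr <- vapply(1:20, function(s) {
    tr <- generate_site_survey(cfg, seed = s)$truth
    mean(tr$fate == "lost")
  }, numeric(1))
  # binomial SE of the mean over 20 seeds
  se <- sqrt(0.2 * 0.8 / 500) / sqrt(20)
  expect_lt(abs(mean(fr) - 0.2), 4 * se)
})

test_that("the packaged study configuration mirrors the published setting", {
  cfgs <- seamount_study_config()
  expect_length(cfgs, 12)
  ab <- dplyr::bind_rows(lapply(cfgs, function(c) c$otu_abundances))
  totals <- tapply(ab$n_t0, ab$phylum, sum)
  expect_equal(unname(totals["Porifera"]), 527)
  expect_equal(unname(totals["Cnidaria"]), 317)
  expect_equal(sum(ab$n_t0), 844)
  # expected gross losses and recruits
  surv <- cfgs[[1]]$survival_prob
  expect_equal(unname((1 - surv["Porifera"]) * 527), 143)
  expect_equal(unname((1 - surv["Cnidaria"]) * 317), 32)
  expect_equal(sum(unlist(lapply(cfgs, function(c) c$recruit_rate))), 12)
  # baseline zone structure: 10 LOW, 1 MID, 1 HIGH
  z <- classify_zone(vapply(cfgs, function(c) c$o2_mean_t0, numeric(1)))
  expect_equal(as.vector(table(z)), c(10, 1, 1))
  # EX-01 holds 190 individuals, 100 of the dominant sponge
  ex1 <- cfgs[[which(vapply(cfgs, function(c) c$site_id, "") == "EX-01")]]
  expect_equal(sum(ex1$otu_abundances$n_t0), 190)
  expect_equal(max(ex1$otu_abundances$n_t0), 100)
})
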