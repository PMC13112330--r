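test_that("delta abundance reproduces the worked percent changes", {
  expect_equal(delta_abundance(100, 90), -10)
  expect_equal(delta_abundance(200, 190), -5)
  expect_equal(delta_abundance(73, 73), 0)
  expect_equal(delta_abundance(100, 21), -79)
  expect_true(is.na(delta_abundance(0, 2)))
  expect_error(delta_abundance(-1, 2), "non-negative")
})

test_that("delta abundance is antisymmetric around the baseline count", {
  for (a0 in c(10, 73, 100)) {
    for (k in c(1, 5, 9)) {
      expect_equal(delta_abundance(a0, a0 + k), -delta_abundance(a0, a0 - k))
    }
  }
})

fates_of <- function(site, otu, phylum, survived = 0, lost = 0, recruit = 0) {
  tibble::tibble(
    site_id = site, otu = otu, phylum = phylum,
    fate = rep(c("survived", "lost", "recruit"), c(survived, lost, recruit))
  )
}

test_that("per-OTU deltas pool counts within the factor level", {
  f <- fates_of("S1", "sp1", "Porifera", survived = 9, lost = 1)
  d <- per_otu_delta(f, by = "site_id")
  expect_equal(d$a0, 10)
  expect_equal(d$a1, 9)
  expect_equal(d$delta_pct, -10)

  # phylum level pools two sites: (100 + 100) -> (95 + 95) = -5%
  f2 <- dplyr::bind_rows(
    fates_of("S1", "sp1", "Porifera", survived = 95, lost = 5),
    fates_of("S2", "sp1", "Porifera", survived = 95, lost = 5)
  )
  d2 <- per_otu_delta(f2, by = "phylum")
  expect_equal(d2$a0, 200)
  expect_equal(d2$delta_pct, -5)
})

test_that("recruit-only OTUs are flagged undefined but tallied as recruits", {
  f <- dplyr::bind_rows(
    fates_of("S1", "sp1", "Porifera", survived = 5),
    fates_of("S1", "new", "Porifera", recruit = 2)
  )
  expect_message(d <- per_otu_delta(f, by = "site_id"), "undefined")
  expect_true(is.na(d$delta_pct[d$otu == "new"]))
  expect_false(d$defined[d$otu == "new"])
  t <- fate_tally(f, by = "site_id")
  expect_equal(t$recruits, 2)
})

test_that("fate tallies satisfy their count identities", {
  f <- dplyr::bind_rows(
    fates_of("S1", "sp1", "Porifera", survived = 3, lost = 2, recruit = 1),
    fates_of("S2", "sp2", "Cnidaria", survived = 4, lost = 1)
  )
  t <- fate_tally(f, by = "site_id")
  expect_equal(t$n_t0, t$survivors + t$lost)
  expect_equal(t$n_t1, t$survivors + t$recruits)
  expect_equal(t$net_change, t$recruits - t$lost)

  # partition property: per-level losses sum to the study-wide loss
  total <- fate_tally(f, by = character())
  expect_equal(sum(t$lost), total$lost)
  by_ph <- fate_tally(f, by = "phylum")
  expect_equal(sum(by_ph$lost), total$lost)

  empty <- fate_tally(f[0, ], by = character())
  expect_equal(empty$n_t0, 0)
  one <- fate_tally(fates_of("S1", "sp1", "Porifera", survived = 1),
                    by = character())
  expect_equal(c(one$n_t0, one$n_t1, one$survivors), c(1, 1, 1))
})

test_that("delta summaries report mean and SE over defined deltas", {
  d <- tibble::tibble(site_id = c("A", "A", "B", "B", "B"),
                      otu = letters[1:5],
                      delta_pct = c(-10, -30, 0, 0, 0),
                      defined = TRUE)
  s <- delta_summary(d, by = "site_id")
  expect_equal(s$mean[s$site_id == "A"], -20)
  expect_equal(s$se[s$site_id == "A"], 10)
  expect_equal(s$mean[s$site_id == "B"], 0)
  expect_equal(s$se[s$site_id == "B"], 0)

  single <- delta_summary(tibble::tibble(site_id = "C", otu = "x",
                                         delta_pct = -24, defined = TRUE),
                          by = "site_id")
  expect_equal(single$mean, -24)
  expect_true(is.na(single$se))

  undef <- tibble::tibble(site_id = "D", otu = "y",
                          delta_pct = NA_real_, defined = FALSE)
  expect_message(out <- delta_summary(undef, by = "site_id"), "omitted")
  expect_equal(nrow(out), 0)
})
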