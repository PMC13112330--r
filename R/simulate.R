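# Synthetic two-timepoint survey generator. Emits the same annotation /
# oxygen / polygon dialects the analysis consumes, plus per-individual ground
# truth, so every pipeline stage can be validated without field data.

#' Default per-phylum condition metric score distributions
#'
#' Probability vectors over score levels (0..4, or 0..2 for orientation) for
#' each phylum, used when drawing T1 condition metrics for survivors. The
#' defaults put roughly a fifth of survivors in some negative change state,
#' with sponges skewed toward tissue loss and corals toward growth, and growth
#' never reaching its top level (score 4 unobserved, mirroring typical
#' revisit-survey data).
#'
#' @return A nested list `phylum -> metric -> probability vector`.
#' @export
default_metric_distributions <- function() {
  list(
    Porifera = list(
      growth      = c(0.90, 0.05, 0.03, 0.02, 0),
      tissue_loss = c(0.84, 0.08, 0.04, 0.03, 0.01),
      biofouling  = c(0.90, 0.05, 0.03, 0.015, 0.005),
      orientation = c(0.93, 0.05, 0.02)
    ),
    Cnidaria = list(
      growth      = c(0.85, 0.08, 0.04, 0.03, 0),
      tissue_loss = c(0.92, 0.04, 0.02, 0.015, 0.005),
      biofouling  = c(0.92, 0.04, 0.02, 0.015, 0.005),
      orientation = c(0.95, 0.03, 0.02)
    )
  )
}

#' Configure one simulated monitoring site
#'
#' Parameters of one site's two-timepoint simulation: baseline abundances per
#' OTU, per-phylum survival probabilities, per-OTU Poisson recruitment rates,
#' condition metric score distributions, isotropic positional jitter
#' (emulating mosaic georeferencing error), and the fraction of the baseline
#' area covered by the revisit survey.
#'
#' @param site_id,seamount Site identity.
#' @param depth_m Site depth (m, positive down).
#' @param o2_mean_t0,o2_mean_t1 Mean dissolved oxygen (mL/L) used for the
#'   emitted sensor series; `NA` for a missing revisit series.
#' @param otu_abundances A tibble with columns `otu`, `phylum`
#'   (`"Porifera"`/`"Cnidaria"`) and `n_t0` (baseline count).
#' @param survival_prob Named vector of per-phylum survival probabilities.
#' @param recruit_rate Named numeric vector of expected recruits per OTU
#'   (Poisson means); empty for no recruitment.
#' @param metric_distributions As [default_metric_distributions()].
#' @param area_m2 Site extent (square site polygon of this area).
#' @param position_jitter_sd Isotropic Gaussian jitter (m) applied to
#'   survivor positions at T1; default 0.25 m (~0.35 m planar RMSE, typical
#'   mosaic-to-mosaic alignment error).
#' @param t1_coverage_fraction Fraction (0, 1] of the site area covered by
#'   the revisit survey (a vertical strip of the site square).
#' @param min_spacing Optional minimum inter-individual spacing (m) at T0.
#' @param o2_noise_sd Gaussian noise sd for the emitted oxygen series.
#' @return A `site_sim_config` list.
#' @export
site_sim_config <- function(site_id, seamount = "SIM", depth_m = 800,
                            o2_mean_t0 = 0.3, o2_mean_t1 = 0.3,
                            otu_abundances,
                            survival_prob = c(Porifera = 0.9, Cnidaria = 0.9),
                            recruit_rate = numeric(),
                            metric_distributions = default_metric_distributions(),
                            area_m2 = 250,
                            position_jitter_sd = 0.25,
                            t1_coverage_fraction = 1,
                            min_spacing = 0,
                            o2_noise_sd = 0.01) {
  if (nrow(otu_abundances) == 0) abort("otu_abundances must have at least one row.")
  if (!all(c("otu", "phylum", "n_t0") %in% names(otu_abundances))) {
    abort("otu_abundances needs columns otu, phylum, n_t0.")
  }
  if (any(survival_prob < 0 | survival_prob > 1)) {
    abort("Survival probabilities must lie in [0, 1].")
  }
  if (position_jitter_sd < 0) abort("position_jitter_sd must be >= 0.")
  if (t1_coverage_fraction <= 0 || t1_coverage_fraction > 1) {
    abort("t1_coverage_fraction must lie in (0, 1].")
  }
  for (ph in names(metric_distributions)) {
    for (m in names(metric_distributions[[ph]])) {
      p <- metric_distributions[[ph]][[m]]
      if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
        abort(paste0("Score distribution for (", ph, ", ", m,
                     ") must be a probability vector."))
      }
    }
  }
  structure(
    list(site_id = site_id, seamount = seamount, depth_m = depth_m,
         o2_mean_t0 = o2_mean_t0, o2_mean_t1 = o2_mean_t1,
         otu_abundances = tibble::as_tibble(otu_abundances),
         survival_prob = survival_prob, recruit_rate = recruit_rate,
         metric_distributions = metric_distributions, area_m2 = area_m2,
         position_jitter_sd = position_jitter_sd,
         t1_coverage_fraction = t1_coverage_fraction,
         min_spacing = min_spacing, o2_noise_sd = o2_noise_sd),
    class = "site_sim_config"
  )
}

# Uniform placement, optionally dart-throwing to keep a minimum spacing from
# previously placed points (including `avoid`, e.g. the baseline individuals
# when placing recruits, so spacing guarantees matchability for all fates).
place_points <- function(n, side, min_spacing, avoid = NULL) {
  if (min_spacing <= 0) {
    return(cbind(runif(n, 0, side), runif(n, 0, side)))
  }
  pts <- matrix(NA_real_, n, 2)
  placed <- 0
  for (attempt in seq_len(n * 2000)) {
    cand <- c(runif(1, 0, side), runif(1, 0, side))
    prev <- rbind(avoid, pts[seq_len(placed), , drop = FALSE])
    if (is.null(prev) || nrow(prev) == 0 ||
        min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2) >= min_spacing^2) {
      placed <- placed + 1
      pts[placed, ] <- cand
      if (placed == n) return(pts)
    }
  }
  abort("Could not place individuals with the requested minimum spacing.")
}

draw_metrics <- function(phylum, dists, n) {
  out <- list()
  specs <- metric_specs()
  for (i in seq_len(nrow(specs))) {
    m <- specs$metric[i]
    p <- dists[[phylum]][[m]]
    out[[m]] <- sample(0:(length(p) - 1), n, replace = TRUE, prob = p)
  }
  tibble::as_tibble(out)
}

#' Simulate one site's baseline and revisit surveys
#'
#' Places baseline individuals uniformly (optionally with minimum spacing) in
#' a square site polygon, survives each independently with its phylum's
#' probability, re-emits survivors at T1 with jittered positions and condition
#' metrics drawn from the configured distributions, adds Poisson recruits
#' (all-zero metrics: they have no baseline), and truncates the T1 table to a
#' coverage window of the configured area fraction. Identical `(config,
#' seed)` give identical output.
#'
#' @param config A [site_sim_config()].
#' @param seed Integer seed for this site's private RNG stream.
#' @return A list with `t0` and `t1` annotation tibbles, `truth`
#'   (per-individual fate and whether it is observable at T1) and
#'   `overlap_polygon` (the coverage window as a vertex matrix).
#' @export
generate_site_survey <- function(config, seed = 1) {
  stopifnot(inherits(config, "site_sim_config"))
  missing_ph <- setdiff(unique(config$otu_abundances$phylum),
                        names(config$survival_prob))
  if (length(missing_ph) > 0) {
    abort(paste0("No survival probability for phylum: ",
                 paste(missing_ph, collapse = ", ")))
  }
  with_seed(seed, {
    ab <- config$otu_abundances
    n0 <- sum(ab$n_t0)
    side <- sqrt(config$area_m2)
    pts <- place_points(n0, side, config$min_spacing)
    otu <- rep(ab$otu, ab$n_t0)
    phylum <- rep(ab$phylum, ab$n_t0)
    t0 <- tibble::tibble(
      individual_id = sprintf("%s-T0-%04d", config$site_id, seq_len(n0)),
      site_id = config$site_id, timepoint = "T0",
      phylum = phylum, otu = otu,
      x_m = pts[, 1], y_m = pts[, 2], depth_m = config$depth_m,
      growth = 0L, tissue_loss = 0L, biofouling = 0L, orientation = 0L
    )

    survived <- rbinom(n0, 1, config$survival_prob[phylum]) == 1
    surv <- t0[survived, , drop = FALSE]
    n_s <- nrow(surv)
    t1_surv <- surv
    t1_surv$timepoint <- "T1"
    t1_surv$individual_id <- sub("-T0-", "-T1-", surv$individual_id)
    if (n_s > 0) {
      t1_surv$x_m <- surv$x_m + rnorm(n_s, 0, config$position_jitter_sd)
      t1_surv$y_m <- surv$y_m + rnorm(n_s, 0, config$position_jitter_sd)
      for (ph in unique(t1_surv$phylum)) {
        idx <- which(t1_surv$phylum == ph)
        mt <- draw_metrics(ph, config$metric_distributions, length(idx))
        for (m in metric_names()) t1_surv[[m]][idx] <- mt[[m]]
      }
    }

    rec_list <- list()
    if (length(config$recruit_rate) > 0) {
      n_rec <- rpois(length(config$recruit_rate), config$recruit_rate)
      for (i in seq_along(n_rec)) {
        if (n_rec[i] == 0) next
        u <- names(config$recruit_rate)[i]
        ph <- ab$phylum[match(u, ab$otu)]
        if (is.na(ph)) ph <- "Porifera"
        rpts <- place_points(n_rec[i], side, config$min_spacing, avoid = pts)
        rec_list[[u]] <- tibble::tibble(
          individual_id = sprintf("%s-R-%s-%03d", config$site_id, i, seq_len(n_rec[i])),
          site_id = config$site_id, timepoint = "T1",
          phylum = ph, otu = u,
          x_m = rpts[, 1], y_m = rpts[, 2], depth_m = config$depth_m,
          growth = 0L, tissue_loss = 0L, biofouling = 0L, orientation = 0L
        )
      }
    }
    recruits <- dplyr::bind_rows(rec_list)
    t1_all <- dplyr::bind_rows(t1_surv, recruits)

    # Partial coverage: the revisit survey sees a vertical strip of the site.
    # At full coverage nothing is clipped (positional jitter at the site edge
    # must not delete survivors from the revisit table).
    window_w <- side * config$t1_coverage_fraction
    t1 <- if (config$t1_coverage_fraction < 1) {
      t1_all[t1_all$x_m <= window_w, , drop = FALSE]
    } else {
      t1_all
    }

    truth <- dplyr::bind_rows(
      tibble::tibble(
        individual_id = t0$individual_id, site_id = config$site_id,
        otu = t0$otu, phylum = t0$phylum,
        fate = ifelse(survived, "survived", "lost"),
        t1_id = ifelse(survived, sub("-T0-", "-T1-", t0$individual_id),
                       NA_character_)
      ),
      if (nrow(recruits) > 0) tibble::tibble(
        individual_id = recruits$individual_id, site_id = config$site_id,
        otu = recruits$otu, phylum = recruits$phylum,
        fate = "recruit", t1_id = recruits$individual_id
      )
    )
    truth$observed_t1 <- truth$t1_id %in% t1$individual_id

    polygon <- cbind(c(0, window_w, window_w, 0), c(0, 0, side, side))
    list(t0 = t0, t1 = t1, truth = truth, overlap_polygon = polygon)
  })
}

#' Simulate a multi-site monitoring study
#'
#' Runs [generate_site_survey()] for every site with deterministic per-site
#' sub-seeds derived from the master seed, and emits the full dataset bundle:
#' site metadata, annotation tables, dissolved oxygen series (Gaussian noise
#' around the configured means), overlap polygons and ground truth.
#'
#' @param configs A list of [site_sim_config()]s with unique `site_id`s.
#' @param seed Master integer seed.
#' @return A list of class `survey_bundle`: `sites`, `annotations` (T0 and T1
#'   for all sites), `oxygen`, `polygons` (named list), `truth`, `seed`.
#' @examples
#' cfg <- site_sim_config("S1", otu_abundances = tibble::tibble(
#'   otu = "sp1", phylum = "Porifera", n_t0 = 20))
#' bundle <- generate_study(list(cfg), seed = 1)
#' names(bundle)
#' @export
generate_study <- function(configs, seed = 1) {
  ids <- vapply(configs, function(c) c$site_id, character(1))
  if (anyDuplicated(ids)) abort("Duplicate site_id among simulation configs.")
  base <- (abs(as.integer(seed)) %% 100000L) * 10000L
  surveys <- lapply(seq_along(configs), function(i) {
    generate_site_survey(configs[[i]], seed = base + i)
  })
  annotations <- dplyr::bind_rows(lapply(surveys, function(s) {
    dplyr::bind_rows(s$t0, s$t1)
  }))
  truth <- dplyr::bind_rows(lapply(surveys, `[[`, "truth"))
  polygons <- setNames(lapply(surveys, `[[`, "overlap_polygon"), ids)
  sites <- dplyr::bind_rows(lapply(configs, function(c) {
    tibble::tibble(site_id = c$site_id, seamount = c$seamount,
                   latitude = NA_real_, longitude = NA_real_,
                   depth_m = c$depth_m, t0_year = 2018L, t1_year = 2022L,
                   o2_t0_ml_l = c$o2_mean_t0, o2_t1_ml_l = c$o2_mean_t1)
  }))
  oxygen <- dplyr::bind_rows(lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    with_seed(base + 5000L + i, {
      out <- list()
      for (tp in c("T0", "T1")) {
        mu <- if (tp == "T0") cfg$o2_mean_t0 else cfg$o2_mean_t1
        if (is.na(mu)) next
        ts <- as.POSIXct(sprintf("%d-07-01 12:00:00",
                                 if (tp == "T0") 2018L else 2022L),
                         tz = "UTC") + 60 * (0:59)
        out[[tp]] <- tibble::tibble(
          site_id = cfg$site_id, timepoint = tp, timestamp = ts,
          o2_ml_per_l = pmax(0, mu + rnorm(60, 0, cfg$o2_noise_sd))
        )
      }
      dplyr::bind_rows(out)
    })
  }))
  structure(list(sites = sites, annotations = annotations, oxygen = oxygen,
                 polygons = polygons, truth = truth, seed = seed),
            class = "survey_bundle")
}

# Split an integer total across a vector of OTU names, remainder to the first.
split_count <- function(total, otus) {
  k <- length(otus)
  base <- total %/% k
  n <- rep(base, k)
  n[seq_len(total - base * k)] <- n[seq_len(total - base * k)] + 1
  tibble::tibble(otu = otus, n_t0 = n)
}

#' Study configuration emulating the Northeast Pacific seamount monitoring sites
#'
#' A packaged 12-site configuration whose expected study-wide totals mirror
#' the published monitoring aggregates: 527 sponges and 317 corals at
#' baseline; per-phylum survival probabilities 384/527 (Porifera) and 285/317
#' (Cnidaria), giving expected gross losses of 143 and 32; expected Poisson
#' recruitment of 12 individuals concentrated at four sites (+1, +1, +4, +6);
#' site depths and mean oxygen concentrations from the monitoring-site table
#' (10 low-oxygen, 1 mid, 1 high site at baseline). Baseline abundance is
#' concentrated at the Explorer site EX-01 (172 sponges, including 100 of the
#' dominant bugle sponge, and 18 corals) with the remainder spread over the
#' other sites, and revisit coverage is partial (25%) at the five NEPDEP 54
#' sites surveyed by drop camera and 85% elsewhere.
#'
#' @return A list of [site_sim_config()]s, one per site.
#' @export
seamount_study_config <- function() {
  sites <- monitoring_sites()
  porifera <- c("Pinulasma n. sp.", "Tretodictyum n. sp.",
                "Aphrocallistes vastus", "Heterochone calyx", "Farrea occa",
                "Rhabdocalyptus dawsoni", "Staurocalyptus dowlingi",
                "Acanthascus platei", "Hexactinella sp.",
                "Poecillastra rickettsi", "Mycale sp.", "Geodia sp.",
                "Chonelasma sp.")
  cnidaria <- c("Primnoa pacifica", "Isidella tentaculum",
                "Paragorgia arborea", "Keratoisis sp.", "Swiftia simplex",
                "Stylaster campylecus", "Heteropolypus ritteri",
                "Anthomastus sp.", "Paramuricea sp.", "Plumarella superba",
                "Desmophyllum dianthus", "Antipathes sp.",
                "Pennatula phosphorea")
  survival <- c(Porifera = 384 / 527, Cnidaria = 285 / 317)
  recruit_map <- list(
    "SK-B-08" = c("Heterochone calyx" = 1),
    "EX-01"   = c("Aphrocallistes vastus" = 1),
    "EX-02"   = c("Farrea occa" = 4),
    "SK-B-11" = c("Stylaster campylecus" = 6)
  )
  # per-site (Porifera, Cnidaria) baseline totals; EX-01 and SK-B-08 match the
  # published site counts (190 and 73), EX-02 absorbs the rounding remainder.
  totals <- list(
    "EX-01" = c(172, 18), "SK-B-08" = c(45, 28), "EX-02" = c(31, 28)
  )
  others <- setdiff(sites$site_id, names(totals))
  for (s in others) totals[[s]] <- c(31, 27)

  configs <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    tot <- totals[[s$site_id]]
    if (s$site_id == "EX-01") {
      ab_p <- tibble::tibble(
        otu = porifera[1:4], n_t0 = c(100, 40, 20, 12))
    } else {
      pick <- ((i - 1) * 2 + 0:3) %% length(porifera) + 1
      ab_p <- split_count(tot[1], porifera[pick])
    }
    pick_c <- ((i - 1) * 2 + 0:3) %% length(cnidaria) + 1
    ab_c <- split_count(tot[2], cnidaria[pick_c])
    ab <- dplyr::bind_rows(
      dplyr::mutate(ab_p, phylum = "Porifera"),
      dplyr::mutate(ab_c, phylum = "Cnidaria")
    )
    site_sim_config(
      site_id = s$site_id, seamount = s$seamount, depth_m = s$depth_m,
      o2_mean_t0 = s$o2_t0_ml_l, o2_mean_t1 = s$o2_t1_ml_l,
      otu_abundances = ab[, c("otu", "phylum", "n_t0")],
      survival_prob = survival,
      recruit_rate = recruit_map[[s$site_id]] %||% numeric(),
      area_m2 = 250,
      position_jitter_sd = 0.25,
      t1_coverage_fraction = if (s$seamount == "NEPDEP 54") 0.25 else 0.85
    )
  })
  configs
}
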