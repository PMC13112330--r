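# End-to-end analysis: read/clip/match -> oxygen zones -> condition scoring ->
# delta abundance -> nonparametric test battery -> report bundle.

join_site_context <- function(df, zones) {
  ctx <- zones[, intersect(c("site_id", "seamount", "zone_t0"), names(zones))]
  names(ctx)[names(ctx) == "zone_t0"] <- "zone"
  dplyr::left_join(df, ctx, by = "site_id")
}

zone_table <- function(sites, oxygen) {
  means <- NULL
  if (!is.null(oxygen) && nrow(oxygen) > 0) {
    means <- oxygen |>
      dplyr::group_by(.data$site_id, .data$timepoint) |>
      dplyr::summarise(o2 = mean_site_oxygen(dplyr::pick(dplyr::everything())),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "timepoint", values_from = "o2",
                         names_prefix = "o2_") |>
      dplyr::rename(o2_t0_ml_l = "o2_T0", o2_t1_ml_l = dplyr::any_of("o2_T1"))
  } else if (!is.null(sites) && all(c("o2_t0_ml_l") %in% names(sites))) {
    means <- sites[, intersect(c("site_id", "o2_t0_ml_l", "o2_t1_ml_l"),
                               names(sites))]
  }
  if (is.null(means)) return(NULL)
  if (!"o2_t1_ml_l" %in% names(means)) means$o2_t1_ml_l <- NA_real_
  out <- means |>
    dplyr::mutate(
      zone_t0 = classify_zone(.data$o2_t0_ml_l),
      zone_t1 = classify_zone(.data$o2_t1_ml_l),
      stable = ifelse(is.na(.data$o2_t1_ml_l), NA,
                      zone_stability(.data$o2_t0_ml_l, .data$o2_t1_ml_l))
    )
  if (!is.null(sites) && "seamount" %in% names(sites)) {
    out <- dplyr::left_join(out, sites[, c("site_id", "seamount")], by = "site_id")
  }
  out
}

kw_with_posthoc <- function(values, level, label, alpha, adjustment) {
  keep <- !is.na(values) & !is.na(level)
  groups <- split(values[keep], as.character(level[keep]))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) return(NULL)
  kw <- kruskal_wallis(groups)
  dunn <- NULL
  if (kw$p_value <= alpha) dunn <- dunn_posthoc(groups, adjustment)
  list(test = kw, dunn = dunn, label = label)
}

#' Analyse a pair of repeat surveys
#'
#' The full change-detection analysis. Per site, baseline annotations are
#' clipped to the survey overlap region and individuals are matched between
#' timepoints ([match_individuals()]); sites are classified into oxygen zones;
#' matched survivors are condition-scored ([condition_scores()]; recruits have
#' no baseline and are excluded); per-OTU percent abundance changes are
#' computed within each factor (site, phylum, oxygen zone, seamount); and the
#' test battery is run: paired one-sided signed-rank tests of baseline vs
#' revisit abundance and condition per OTU (Bonferroni-corrected as a family
#' of two), Kruskal-Wallis comparisons of delta abundance and condition
#' across sites, zones and seamounts with Dunn's post hoc on significance,
#' and rank-sum comparisons between the two phyla.
#'
#' @param annotations Annotation tibble with both timepoints (see
#'   [validate_annotations()]).
#' @param sites Optional site metadata ([monitoring_sites()] format).
#' @param oxygen Optional dissolved oxygen series ([read_oxygen_series()]
#'   format); used in preference to the `sites` oxygen columns.
#' @param polygons Optional named list of per-site overlap polygons.
#' @param tolerance Matching distance cap in metres.
#' @param pooling,denominator Condition-weighting options (see
#'   [condition_scores()]).
#' @param alpha Significance level gating the Dunn post hoc (default 0.05).
#' @param adjustment Dunn adjustment method, `"holm"` or `"bonferroni"`.
#' @param exact_limit Passed to the rank tests.
#' @return A list of class `survey_report`: matched `fates`, `fate_tally_*`
#'   tables, `zones`, per-factor `deltas` and `delta_summaries`, `condition`
#'   scores and `condition_summaries`, a tidy `stats` table, `dunn` post hoc
#'   tables, and a run `log`.
#' @export
analyze_surveys <- function(annotations, sites = NULL, oxygen = NULL,
                            polygons = NULL, tolerance = 0.5,
                            pooling = c("global", "per_site"),
                            denominator = c("per_metric", "any_change"),
                            alpha = 0.05,
                            adjustment = c("holm", "bonferroni"),
                            exact_limit = 30) {
  pooling <- match.arg(pooling)
  denominator <- match.arg(denominator)
  adjustment <- match.arg(adjustment)
  ann <- validate_annotations(annotations)
  if (!any(ann$timepoint == "T1")) abort("No T1 annotations supplied.")
  if (!any(ann$timepoint == "T0")) abort("No T0 annotations supplied.")

  zones <- zone_table(sites, oxygen)

  # match per site
  fates <- purrr::map_dfr(sort(unique(ann$site_id)), function(sid) {
    t0 <- ann[ann$site_id == sid & ann$timepoint == "T0", , drop = FALSE]
    t1 <- ann[ann$site_id == sid & ann$timepoint == "T1", , drop = FALSE]
    t0 <- clip_to_overlap(t0, polygons[[sid]])
    match_individuals(t0, t1, tolerance = tolerance)
  })
  if (!is.null(zones)) fates <- join_site_context(fates, zones)

  tally_site <- fate_tally(fates, by = "site_id")
  tally_phylum <- fate_tally(fates, by = "phylum")
  tally_total <- fate_tally(fates, by = character())

  factors <- c("site_id", "phylum")
  if (!is.null(zones)) factors <- c(factors, "zone", "seamount")
  factors <- intersect(factors, names(fates))
  deltas <- lapply(setNames(factors, factors), function(f) {
    suppressMessages(per_otu_delta(fates, by = f))
  })
  delta_summaries <- lapply(deltas, function(d) {
    suppressMessages(delta_summary(d, by = setdiff(names(d),
      c("otu", "a0", "a1", "delta_pct", "defined"))))
  })

  # condition: matched survivors only (recruits have no baseline)
  surv_t1 <- ann[ann$timepoint == "T1" &
                   ann$individual_id %in% fates$t1_id[fates$fate == "survived"], ,
                 drop = FALSE]
  condition <- NULL
  condition_summaries <- NULL
  if (nrow(surv_t1) > 0 &&
      sum(rowSums(as.matrix(surv_t1[, metric_names()])) > 0) > 0) {
    condition <- condition_scores(surv_t1, pooling = pooling,
                                  denominator = denominator)
    if (!is.null(zones)) condition <- join_site_context(condition, zones)
    cond_factors <- intersect(c("site_id", "phylum", "zone", "seamount"),
                              names(condition))
    condition_summaries <- lapply(setNames(cond_factors, cond_factors),
                                  function(f) {
      dplyr::bind_rows(
        dplyr::mutate(condition_summary(condition, by = f), cohort = "assessed"),
        dplyr::mutate(condition_summary(condition, by = f, changed_only = TRUE),
                      cohort = "changed")
      )
    })
  }

  # headline paired tests (Bonferroni family of two)
  otu_pooled <- suppressMessages(per_otu_delta(fates, by = character()))
  abund_test <- NULL
  if (any(otu_pooled$a0 != otu_pooled$a1)) {
    abund_test <- signed_rank_test(otu_pooled$a0, otu_pooled$a1,
                                   alternative = "greater",
                                   exact_limit = exact_limit)
  }
  cond_test <- NULL
  if (!is.null(condition)) {
    otu_cond <- condition |>
      dplyr::group_by(.data$otu) |>
      dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
    if (any(otu_cond$mean_value != 0)) {
      cond_test <- signed_rank_test(rep(0, nrow(otu_cond)), otu_cond$mean_value,
                                    alternative = "greater",
                                    exact_limit = exact_limit)
    }
  }
  if (!is.null(abund_test)) {
    abund_test$p_adjusted <- adjust_pvalues(abund_test$p_value, "bonferroni", m = 2)
    abund_test$adjustment <- "bonferroni"
  }
  if (!is.null(cond_test)) {
    cond_test$p_adjusted <- adjust_pvalues(cond_test$p_value, "bonferroni", m = 2)
    cond_test$adjustment <- "bonferroni"
  }

  stats_rows <- list(
    if (!is.null(abund_test)) {
      dplyr::mutate(tidy(abund_test), test = "abundance_t0_vs_t1", factor = "otu")
    },
    if (!is.null(cond_test)) {
      dplyr::mutate(tidy(cond_test), test = "condition_t0_vs_t1", factor = "otu")
    }
  )
  dunn_tables <- list()

  # delta abundance across factors
  for (f in intersect(c("site_id", "zone", "seamount"), factors)) {
    d <- deltas[[f]]
    res <- kw_with_posthoc(d$delta_pct, d[[f]],
                           paste0("delta_abundance_by_", f), alpha, adjustment)
    if (!is.null(res)) {
      stats_rows <- c(stats_rows, list(
        dplyr::mutate(tidy(res$test), test = "delta_abundance", factor = f)))
      if (!is.null(res$dunn)) dunn_tables[[res$label]] <- res$dunn
    }
  }
  d_ph <- deltas[["phylum"]]
  d_ph <- d_ph[!is.na(d_ph$delta_pct), , drop = FALSE]
  if (length(unique(d_ph$phylum)) == 2) {
    gs <- split(d_ph$delta_pct, d_ph$phylum)
    ph_test <- rank_sum_test(gs[[1]], gs[[2]], alternative = "two_sided",
                             exact_limit = exact_limit)
    stats_rows <- c(stats_rows, list(
      dplyr::mutate(tidy(ph_test), test = "delta_abundance", factor = "phylum")))
  }

  # condition across factors
  if (!is.null(condition)) {
    for (f in intersect(c("site_id", "zone", "seamount"), names(condition))) {
      res <- kw_with_posthoc(condition$value, condition[[f]],
                             paste0("condition_by_", f), alpha, adjustment)
      if (!is.null(res)) {
        stats_rows <- c(stats_rows, list(
          dplyr::mutate(tidy(res$test), test = "condition", factor = f)))
        if (!is.null(res$dunn)) dunn_tables[[res$label]] <- res$dunn
      }
    }
    if (length(unique(condition$phylum)) == 2) {
      gs <- split(condition$value, condition$phylum)
      ct <- rank_sum_test(gs[[1]], gs[[2]], alternative = "two_sided",
                          exact_limit = exact_limit)
      stats_rows <- c(stats_rows, list(
        dplyr::mutate(tidy(ct), test = "condition", factor = "phylum")))
    }
  }

  stats_tbl <- dplyr::bind_rows(purrr::compact(stats_rows)) |>
    dplyr::relocate("test", "factor")

  params <- list(tolerance = tolerance, pooling = pooling,
                 denominator = denominator, alpha = alpha,
                 adjustment = adjustment, exact_limit = exact_limit)
  log <- list(
    timestamp = format(Sys.time(), tz = "UTC"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("benthochange")),
    params = params,
    config_hash = rlang::hash(list(ann, sites, oxygen, polygons, params)),
    matcher = "greedy nearest-neighbour within OTU (automated stand-in for manual individual tracking)"
  )

  structure(list(
    fates = fates,
    fate_tally_site = tally_site,
    fate_tally_phylum = tally_phylum,
    fate_tally_total = tally_total,
    zones = zones,
    deltas = deltas,
    delta_summaries = delta_summaries,
    condition = condition,
    condition_summaries = condition_summaries,
    stats = stats_tbl,
    dunn = dunn_tables,
    log = log
  ), class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  t <- x$fate_tally_total
  cat("Repeat-survey change report\n")
  cat(sprintf("  sites: %d, individuals T0: %d, T1: %d\n",
              nrow(x$fate_tally_site), t$n_t0, t$n_t1))
  cat(sprintf("  survivors: %d, lost: %d, recruits: %d (net %+d)\n",
              t$survivors, t$lost, t$recruits, t$net_change))
  cat(sprintf("  tests run: %d (see $stats)\n", nrow(x$stats)))
  invisible(x)
}

#' Run the pipeline from a survey bundle or file paths
#'
#' Thin orchestration over [analyze_surveys()]. Accepts either a simulated
#' [generate_study()] bundle or a list of input file paths
#' (`annotations` CSV(s), optional `sites` CSV, `oxygen` CSV, `polygons`
#' GeoJSON).
#'
#' @param x A `survey_bundle`, or a named list of file paths.
#' @param ... Passed to [analyze_surveys()].
#' @return A `survey_report`.
#' @export
run_pipeline <- function(x, ...) {
  if (inherits(x, "survey_bundle")) {
    return(analyze_surveys(x$annotations, sites = x$sites, oxygen = x$oxygen,
                           polygons = x$polygons, ...))
  }
  if (!is.list(x) || is.null(x$annotations)) {
    abort("run_pipeline needs a survey_bundle or a list with an 'annotations' path.")
  }
  ann <- dplyr::bind_rows(lapply(x$annotations, read_annotations))
  sites <- if (!is.null(x$sites)) read_site_metadata(x$sites)
  oxygen <- if (!is.null(x$oxygen)) read_oxygen_series(x$oxygen)
  polygons <- if (!is.null(x$polygons)) read_overlap_polygons(x$polygons)
  analyze_surveys(ann, sites = sites, oxygen = oxygen, polygons = polygons, ...)
}

#' Headline metrics of a survey report
#'
#' Study-wide summary counts: sites with a net abundance decline, sites whose
#' assessed survivors have a negative mean condition score, total net loss,
#' and per-phylum percent of baseline individuals lost.
#'
#' @param report A `survey_report`.
#' @return A one-row tibble.
#' @export
summarize_headline <- function(report) {
  t <- report$fate_tally_total
  ph <- report$fate_tally_phylum
  loss_pct <- setNames(100 * ph$lost / ph$n_t0, ph$phylum)
  cond_sites <- 0L
  if (!is.null(report$condition_summaries$site_id)) {
    cs <- report$condition_summaries$site_id
    cs <- cs[cs$cohort == "assessed", , drop = FALSE]
    cond_sites <- sum(cs$mean < 0)
  }
  tibble::tibble(
    n_sites = nrow(report$fate_tally_site),
    sites_abundance_decline = sum(report$fate_tally_site$net_change < 0),
    sites_condition_decline = cond_sites,
    net_loss = -t$net_change,
    individuals_t0 = t$n_t0,
    porifera_loss_pct = unname(loss_pct["Porifera"]),
    cnidaria_loss_pct = unname(loss_pct["Cnidaria"])
  )
}

#' Write a survey report's tables to disk
#'
#' Emits the report's tables as CSV files (plus the run log as JSON) under a
#' directory.
#'
#' @param report A `survey_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$fates, file.path(dir, "fates.csv"))
  readr::write_csv(report$fate_tally_site, file.path(dir, "fate_tally_site.csv"))
  readr::write_csv(report$fate_tally_phylum, file.path(dir, "fate_tally_phylum.csv"))
  if (!is.null(report$zones)) {
    readr::write_csv(report$zones, file.path(dir, "oxygen_zones.csv"))
  }
  for (f in names(report$deltas)) {
    readr::write_csv(report$deltas[[f]],
                     file.path(dir, paste0("delta_abundance_", f, ".csv")))
  }
  if (!is.null(report$condition)) {
    readr::write_csv(report$condition, file.path(dir, "condition_scores.csv"))
    for (f in names(report$condition_summaries)) {
      readr::write_csv(report$condition_summaries[[f]],
                       file.path(dir, paste0("condition_summary_", f, ".csv")))
    }
  }
  readr::write_csv(report$stats, file.path(dir, "statistics.csv"))
  for (nm in names(report$dunn)) {
    readr::write_csv(tidy(report$dunn[[nm]]),
                     file.path(dir, paste0("dunn_", nm, ".csv")))
  }
  readr::write_csv(summarize_headline(report), file.path(dir, "headline.csv"))
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
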