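# Frequency-weighted, severity-scaled condition scoring.
#
# Each of the four qualitative metrics is rescaled to [0, 1] by the cumulative
# frequency of its nonzero scores across the assessed cohort (frequency
# weighting), then multiplied by s / s_max to preserve the ordinal severity
# ranking within the metric (severity scaling). Negative metrics flip sign and
# the per-metric components sum to the overall condition score in [-1, 1].

#' Tabulate nonzero metric scores across a cohort
#'
#' Counts how many individuals received each nonzero score of one condition
#' metric, together with the weighting denominator `n_total`. With
#' `denominator = "per_metric"` (default) `n_total` counts individuals with a
#' nonzero score *for this metric*, which makes the cumulative weight of the
#' highest observed score exactly 1. With `denominator = "any_change"`
#' `n_total` counts individuals with a change in any metric.
#'
#' @param annotations A T1 annotation tibble (one row per assessed individual).
#' @param metric One of `"growth"`, `"tissue_loss"`, `"biofouling"`,
#'   `"orientation"`.
#' @param pooling `"global"` (one cohort) or `"per_site"` (tabulate within
#'   each `site_id`).
#' @param denominator `"per_metric"` or `"any_change"` (see above).
#' @return A tibble with columns `score`, `n`, `n_total` (plus `site_id` when
#'   pooling per site). Errors if no individual shows any change to weight.
#' @examples
#' ann <- tibble::tibble(site_id = "S1",
#'                       growth = c(0, 0, 1, 1, 2, 3), tissue_loss = 0,
#'                       biofouling = 0, orientation = 0)
#' tabulate_metric_counts(ann, "growth")
#' @export
tabulate_metric_counts <- function(annotations, metric,
                                   pooling = c("global", "per_site"),
                                   denominator = c("per_metric", "any_change")) {
  pooling <- match.arg(pooling)
  denominator <- match.arg(denominator)
  metric <- match.arg(metric, metric_names())
  if (nrow(annotations) == 0) abort("Annotation table is empty.")
  tab_one <- function(df) {
    v <- df[[metric]]
    nz <- v[v > 0]
    if (length(nz) == 0) {
      abort(paste0("No condition changes to weight for metric '", metric, "'."))
    }
    n_total <- if (denominator == "per_metric") {
      length(nz)
    } else {
      present <- metric_names()[metric_names() %in% names(df)]
      sum(rowSums(as.matrix(df[, present, drop = FALSE])) > 0)
    }
    counts <- table(nz)
    tibble::tibble(score = as.integer(names(counts)),
                   n = as.integer(counts),
                   n_total = n_total)
  }
  if (pooling == "global") {
    tab_one(annotations)
  } else {
    annotations |>
      dplyr::group_by(.data$site_id) |>
      dplyr::group_modify(~ tab_one(.x)) |>
      dplyr::ungroup()
  }
}

#' Cumulative frequency weights for a metric
#'
#' Converts score occurrence counts into frequency weights:
#' `w(s) = (n_1 + ... + n_s) / n_total`, with `w(0) = 0` and scores absent
#' from the counts carrying the cumulative value forward. With the per-metric
#' denominator the maximum observed score always has weight 1.
#'
#' @param counts Either the tibble returned by [tabulate_metric_counts()]
#'   (for one pooling unit) or a named numeric vector mapping nonzero scores
#'   to counts.
#' @param n_total The weighting denominator; taken from the tibble if omitted.
#' @return A tibble with `score` (0 up to the maximum observed score) and
#'   `weight`, carrying `n_total` as an attribute.
#' @examples
#' frequency_weights(c("1" = 2, "2" = 1, "3" = 1), n_total = 4)
#' @export
frequency_weights <- function(counts, n_total = NULL) {
  if (is.data.frame(counts)) {
    n_total <- n_total %||% counts$n_total[1]
    counts <- setNames(counts$n, counts$score)
  }
  if (is.null(n_total) || n_total < 1) {
    abort("n_total must be a positive count of changed individuals.")
  }
  scores <- as.integer(names(counts))
  if (any(is.na(scores)) || any(scores < 1)) {
    abort("counts must be keyed by integer scores >= 1.")
  }
  s_max_obs <- max(scores)
  full <- integer(s_max_obs)
  full[scores] <- as.integer(counts)
  out <- tibble::tibble(
    score = 0:s_max_obs,
    weight = c(0, cumsum(full) / n_total)
  )
  attr(out, "n_total") <- as.integer(n_total)
  out
}

#' Severity-scale a frequency weight
#'
#' Frequency weighting alone can rank a mild score of one metric above a
#' severe score of another; multiplying by `s / s_max` restores the ordinal
#' severity ranking within each metric: `severity-scaled score = w * s / s_max`.
#'
#' @param w Frequency weight(s) in \[0, 1\].
#' @param s Initial score(s), `0 <= s <= s_max`.
#' @param s_max Maximum possible score for the metric (4, or 2 for
#'   orientation change).
#' @return The severity-scaled score(s), in \[0, 1\].
#' @examples
#' severity_scaled_score(0.5, 1, 4)
#' @export
severity_scaled_score <- function(w, s, s_max) {
  if (any(w < 0 | w > 1)) abort("Weights must lie in [0, 1].")
  if (any(s < 0) || any(s > s_max)) {
    abort("Scores must satisfy 0 <= s <= s_max.")
  }
  w * s / s_max
}

# Look up w(s) in a weight table; scores above the table's domain are an
# error (they cannot arise when the table was built from the same cohort).
weight_lookup <- function(wt, s) {
  if (s == 0) return(0)
  hit <- match(s, wt$score)
  if (is.na(hit)) {
    abort(paste0("Score ", s, " is absent from the weight table's domain ",
                 "(built from a different cohort?)."))
  }
  wt$weight[hit]
}

#' Overall condition score for one individual
#'
#' Sums the signed severity-scaled components across the four metrics
#' (growth positive; tissue loss, biofouling and orientation change negative)
#' and clamps the total to \[-1, 1\]. Components are recorded pre-clamp.
#'
#' @param metrics A named list or one-row data frame with the four metric
#'   scores.
#' @param weight_tables A named list of per-metric weight tables from
#'   [frequency_weights()], built from the same cohort as the individual.
#' @return A one-row tibble with the signed components, `value` and `clamped`.
#' @export
individual_condition <- function(metrics, weight_tables) {
  specs <- metric_specs()
  comps <- purrr::map_dbl(seq_len(nrow(specs)), function(i) {
    m <- specs$metric[i]
    s <- as.numeric(metrics[[m]])
    if (s == 0) return(0)
    wt <- weight_tables[[m]]
    if (is.null(wt)) {
      abort(paste0("No weight table for metric '", m, "'."))
    }
    specs$sign[i] * severity_scaled_score(weight_lookup(wt, s), s, specs$s_max[i])
  })
  total <- sum(comps)
  value <- min(1, max(-1, total))
  tibble::tibble(
    !!!setNames(as.list(comps), paste0(specs$metric, "_component")),
    value = value,
    clamped = value != total
  )
}

#' Condition scores for an assessed cohort
#'
#' Builds the per-metric frequency weight tables from the cohort itself and
#' scores every individual. Baseline (T0) individuals are identically zero by
#' definition, so this is applied to the T1 table of assessed survivors.
#' Metrics in which no individual changed contribute zero for everyone.
#'
#' @param annotations A T1 annotation tibble.
#' @param pooling `"global"` (weights from the whole cohort, default) or
#'   `"per_site"` (weights computed within each site).
#' @param denominator Passed to [tabulate_metric_counts()].
#' @return A tibble: identity columns, the four signed components, `value`
#'   in \[-1, 1\], `clamped`, and `changed` (any nonzero metric).
#' @examples
#' ann <- tibble::tibble(individual_id = c("a", "b", "c"), site_id = "S1",
#'                       phylum = "Porifera", otu = "sp1",
#'                       growth = c(0, 3, 0), tissue_loss = c(4, 0, 0),
#'                       biofouling = 0, orientation = 0)
#' condition_scores(ann)
#' @export
condition_scores <- function(annotations,
                             pooling = c("global", "per_site"),
                             denominator = c("per_metric", "any_change")) {
  pooling <- match.arg(pooling)
  denominator <- match.arg(denominator)
  if (nrow(annotations) == 0) abort("Annotation table is empty.")
  score_cohort <- function(df) {
    wts <- list()
    for (m in metric_names()) {
      wts[[m]] <- tryCatch(
        frequency_weights(tabulate_metric_counts(df, m, pooling = "global",
                                                 denominator = denominator)),
        error = function(e) tibble::tibble(score = 0L, weight = 0) # no changes
      )
    }
    comp <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
      individual_condition(df[i, ], wts)
    })
    id_cols <- intersect(c("individual_id", "site_id", "phylum", "otu"),
                         names(df))
    dplyr::bind_cols(
      df[, id_cols, drop = FALSE],
      comp,
      changed = rowSums(as.matrix(df[, metric_names(), drop = FALSE])) > 0
    )
  }
  if (pooling == "global") {
    score_cohort(annotations)
  } else {
    annotations |>
      dplyr::group_by(.data$site_id) |>
      dplyr::group_modify(~ score_cohort(.x)) |>
      dplyr::ungroup()
  }
}

#' Summarise condition scores within a factor
#'
#' Mean, standard error and count of individual condition scores per level of
#' a grouping factor (site, phylum, oxygen zone, seamount, ...). Scores are
#' pooled at the individual level — never summed or averaged per OTU first.
#'
#' @param scores Output of [condition_scores()] (optionally joined to site
#'   metadata for zone/seamount grouping).
#' @param by Character vector of grouping column names.
#' @param changed_only If `TRUE`, restrict to individuals with a condition
#'   change in at least one metric (survivors with no change score 0 and are
#'   included by default).
#' @return A tibble with the grouping columns, `mean`, `se` (NA when n = 1)
#'   and `n`. Empty levels are absent.
#' @export
condition_summary <- function(scores, by = "site_id", changed_only = FALSE) {
  missing <- setdiff(by, names(scores))
  if (length(missing) > 0) {
    abort(paste0("Grouping column(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (changed_only) scores <- dplyr::filter(scores, .data$changed)
  scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean = mean(.data$value), se = se_mean(.data$value),
                     n = dplyr::n(), .groups = "drop")
}
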