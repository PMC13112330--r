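# Fate accounting and the per-OTU percent abundance change statistic.

#' Percent change in abundance
#'
#' `delta = 100 * (a1 - a0) / a0`: the percent change in the number of
#' individuals of an OTU within a factor level between surveys. Undefined when
#' no individuals were present at baseline (`a0 = 0`); those cases return `NA`
#' and belong in the fate tally (recruit-only OTUs), not in delta summaries.
#'
#' @param a0,a1 Non-negative counts at T0 and T1 (vectorised).
#' @return Percent change; `NA` where `a0 = 0`.
#' @examples
#' delta_abundance(100, 90)  # -10
#' delta_abundance(100, 21)  # -79
#' @export
delta_abundance <- function(a0, a1) {
  if (any(a0 < 0) || any(a1 < 0)) abort("Counts must be non-negative.")
  if (any(a0 != round(a0)) || any(a1 != round(a1))) {
    abort("Counts must be integers.")
  }
  ifelse(a0 > 0, 100 * (a1 - a0) / a0, NA_real_)
}

# Resolve the fates input: a match_set tibble or a bind_rows of several.
check_fates <- function(fates) {
  required <- c("otu", "fate")
  missing <- setdiff(required, names(fates))
  if (length(missing) > 0) {
    abort(paste0("Fates table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(fates$fate %in% c("survived", "lost", "recruit"))) {
    abort("fate must be 'survived', 'lost' or 'recruit'.")
  }
  fates
}

#' Per-OTU abundance change within factor levels
#'
#' Counts each OTU's individuals at T0 (`survived + lost`) and T1
#' (`survived + recruit`) within every level of a grouping factor and computes
#' the percent abundance change. Counts are pooled across the level's member
#' sites before the delta is taken (so a phylum-level delta uses phylum-level
#' totals, not an average of site deltas). OTUs absent at baseline within a
#' level have an undefined delta (`NA`) and are flagged.
#'
#' @param fates One or more row-bound [match_individuals()] results,
#'   optionally joined to site metadata for zone/seamount grouping.
#' @param by Character vector of grouping columns (default `"site_id"`); use
#'   `character()` for study-wide per-OTU deltas.
#' @return A tibble with the grouping columns, `otu`, `a0`, `a1`,
#'   `delta_pct` and `defined` (FALSE where `a0 = 0`).
#' @export
per_otu_delta <- function(fates, by = "site_id") {
  fates <- check_fates(fates)
  missing <- setdiff(by, names(fates))
  if (length(missing) > 0) {
    abort(paste0("Grouping column(s) not found: ", paste(missing, collapse = ", ")))
  }
  out <- fates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "otu")))) |>
    dplyr::summarise(
      a0 = sum(.data$fate != "recruit"),
      a1 = sum(.data$fate != "lost"),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta_pct = delta_abundance(.data$a0, .data$a1),
                  defined = .data$a0 > 0)
  n_undef <- sum(!out$defined)
  if (n_undef > 0) {
    inform(paste0(n_undef, " recruit-only OTU-level row(s) have undefined ",
                  "delta abundance (a0 = 0) and are excluded from summaries."))
  }
  out
}

#' Tally fates within factor levels
#'
#' Per-level totals of baseline individuals, revisit individuals, losses,
#' recruits and survivors, with the identities
#' `n_t0 = survivors + lost`, `n_t1 = survivors + recruits` and
#' `net_change = recruits - lost`.
#'
#' @inheritParams per_otu_delta
#' @param by Grouping columns; `character()` gives a study-wide tally.
#' @return A tibble with the grouping columns and `n_t0`, `n_t1`, `survivors`,
#'   `lost`, `recruits`, `net_change`.
#' @export
fate_tally <- function(fates, by = "site_id") {
  fates <- check_fates(fates)
  missing <- setdiff(by, names(fates))
  if (length(missing) > 0) {
    abort(paste0("Grouping column(s) not found: ", paste(missing, collapse = ", ")))
  }
  grouped <- if (length(by) > 0) {
    dplyr::group_by(fates, dplyr::across(dplyr::all_of(by)))
  } else {
    fates
  }
  grouped |>
    dplyr::summarise(
      survivors = sum(.data$fate == "survived"),
      lost = sum(.data$fate == "lost"),
      recruits = sum(.data$fate == "recruit"),
      n_t0 = .data$survivors + .data$lost,
      n_t1 = .data$survivors + .data$recruits,
      net_change = .data$recruits - .data$lost,
      .groups = "drop"
    ) |>
    dplyr::relocate(dplyr::all_of(by), "n_t0", "n_t1", "survivors", "lost",
                    "recruits", "net_change")
}

#' Summarise per-OTU abundance deltas within factor levels
#'
#' Arithmetic mean and standard error of the defined per-OTU percent
#' abundance changes within each level of a grouping factor. Levels with no
#' defined delta are omitted with a message.
#'
#' @param deltas Output of [per_otu_delta()].
#' @param by Grouping columns (default `"site_id"`).
#' @return A tibble with the grouping columns, `mean`, `se` (NA when n = 1)
#'   and `n_otu`.
#' @export
delta_summary <- function(deltas, by = "site_id") {
  missing <- setdiff(by, names(deltas))
  if (length(missing) > 0) {
    abort(paste0("Grouping column(s) not found: ", paste(missing, collapse = ", ")))
  }
  all_levels <- dplyr::distinct(deltas, dplyr::across(dplyr::all_of(by)))
  defined <- dplyr::filter(deltas, !is.na(.data$delta_pct))
  out <- defined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean = mean(.data$delta_pct), se = se_mean(.data$delta_pct),
                     n_otu = dplyr::n(), .groups = "drop")
  dropped <- nrow(all_levels) - nrow(out)
  if (dropped > 0) {
    inform(paste0(dropped, " level(s) with no defined delta omitted from summary."))
  }
  out
}
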