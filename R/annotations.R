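#' Condition metric specifications
#'
#' The four qualitative condition metrics scored on every individual at the
#' revisit survey. Growth is the only positive metric; tissue loss, biofouling
#' and vertical orientation change are negative. Growth, tissue loss and
#' biofouling are scored 0-4 (0%, 1%-25%, 26%-50%, 51%-75%, 76%-100% change);
#' orientation change is scored 0-2 (none, ~1-45 degrees, >= ~46 degrees).
#'
#' @return A tibble with columns `metric`, `s_max` (maximum possible score)
#'   and `sign` (+1 for growth, -1 otherwise).
#' @examples
#' metric_specs()
#' @export
metric_specs <- function() {
  tibble::tibble(
    metric = c("growth", "tissue_loss", "biofouling", "orientation"),
    s_max  = c(4L, 4L, 4L, 2L),
    sign   = c(1L, -1L, -1L, -1L)
  )
}

metric_names <- function() metric_specs()$metric

#' Required annotation table columns
#'
#' @return Character vector of the column names every annotation table must
#'   carry.
#' @export
annotation_columns <- function() {
  c("individual_id", "site_id", "timepoint", "phylum", "otu",
    "x_m", "y_m", "depth_m", metric_names())
}

#' Validate an annotation table
#'
#' Checks an in-memory annotation table against the annotation schema: one row
#' per individual at one timepoint, with identity (`phylum`, `otu`), projected
#' planar position (`x_m`, `y_m`, metres), depth, and the four condition
#' metric scores. Baseline (T0) records must carry all-zero metrics, since the
#' baseline mosaic defines condition zero for all future monitoring.
#'
#' @param annotations A data frame with the columns of [annotation_columns()];
#'   an optional logical `min_size_ok` column marks individuals above the 5 cm
#'   annotation threshold (rows failing it are dropped with a message).
#' @param timepoint Optional; if given (`"T0"` or `"T1"`), all rows must carry
#'   this timepoint.
#' @return The validated tibble (rows failing the minimum-size rule removed).
#' @export
validate_annotations <- function(annotations, timepoint = NULL) {
  required <- annotation_columns()
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    abort(paste0("Annotation table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ann <- tibble::as_tibble(annotations)
  if (!all(ann$timepoint %in% c("T0", "T1"))) {
    abort("timepoint must be 'T0' or 'T1' for every row.")
  }
  if (!is.null(timepoint)) {
    timepoint <- match.arg(timepoint, c("T0", "T1"))
    if (!all(ann$timepoint == timepoint)) {
      abort(paste0("All rows must have timepoint ", timepoint, "."))
    }
  }
  if (any(!nzchar(ann$phylum)) || any(is.na(ann$phylum)) ||
      any(!nzchar(ann$otu)) || any(is.na(ann$otu))) {
    abort("phylum and otu must be non-empty for every row.")
  }
  if (!all(ann$phylum %in% c("Cnidaria", "Porifera"))) {
    abort("phylum must be 'Cnidaria' or 'Porifera'.")
  }
  dup <- ann |>
    dplyr::count(.data$site_id, .data$timepoint, .data$individual_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate individual_id within (site, timepoint): ",
                 paste(utils::head(dup$individual_id, 5), collapse = ", ")))
  }
  specs <- metric_specs()
  for (i in seq_len(nrow(specs))) {
    m <- specs$metric[i]
    v <- ann[[m]]
    if (any(is.na(v))) abort(paste0("Missing values in metric '", m, "'."))
    bad <- which(v < 0 | v > specs$s_max[i] | v != round(v))
    if (length(bad) > 0) {
      abort(paste0("Metric '", m, "' out of range 0-", specs$s_max[i],
                   " (must be an integer) at row(s) ",
                   paste(utils::head(bad, 5), collapse = ", "), "."))
    }
  }
  t0_rows <- ann$timepoint == "T0"
  if (any(t0_rows)) {
    nz <- rowSums(as.matrix(ann[t0_rows, metric_names()])) > 0
    if (any(nz)) {
      abort(paste0("Baseline rule violated: T0 records must carry all-zero ",
                   "condition metrics (the baseline survey defines condition ",
                   "zero); offending row(s) ",
                   paste(utils::head(which(t0_rows)[nz], 5), collapse = ", "), "."))
    }
  }
  if ("min_size_ok" %in% names(ann)) {
    n_small <- sum(!ann$min_size_ok)
    if (n_small > 0) {
      inform(paste0("Dropping ", n_small,
                    " record(s) below the 5 cm annotation threshold."))
      ann <- ann[ann$min_size_ok, , drop = FALSE]
    }
  }
  ann
}

#' Read an organism annotation table
#'
#' Reads a delimited (CSV) per-timepoint annotation export — one row per coral
#' or sponge individual — and validates it with [validate_annotations()].
#'
#' @param path Path to a UTF-8 CSV file with columns `individual_id`,
#'   `site_id`, `timepoint`, `phylum`, `otu`, `x_m`, `y_m`, `depth_m`,
#'   `growth`, `tissue_loss`, `biofouling`, `orientation` (and optionally
#'   `min_size_ok`).
#' @inheritParams validate_annotations
#' @return A validated annotation tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(
#'   tibble::tibble(
#'     individual_id = c("a", "b"), site_id = "S1", timepoint = "T0",
#'     phylum = "Porifera", otu = "Pinulasma n. sp.",
#'     x_m = c(1, 2), y_m = c(1, 2), depth_m = 800,
#'     growth = 0, tissue_loss = 0, biofouling = 0, orientation = 0
#'   ),
#'   path
#' )
#' read_annotations(path, timepoint = "T0")
#' @export
read_annotations <- function(path, timepoint = NULL) {
  if (!file.exists(path)) abort(paste0("Annotation file not found: ", path))
  ann <- readr::read_csv(path, show_col_types = FALSE)
  validate_annotations(ann, timepoint = timepoint)
}
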