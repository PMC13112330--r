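# Planar geometry helpers for overlap clipping. All coordinates are projected
# metres (the mosaics are exported in a metric projection); no geodesic math.

as_ring <- function(region) {
  if (is.data.frame(region)) region <- as.matrix(region[, 1:2])
  if (!is.matrix(region) || ncol(region) < 2 || nrow(region) < 3) {
    abort("region must be a polygon: a matrix or data frame of >= 3 (x, y) vertices.")
  }
  ring <- unname(region[, 1:2, drop = FALSE])
  # drop an explicit closing vertex
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  if (nrow(ring) < 3) abort("region must have at least 3 distinct vertices.")
  ring
}

# Signed shoelace area of a ring (open; first vertex not repeated).
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Boundary-inclusive point-in-polygon test, vectorised over points.
# Crossing-number ray cast with an explicit on-segment check so that points
# exactly on the boundary are always inside.
point_in_polygon <- function(px, py, ring) {
  nv <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  eps <- 1e-9
  for (i in seq_len(nv)) {
    j <- if (i == 1L) nv else i - 1L
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-segment: collinear and within the bounding box
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    on_seg <- abs(cross) <= eps * max(1, sqrt(seg_len2)) &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Clip an annotation table to an overlap region
#'
#' Revisit mosaics rarely cover the whole baseline mosaic, and only
#' individuals inside the area common to both surveys can be compared. This
#' restricts an annotation table to records whose position lies inside (or on
#' the boundary of) a simple polygon in the same projected coordinate system.
#' With `region = NULL` the table is returned unchanged (assumed pre-clipped).
#'
#' @param annotations An annotation tibble with `x_m`, `y_m` columns.
#' @param region A simple polygon: a matrix or data frame of (x, y) vertices
#'   in metres, or `NULL`.
#' @return The subset of `annotations` inside the region.
#' @examples
#' ann <- tibble::tibble(individual_id = c("a", "b"),
#'                       x_m = c(0.5, 2), y_m = c(0.5, 2))
#' square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' clip_to_overlap(ann, square)
#' @export
clip_to_overlap <- function(annotations, region = NULL) {
  if (is.null(region)) return(tibble::as_tibble(annotations))
  ring <- as_ring(region)
  if (abs(polygon_area(ring)) < 1e-12) {
    abort("Degenerate overlap region: polygon has zero area.")
  }
  keep <- point_in_polygon(annotations$x_m, annotations$y_m, ring)
  tibble::as_tibble(annotations[keep, , drop = FALSE])
}

#' Read site overlap polygons from GeoJSON
#'
#' Reads a GeoJSON `FeatureCollection` of overlap polygons, one feature per
#' site, keyed by a `site_id` property. Only simple (single-ring) polygons are
#' supported; coordinates must be in the same projected metric system as the
#' annotations.
#'
#' @param path Path to a GeoJSON file.
#' @return A named list of vertex matrices, keyed by `site_id`.
#' @export
read_overlap_polygons <- function(path) {
  if (!file.exists(path)) abort(paste0("Polygon file not found: ", path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) abort("Expected a GeoJSON FeatureCollection.")
  polys <- list()
  for (feat in gj$features) {
    sid <- feat$properties$site_id
    if (is.null(sid)) abort("Every feature needs a 'site_id' property.")
    geom <- feat$geometry
    if (is.null(geom$type) || geom$type != "Polygon") {
      abort(paste0("Feature for site ", sid, " is not a Polygon."))
    }
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    polys[[sid]] <- as_ring(ring)
  }
  polys
}

# Serialise a named list of vertex matrices back to GeoJSON.
write_overlap_polygons <- function(polygons, path) {
  feats <- lapply(names(polygons), function(sid) {
    ring <- as_ring(polygons[[sid]])
    ring <- rbind(ring, ring[1, ])
    list(
      type = "Feature",
      properties = list(site_id = sid),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          as.list(unname(ring[i, ]))
        }))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
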