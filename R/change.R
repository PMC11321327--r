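# maxSSS thresholding, binarization, four-category change mapping, zonal
# area accounting, and centroid-based direction of distributional shift.

#' Threshold maximizing sensitivity + specificity (maxSSS)
#'
#' Exhaustive search over the candidate set (sorted unique probabilities plus
#' 0 and 1) under the rule `p >= t`; ties are broken toward the smallest
#' maximizing candidate.
#'
#' @param labels 0/1 vector with both classes present.
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @return the maxSSS threshold.
#' @export
max_sss_threshold <- function(labels, probabilities) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  cand <- sort(unique(c(0, 1, probabilities)))
  sss <- vapply(cand, function(t) {
    s <- evaluate_binary(labels, probabilities, t)
    s$sensitivity + s$specificity
  }, numeric(1))
  cand[which.max(sss)]          # which.max returns the first (smallest) max
}

#' Binarize a suitability map
#'
#' @param suitability probability [grid_layer()].
#' @param threshold cut-off in `[0, 1]`; a cell is suitable (1) iff its value
#'   is `>= threshold`. The published maps use the rounded 50% cut-off; use
#'   [max_sss_threshold()] for the species-specific alternative.
#' @return binary [grid_layer()] with the threshold recorded as an attribute.
#' @export
binarize <- function(suitability, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  g <- blank_like(suitability, "binary_suitability")
  g$values <- (suitability$values >= threshold) * 1
  attr(g, "threshold") <- threshold
  g
}

CHANGE_CATEGORIES <- c(absence = 0, negative = 1, no_change = 2, positive = 3)

#' Current-vs-future change map
#'
#' Cellwise category algebra: negative = suitable now only, positive = newly
#' suitable, no_change = suitable in both, absence = suitable in neither;
#' nodata in either input propagates. Categories are coded 0 = absence,
#' 1 = negative, 2 = no_change, 3 = positive.
#'
#' @param current,future co-registered binary maps from [binarize()].
#' @return categorical [grid_layer()] of class `change_map`.
#' @export
change_map <- function(current, future) {
  if (!same_geometry(current, future))
    stop("current and future maps are not co-registered", call. = FALSE)
  cur <- current$values; fut <- future$values
  m <- matrix(NA_real_, nrow(cur), ncol(cur))
  m[cur == 0 & fut == 0] <- CHANGE_CATEGORIES["absence"]
  m[cur == 1 & fut == 0] <- CHANGE_CATEGORIES["negative"]
  m[cur == 1 & fut == 1] <- CHANGE_CATEGORIES["no_change"]
  m[cur == 0 & fut == 1] <- CHANGE_CATEGORIES["positive"]
  g <- blank_like(current, "change")
  g$values <- m
  class(g) <- c("change_map", class(g))
  g
}

#' Quantify change-category areas, optionally by zone
#'
#' Area per category = cell count times `cell_size^2 / 1e6` square km.
#' Derived columns: `current_km2` = negative + no_change and `future_km2` =
#' no_change + positive.
#'
#' @param cm a [change_map()].
#' @param zones optional co-registered integer zone [grid_layer()].
#' @return data frame with one row per zone plus a `total` row; columns
#'   `zone`, the four category areas (km2), `current_km2`, `future_km2`.
#' @export
quantify_areas <- function(cm, zones = NULL) {
  if (!is.null(zones) && !same_geometry(cm, zones))
    stop("zones are not co-registered with the change map", call. = FALSE)
  km2 <- cm$cell_size^2 / 1e6
  zone_vals <- if (is.null(zones)) matrix(1, nrow(cm$values), ncol(cm$values))
               else zones$values
  row_for <- function(sel, label) {
    counts <- vapply(CHANGE_CATEGORIES, function(code)
      sum(cm$values[sel] == code, na.rm = TRUE), numeric(1))
    area <- counts * km2
    data.frame(zone = label, absence_km2 = area[["absence"]],
               negative_km2 = area[["negative"]],
               no_change_km2 = area[["no_change"]],
               positive_km2 = area[["positive"]],
               current_km2 = area[["negative"]] + area[["no_change"]],
               future_km2 = area[["no_change"]] + area[["positive"]])
  }
  zl <- sort(unique(zone_vals[!is.na(zone_vals)]))
  out <- do.call(rbind, lapply(zl, function(z)
    row_for(!is.na(zone_vals) & zone_vals == z, as.character(z))))
  rbind(out, row_for(!is.na(zone_vals), "total"))
}

#' Centroid shift between two binary maps
#'
#' Centroids are the unweighted means of suitable-cell centre coordinates.
#' The bearing is `atan2(dx, dy)` mapped to `[0, 360)` degrees clockwise from
#' north (90 = east, 225 = southwest); distance is planar Euclidean in km.
#' Identical centroids report bearing 0 by convention.
#'
#' @param current,future binary maps from [binarize()].
#' @param weighted if `TRUE`, weight cell centres by the suitability values
#'   of the supplied maps instead of treating them as binary.
#' @return list `bearing` (degrees), `distance_km`, and both centroids.
#' @export
centroid_shift <- function(current, future, weighted = FALSE) {
  centroid <- function(g) {
    v <- g$values
    sel <- which(!is.na(v) & v > 0)
    if (!length(sel)) stop("map has no suitable cells", call. = FALSE)
    rows <- (sel - 1L) %% nrow(v) + 1L
    cols <- (sel - 1L) %/% nrow(v) + 1L
    ctr <- cell_center(g, rows, cols)
    w <- if (weighted) v[sel] else rep(1, length(sel))
    c(x = sum(w * ctr[, "x"]) / sum(w), y = sum(w * ctr[, "y"]) / sum(w))
  }
  c0 <- centroid(current); c1 <- centroid(future)
  dx <- c1["x"] - c0["x"]; dy <- c1["y"] - c0["y"]
  dist_km <- sqrt(dx^2 + dy^2) / 1000
  bearing <- if (dist_km == 0) 0 else (atan2(dx, dy) * 180 / pi) %% 360
  list(bearing = unname(bearing), distance_km = unname(dist_km),
       current_centroid = c0, future_centroid = c1)
}
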