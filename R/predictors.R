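# Predictor-stack assembly: depth-weighted soil aggregation, Euclidean
# distance to water, per-cell occurrence thinning, and canonical stacking
# including the habitat-suitability (ESRm) biotic layer.

#' Soil variable as a stack of depth-interval layers
#'
#' @param variable soil variable name (e.g. `"bdod"`).
#' @param layers list of `list(top =, bottom =, grid =)` entries in cm;
#'   intervals must be sorted, non-overlapping and co-registered.
#' @return a `depth_profile` object.
#' @export
depth_profile <- function(variable, layers) {
  tops <- vapply(layers, `[[`, numeric(1), "top")
  bots <- vapply(layers, `[[`, numeric(1), "bottom")
  if (any(tops < 0) || any(bots <= tops))
    stop("depth intervals must satisfy 0 <= top < bottom", call. = FALSE)
  o <- order(tops)
  layers <- layers[o]; tops <- tops[o]; bots <- bots[o]
  if (any(tops[-1L] < bots[-length(bots)]))
    stop("depth intervals overlap", call. = FALSE)
  for (l in layers[-1L])
    if (!same_geometry(layers[[1L]]$grid, l$grid))
      stop("depth layers are not co-registered", call. = FALSE)
  structure(list(variable = variable, layers = layers),
            class = "depth_profile")
}

#' Per-species modelling configuration
#'
#' Soil depth intervals follow the species' burrowing ecology: 5-30 cm for
#' *Anadara tuberculosa*, 15-30 cm for *A. similis*, and 0-200 cm (the full
#' profile) for the mangrove *Rhizophora mangle*.
#'
#' @param species species name.
#' @param soil_interval numeric `c(top_cm, bottom_cm)`, `top < bottom`.
#' @param uses_esrm does this species' model take the habitat-suitability
#'   layer (ESRm) as a biotic predictor? `FALSE` for the habitat species
#'   itself.
#' @param is_habitat is this species the habitat provider whose suitability
#'   map becomes the ESRm layer?
#' @return a `species_config` object.
#' @export
species_config <- function(species, soil_interval, uses_esrm = FALSE,
                           is_habitat = FALSE) {
  if (length(soil_interval) != 2L || soil_interval[1L] >= soil_interval[2L])
    stop("soil_interval must be c(top, bottom) with top < bottom",
         call. = FALSE)
  if (uses_esrm && is_habitat)
    stop("the habitat species cannot use its own suitability as a predictor",
         call. = FALSE)
  structure(list(species = species, soil_interval = as.numeric(soil_interval),
                 uses_esrm = isTRUE(uses_esrm),
                 is_habitat = isTRUE(is_habitat)),
            class = "species_config")
}

#' Depth-weighted mean of a soil profile over an interval
#'
#' Cellwise mean of the depth layers weighted by the thickness of each
#' layer's overlap with the requested interval; layers with no overlap are
#' excluded, and nodata in any contributing layer propagates. With
#' `weighting = "equal"` every overlapping layer contributes equally (simple
#' layer mean).
#'
#' @param profile a [depth_profile()].
#' @param interval numeric `c(top_cm, bottom_cm)`.
#' @param weighting `"thickness"` (default) or `"equal"`.
#' @return a [grid_layer()] named `<variable>` with the interval recorded in
#'   its units field.
#' @export
depth_weighted_mean <- function(profile, interval,
                                weighting = c("thickness", "equal")) {
  weighting <- match.arg(weighting)
  top <- interval[1L]; bottom <- interval[2L]
  w <- vapply(profile$layers, function(l)
    max(0, min(bottom, l$bottom) - max(top, l$top)), numeric(1))
  if (weighting == "equal") w <- as.numeric(w > 0)
  if (all(w == 0))
    stop("interval [", top, ", ", bottom, "] overlaps no depth layer",
         call. = FALSE)
  ref <- profile$layers[[1L]]$grid
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (k in seq_along(profile$layers))
    if (w[k] > 0) acc <- acc + w[k] * profile$layers[[k]]$grid$values
  grid_layer(profile$variable, acc / sum(w), ref$origin_x, ref$origin_y,
             ref$cell_size, ref$nodata,
             units = sprintf("%s, %g-%g cm mean",
                             profile$layers[[1L]]$grid$units, top, bottom))
}

#' Euclidean distance to the nearest water cell
#'
#' Centre-to-centre planar distance in metres; zero on water cells.
#'
#' @param water_mask binary [grid_layer()] (1 = water).
#' @return [grid_layer()] `dwb` of distances in metres.
#' @export
distance_to_water <- function(water_mask) {
  m <- water_mask$values
  wet <- which(!is.na(m) & m == 1)
  if (!length(wet)) stop("mask contains no water cells", call. = FALSE)
  nr <- nrow(m)
  wr <- (wet - 1L) %% nr + 1L
  wc <- (wet - 1L) %/% nr + 1L
  rows <- matrix(seq_len(nr), nr, ncol(m))
  cols <- matrix(rep(seq_len(ncol(m)), each = nr), nr, ncol(m))
  d2 <- matrix(Inf, nr, ncol(m))
  for (k in seq_along(wet))
    d2 <- pmin(d2, (rows - wr[k])^2 + (cols - wc[k])^2)
  g <- blank_like(water_mask, "dwb")
  g$values <- sqrt(d2) * water_mask$cell_size
  g$units <- "m"
  g
}

#' Thin occurrences to one per grid cell
#'
#' Records falling in the same template cell are condensed into a single
#' occurrence; the first record by input order is kept.
#'
#' @param occ an [occurrence_set()].
#' @param template [grid_layer()] defining the cells (the fine model grid).
#' @return a thinned [occurrence_set()].
#' @export
thin_occurrences <- function(occ, template) {
  if (!n_records(occ)) stop("occurrence set is empty", call. = FALSE)
  idx <- cell_index(template, occ$records$x, occ$records$y)
  key <- paste(idx[, "row"], idx[, "col"])
  keep <- !duplicated(key)
  occurrence_set(occ$species, occ$records$x[keep], occ$records$y[keep],
                 occ$records$label[keep])
}

# Canonical predictor order: bioclim roster, soil physicochemical variables,
# distance to water, elevation, and the biotic ESRm layer last.
CANONICAL_ORDER <- c(paste0("bio", 1:19),
                     "bdod", "cec", "cfvo", "clay", "nitrogen", "ocd", "ph",
                     "sand", "silt", "soc", "dwb", "dem", "esrm")

#' Assemble the predictor stack for one species
#'
#' Stacks climate layers, per-species soil means, DEM, distance to water and
#' (for species that take it) the habitat-suitability ESRm layer, in
#' canonical roster order with ESRm last. Layer names are canonicalized to
#' lower case.
#'
#' @param climate_fine [raster_stack()] of fine-resolution climate layers.
#' @param soil_means [raster_stack()] (or list of [grid_layer()]s) of
#'   depth-aggregated soil layers.
#' @param dem fine DEM [grid_layer()].
#' @param dwb distance-to-water [grid_layer()].
#' @param esrm habitat suitability [grid_layer()] or `NULL`.
#' @param species_cfg a [species_config()].
#' @return a [raster_stack()] with layer types recorded.
#' @export
assemble_predictors <- function(climate_fine, soil_means, dem, dwb,
                                esrm = NULL, species_cfg) {
  if (species_cfg$uses_esrm && is.null(esrm))
    stop("species uses ESRm but no habitat-suitability layer was given",
         call. = FALSE)
  soil_layers <- if (inherits(soil_means, "raster_stack")) soil_means$layers
                 else soil_means
  layers <- c(climate_fine$layers, soil_layers, list(dem = dem, dwb = dwb))
  types <- c(rep("climate", length(climate_fine$layers)),
             rep("soil", length(soil_layers)), "terrain", "terrain")
  if (species_cfg$uses_esrm) {
    esrm$name <- "esrm"
    layers <- c(layers, list(esrm = esrm))
    types <- c(types, "biotic")
  }
  for (i in seq_along(layers)) layers[[i]]$name <- tolower(layers[[i]]$name)
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate predictor names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  ord <- order(match(nms, CANONICAL_ORDER, nomatch = length(CANONICAL_ORDER)),
               seq_along(nms))
  if (!check_coregistered(layers))
    stop("predictor layers are not co-registered", call. = FALSE)
  raster_stack(layers[ord], types = stats::setNames(types[ord], nms[ord]))
}
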