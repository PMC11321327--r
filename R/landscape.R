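# Synthetic study landscapes with known environmental structure, known
# niches, and known future climate displacement, so downstream stages have a
# recoverable ground truth.

#' Evaluate code with a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic environmental variable
#'
#' @param name layer name (e.g. `"bio1"`, `"bdod"`).
#' @param type `"climate"` or `"soil"`; climate variables exist at both
#'   resolutions and receive scenario deltas, soil variables come as depth
#'   profiles and are held fixed under scenarios.
#' @param mean,sd target spatial mean and standard deviation of the field, in
#'   the variable's units.
#' @param corr_range spatial autocorrelation length in fine cells (Gaussian
#'   smoothing scale of the underlying noise field).
#' @param trend optional linear trend: `list(direction = degrees clockwise
#'   from north, amplitude = total span across the domain)` added to the
#'   smooth field.
#' @param units unit string carried into the layers.
#' @return a `variable_spec` list.
#' @export
variable_spec <- function(name, type = c("climate", "soil"), mean = 0, sd = 1,
                          corr_range = 8, trend = NULL, units = "") {
  type <- match.arg(type)
  if (!is.null(trend)) stopifnot(is.numeric(trend$direction),
                                 is.numeric(trend$amplitude))
  list(name = name, type = type, mean = mean, sd = sd,
       corr_range = corr_range, trend = trend, units = units)
}

#' Species niche on environmental space
#'
#' True suitability is logistic-quadratic:
#' `s(x) = plogis(intercept - sum_v w_v ((x_v - opt_v) / tol_v)^2)`.
#'
#' @param responses named list, one entry per variable:
#'   `list(optimum =, tolerance =, weight =)` with `tolerance > 0`,
#'   `weight >= 0`.
#' @param intercept baseline log-odds at the optimum.
#' @return a `niche_spec` object.
#' @export
niche_spec <- function(responses, intercept = 2) {
  stopifnot(length(responses) >= 1L)
  w <- vapply(responses, `[[`, numeric(1), "weight")
  tl <- vapply(responses, `[[`, numeric(1), "tolerance")
  if (any(tl <= 0)) stop("tolerances must be > 0", call. = FALSE)
  if (any(w < 0) || !any(w > 0))
    stop("weights must be >= 0 with at least one > 0", call. = FALSE)
  structure(list(responses = responses, intercept = intercept),
            class = "niche_spec")
}

#' Future climate scenario as additive deltas
#'
#' Each climate variable gets `delta(cell) = mean + gradient * p(cell)` where
#' `p` is the centred projection of the cell position onto the compass
#' direction, scaled to `[-1/2, 1/2]` across the domain — so the delta
#' increases toward the stated direction and spans `gradient` units corner to
#' corner along it.
#'
#' @param label scenario name (e.g. `"ssp5"`).
#' @param deltas named list per climate variable:
#'   `list(mean =, direction =, gradient =)`; `direction` in degrees
#'   clockwise from north, `gradient` defaults to 0 (uniform shift).
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(label, deltas) {
  for (d in deltas) {
    dir <- d$direction
    if (!is.null(dir) && (dir < 0 || dir >= 360))
      stop("gradient direction must lie in [0, 360)", call. = FALSE)
  }
  structure(list(label = label, deltas = deltas), class = "scenario_spec")
}

# Dense Gaussian smoothing along both axes: row/column weight matrices with
# weights exp(-d^2 / (2 sigma^2)), row-normalized. Fine for desk-scale grids.
smooth_field <- function(noise, sigma) {
  if (sigma <= 0) return(noise)
  wmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    w <- exp(-d^2 / (2 * sigma^2))
    w / rowSums(w)
  }
  wmat(nrow(noise)) %*% noise %*% t(wmat(ncol(noise)))
}

gaussian_random_field <- function(n_rows, n_cols, sigma) {
  f <- smooth_field(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                    sigma)
  (f - mean(f)) / stats::sd(f)
}

# Projection of cell centres onto a compass bearing, scaled to [-1/2, 1/2].
bearing_projection <- function(n_rows, n_cols, direction) {
  theta <- direction * pi / 180
  # x east, y north; row 1 is northmost
  cx <- (seq_len(n_cols) - (n_cols + 1) / 2)
  cy <- -(seq_len(n_rows) - (n_rows + 1) / 2)
  p <- outer(cy * cos(theta), cx * sin(theta), "+")
  span <- max(p) - min(p)
  if (span == 0) p else (p - (max(p) + min(p)) / 2) / span
}

make_variable_field <- function(spec, n_rows, n_cols) {
  f <- gaussian_random_field(n_rows, n_cols, spec$corr_range) * spec$sd +
    spec$mean
  if (!is.null(spec$trend))
    f <- f + spec$trend$amplitude *
      bearing_projection(n_rows, n_cols, spec$trend$direction)
  f
}

#' Aggregate a fine grid to coarse blocks by the block mean
#'
#' @param grid a [grid_layer()] whose dimensions are divisible by `factor`.
#' @param factor integer block edge in fine cells.
#' @return a coarse [grid_layer()]; blocks containing any `NA` become `NA`.
#' @export
aggregate_blocks <- function(grid, factor) {
  factor <- as.integer(factor)
  m <- grid$values
  if (nrow(m) %% factor || ncol(m) %% factor)
    stop("grid dimensions are not divisible by the aggregation factor",
         call. = FALSE)
  nr <- nrow(m) %/% factor; nc <- ncol(m) %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- m[((i - 1L) * factor + 1L):(i * factor),
             ((j - 1L) * factor + 1L):(j * factor)]
    out[i, j] <- mean(blk)
  }
  grid_layer(grid$name, out, grid$origin_x, grid$origin_y,
             grid$cell_size * factor, grid$nodata, grid$units)
}

#' Default variable roster for synthetic landscapes
#'
#' Two temperature-like and two precipitation-like bioclim variables plus two
#' soil physicochemical variables, with magnitudes typical of humid tropical
#' coasts (annual mean temperature ~26 degC, annual precipitation ~4000 mm,
#' bulk density ~80 cg/cm3, silt ~300 g/kg).
#'
#' @return list of [variable_spec()]s.
#' @export
default_variables <- function() {
  list(
    variable_spec("bio1", "climate", mean = 26, sd = 0.5, corr_range = 8,
                  trend = list(direction = 45, amplitude = 5), units = "degC"),
    variable_spec("bio12", "climate", mean = 4000, sd = 300, corr_range = 10,
                  trend = list(direction = 225, amplitude = 2500), units = "mm"),
    variable_spec("bio8", "climate", mean = 25.5, sd = 0.35, corr_range = 8,
                  trend = list(direction = 135, amplitude = 4), units = "degC"),
    variable_spec("bio17", "climate", mean = 500, sd = 150, corr_range = 10,
                  units = "mm"),
    variable_spec("bdod", "soil", mean = 80, sd = 15, corr_range = 6,
                  units = "cg/cm3"),
    variable_spec("silt", "soil", mean = 300, sd = 60, corr_range = 6,
                  units = "g/kg"))
}

SOIL_DEPTHS <- cbind(top = c(0, 5, 15, 30, 60, 100),
                     bottom = c(5, 15, 30, 60, 100, 200))

#' Generate a synthetic study landscape
#'
#' Builds spatially autocorrelated environmental surfaces on a fine grid,
#' defines the coarse climate layers as exact block means of the fine truth
#' (so downscaling has a known target), generates soil variables as standard
#' depth-interval profiles, a DEM, a connected curvilinear water band, and a
#' zone partition. Deterministic for a fixed seed.
#'
#' @param n_rows,n_cols fine-grid dimensions (>= 16), divisible by
#'   `coarse_factor`.
#' @param cell_size fine cell size in metres (default 250).
#' @param variables list of [variable_spec()]s with at least two climate and
#'   two soil entries; default [default_variables()].
#' @param coarse_factor ratio of coarse to fine cell size (integer, default 4
#'   for 1 km over 250 m).
#' @param n_zones number of horizontal reporting zones.
#' @param seed RNG seed.
#' @return a `landscape` object: `$climate_fine` and `$climate_coarse`
#'   [raster_stack()]s, `$soil` (named list of `depth_profile`s), `$dem` and
#'   `$dem_coarse`, `$water` (binary mask), `$zones` (integer labels),
#'   `$study` (all-ones study mask), and the generating `$variables`/`$seed`.
#' @export
make_landscape <- function(n_rows = 48, n_cols = 48, cell_size = 250,
                           variables = default_variables(), coarse_factor = 4,
                           n_zones = 4, seed = 1) {
  if (n_rows < 16 || n_cols < 16)
    stop("landscape must be at least 16 x 16", call. = FALSE)
  if (coarse_factor != round(coarse_factor))
    stop("coarse/fine resolution ratio must be an integer", call. = FALSE)
  coarse_factor <- as.integer(coarse_factor)
  if (n_rows %% coarse_factor || n_cols %% coarse_factor)
    stop("grid dimensions must be divisible by coarse_factor", call. = FALSE)
  types <- vapply(variables, `[[`, character(1), "type")
  if (sum(types == "climate") < 2L || sum(types == "soil") < 2L)
    stop("need at least two climate and two soil variables", call. = FALSE)

  with_seed(seed, {
    gl <- function(name, m, units = "")
      grid_layer(name, m, 0, n_rows * cell_size, cell_size, units = units)

    clim <- list()
    for (v in variables[types == "climate"])
      clim[[v$name]] <- gl(v$name, make_variable_field(v, n_rows, n_cols),
                           v$units)
    climate_fine <- raster_stack(clim,
                                 types = stats::setNames(rep("climate", length(clim)),
                                                         names(clim)))
    climate_coarse <- raster_stack(lapply(clim, aggregate_blocks,
                                          factor = coarse_factor),
                                   types = climate_fine$types)

    soil <- list()
    for (v in variables[types == "soil"]) {
      base <- make_variable_field(v, n_rows, n_cols)
      layers <- vector("list", nrow(SOIL_DEPTHS))
      for (k in seq_len(nrow(SOIL_DEPTHS))) {
        mid <- mean(SOIL_DEPTHS[k, ])
        # gentle depth drift plus an independent small-scale perturbation
        lay <- base + 0.1 * v$sd * log1p(mid / 10) +
          0.2 * v$sd * gaussian_random_field(n_rows, n_cols, v$corr_range)
        layers[[k]] <- list(top = SOIL_DEPTHS[k, "top"],
                            bottom = SOIL_DEPTHS[k, "bottom"],
                            grid = gl(sprintf("%s_%d_%dcm", v$name,
                                              SOIL_DEPTHS[k, "top"],
                                              SOIL_DEPTHS[k, "bottom"]),
                                      lay, v$units))
      }
      soil[[v$name]] <- depth_profile(v$name, layers)
    }

    dem_f <- 40 * gaussian_random_field(n_rows, n_cols, 10) + 60 +
      100 * bearing_projection(n_rows, n_cols, 90)
    dem_f[dem_f < 0] <- 0
    dem <- gl("dem", dem_f, "m")

    # connected curvilinear water band crossing the domain west to east
    phase <- stats::runif(1, 0, 2 * pi)
    water_m <- matrix(0, n_rows, n_cols)
    path <- n_rows / 2 + 0.2 * n_rows *
      sin(2 * pi * seq_len(n_cols) / n_cols + phase)
    for (cc in seq_len(n_cols)) {
      rr <- round(path[cc]) + (-1L:1L)
      rr <- rr[rr >= 1 & rr <= n_rows]
      water_m[rr, cc] <- 1
    }
    water <- gl("water", water_m)

    zone_m <- matrix(rep(ceiling(seq_len(n_rows) / (n_rows / n_zones)),
                         n_cols), n_rows, n_cols)
    zones <- gl("zones", zone_m)
    study <- gl("study", matrix(1, n_rows, n_cols))

    structure(list(climate_fine = climate_fine,
                   climate_coarse = climate_coarse, soil = soil,
                   dem = dem, dem_coarse = aggregate_blocks(dem, coarse_factor),
                   water = water, zones = zones, study = study,
                   variables = variables, coarse_factor = coarse_factor,
                   seed = seed),
              class = "landscape")
  })
}

#' True suitability of a niche over a predictor stack
#'
#' @param stack [raster_stack()] containing every niche variable.
#' @param niche a [niche_spec()].
#' @return probability [grid_layer()] in `[0, 1]`; nodata propagates.
#' @export
true_suitability <- function(stack, niche) {
  missing <- setdiff(names(niche$responses), names(stack))
  if (length(missing))
    stop("niche variables absent from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- stack$layers[[1L]]
  lp <- matrix(niche$intercept, nrow(ref$values), ncol(ref$values))
  for (v in names(niche$responses)) {
    r <- niche$responses[[v]]
    lp <- lp - r$weight * ((stack[[v]]$values - r$optimum) / r$tolerance)^2
  }
  grid_layer("true_suitability", stats::plogis(lp), ref$origin_x,
             ref$origin_y, ref$cell_size)
}

#' Sample presence points from a suitability surface
#'
#' Draws `n` distinct cells without replacement with probability proportional
#' to suitability and places one presence at each cell centre.
#'
#' @param suitability [grid_layer()] with values in `[0, 1]`.
#' @param n number of presences (>= 1).
#' @param seed RNG seed.
#' @param species species name for the result.
#' @return an [occurrence_set()] of `n` presences.
#' @export
sample_occurrences <- function(suitability, n, seed = 1,
                               species = "synthetic") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  w <- as.vector(suitability$values)
  pos <- which(!is.na(w) & w > 0)
  if (n > length(pos))
    stop("n exceeds the ", length(pos), " cells with positive suitability",
         call. = FALSE)
  idx <- with_seed(seed, pos[sample.int(length(pos), n, prob = w[pos])])
  rows <- (idx - 1L) %% nrow(suitability$values) + 1L
  cols <- (idx - 1L) %/% nrow(suitability$values) + 1L
  ctr <- cell_center(suitability, rows, cols)
  occurrence_set(species, ctr[, "x"], ctr[, "y"], "presence")
}

#' Apply a climate scenario's additive deltas to a stack
#'
#' Shifts the named climate layers by the scenario's mean delta plus a planar
#' gradient oriented along the stated compass direction; all other layers are
#' untouched (soils are held fixed under future scenarios).
#'
#' @param stack a [raster_stack()] carrying layer `types`.
#' @param scenario a [scenario_spec()].
#' @return a new [raster_stack()] with shifted climate layers.
#' @export
apply_climate_delta <- function(stack, scenario) {
  layers <- stack$layers
  for (v in names(scenario$deltas)) {
    if (!v %in% names(layers))
      stop("scenario variable absent from stack: ", v, call. = FALSE)
    if (!is.null(stack$types) && !identical(unname(stack$types[v]), "climate"))
      stop("climate delta on non-climate layer: ", v, call. = FALSE)
    d <- scenario$deltas[[v]]
    g <- layers[[v]]
    delta <- matrix(d$mean %||% 0, nrow(g$values), ncol(g$values))
    grad <- d$gradient %||% 0
    if (grad != 0)
      delta <- delta + grad * bearing_projection(nrow(g$values),
                                                 ncol(g$values), d$direction)
    g$values <- g$values + delta
    layers[[v]] <- g
  }
  raster_stack(layers, types = stack$types)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Habitat-cover mask from a suitability surface
#'
#' Thresholds suitability at `level` and dilates by one cell
#' (8-neighbourhood) — the synthetic analogue of a mapped mangrove-cover
#' polygon enclosing the suitable habitat.
#'
#' @param suitability probability [grid_layer()].
#' @param level threshold (default 0.5).
#' @param dilate number of one-cell dilation passes.
#' @return binary [grid_layer()] (1 = cover).
#' @export
habitat_cover_mask <- function(suitability, level = 0.5, dilate = 1) {
  m <- (!is.na(suitability$values) & suitability$values >= level) * 1
  for (k in seq_len(dilate)) {
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      out <- pmax(out, m[rs, cs])
    }
    m <- out
  }
  g <- blank_like(suitability, "habitat_cover")
  g$values <- m
  g
}
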