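#' Single-layer raster grid
#'
#' A `grid_layer` is a named single-band raster on a regular planar grid in
#' projected metre coordinates. Values are stored as a numeric matrix whose
#' first row is the northmost row; missing cells are held as `NA` internally
#' and serialized with the `nodata` sentinel. The cell with (1-based) indices
#' `(r, c)` covers the half-open square
#' `[origin_x + (c-1)*cs, origin_x + c*cs) x (origin_y - r*cs, origin_y - (r-1)*cs]`
#' and its centre is at `(origin_x + (c-0.5)*cs, origin_y - (r-0.5)*cs)`.
#'
#' @param name layer name (unique within a stack).
#' @param values numeric matrix, rows north-to-south. `NA` marks nodata.
#' @param origin_x,origin_y projected coordinates (m) of the top-left corner
#'   of the top-left cell.
#' @param cell_size cell side length in metres (> 0).
#' @param nodata sentinel written to file for `NA` cells.
#' @param units free-text unit string carried as metadata.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(name, values, origin_x = 0, origin_y = NULL,
                       cell_size = 250, nodata = -9999, units = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one cell", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  if (is.null(origin_y)) origin_y <- nrow(values) * cell_size
  structure(
    list(name = as.character(name), values = values,
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata),
         units = as.character(units)),
    class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_layer '%s'> %d x %d @ %gm, origin (%g, %g)\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_x, x$origin_y))
  if (length(v))
    cat(sprintf("  values: [%g, %g], nodata cells: %d%s\n",
                min(v), max(v), sum(is.na(x$values)),
                if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  else cat("  all nodata\n")
  invisible(x)
}

#' Coordinates of cell centres
#'
#' @param grid a `grid_layer`.
#' @param rows,cols 1-based row/column indices (vectorized).
#' @return two-column matrix of `x`, `y` centre coordinates in metres.
#' @export
cell_center <- function(grid, rows, cols) {
  cbind(x = grid$origin_x + (cols - 0.5) * grid$cell_size,
        y = grid$origin_y - (rows - 0.5) * grid$cell_size)
}

#' Cell indices containing points
#'
#' Maps planar coordinates to 1-based `(row, col)` indices under the half-open
#' pixel model; points outside the extent give `NA`.
#'
#' @param grid a `grid_layer`.
#' @param x,y point coordinates in metres (vectorized).
#' @return two-column integer matrix `row`, `col`.
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  # top edge belongs to row 1 (y interval is half-open at the bottom)
  row[!is.na(y) & y == grid$origin_y] <- 1L
  bad <- is.na(row) | is.na(col) |
    row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Look up grid values at point coordinates
#'
#' @inheritParams cell_index
#' @return numeric vector of cell values (`NA` outside the extent or on
#'   nodata cells).
#' @export
grid_extract <- function(grid, x, y) {
  idx <- cell_index(grid, x, y)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx[, 1L])
  out[ok] <- grid$values[cbind(idx[ok, 1L], idx[ok, 2L])]
  out
}

same_geometry <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$origin_x - b$origin_x) <= tol && abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol
}

#' Stack of co-registered raster layers
#'
#' @param layers list of `grid_layer` objects sharing one geometry; names are
#'   taken from the layers and must be unique.
#' @param types optional named character vector tagging layers as
#'   `"climate"`, `"soil"`, `"terrain"`, `"mask"`, or `"biotic"`; used by the
#'   scenario machinery to refuse climate deltas on non-climate layers.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers, types = NULL) {
  if (!length(layers)) stop("empty stack", call. = FALSE)
  stopifnot(all(vapply(layers, inherits, logical(1), "grid_layer")))
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate layer names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(layers) <- nms
  for (l in layers[-1L])
    if (!same_geometry(layers[[1L]], l))
      stop("layers are not co-registered: ", l$name, call. = FALSE)
  structure(list(layers = layers, types = types), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  g <- x$layers[[1L]]
  cat(sprintf("<raster_stack> %d layers, %d x %d @ %gm\n  %s\n",
              length(x$layers), nrow(g$values), ncol(g$values), g$cell_size,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
`[[.raster_stack` <- function(x, i) x$layers[[i]]

#' @export
names.raster_stack <- function(x) names(x$layers)

#' @export
length.raster_stack <- function(x) length(x$layers)

#' Check that all layers of a stack share one geometry
#'
#' Returns a boolean rather than throwing so callers can decide how to react;
#' only an empty stack is an error.
#'
#' @param stack a `raster_stack`, or a bare list of `grid_layer`s.
#' @return `TRUE` iff every layer shares shape, origin and cell size.
#' @export
check_coregistered <- function(stack) {
  layers <- if (inherits(stack, "raster_stack")) stack$layers else stack
  if (!length(layers)) stop("empty stack", call. = FALSE)
  ref <- layers[[1L]]
  all(vapply(layers, same_geometry, logical(1), a = ref))
}

#' Convert a stack to a per-cell feature matrix
#'
#' @param stack a `raster_stack`.
#' @return numeric matrix with one row per cell (row-major over the grid) and
#'   one column per layer.
#' @keywords internal
stack_as_matrix <- function(stack) {
  vapply(stack$layers, function(l) as.vector(l$values),
         numeric(length(stack$layers[[1L]]$values)))
}

#' Template grid (geometry without values) from a stack or grid
#' @keywords internal
blank_like <- function(grid, name = grid$name, fill = NA_real_) {
  g <- grid
  g$name <- name
  g$values <- matrix(fill, nrow(grid$values), ncol(grid$values))
  g
}
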