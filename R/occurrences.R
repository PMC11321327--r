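#' Presence / pseudo-absence point set
#'
#' @param species species name.
#' @param x,y projected point coordinates in metres.
#' @param label `"presence"` or `"pseudo_absence"` per record (recycled).
#' @return an object of class `occurrence_set` with a `species` field and a
#'   `records` data frame (`x`, `y`, `label`).
#' @export
occurrence_set <- function(species, x = numeric(0), y = numeric(0),
                           label = "presence") {
  stopifnot(length(x) == length(y))
  label <- rep_len(as.character(label), length(x))
  if (length(label) && !all(label %in% c("presence", "pseudo_absence")))
    stop("labels must be 'presence' or 'pseudo_absence'", call. = FALSE)
  structure(list(species = as.character(species),
                 records = data.frame(x = as.numeric(x), y = as.numeric(y),
                                      label = label,
                                      stringsAsFactors = FALSE)),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set '%s'> %d presences, %d pseudo-absences\n",
              x$species, sum(x$records$label == "presence"),
              sum(x$records$label == "pseudo_absence")))
  invisible(x)
}

#' Number of records
#' @param occ an `occurrence_set`.
#' @return integer record count.
#' @export
n_records <- function(occ) nrow(occ$records)

#' Read and filter an occurrence table
#'
#' Reads a delimited table with columns `species`, `x`, `y` (and optionally
#' `label`) and applies the standard cleaning rules for presence-only
#' occurrence data: rows with missing coordinates are dropped, exact
#' coordinate duplicates are collapsed to the first record, and rows outside
#' the study extent are dropped. Survivors keep their label (default
#' presence). Per-cell thinning is a separate later step
#' ([thin_occurrences()]).
#'
#' @param path CSV path with header `species,x,y[,label]`.
#' @param species species to extract (rows for other species are ignored).
#' @param extent study extent as a [grid_layer()] or a list with `xmin`,
#'   `xmax`, `ymin`, `ymax`; `NULL` skips the extent filter.
#' @return an `occurrence_set`.
#' @export
read_occurrences <- function(path, species, extent = NULL) {
  if (!file.exists(path)) stop("cannot read occurrences: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y")
  if (!all(need %in% names(tab)))
    stop("occurrence table must have columns species, x, y", call. = FALSE)
  tab <- tab[tab$species == species, , drop = FALSE]
  tab <- tab[!is.na(tab$x) & !is.na(tab$y), , drop = FALSE]
  tab <- tab[!duplicated(tab[, c("x", "y")]), , drop = FALSE]
  if (!is.null(extent)) {
    if (inherits(extent, "grid_layer"))
      extent <- list(xmin = extent$origin_x,
                     xmax = extent$origin_x + ncol(extent$values) * extent$cell_size,
                     ymin = extent$origin_y - nrow(extent$values) * extent$cell_size,
                     ymax = extent$origin_y)
    keep <- tab$x >= extent$xmin & tab$x < extent$xmax &
      tab$y > extent$ymin & tab$y <= extent$ymax
    tab <- tab[keep, , drop = FALSE]
  }
  lab <- if ("label" %in% names(tab)) tab$label else "presence"
  occurrence_set(species, tab$x, tab$y, lab)
}

#' Write an occurrence set as CSV
#'
#' @param occ an `occurrence_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  out <- cbind(species = occ$species, occ$records)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
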