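# Surface Range Envelope (SRE) classification and three-criterion
# pseudo-absence sampling: 1:1 with presences, outside the habitat-cover
# mask, and inside the SRE-unsuitable zone.

#' Fit a surface range envelope to presence records
#'
#' For each predictor layer the envelope bounds are the `q` and `1 - q`
#' empirical quantiles (linear interpolation between order statistics) of the
#' values at presence cells; `q = 0.025` keeps the central 95% of the
#' presence distribution per variable. Presences falling on nodata cells are
#' skipped with a warning.
#'
#' @param presences [occurrence_set()]; pseudo-absence records are ignored.
#' @param stack predictor [raster_stack()].
#' @param q quantile in `(0, 0.5)`; `q = 0` uses the presence min/max.
#' @return an `sre_envelope` object: per-variable `lower`/`upper` bounds.
#' @export
fit_sre <- function(presences, stack, q = 0.025) {
  if (q < 0 || q >= 0.5) stop("q must lie in [0, 0.5)", call. = FALSE)
  pres <- presences$records[presences$records$label == "presence", ]
  if (nrow(pres) < 5L) stop("need at least 5 presences", call. = FALSE)
  bounds <- list()
  for (nm in names(stack)) {
    v <- grid_extract(stack[[nm]], pres$x, pres$y)
    n_bad <- sum(is.na(v))
    if (n_bad) {
      warning(n_bad, " presence(s) on nodata cells skipped for ", nm,
              call. = FALSE)
      v <- v[!is.na(v)]
    }
    if (!length(v)) stop("all presences fall on nodata for ", nm,
                         call. = FALSE)
    qs <- stats::quantile(v, c(q, 1 - q), type = 7, names = FALSE)
    bounds[[nm]] <- c(lower = qs[1L], upper = qs[2L])
  }
  structure(list(q = q, bounds = bounds), class = "sre_envelope")
}

#' @export
print.sre_envelope <- function(x, ...) {
  cat(sprintf("<sre_envelope> q = %g, %d variables\n", x$q, length(x$bounds)))
  for (nm in names(x$bounds))
    cat(sprintf("  %s: [%.4g, %.4g]\n", nm, x$bounds[[nm]]["lower"],
                x$bounds[[nm]]["upper"]))
  invisible(x)
}

#' Classify a study area with a fitted envelope
#'
#' A cell is suitable (1) iff every envelope variable lies within its
#' `[lower, upper]` bounds; nodata in any layer propagates.
#'
#' @param env an `sre_envelope` from [fit_sre()].
#' @param stack predictor [raster_stack()] containing every envelope
#'   variable.
#' @return binary [grid_layer()] (1 = environmentally suitable).
#' @export
classify_sre <- function(env, stack) {
  missing <- setdiff(names(env$bounds), names(stack))
  if (length(missing))
    stop("envelope variables absent from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- stack$layers[[1L]]
  inside <- matrix(TRUE, nrow(ref$values), ncol(ref$values))
  bad <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (nm in names(env$bounds)) {
    v <- stack[[nm]]$values
    bad <- bad | is.na(v)
    b <- env$bounds[[nm]]
    inside <- inside & !is.na(v) & v >= b["lower"] & v <= b["upper"]
  }
  g <- blank_like(ref, "sre_suitable")
  g$values <- inside * 1
  g$values[bad] <- NA_real_
  g
}

#' Draw pseudo-absences under the three-criterion design
#'
#' Samples exactly as many pseudo-absences as there are presences (1:1),
#' uniformly without replacement from cells that are (a) inside the study
#' mask, (b) outside the habitat-cover mask, (c) SRE-unsuitable, and (d) not
#' occupied by a presence. Points are placed at cell centres.
#'
#' @param presences [occurrence_set()] of presences.
#' @param sre_map binary suitability map from [classify_sre()].
#' @param habitat_mask binary habitat-cover [grid_layer()] (1 = cover) or
#'   `NULL` to skip the cover exclusion.
#' @param study_mask binary study-area [grid_layer()] or `NULL` for the whole
#'   grid.
#' @param seed RNG seed; sampling is deterministic per seed.
#' @return [occurrence_set()] combining the presences with the sampled
#'   pseudo-absences.
#' @export
sample_pseudo_absences <- function(presences, sre_map, habitat_mask = NULL,
                                   study_mask = NULL, seed = 1) {
  pres <- presences$records[presences$records$label == "presence", ]
  n <- nrow(pres)
  if (!n) stop("no presence records", call. = FALSE)
  candidate <- !is.na(sre_map$values) & sre_map$values == 0
  if (!is.null(habitat_mask))
    candidate <- candidate & !is.na(habitat_mask$values) &
      habitat_mask$values == 0
  if (!is.null(study_mask))
    candidate <- candidate & !is.na(study_mask$values) &
      study_mask$values == 1
  pidx <- cell_index(sre_map, pres$x, pres$y)
  pok <- !is.na(pidx[, 1L])
  candidate[cbind(pidx[pok, 1L], pidx[pok, 2L])] <- FALSE
  pool <- which(candidate)
  if (length(pool) < n)
    stop("pseudo-absence pool (", length(pool),
         " cells) is smaller than the ", n, " presences", call. = FALSE)
  chosen <- with_seed(seed, if (length(pool) == n) pool
                            else sort(sample(pool, n)))
  rows <- (chosen - 1L) %% nrow(sre_map$values) + 1L
  cols <- (chosen - 1L) %/% nrow(sre_map$values) + 1L
  ctr <- cell_center(sre_map, rows, cols)
  occurrence_set(presences$species,
                 c(pres$x, ctr[, "x"]), c(pres$y, ctr[, "y"]),
                 c(rep("presence", n), rep("pseudo_absence", n)))
}
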