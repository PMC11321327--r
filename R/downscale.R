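# Regression-kriging downscaling of coarse climate layers to the fine grid,
# with elevation as the regression covariate and a held-out validation split.

#' Convert a raster layer to point samples
#'
#' One point per non-nodata cell, located at the cell centre and carrying the
#' cell value; optionally annotated with a covariate layer's value at the
#' same cell.
#'
#' @param grid a [grid_layer()].
#' @param covariate optional co-registered covariate layer (e.g. a DEM).
#' @return data frame with columns `x`, `y`, `value` and (if requested)
#'   `covariate`.
#' @export
raster_to_points <- function(grid, covariate = NULL) {
  keep <- which(!is.na(grid$values))
  if (!length(keep)) stop("grid is all nodata", call. = FALSE)
  rows <- (keep - 1L) %% nrow(grid$values) + 1L
  cols <- (keep - 1L) %/% nrow(grid$values) + 1L
  ctr <- cell_center(grid, rows, cols)
  out <- data.frame(x = ctr[, "x"], y = ctr[, "y"],
                    value = grid$values[keep])
  if (!is.null(covariate)) {
    if (!same_geometry(grid, covariate))
      stop("covariate is not co-registered with the grid", call. = FALSE)
    out$covariate <- covariate$values[keep]
  }
  out
}

#' Random train/test split of point samples
#'
#' @param points data frame of point samples.
#' @param train_fraction fraction assigned to training (default 0.7);
#'   `|train| = round(f * n)`.
#' @param seed RNG seed; the split is deterministic per seed.
#' @return list with `train` and `test` data frames (disjoint, exhaustive).
#' @export
split_points <- function(points, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  n <- nrow(points)
  if (n < 10) stop("need at least 10 points to split", call. = FALSE)
  n_train <- round(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = points[idx, , drop = FALSE],
       test = points[-idx, , drop = FALSE])
}

#' Empirical semivariogram
#'
#' @param points data frame with `x`, `y` and a `resid` (or `value`) column.
#' @param n_bins number of lag bins (default 12).
#' @param max_lag maximum lag; default half the domain diagonal.
#' @return data frame `lag` (mean pair distance per bin), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(points, n_bins = 12, max_lag = NULL) {
  z <- if ("resid" %in% names(points)) points$resid else points$value
  d <- as.matrix(stats::dist(points[, c("x", "y")]))
  iu <- upper.tri(d)
  h <- d[iu]
  g <- 0.5 * outer(z, z, "-")[iu]^2
  if (is.null(max_lag))
    max_lag <- 0.5 * sqrt(diff(range(points$x))^2 + diff(range(points$y))^2)
  keep <- h > 0 & h <= max_lag
  h <- h[keep]; g <- g[keep]
  bin <- cut(h, breaks = seq(0, max_lag, length.out = n_bins + 1L),
             include.lowest = TRUE)
  out <- data.frame(
    lag = as.numeric(tapply(h, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean)),
    n_pairs = as.integer(tapply(g, bin, length)))
  out[!is.na(out$gamma), , drop = FALSE]
}

vgm_gamma <- function(family, nugget, psill, range) {
  force(nugget); force(psill); force(range)
  base <- switch(family,
    exponential = function(h) 1 - exp(-h / range),
    spherical = function(h) ifelse(h >= range, 1,
                                   1.5 * h / range - 0.5 * (h / range)^3),
    gaussian = function(h) 1 - exp(-(h / range)^2),
    stop("unknown variogram family: ", family, call. = FALSE))
  function(h) ifelse(h == 0, 0, nugget + psill * base(h))
}

#' Fit a variogram model by weighted least squares
#'
#' Weights are proportional to per-bin pair counts.
#'
#' @param emp empirical variogram from [empirical_variogram()].
#' @param family `"exponential"` (default), `"spherical"` or `"gaussian"`.
#' @return list `family`, `nugget`, `psill`, `range`.
#' @export
fit_variogram <- function(emp, family = "exponential") {
  if (nrow(emp) < 3L) stop("too few variogram bins to fit", call. = FALSE)
  sill0 <- max(emp$gamma)
  if (sill0 <= 0)            # flat field: residuals carry no variance
    return(list(family = family, nugget = 0, psill = 0,
                range = max(emp$lag) / 3))
  obj <- function(p) {
    gfun <- vgm_gamma(family, p[1L], p[2L], p[3L])
    sum(emp$n_pairs * (gfun(emp$lag) - emp$gamma)^2)
  }
  # the range is not identifiable beyond the observed lags; cap it there
  init <- c(max(min(emp$gamma), 0) / 2, sill0, max(emp$lag) / 3)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 0, max(emp$lag) * 1e-3),
                      upper = c(sill0, 10 * sill0, 2 * max(emp$lag)))
  list(family = family, nugget = fit$par[1L], psill = fit$par[2L],
       range = fit$par[3L])
}

#' Fit a regression-kriging model on training points
#'
#' Ordinary least squares of the value on the covariate (elevation) when
#' `use_covariate` is `TRUE`, followed by an empirical semivariogram of the
#' residuals and a weighted-least-squares variogram fit. With
#' `use_covariate = FALSE` the model degenerates to ordinary kriging of the
#' raw values.
#'
#' @param train training points from [split_points()]; needs a `covariate`
#'   column when `use_covariate` is `TRUE`.
#' @param use_covariate include the linear trend on the covariate?
#' @param family variogram family passed to [fit_variogram()].
#' @param n_bins lag bins for the empirical variogram (>= 8).
#' @return a `kriging_model` object.
#' @export
fit_regression_kriging <- function(train, use_covariate = TRUE,
                                   family = "exponential", n_bins = 12) {
  if (nrow(train) < 10) stop("need at least 10 training points", call. = FALSE)
  if (use_covariate) {
    if (is.null(train$covariate))
      stop("training points carry no covariate", call. = FALSE)
    if (stats::sd(train$covariate) == 0)
      stop("covariate is constant; refit with use_covariate = FALSE",
           call. = FALSE)
    lmfit <- stats::lm(value ~ covariate, data = train)
    regression <- stats::coef(lmfit)
    train$resid <- stats::resid(lmfit)
  } else {
    regression <- NULL
    train$resid <- train$value
  }
  emp <- empirical_variogram(train, n_bins = n_bins)
  structure(list(regression = regression,
                 variogram = fit_variogram(emp, family),
                 empirical = emp, train = train),
            class = "kriging_model")
}

#' @export
print.kriging_model <- function(x, ...) {
  v <- x$variogram
  cat(sprintf("<kriging_model> %s trend, %s variogram (nugget %.4g, psill %.4g, range %.4g), %d points\n",
              if (is.null(x$regression)) "no" else "covariate",
              v$family, v$nugget, v$psill, v$range, nrow(x$train)))
  invisible(x)
}

# Ordinary-kriging weights for one target from its neighbours' coordinates.
ok_weights <- function(gfun, coords, px, py) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  A <- rbind(cbind(gfun(d), 1), c(rep(1, n), 0))
  h0 <- sqrt((coords[, 1L] - px)^2 + (coords[, 2L] - py)^2)
  b <- c(gfun(h0), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) rep(1 / n, n) else sol[seq_len(n)]
}

predict_points <- function(model, x, y, covariate = NULL,
                           n_neighbors = 32L) {
  v <- model$variogram
  gfun <- vgm_gamma(v$family, v$nugget, v$psill, v$range)
  flat <- (v$nugget + v$psill) < 1e-12
  tx <- model$train$x; ty <- model$train$y; tz <- model$train$resid
  n_nb <- min(n_neighbors, length(tx))
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    d2 <- (tx - x[i])^2 + (ty - y[i])^2
    nb <- order(d2)[seq_len(n_nb)]
    w <- if (flat) rep(1 / n_nb, n_nb)
         else ok_weights(gfun, cbind(tx[nb], ty[nb]), x[i], y[i])
    out[i] <- sum(w * tz[nb])
  }
  if (!is.null(model$regression)) {
    if (is.null(covariate))
      stop("model has a covariate trend but no covariate was supplied",
           call. = FALSE)
    out <- out + model$regression[1L] + model$regression[2L] * covariate
  }
  out
}

#' Predict a fine-resolution layer from a kriging model
#'
#' Cellwise prediction = regression trend at the cell's covariate value plus
#' the ordinary-kriged residual from the nearest training points. With a zero
#' nugget the surface interpolates the training values exactly.
#'
#' @param model a `kriging_model`.
#' @param fine_template [grid_layer()] defining the output geometry; its
#'   nodata cells stay nodata.
#' @param covariate_fine co-registered covariate layer at fine resolution
#'   (required when the model has a regression part); covariate nodata gives
#'   nodata output.
#' @param n_neighbors kriging neighbourhood size (default 32).
#' @param name output layer name.
#' @return a fine-resolution [grid_layer()].
#' @export
predict_fine <- function(model, fine_template, covariate_fine = NULL,
                         n_neighbors = 32L, name = "downscaled") {
  if (!is.null(covariate_fine) && !same_geometry(fine_template, covariate_fine))
    stop("template and covariate are not co-registered", call. = FALSE)
  ok <- !is.na(fine_template$values)
  if (!is.null(model$regression)) {
    if (is.null(covariate_fine))
      stop("model has a covariate trend but no covariate layer was supplied",
           call. = FALSE)
    ok <- ok & !is.na(covariate_fine$values)
  }
  keep <- which(ok)
  rows <- (keep - 1L) %% nrow(fine_template$values) + 1L
  cols <- (keep - 1L) %/% nrow(fine_template$values) + 1L
  ctr <- cell_center(fine_template, rows, cols)
  cov <- if (is.null(model$regression)) NULL else covariate_fine$values[keep]
  pred <- predict_points(model, ctr[, "x"], ctr[, "y"], cov, n_neighbors)
  g <- blank_like(fine_template, name)
  g$values[keep] <- pred
  g
}

#' Validate downscaling predictions on held-out points
#'
#' @param model a `kriging_model`.
#' @param test held-out points from [split_points()].
#' @param n_neighbors kriging neighbourhood size.
#' @return list `mae`, `rmse`, `r_squared`, `n_test`; R-squared is
#'   `1 - SS_res / SS_tot` about the test mean.
#' @export
validate_downscaling <- function(model, test, n_neighbors = 32L) {
  if (!nrow(test)) stop("test set is empty", call. = FALSE)
  if (stats::var(test$value) == 0)
    stop("test values have zero variance; R-squared is undefined",
         call. = FALSE)
  pred <- predict_points(model, test$x, test$y, test$covariate, n_neighbors)
  err <- test$value - pred
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
       r_squared = 1 - sum(err^2) / sum((test$value - mean(test$value))^2),
       n_test = nrow(test))
}

#' Downscale one coarse climate layer to the fine grid
#'
#' Convenience wrapper over the four-step procedure: raster to points, 70/30
#' split, regression-kriging fit (elevation covariate for temperature-type
#' variables), fine-grid prediction, and held-out validation.
#'
#' @param coarse coarse [grid_layer()].
#' @param dem_coarse co-registered coarse DEM (covariate source).
#' @param fine_template fine-geometry [grid_layer()].
#' @param dem_fine fine DEM for the trend surface.
#' @param use_covariate use the elevation regressor?
#' @param train_fraction,seed split parameters.
#' @param n_neighbors kriging neighbourhood size.
#' @return list `layer` (fine [grid_layer()]), `model`, `validation`.
#' @export
downscale_layer <- function(coarse, dem_coarse, fine_template, dem_fine,
                            use_covariate = TRUE, train_fraction = 0.7,
                            seed = 1, n_neighbors = 32L) {
  pts <- raster_to_points(coarse, covariate = dem_coarse)
  parts <- split_points(pts, train_fraction, seed)
  model <- fit_regression_kriging(parts$train, use_covariate = use_covariate)
  layer <- predict_fine(model, fine_template,
                        covariate_fine = if (use_covariate) dem_fine,
                        n_neighbors = n_neighbors, name = coarse$name)
  list(layer = layer, model = model,
       validation = validate_downscaling(model, parts$test, n_neighbors))
}
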