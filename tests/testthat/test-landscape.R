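test_that("landscape generation is deterministic per seed", {
  a <- make_landscape(n_rows = 24, n_cols = 24, seed = 7)
  b <- make_landscape(n_rows = 24, n_cols = 24, seed = 7)
  expect_identical(a$climate_fine[["bio1"]]$values,
                   b$climate_fine[["bio1"]]$values)
  expect_identical(a$soil[["bdod"]]$layers[[3]]$grid$values,
                   b$soil[["bdod"]]$layers[[3]]$grid$values)
  expect_identical(a$water$values, b$water$values)
  c_ <- make_landscape(n_rows = 24, n_cols = 24, seed = 8)
  expect_false(identical(a$climate_fine[["bio1"]]$values,
                         c_$climate_fine[["bio1"]]$values))
})

test_that("coarse climate layers are exact block means of the fine truth", {
  land <- make_landscape(n_rows = 32, n_cols = 32, coarse_factor = 4,
                         seed = 3)
  for (nm in names(land$climate_fine)) {
    agg <- aggregate_blocks(land$climate_fine[[nm]], 4)
    expect_lt(max(abs(agg$values - land$climate_coarse[[nm]]$values)), 1e-9)
  }
  expect_equal(land$climate_coarse[["bio1"]]$cell_size, 1000)
})

test_that("invalid geometry requests are refused", {
  expect_error(make_landscape(n_rows = 8, n_cols = 8), "16")
  expect_error(make_landscape(coarse_factor = 2.5), "integer")
  expect_error(make_landscape(n_rows = 18, n_cols = 48, coarse_factor = 4),
               "divisible")
})

test_that("generated fields are spatially autocorrelated", {
  land <- make_landscape(seed = 5)
  pts <- raster_to_points(land$climate_fine[["bio8"]])
  emp <- empirical_variogram(pts, n_bins = 10)
  # semivariance rises with lag over the first bins
  expect_gt(stats::cor(seq_len(5), emp$gamma[1:5], method = "spearman"), 0.8)
  expect_gt(emp$gamma[5], emp$gamma[1])
})

test_that("the water band is connected and curvilinear", {
  land <- make_landscape(seed = 2)
  w <- land$water$values
  expect_setequal(unique(as.vector(w)), c(0, 1))
  expect_true(all(colSums(w) >= 1))       # crosses every column
  expect_gt(length(unique(apply(w, 2, which.max))), 3)  # not a straight line
})

test_that("true suitability matches the logistic-quadratic closed form", {
  g1 <- tiny_grid(matrix(5, 2, 2), name = "v1")
  g2 <- tiny_grid(matrix(7, 2, 2), name = "v2")
  stack <- raster_stack(list(g1, g2))
  niche <- niche_spec(list(v1 = list(optimum = 5, tolerance = 1, weight = 1),
                           v2 = list(optimum = 7, tolerance = 2, weight = 3)),
                      intercept = 2)
  s <- true_suitability(stack, niche)
  expect_equal(s$values[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)

  # zero weights on all variables must be rejected by the constructor
  expect_error(niche_spec(list(v1 = list(optimum = 0, tolerance = 1,
                                         weight = 0))), "at least one")
  # a weightless variable leaves a 0.5 map at intercept 0
  niche0 <- niche_spec(list(v1 = list(optimum = 0, tolerance = 1, weight = 0),
                            v2 = list(optimum = 7, tolerance = 2, weight = 1)),
                       intercept = 0)
  s0 <- true_suitability(stack, niche0)
  expect_equal(as.vector(s0$values), rep(0.5, 4))
})

test_that("suitability values agree with independent cellwise evaluation", {
  land <- make_landscape(n_rows = 16, n_cols = 16, seed = 9)
  niche <- habitat_niche()
  s <- true_suitability(land$climate_fine, niche)
  set.seed(1)
  for (i in sample(16, 5)) {
    j <- sample(16, 1)
    lp <- 3
    for (v in names(niche$responses)) {
      r <- niche$responses[[v]]
      lp <- lp - r$weight *
        ((land$climate_fine[[v]]$values[i, j] - r$optimum) / r$tolerance)^2
    }
    expect_equal(s$values[i, j], 1 / (1 + exp(-lp)), tolerance = 1e-12)
  }
  # missing niche variable is a configuration error
  expect_error(true_suitability(land$climate_fine,
                                niche_spec(list(absent = list(optimum = 0,
                                                              tolerance = 1,
                                                              weight = 1)))),
               "absent")
})

test_that("occurrence sampling honours forced support and feasibility", {
  m <- matrix(0, 5, 5); m[c(3, 9, 17)] <- 1
  suit <- tiny_grid(m, name = "s")
  occ <- sample_occurrences(suit, 3, seed = 1)
  idx <- cell_index(suit, occ$records$x, occ$records$y)
  expect_setequal((idx[, "col"] - 1) * 5 + idx[, "row"], c(3, 9, 17))
  expect_error(sample_occurrences(suit, 0), ">= 1")
  expect_error(sample_occurrences(suit, 4), "positive suitability")
})

test_that("sampling weights follow suitability (Monte-Carlo)", {
  suit <- tiny_grid(matrix(c(0.9, 0.1), 1, 2), name = "s")
  hits <- vapply(1:2000, function(s) {
    occ <- sample_occurrences(suit, 1, seed = s)
    cell_index(suit, occ$records$x, occ$records$y)[1, "col"] == 1
  }, logical(1))
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 0.92)
})

test_that("presence density tracks true suitability", {
  rhos <- vapply(1:20, function(s) {
    land <- make_landscape(n_rows = 32, n_cols = 32, seed = s)
    truth <- true_suitability(land$climate_fine, habitat_niche())
    occ <- sample_occurrences(truth, 500, seed = s + 100)
    idx <- cell_index(truth, occ$records$x, occ$records$y)
    counts <- matrix(0, 32, 32)
    for (k in seq_len(nrow(idx)))
      counts[idx[k, "row"], idx[k, "col"]] <-
        counts[idx[k, "row"], idx[k, "col"]] + 1
    dec <- cut(as.vector(truth$values), stats::quantile(truth$values,
               0:10 / 10), include.lowest = TRUE, labels = FALSE)
    stats::cor(tapply(as.vector(counts), dec, mean), 1:10,
               method = "spearman")
  }, numeric(1))
  expect_gt(stats::median(rhos), 0.5)
  expect_gt(min(rhos), 0.3)
})

test_that("climate deltas shift the named layers and only those", {
  land <- make_landscape(n_rows = 16, n_cols = 16, seed = 4)
  stack <- land$climate_fine
  # zero delta is the identity
  z <- apply_climate_delta(stack, scenario_spec("none",
                                                list(bio1 = list(mean = 0))))
  expect_identical(z[["bio1"]]$values, stack[["bio1"]]$values)
  # uniform +2 on a temperature layer
  w <- apply_climate_delta(stack, scenario_spec("warm",
                                                list(bio1 = list(mean = 2))))
  expect_equal(w[["bio1"]]$values, stack[["bio1"]]$values + 2)
  expect_identical(w[["bio12"]]$values, stack[["bio12"]]$values)
})

test_that("gradient deltas increase toward the stated bearing", {
  land <- make_landscape(n_rows = 16, n_cols = 16, seed = 4)
  sw <- apply_climate_delta(land$climate_fine,
          scenario_spec("sw", list(bio1 = list(mean = 0, gradient = 2,
                                               direction = 225))))
  delta <- sw[["bio1"]]$values - land$climate_fine[["bio1"]]$values
  # delta grows southward (down rows) and westward (down columns)
  expect_true(all(diff(delta[, 1]) > 0))
  expect_true(all(diff(delta[1, ]) < 0))
  expect_equal(max(delta) - min(delta), 2, tolerance = 1e-9)
})

test_that("deltas on non-climate layers are refused", {
  land <- make_landscape(n_rows = 16, n_cols = 16, seed = 4)
  stack <- raster_stack(c(land$climate_fine$layers, list(dem = land$dem)),
                        types = c(land$climate_fine$types, dem = "terrain"))
  expect_error(apply_climate_delta(stack, scenario_spec("bad",
                 list(dem = list(mean = 5)))), "non-climate")
  expect_error(apply_climate_delta(stack, scenario_spec("bad",
                 list(bio99 = list(mean = 5)))), "absent")
  expect_error(scenario_spec("bad", list(bio1 = list(mean = 1,
                 direction = 380))), "direction")
})

test_that("the designed scenario displaces the true suitable area southwest", {
  bearings <- vapply(1:20, function(s) {
    land <- make_landscape(seed = s)
    cur <- true_suitability(land$climate_fine, habitat_niche())
    fut <- true_suitability(apply_climate_delta(land$climate_fine,
                                                pessimistic_scenario()),
                            habitat_niche())
    centroid_shift(binarize(cur, 0.5), binarize(fut, 0.5))$bearing
  }, numeric(1))
  expect_gte(sum(bearings >= 202.5 & bearings <= 247.5), 18)
})

test_that("habitat cover mask contains the suitable core plus a one-cell rim", {
  land <- make_landscape(n_rows = 24, n_cols = 24, seed = 6)
  truth <- true_suitability(land$climate_fine, habitat_niche())
  mask <- habitat_cover_mask(truth)
  core <- truth$values >= 0.5
  expect_true(all(mask$values[core] == 1))
  expect_gt(sum(mask$values), sum(core))   # dilation adds the rim
})
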