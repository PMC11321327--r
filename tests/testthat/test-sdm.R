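toy_dataset <- function(n = 60, seed = 31, sep = 3) {
  # linearly separable-ish two-feature toy
  set.seed(seed)
  x1 <- c(rnorm(n / 2, 0), rnorm(n / 2, sep))
  x2 <- c(rnorm(n / 2, 0), rnorm(n / 2, sep))
  structure(list(features = data.frame(v1 = x1, v2 = x2),
                 labels = rep(c(0L, 1L), each = n / 2),
                 xy = cbind(x = seq_len(n), y = seq_len(n)),
                 species = "toy"), class = "pa_dataset")
}

test_that("training tables carry per-cell feature lookups", {
  land <- make_landscape(n_rows = 16, n_cols = 16, seed = 31)
  truth <- true_suitability(land$climate_fine, habitat_niche())
  occ <- sample_occurrences(truth, 30, seed = 32)
  sre_map <- classify_sre(fit_sre(occ, land$climate_fine, 0.025),
                          land$climate_fine)
  pa <- sample_pseudo_absences(occ, sre_map, seed = 33)
  ds <- extract_training_table(land$climate_fine, pa)
  expect_equal(nrow(ds$features), 60)
  expect_equal(sum(ds$labels), 30)
  set.seed(34)
  for (k in sample(60, 20)) {
    for (nm in names(land$climate_fine))
      expect_equal(ds$features[k, nm],
                   grid_extract(land$climate_fine[[nm]],
                                ds$xy[k, "x"], ds$xy[k, "y"]))
  }
})

test_that("records on nodata cells are dropped with a warning", {
  land <- make_landscape(n_rows = 16, n_cols = 16, seed = 35)
  g <- land$climate_fine[["bio1"]]
  truth <- true_suitability(land$climate_fine, habitat_niche())
  occ <- sample_occurrences(truth, 20, seed = 36)
  sre_map <- classify_sre(fit_sre(occ, land$climate_fine, 0.025),
                          land$climate_fine)
  pa <- sample_pseudo_absences(occ, sre_map, seed = 37)
  idx <- cell_index(g, pa$records$x[1], pa$records$y[1])
  g$values[idx[1, "row"], idx[1, "col"]] <- NA
  stack2 <- raster_stack(c(list(g), land$climate_fine$layers[-1]))
  expect_warning(ds <- extract_training_table(stack2, pa), "dropped")
  expect_equal(nrow(ds$features), 39)
  expect_equal(ds$n_dropped, 1L)
  # single-label input is refused outright
  expect_error(extract_training_table(land$climate_fine, occ), "both")
})

test_that("CV splits partition the data, stratified and seeded", {
  ds <- toy_dataset(120)
  cfg <- cv_config(k = 3, repetitions = 10, seed = 41)
  splits <- make_cv_splits(ds, cfg)
  expect_length(splits, 30)                    # k x repetitions
  for (rep_i in 1:10) {
    vals <- lapply(splits[(rep_i - 1) * 3 + 1:3], `[[`, "val")
    expect_equal(sort(unlist(vals)), 1:120)    # disjoint + exhaustive
    for (v in vals) {
      expect_length(intersect(v, splits[[(rep_i - 1) * 3 + 1]]$cal),
                    if (identical(v, splits[[(rep_i - 1) * 3 + 1]]$val)) 0
                    else length(v))
      # class ratio within one sample of the global 50/50
      expect_lte(abs(sum(ds$labels[v] == 1) - length(v) / 2), 1)
    }
  }
  expect_identical(make_cv_splits(ds, cfg), splits)
  expect_error(make_cv_splits(toy_dataset(4), cv_config(k = 3)), "k rows")
  expect_error(cv_config(k = 1), "k must")
})

test_that("evaluation scores match their textbook definitions", {
  # perfect separation
  s <- evaluate_binary(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 0.5)
  expect_equal(unlist(s[c("sensitivity", "specificity", "tss", "kappa",
                          "auc")]),
               c(sensitivity = 1, specificity = 1, tss = 1, kappa = 1,
                 auc = 1))
  # constant 0.5 probabilities: all predicted presence, AUC chance level
  s2 <- evaluate_binary(c(0, 0, 1, 1), rep(0.5, 4), 0.5)
  expect_equal(s2$sensitivity, 1); expect_equal(s2$specificity, 0)
  expect_equal(s2$tss, 0); expect_equal(s2$auc, 0.5)
  # hand-worked confusion TP=40 FN=10 TN=35 FP=15
  labels <- rep(c(1, 0), c(50, 50))
  probs <- c(rep(0.9, 40), rep(0.1, 10), rep(0.1, 35), rep(0.9, 15))
  s3 <- evaluate_binary(labels, probs, 0.5)
  expect_equal(s3$sensitivity, 0.8); expect_equal(s3$specificity, 0.7)
  expect_equal(s3$tss, 0.5, tolerance = 1e-12)
  expect_equal(s3$kappa, 0.5, tolerance = 1e-12)
  expect_error(evaluate_binary(c(1, 1), c(0.4, 0.6)), "both classes")
})

test_that("scores equal brute-force oracles on random vectors", {
  set.seed(42)
  for (case in 1:500) {
    n <- sample(6:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    probs <- round(runif(n), 2)
    t <- runif(1)
    s <- evaluate_binary(labels, probs, t)
    # brute-force confusion
    pred <- ifelse(probs >= t, 1, 0)
    tp <- sum(pred & labels); fn <- sum(!pred & labels)
    tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
    expect_equal(s$sensitivity, tp / (tp + fn), tolerance = 1e-9)
    expect_equal(s$specificity, tn / (tn + fp), tolerance = 1e-9)
    expect_equal(s$tss, s$sensitivity + s$specificity - 1, tolerance = 1e-12)
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    expect_equal(s$kappa, (po - pe) / (1 - pe), tolerance = 1e-9)
    # pairwise Mann-Whitney AUC oracle with half credit for ties
    pos <- probs[labels == 1]; neg <- probs[labels == 0]
    cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    expect_equal(s$auc, mean(cmp), tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(43)
  labels <- rbinom(100, 1, 0.5); labels[1:2] <- c(0, 1)
  probs <- runif(100)
  a0 <- evaluate_binary(labels, probs)$auc
  expect_equal(evaluate_binary(labels, exp(probs) / 4)$auc, a0)
  expect_equal(evaluate_binary(labels, rank(probs) / 101)$auc, a0)
})

test_that("cross-check against pROC on a shared vector", {
  skip_if_not_installed("pROC")
  set.seed(44)
  labels <- rbinom(200, 1, 0.4); labels[1:2] <- c(0, 1)
  probs <- runif(200)
  expect_equal(evaluate_binary(labels, probs)$auc,
               as.numeric(suppressMessages(
                 pROC::auc(labels, probs, direction = "<",
                           levels = c(0, 1)))),
               tolerance = 1e-9)
})

test_that("members fit on calibration rows and validate held out", {
  ds <- toy_dataset(60, sep = 5)
  split <- make_cv_splits(ds, cv_config(k = 3, repetitions = 1,
                                        seed = 45))[[1]]
  for (alg in c("random_forest", "logistic", "decision_tree")) {
    run <- fit_member(ds, alg, split, seed = 46)
    expect_s3_class(run, "model_run")
    expect_equal(run$scores$tss, 1)            # cleanly separable
  }
  run_a <- fit_member(ds, "random_forest", split, seed = 47)
  run_b <- fit_member(ds, "random_forest", split, seed = 47)
  expect_identical(run_a$scores, run_b$scores)
  expect_error(fit_member(ds, "maxent", split), "unknown algorithm")
})

test_that("permuted labels give chance-level validation AUC", {
  ds <- toy_dataset(240, sep = 5)
  aucs <- vapply(1:20, function(s) {
    set.seed(s + 400)
    ds_null <- ds
    ds_null$labels <- sample(ds$labels)
    split <- make_cv_splits(ds_null, cv_config(k = 3, repetitions = 1,
                                               seed = s))[[1]]
    fit_member(ds_null, "logistic", split, seed = s)$scores$auc
  }, numeric(1))
  expect_true(all(aucs > 0.25 & aucs < 0.75))
  expect_gt(mean(aucs), 0.4); expect_lt(mean(aucs), 0.6)
})

test_that("ensemble filtering and weighting follow the TSS rule", {
  mk_run <- function(tss) structure(list(algorithm = "logistic",
                                         scores = list(tss = tss)),
                                    class = "model_run")
  runs <- lapply(c(0.9, 0.85, 0.5), mk_run)
  ens <- build_ensemble(runs, cutoff = 0.8)
  expect_length(ens$members, 2)
  expect_equal(ens$weights, c(0.9, 0.85) / 1.75, tolerance = 1e-12)
  # equal scores give uniform weights
  ens_u <- build_ensemble(lapply(rep(0.9, 4), mk_run), cutoff = 0.8)
  expect_equal(ens_u$weights, rep(0.25, 4))
  # the cutoff is strict
  expect_error(build_ensemble(lapply(c(0.8, 0.7), mk_run), cutoff = 0.8),
               "no member")
})

test_that("dropping a non-member run leaves ensemble predictions unchanged", {
  ds <- toy_dataset(90, sep = 4)
  runs <- run_members(ds, c("random_forest", "decision_tree"),
                      cv_config(k = 3, repetitions = 2, runs = 1, seed = 48),
                      ntree = 100)
  scores <- vapply(runs, function(r) r$scores$tss, numeric(1))
  if (any(scores <= 0.8)) {
    ens_all <- build_ensemble(runs)
    ens_members_only <- build_ensemble(runs[scores > 0.8])
    expect_equal(predict_ensemble_table(ens_all, ds$features),
                 predict_ensemble_table(ens_members_only, ds$features))
  } else succeed("all runs passed the cutoff on this fixture")
})

test_that("ensemble maps are weighted means inside the member envelope", {
  land <- make_landscape(n_rows = 16, n_cols = 16, seed = 49)
  ds <- make_benchmark_dataset(land, habitat_niche(), n = 60, seed = 50)
  runs <- run_members(ds, "random_forest",
                      cv_config(k = 3, repetitions = 2, runs = 1, seed = 51),
                      ntree = 100)
  ens <- build_ensemble(runs)
  suit <- predict_ensemble(ens, land$climate_fine)
  expect_true(all(suit$values >= 0 & suit$values <= 1, na.rm = TRUE))
  member_preds <- vapply(ens$members, mangroveSDM:::predict_member,
                         numeric(16 * 16),
                         features = as.data.frame(
                           mangroveSDM:::stack_as_matrix(land$climate_fine)))
  lo <- apply(member_preds, 1, min); hi <- apply(member_preds, 1, max)
  expect_true(all(as.vector(suit$values) >= lo - 1e-12))
  expect_true(all(as.vector(suit$values) <= hi + 1e-12))
  # single-member ensemble reproduces that member's map
  ens1 <- ens; ens1$members <- ens$members[1]; ens1$weights <- 1
  expect_equal(as.vector(predict_ensemble(ens1, land$climate_fine)$values),
               member_preds[, 1], tolerance = 1e-12)
  expect_error(predict_ensemble(ens, raster_stack(land$climate_fine$layers[1])),
               "lacks predictors")
})

test_that("two equal-weight members average their predictions", {
  # stub algorithms predicting constants 0.2 and 0.8
  register_algorithm("const_lo", fit = function(features, labels, seed, ...)
    list(), predict = function(object, features) rep(0.2, nrow(features)))
  register_algorithm("const_hi", fit = function(features, labels, seed, ...)
    list(), predict = function(object, features) rep(0.8, nrow(features)))
  mk <- function(alg) structure(list(algorithm = alg, model = list(),
                                     scores = list(tss = 0.9),
                                     predictors = c("v1", "v2")),
                                class = "model_run")
  ens <- build_ensemble(list(mk("const_lo"), mk("const_hi")))
  out <- predict_ensemble_table(ens, data.frame(v1 = 1:3, v2 = 1:3))
  expect_equal(out, rep(0.5, 3))
})

test_that("permutation importance sums to 100 and spots silent variables", {
  land <- make_landscape(n_rows = 24, n_cols = 24, seed = 52)
  niche <- niche_spec(list(bio1 = list(optimum = 26, tolerance = 1,
                                       weight = 10),
                           bio12 = list(optimum = 4000, tolerance = 800,
                                        weight = 1)), intercept = 3)
  ds <- make_benchmark_dataset(land, niche, n = 80, seed = 53)
  ens <- fit_light_ensemble(ds, seed = 54)
  imp <- variable_importance(ens, ds, n_perm = 3, seed = 55)
  expect_equal(sum(imp$importance), 100, tolerance = 1e-6)
  expect_identical(imp$variable[1], "bio1")
  # a never-split constant column has (near) zero importance
  ds2 <- ds
  ds2$features$flat <- 7
  runs2 <- run_members(ds2, "random_forest",
                       cv_config(k = 3, repetitions = 2, runs = 1, seed = 56),
                       ntree = 100)
  imp2 <- variable_importance(build_ensemble(runs2), ds2, n_perm = 3,
                              seed = 57)
  expect_lt(imp2$importance[imp2$variable == "flat"], 1)
})

test_that("response curves sweep the focal variable and stay in [0, 1]", {
  land <- make_landscape(n_rows = 24, n_cols = 24, seed = 58)
  ds <- make_benchmark_dataset(land, habitat_niche(), n = 80, seed = 59)
  ens <- fit_light_ensemble(ds, seed = 60)
  curve <- response_curve(ens, ds, "bio1", n_steps = 60)
  expect_equal(nrow(curve), 60)
  expect_equal(curve$value[1], min(ds$features$bio1))
  expect_equal(curve$value[60], max(ds$features$bio1))
  expect_true(all(curve$suitability >= 0 & curve$suitability <= 1))
  # a flat added variable produces a flat curve
  ds2 <- ds
  set.seed(61)
  ds2$features$noise <- rnorm(nrow(ds$features))
  runs2 <- run_members(ds2, "random_forest",
                       cv_config(k = 3, repetitions = 2, runs = 1, seed = 62),
                       ntree = 200)
  curve2 <- response_curve(build_ensemble(runs2), ds2, "noise")
  expect_lt(max(curve2$suitability) - min(curve2$suitability), 0.05)
  ds3 <- ds; ds3$features$flat <- 1
  expect_error(response_curve(ens, ds3, "flat"), "constant")
  expect_error(response_curve(ens, ds, "nope"), "not in dataset")
})

test_that("suitability ranges read the curve at the 50% level", {
  curve <- data.frame(value = 1:10, suitability = c(0.1, 0.2, 0.6, 0.7, 0.9,
                                                    0.8, 0.55, 0.4, 0.2, 0.1))
  expect_equal(suitability_range(curve), c(low = 3, high = 7))
  low_curve <- data.frame(value = 1:5, suitability = rep(0.2, 5))
  expect_null(suitability_range(low_curve))
  expect_equal(suitability_range(low_curve, level = 0.1),
               c(low = 1, high = 5))
})

test_that("the ESRm layer improves bivalve models (hierarchy property)", {
  deltas <- vapply(1:10, function(s) {
    land <- make_landscape(n_rows = 32, n_cols = 32, seed = s + 70)
    hab_truth <- true_suitability(land$climate_fine, habitat_niche())
    soil <- lapply(land$soil, depth_weighted_mean, interval = c(5, 30))
    dwb <- distance_to_water(land$water)
    cfg_with <- species_config("bv", c(5, 30), uses_esrm = TRUE)
    cfg_without <- species_config("bv", c(5, 30))
    stack_with <- assemble_predictors(land$climate_fine, soil, land$dem, dwb,
                                      esrm = hab_truth, species_cfg = cfg_with)
    stack_without <- assemble_predictors(land$climate_fine, soil, land$dem,
                                         dwb, species_cfg = cfg_without)
    # bivalve truth leans mostly on the habitat layer
    niche <- niche_spec(list(esrm = list(optimum = 1, tolerance = 0.4,
                                         weight = 4),
                             bdod = list(optimum = 78, tolerance = 30,
                                         weight = 0.5)), intercept = 2)
    truth_stack <- raster_stack(c(land$climate_fine$layers, soil,
                                  list(dem = land$dem, dwb = dwb,
                                       esrm = local({
                                         g <- hab_truth; g$name <- "esrm"; g
                                       }))))
    truth <- true_suitability(truth_stack, niche)
    occ <- thin_occurrences(sample_occurrences(truth, 80, seed = s + 80),
                            land$dem)
    sre_map <- classify_sre(fit_sre(occ, stack_with, 0.025), stack_with)
    pa <- sample_pseudo_absences(occ, sre_map, seed = s + 90)
    auc_of <- function(stack) {
      ds <- extract_training_table(stack, pa)
      runs <- run_members(ds, "random_forest",
                          cv_config(k = 3, repetitions = 1, runs = 1,
                                    seed = s), ntree = 150)
      mean(vapply(runs, function(r) r$scores$auc, numeric(1)))
    }
    auc_of(stack_with) - auc_of(stack_without)
  }, numeric(1))
  expect_gt(stats::median(deltas), 0)
})
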