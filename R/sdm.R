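# Member classifiers under repeated stratified cross-validation, evaluation
# scores (sensitivity, specificity, TSS, KAPPA, AUC-ROC), the TSS-weighted
# mean ensemble, suitability projection, permutation variable importance and
# response curves.

# ---- algorithm registry -----------------------------------------------------

.sdm_registry <- new.env(parent = emptyenv())

#' Register a member algorithm
#'
#' Algorithms are plug-ins behind a common interface: `fit(features, labels,
#' seed, ...)` returning an opaque fitted object and `predict(object,
#' features)` returning presence probabilities in `[0, 1]`.
#'
#' @param name registry key.
#' @param fit,predict the two interface functions.
#' @export
register_algorithm <- function(name, fit, predict) {
  assign(name, list(fit = fit, predict = predict), envir = .sdm_registry)
  invisible(name)
}

#' Names of registered member algorithms
#' @return character vector.
#' @export
list_algorithms <- function() sort(ls(.sdm_registry))

get_algorithm <- function(name) {
  if (!exists(name, envir = .sdm_registry))
    stop("unknown algorithm '", name, "'; registered: ",
         paste(list_algorithms(), collapse = ", "), call. = FALSE)
  get(name, envir = .sdm_registry)
}

register_default_algorithms <- function() {
  register_algorithm("random_forest",
    fit = function(features, labels, seed, ntree = 300, ...)
      with_seed(seed, randomForest::randomForest(
        x = features, y = factor(labels, levels = c(0, 1)), ntree = ntree)),
    predict = function(object, features)
      unname(stats::predict(object, newdata = features, type = "prob")[, "1"]))
  register_algorithm("logistic",
    fit = function(features, labels, seed, ...) {
      d <- cbind(.label = labels, features)
      suppressWarnings(stats::glm(.label ~ ., data = d, family = stats::binomial()))
    },
    predict = function(object, features)
      unname(suppressWarnings(stats::predict(object, newdata = features,
                                             type = "response"))))
  register_algorithm("decision_tree",
    fit = function(features, labels, seed, ...) {
      d <- cbind(.label = factor(labels, levels = c(0, 1)), features)
      with_seed(seed, rpart::rpart(.label ~ ., data = d, method = "class"))
    },
    predict = function(object, features)
      unname(stats::predict(object, newdata = features, type = "prob")[, "1"]))
}

# ---- datasets and CV design -------------------------------------------------

#' Presence/pseudo-absence training table
#'
#' Extracts one feature row per occurrence record from the predictor stack;
#' rows falling on nodata in any layer are dropped with a warning.
#'
#' @param stack predictor [raster_stack()].
#' @param occ [occurrence_set()] with both labels present.
#' @return a `pa_dataset`: `features` data frame (columns in stack order),
#'   `labels` (1 presence / 0 pseudo-absence), `xy` coordinates, `species`.
#' @export
extract_training_table <- function(stack, occ) {
  rec <- occ$records
  if (!all(c("presence", "pseudo_absence") %in% rec$label))
    stop("dataset needs both presences and pseudo-absences", call. = FALSE)
  feat <- vapply(names(stack),
                 function(nm) grid_extract(stack[[nm]], rec$x, rec$y),
                 numeric(nrow(rec)))
  feat <- as.data.frame(feat)
  ok <- stats::complete.cases(feat)
  if (any(!ok))
    warning(sum(!ok), " record(s) on nodata cells dropped", call. = FALSE)
  labels <- as.integer(rec$label[ok] == "presence")
  if (length(unique(labels)) < 2L)
    stop("a class was fully lost to nodata cells", call. = FALSE)
  structure(list(features = feat[ok, , drop = FALSE], labels = labels,
                 xy = cbind(x = rec$x[ok], y = rec$y[ok]),
                 species = occ$species, n_dropped = sum(!ok)),
            class = "pa_dataset")
}

#' Cross-validation design
#'
#' Defaults follow the standard ensemble-platform setup: three partitions
#' with ten repetitions, ten runs per algorithm, three permutations for
#' variable importance.
#'
#' @param k folds (>= 2).
#' @param repetitions repeated random partitions (>= 1).
#' @param runs seeds per algorithm over the whole CV design.
#' @param n_perm importance permutations.
#' @param seed base RNG seed.
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 3, repetitions = 10, runs = 10, n_perm = 3,
                      seed = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  structure(list(k = as.integer(k), repetitions = as.integer(repetitions),
                 runs = as.integer(runs), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)), class = "cv_config")
}

#' Stratified k-fold splits, repeated
#'
#' Per repetition, rows are partitioned into `k` folds stratified by label;
#' every fold serves once as the validation set.
#'
#' @param dataset a `pa_dataset`.
#' @param cfg a [cv_config()].
#' @return list of `k * repetitions` elements, each
#'   `list(cal =, val =, repetition =, fold =)` of row indices.
#' @export
make_cv_splits <- function(dataset, cfg) {
  y <- dataset$labels
  if (min(table(y)) < cfg$k)
    stop("each class needs at least k rows", call. = FALSE)
  with_seed(cfg$seed, {
    splits <- list()
    for (rep_i in seq_len(cfg$repetitions)) {
      fold <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(cfg$k), length(idx))
      }
      for (f in seq_len(cfg$k))
        splits[[length(splits) + 1L]] <-
          list(cal = which(fold != f), val = which(fold == f),
               repetition = rep_i, fold = f)
    }
    splits
  })
}

# ---- evaluation -------------------------------------------------------------

#' Binary evaluation scores
#'
#' Confusion-matrix scores at the rule `p >= threshold`, plus rank-based
#' AUC-ROC (Mann-Whitney statistic with mid-ranks for ties). TSS =
#' sensitivity + specificity - 1; KAPPA is chance-corrected agreement.
#'
#' @param labels 0/1 vector with both classes present.
#' @param probabilities predicted presence probabilities in `[0, 1]`.
#' @param threshold classification threshold (default 0.5).
#' @return list `sensitivity`, `specificity`, `tss`, `kappa`, `auc`,
#'   `threshold`.
#' @export
evaluate_binary <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L); fp <- sum(pred == 1L & labels == 0L)
  n <- length(labels)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  r <- rank(probabilities)                      # mid-ranks for ties
  n1 <- sum(labels == 1L); n0 <- n - n1
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       kappa = kappa, auc = auc, threshold = threshold)
}

# ---- members and ensemble ---------------------------------------------------

#' Fit one member model on a calibration/validation split
#'
#' The classifier is fit on calibration rows only; scores (threshold 0.5
#' plus AUC) are computed on the held-out validation rows.
#'
#' @param dataset a `pa_dataset`.
#' @param algorithm registry name (see [list_algorithms()]).
#' @param split one element of [make_cv_splits()].
#' @param seed RNG seed for the fit.
#' @param ... passed to the algorithm's fit function.
#' @return a `model_run` object.
#' @export
fit_member <- function(dataset, algorithm, split, seed = 1, ...) {
  alg <- get_algorithm(algorithm)
  X <- dataset$features
  model <- alg$fit(X[split$cal, , drop = FALSE], dataset$labels[split$cal],
                   seed = seed, ...)
  p_val <- alg$predict(model, X[split$val, , drop = FALSE])
  scores <- evaluate_binary(dataset$labels[split$val], p_val)
  structure(list(algorithm = algorithm, model = model, seed = seed,
                 repetition = split$repetition, fold = split$fold,
                 cal = split$cal, val = split$val, scores = scores,
                 predictors = names(X)),
            class = "model_run")
}

predict_member <- function(run, features)
  get_algorithm(run$algorithm)$predict(run$model, features)

#' Run member algorithms over the full cross-validation design
#'
#' Realizes the `runs x repetitions x k` design: each run re-draws the
#' stratified partitions under a run-specific seed and fits every requested
#' algorithm on every split.
#'
#' @param dataset a `pa_dataset`.
#' @param algorithms character vector of registry names.
#' @param cfg a [cv_config()].
#' @param ... passed to the fit functions (e.g. `ntree`).
#' @return list of `model_run`s.
#' @export
run_members <- function(dataset, algorithms = "random_forest",
                        cfg = cv_config(), ...) {
  runs <- list()
  for (r in seq_len(cfg$runs)) {
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + 131L * (r - 1L)
    splits <- make_cv_splits(dataset, run_cfg)
    for (alg in algorithms)
      for (s in seq_along(splits)) {
        m <- fit_member(dataset, alg, splits[[s]],
                        seed = run_cfg$seed + s, ...)
        m$run <- r
        runs[[length(runs) + 1L]] <- m
      }
  }
  runs
}

#' Build the TSS-weighted mean ensemble
#'
#' Members with validation scores above the cutoff are retained and weighted
#' proportionally to their score (weights sum to 1) — the weighted-mean
#' ensemble (EMwMean) with proportional decay.
#'
#' @param runs list of `model_run`s.
#' @param metric score used for filtering and weighting (default `"tss"`).
#' @param cutoff strict inclusion threshold (default 0.8).
#' @return an `ensemble_model`.
#' @export
build_ensemble <- function(runs, metric = "tss", cutoff = 0.8) {
  scores <- vapply(runs, function(r) r$scores[[metric]], numeric(1))
  keep <- which(scores > cutoff)
  if (!length(keep))
    stop("no member exceeds ", metric, " > ", cutoff,
         " (best: ", signif(max(scores), 4), ")", call. = FALSE)
  w <- scores[keep] / sum(scores[keep])
  structure(list(members = runs[keep], weights = w, metric = metric,
                 cutoff = cutoff, member_scores = scores[keep]),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members (%s > %g), weighted mean\n",
              length(x$members), x$metric, x$cutoff))
  cat(sprintf("  member %s: min %.3f, median %.3f, max %.3f\n", x$metric,
              min(x$member_scores), stats::median(x$member_scores),
              max(x$member_scores)))
  invisible(x)
}

#' Ensemble predictions on a feature table
#'
#' @param ens an `ensemble_model`.
#' @param features data frame with the members' predictor columns.
#' @return weighted-mean presence probabilities.
#' @export
predict_ensemble_table <- function(ens, features) {
  missing <- setdiff(ens$members[[1L]]$predictors, names(features))
  if (length(missing))
    stop("missing predictors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  preds <- vapply(ens$members, predict_member, numeric(nrow(features)),
                  features = features)
  if (nrow(features) == 1L) preds <- matrix(preds, nrow = 1L)
  as.vector(preds %*% ens$weights)
}

#' Project ensemble suitability over a predictor stack
#'
#' @param ens an `ensemble_model`.
#' @param stack [raster_stack()] providing every trained predictor.
#' @return suitability [grid_layer()] in `[0, 1]`; nodata propagates.
#' @export
predict_ensemble <- function(ens, stack) {
  preds <- ens$members[[1L]]$predictors
  missing <- setdiff(preds, names(stack))
  if (length(missing))
    stop("stack lacks predictors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- as.data.frame(stack_as_matrix(stack))[, preds, drop = FALSE]
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok)) out[ok] <- predict_ensemble_table(ens, X[ok, , drop = FALSE])
  g <- blank_like(stack$layers[[1L]], "suitability")
  g$values[] <- out
  g$units <- "probability"
  g
}

#' Held-out evaluation of the ensemble under the CV design
#'
#' For every data row, member predictions are pooled from exactly those
#' splits where the row was held out of calibration, combined with the
#' ensemble weights (renormalized over the members that validate the row),
#' and the pooled out-of-sample probabilities are scored once.
#'
#' @param ens an `ensemble_model` whose members carry their split indices.
#' @param dataset the `pa_dataset` the members were run on.
#' @param threshold classification threshold for the contingency scores.
#' @return [evaluate_binary()] scores of the out-of-sample ensemble
#'   predictions.
#' @export
evaluate_ensemble_cv <- function(ens, dataset, threshold = 0.5) {
  n <- nrow(dataset$features)
  num <- numeric(n); den <- numeric(n)
  for (j in seq_along(ens$members)) {
    m <- ens$members[[j]]
    p <- predict_member(m, dataset$features[m$val, , drop = FALSE])
    num[m$val] <- num[m$val] + ens$weights[j] * p
    den[m$val] <- den[m$val] + ens$weights[j]
  }
  seen <- den > 0
  if (!any(seen)) stop("no row was ever held out", call. = FALSE)
  evaluate_binary(dataset$labels[seen], (num / den)[seen], threshold)
}

# ---- interpretation ---------------------------------------------------------

#' Permutation variable importance of the ensemble
#'
#' Each predictor column is shuffled `n_perm` times; the raw importance is
#' `1 - cor(original, shuffled predictions)` clipped to `[0, 1]` and averaged
#' over permutations, then normalized across variables to sum to 100.
#'
#' @param ens an `ensemble_model`.
#' @param dataset the `pa_dataset` (columns must match the predictors).
#' @param n_perm permutations per variable (default 3).
#' @param seed RNG seed.
#' @return data frame `variable`, `importance` (percent, sums to 100),
#'   sorted decreasing.
#' @export
variable_importance <- function(ens, dataset, n_perm = 3, seed = 1) {
  X <- dataset$features
  orig <- predict_ensemble_table(ens, X)
  if (stats::sd(orig) == 0)
    stop("ensemble predictions have zero variance; importance is undefined",
         call. = FALSE)
  raw <- with_seed(seed, vapply(names(X), function(v) {
    vals <- vapply(seq_len(n_perm), function(p) {
      Xp <- X
      Xp[[v]] <- sample(Xp[[v]])
      pp <- predict_ensemble_table(ens, Xp)
      if (stats::sd(pp) == 0) 1 else
        min(max(1 - stats::cor(orig, pp), 0), 1)
    }, numeric(1))
    mean(vals)
  }, numeric(1)))
  if (sum(raw) == 0) raw[] <- 1 / length(raw)     # no variable moves the model
  out <- data.frame(variable = names(X),
                    importance = 100 * raw / sum(raw), row.names = NULL)
  out[order(-out$importance), , drop = FALSE]
}

#' Response curve of one predictor
#'
#' Evaluation-strip construction: the focal variable is swept over its
#' observed range while all other predictors sit at their dataset medians.
#'
#' @param ens an `ensemble_model`.
#' @param dataset the `pa_dataset`.
#' @param variable focal predictor name.
#' @param n_steps sweep resolution (default 100).
#' @return data frame `value`, `suitability`.
#' @export
response_curve <- function(ens, dataset, variable, n_steps = 100) {
  X <- dataset$features
  if (!variable %in% names(X))
    stop("variable not in dataset: ", variable, call. = FALSE)
  rng <- range(X[[variable]])
  if (diff(rng) == 0)
    stop("focal variable is constant; curve is degenerate", call. = FALSE)
  sweep_vals <- seq(rng[1L], rng[2L], length.out = n_steps)
  strip <- as.data.frame(lapply(X, function(col)
    rep(stats::median(col), n_steps)))
  strip[[variable]] <- sweep_vals
  data.frame(value = sweep_vals,
             suitability = predict_ensemble_table(ens, strip))
}

#' Suitability range of a response curve
#'
#' @param curve data frame from [response_curve()].
#' @param level suitability level (default 0.5, the "at least 50%" rule).
#' @return `c(low, high)` — the extreme focal values whose curve value
#'   reaches `level` — or `NULL` if no point qualifies.
#' @export
suitability_range <- function(curve, level = 0.5) {
  qual <- curve$value[curve$suitability >= level]
  if (!length(qual)) return(NULL)
  c(low = min(qual), high = max(qual))
}
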