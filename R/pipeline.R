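# Full-analysis orchestration: habitat species first, then focal species
# with the habitat-suitability (ESRm) layer injected as a biotic predictor,
# across periods and climate scenarios, from a single config.

PIPELINE_KEYS <- c("landscape", "species", "cv", "algorithms",
                   "ensemble_cutoff", "sre_q", "threshold", "scenarios",
                   "periods", "downscale", "freeze_esrm", "output_dir",
                   "seed")

parse_threshold <- function(x) {
  if (is.list(x) && !is.null(x$policy)) return(x)   # already parsed
  if (identical(x, "maxsss")) return(list(policy = "maxsss", value = NA_real_))
  if (is.numeric(x)) x <- paste0("fixed:", x)
  if (grepl("^fixed:", x)) {
    v <- as.numeric(sub("^fixed:", "", x))
    if (is.na(v) || v < 0 || v > 1)
      stop("fixed threshold must lie in [0, 1]", call. = FALSE)
    return(list(policy = "fixed", value = v))
  }
  stop("threshold must be 'maxsss' or 'fixed:<p>'", call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or an R list; fills defaults (SRE `q = 0.025`,
#' `k = 3` with ten repetitions and ten runs, ensemble cutoff 0.8, fixed 0.5
#' binarization threshold) and checks the structural invariants: exactly one
#' habitat-provider species, every ESRm-using species ordered after it,
#' unknown keys rejected.
#'
#' @param config path to a YAML file, or a config list.
#' @return the validated, defaults-filled config (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  config$sre_q <- config$sre_q %||% 0.025
  cv <- config$cv %||% list()
  config$cv <- cv_config(k = cv$k %||% 3, repetitions = cv$repetitions %||% 10,
                         runs = cv$runs %||% 10, n_perm = cv$n_perm %||% 3,
                         seed = config$seed %||% 1)
  config$algorithms <- config$algorithms %||% "random_forest"
  config$ensemble_cutoff <- config$ensemble_cutoff %||% 0.8
  config$threshold <- parse_threshold(config$threshold %||% "fixed:0.5")
  config$seed <- config$seed %||% 1
  config$freeze_esrm <- isTRUE(config$freeze_esrm)
  config$periods <- config$periods %||% list(list(label = "2050", scale = 1))
  config$scenarios <- config$scenarios %||% list()

  problems <- character(0)
  if (config$sre_q < 0 || config$sre_q >= 0.5)
    problems <- c(problems, "sre_q must lie in [0, 0.5)")
  if (!length(config$species)) problems <- c(problems, "no species configured")
  is_hab <- vapply(config$species, function(s) isTRUE(s$is_habitat), logical(1))
  uses <- vapply(config$species, function(s) isTRUE(s$uses_esrm), logical(1))
  if (sum(is_hab) != 1L)
    problems <- c(problems, "exactly one species must be the habitat provider")
  else if (any(uses & seq_along(uses) < which(is_hab)))
    problems <- c(problems,
                  "every uses_esrm species must be ordered after the habitat species")
  if (any(is_hab & uses))
    problems <- c(problems, "the habitat species cannot use ESRm")
  for (s in config$species)
    if (length(s$soil_interval) != 2L ||
        s$soil_interval[1L] >= s$soil_interval[2L])
      problems <- c(problems,
                    paste0(s$name, ": soil_interval must be c(top, bottom)"))
  unknown_alg <- setdiff(config$algorithms, list_algorithms())
  if (length(unknown_alg))
    problems <- c(problems, paste("unknown algorithms:",
                                  paste(unknown_alg, collapse = ", ")))
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  if (!is.null(config$output_dir) && !dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
    message("created output directory: ", config$output_dir)
  }
  class(config) <- "pipeline_config"
  config
}

#' Synthetic demonstration configuration
#'
#' Three species on a seeded synthetic landscape: the habitat provider
#' (mangrove analogue, niche on the two trending climate variables) plus two
#' infaunal bivalve analogues whose true niches depend on the habitat
#' suitability itself, with soil preferences at their burrowing depths.
#' Futures cover two periods and three scenario intensities whose warming
#' displaces the suitable belt toward the southwest. The cross-validation
#' design is kept deliberately small (two repetitions, one run, random
#' forest only) so a demo run completes in well under a minute.
#'
#' @param seed global pipeline seed.
#' @param output_dir optional directory for written artifacts.
#' @return a validated `pipeline_config`.
#' @export
demo_config <- function(seed = 1, output_dir = NULL) {
  cfg <- list(
    landscape = list(n_rows = 48, n_cols = 48, cell_size = 250,
                     coarse_factor = 4, n_zones = 4),
    species = list(
      list(name = "habitat_mangrove", soil_interval = c(0, 200),
           is_habitat = TRUE, uses_esrm = FALSE, n_presences = 100,
           niche = list(bio1 = list(optimum = 26.75, tolerance = 1.0, weight = 4),
                        bio12 = list(optimum = 3650, tolerance = 700, weight = 2),
                        bio8 = list(optimum = 25.5, tolerance = 1.2, weight = 2)),
           niche_intercept = 3),
      list(name = "bivalve_deep", soil_interval = c(5, 30),
           uses_esrm = TRUE, n_presences = 130,
           niche = list(esrm = list(optimum = 1, tolerance = 0.45, weight = 3),
                        bdod = list(optimum = 78, tolerance = 25, weight = 1.5),
                        bio17 = list(optimum = 500, tolerance = 250, weight = 0.5)),
           niche_intercept = 3),
      list(name = "bivalve_shallow", soil_interval = c(15, 30),
           uses_esrm = TRUE, n_presences = 94,
           niche = list(esrm = list(optimum = 1, tolerance = 0.5, weight = 3),
                        silt = list(optimum = 320, tolerance = 90, weight = 1.5)),
           niche_intercept = 3)),
    cv = list(k = 3, repetitions = 2, runs = 1, n_perm = 3),
    algorithms = "random_forest",
    scenarios = list(
      list(label = "ssp1", deltas = list(bio1 = list(mean = 0.8),
                                         bio12 = list(mean = -400))),
      list(label = "ssp2", deltas = list(bio1 = list(mean = 1.2),
                                         bio12 = list(mean = -600))),
      list(label = "ssp5", deltas = list(bio1 = list(mean = 1.8),
                                         bio12 = list(mean = -900)))),
    periods = list(list(label = "2030", scale = 0.55),
                   list(label = "2050", scale = 1)),
    seed = seed,
    output_dir = output_dir)
  validate_config(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

niche_from_config <- function(sp)
  niche_spec(sp$niche, intercept = sp$niche_intercept %||% 2)

# temperature-type bioclim variables (bio1-bio11) take the elevation
# regressor; precipitation-type (bio12-bio19) do not
uses_elevation_covariate <- function(name, override = NULL) {
  if (!is.null(override)) return(name %in% override)
  grepl("^bio(0?[1-9]|1[01])$", name)
}

#' Run the full ensemble-SDM pipeline on a synthetic landscape
#'
#' Stage order: landscape generation, regression-kriging downscaling of every
#' coarse climate layer, per-species soil aggregation, distance to water, SRE
#' and three-criterion pseudo-absences, habitat-species ensemble, ESRm
#' injection, focal-species ensembles, current projection, per
#' period-by-scenario future projection (with scenario-matched ESRm unless
#' `freeze_esrm`), thresholding, change maps, zonal areas and centroid
#' direction of shift. Fully deterministic per the config seed.
#'
#' @param config a `pipeline_config` (see [validate_config()],
#'   [demo_config()]).
#' @return a results bundle: `$landscape`, `$downscale_validation`,
#'   `$species` (per species: dataset, member score table, ensemble,
#'   importance, response ranges, current suitability and binary map,
#'   threshold, and per-future suitability/binary/change/areas/shift),
#'   `$run_log`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(unclass(config))
  log <- list()
  note <- function(...) log[[length(log) + 1L]] <<- sprintf(...)

  land <- stage("landscape", {
    ls_cfg <- config$landscape %||% list()
    make_landscape(n_rows = ls_cfg$n_rows %||% 48,
                   n_cols = ls_cfg$n_cols %||% 48,
                   cell_size = ls_cfg$cell_size %||% 250,
                   coarse_factor = ls_cfg$coarse_factor %||% 4,
                   n_zones = ls_cfg$n_zones %||% 4,
                   seed = config$seed)
  })
  note("landscape %dx%d seed %d", nrow(land$dem$values),
       ncol(land$dem$values), config$seed)

  # -- downscale every coarse climate layer to the fine grid ------------------
  ds <- stage("downscale", {
    out <- list(layers = list(), validation = NULL)
    for (nm in names(land$climate_coarse)) {
      use_cov <- uses_elevation_covariate(nm, config$downscale$covariate_vars)
      d <- downscale_layer(land$climate_coarse[[nm]], land$dem_coarse,
                           land$dem, land$dem, use_covariate = use_cov,
                           seed = config$seed + match(nm, names(land$climate_coarse)))
      out$layers[[nm]] <- d$layer
      out$validation <- rbind(out$validation,
        data.frame(variable = nm, covariate = use_cov, mae = d$validation$mae,
                   rmse = d$validation$rmse, r_squared = d$validation$r_squared,
                   n_test = d$validation$n_test))
    }
    out
  })
  climate_fine <- raster_stack(ds$layers, types = land$climate_fine$types)
  note("downscaled %d climate layers, mean R2 %.3f",
       nrow(ds$validation), mean(ds$validation$r_squared))

  dwb <- stage("predictor_prep", distance_to_water(land$water))

  # ground-truth habitat suitability (on the true fine climate) drives both
  # the presence sampling and the habitat-cover mask
  hab_idx <- which(vapply(config$species, function(s) isTRUE(s$is_habitat),
                          logical(1)))
  hab_sp <- config$species[[hab_idx]]
  truth_base <- raster_stack(c(land$climate_fine$layers,
                               list(dem = land$dem, dwb = dwb)))
  hab_truth <- stage("habitat_truth",
                     true_suitability(truth_base, niche_from_config(hab_sp)))
  hab_mask <- habitat_cover_mask(hab_truth)

  esrm_current <- NULL
  hab_ens <- NULL
  species_out <- list()

  for (si in seq_along(config$species)) {
    sp <- config$species[[si]]
    sp_cfg <- species_config(sp$name, sp$soil_interval,
                             uses_esrm = isTRUE(sp$uses_esrm),
                             is_habitat = isTRUE(sp$is_habitat))
    sp_seed <- config$seed + 1000L * si

    soil_means <- stage("predictor_prep", {
      lapply(land$soil, depth_weighted_mean, interval = sp$soil_interval)
    })
    predictors <- stage("predictor_prep",
      assemble_predictors(climate_fine, soil_means, land$dem, dwb,
                          esrm = if (sp_cfg$uses_esrm) esrm_current,
                          species_cfg = sp_cfg))

    # truth stack for presence sampling: true climate + this species' soil
    # means + habitat truth as the biotic layer
    truth_layers <- c(land$climate_fine$layers, soil_means,
                      list(dem = land$dem, dwb = dwb))
    truth_layers$esrm <- hab_truth
    truth_layers$esrm$name <- "esrm"
    truth <- true_suitability(raster_stack(truth_layers),
                              niche_from_config(sp))

    occ <- stage("occurrences", {
      o <- sample_occurrences(truth, sp$n_presences %||% 100, seed = sp_seed,
                              species = sp$name)
      thin_occurrences(o, land$dem)
    })

    pa <- stage("pseudo_absence", {
      env <- fit_sre(occ, predictors, q = config$sre_q)
      sre_map <- classify_sre(env, predictors)
      sample_pseudo_absences(occ, sre_map, habitat_mask = hab_mask,
                             study_mask = land$study, seed = sp_seed + 1L)
    })
    note("%s: %d presences, %d pseudo-absences", sp$name,
         sum(pa$records$label == "presence"),
         sum(pa$records$label == "pseudo_absence"))

    dataset <- stage("sdm_fit", extract_training_table(predictors, pa))
    cv <- config$cv
    cv$seed <- sp_seed + 2L
    members <- stage("sdm_fit",
                     run_members(dataset, config$algorithms, cv))
    ens <- stage("sdm_fit",
                 build_ensemble(members, cutoff = config$ensemble_cutoff))
    cv_scores <- evaluate_ensemble_cv(ens, dataset)
    note("%s: ensemble of %d members, held-out TSS %.3f", sp$name,
         length(ens$members), cv_scores$tss)

    current_suit <- stage("projection", predict_ensemble(ens, predictors))
    thr <- if (config$threshold$policy == "fixed") config$threshold$value
           else max_sss_threshold(dataset$labels,
                                  predict_ensemble_table(ens, dataset$features))
    current_bin <- binarize(current_suit, thr)

    importance <- stage("interpretation",
                        variable_importance(ens, dataset,
                                            n_perm = config$cv$n_perm,
                                            seed = sp_seed + 3L))
    ranges <- stage("interpretation", {
      do.call(rbind, lapply(names(dataset$features), function(v) {
        rng <- tryCatch(suitability_range(response_curve(ens, dataset, v)),
                        error = function(e) NULL)
        data.frame(variable = v,
                   low = if (is.null(rng)) NA_real_ else rng[["low"]],
                   high = if (is.null(rng)) NA_real_ else rng[["high"]])
      }))
    })

    if (sp_cfg$is_habitat) {
      esrm_current <- current_suit
      hab_ens <- ens
    }

    # -- futures --------------------------------------------------------------
    futures <- list()
    for (per in config$periods) for (scn in config$scenarios) {
      key <- paste(per$label, scn$label, sep = "_")
      scaled <- scn
      scaled$deltas <- lapply(scn$deltas, function(d) {
        d$mean <- (d$mean %||% 0) * (per$scale %||% 1)
        d$gradient <- (d$gradient %||% 0) * (per$scale %||% 1)
        d
      })
      fut <- stage(paste0("future_", key), {
        clim_fut <- apply_climate_delta(climate_fine,
                                        scenario_spec(scn$label, scaled$deltas))
        esrm_fut <- NULL
        if (sp_cfg$uses_esrm) {
          esrm_fut <- if (config$freeze_esrm) esrm_current else {
            hab_pred_fut <- assemble_predictors(
              clim_fut, lapply(land$soil, depth_weighted_mean,
                               interval = hab_sp$soil_interval),
              land$dem, dwb, esrm = NULL,
              species_cfg = species_config(hab_sp$name, hab_sp$soil_interval,
                                           is_habitat = TRUE))
            predict_ensemble(hab_ens, hab_pred_fut)
          }
        }
        pred_fut <- assemble_predictors(clim_fut, soil_means, land$dem, dwb,
                                        esrm = esrm_fut, species_cfg = sp_cfg)
        suit <- predict_ensemble(ens, pred_fut)
        bin <- binarize(suit, thr)
        cm <- change_map(current_bin, bin)
        list(period = per$label, scenario = scn$label, suitability = suit,
             binary = bin, change = cm,
             areas = quantify_areas(cm, land$zones),
             shift = centroid_shift(current_bin, bin))
      })
      futures[[key]] <- fut
    }

    species_out[[sp$name]] <- list(
      config = sp_cfg, dataset = dataset, ensemble = ens,
      cv_scores = cv_scores,
      member_scores = data.frame(
        algorithm = vapply(members, `[[`, character(1), "algorithm"),
        run = vapply(members, function(m) m$run %||% NA_integer_, numeric(1)),
        repetition = vapply(members, `[[`, numeric(1), "repetition"),
        fold = vapply(members, `[[`, numeric(1), "fold"),
        tss = vapply(members, function(m) m$scores$tss, numeric(1)),
        kappa = vapply(members, function(m) m$scores$kappa, numeric(1)),
        auc = vapply(members, function(m) m$scores$auc, numeric(1))),
      importance = importance, ranges = ranges, truth = truth,
      occurrences = pa, threshold = thr, current = current_suit,
      current_binary = current_bin, futures = futures)
  }

  bundle <- list(config = config, landscape = land,
                 downscale_validation = ds$validation,
                 habitat_truth = hab_truth, habitat_mask = hab_mask,
                 species = species_out, run_log = unlist(log))
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  utils::write.csv(bundle$downscale_validation,
                   file.path(dir, "downscale_validation.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$species)) {
    sp <- bundle$species[[nm]]
    write_raster(sp$current, file.path(dir, paste0(nm, "_current.tif")))
    utils::write.csv(sp$importance,
                     file.path(dir, paste0(nm, "_importance.csv")),
                     row.names = FALSE)
    utils::write.csv(sp$ranges, file.path(dir, paste0(nm, "_ranges.csv")),
                     row.names = FALSE)
    utils::write.csv(sp$member_scores,
                     file.path(dir, paste0(nm, "_member_scores.csv")),
                     row.names = FALSE)
    shifts <- NULL
    for (key in names(sp$futures)) {
      f <- sp$futures[[key]]
      write_raster(f$change, file.path(dir, paste0(nm, "_change_", key, ".tif")))
      utils::write.csv(f$areas, file.path(dir, paste0(nm, "_areas_", key, ".csv")),
                       row.names = FALSE)
      shifts <- rbind(shifts, data.frame(period = f$period,
                                         scenario = f$scenario,
                                         bearing = f$shift$bearing,
                                         distance_km = f$shift$distance_km))
    }
    utils::write.csv(shifts, file.path(dir, paste0(nm, "_direction.csv")),
                     row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(list(log = bundle$run_log,
                                   seed = bundle$config$seed),
                              auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "run_log.json"))
  invisible(dir)
}
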