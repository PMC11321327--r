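# Shared fixtures: tiny grids, toy niches and a light ensemble-fitting
# helper used across the model-level tests.

tiny_grid <- function(values = matrix(1:12, 3, 4), cell_size = 250,
                      name = "t") {
  grid_layer(name, values, origin_x = 0,
             origin_y = nrow(as.matrix(values)) * cell_size,
             cell_size = cell_size)
}

# niche used by the displacement and benchmark tests: optimum offset to the
# northeast so the warming-driven shift stays inside the domain
habitat_niche <- function() {
  niche_spec(list(bio1 = list(optimum = 26.75, tolerance = 1, weight = 4),
                  bio12 = list(optimum = 3650, tolerance = 700, weight = 2),
                  bio8 = list(optimum = 25.5, tolerance = 1.2, weight = 2)),
             intercept = 3)
}

# steep two-variable niche for the separability benchmark
steep_niche <- function() {
  niche_spec(list(bio1 = list(optimum = 26, tolerance = 0.8, weight = 6),
                  bio12 = list(optimum = 4000, tolerance = 500, weight = 3)),
             intercept = 4)
}

pessimistic_scenario <- function() {
  scenario_spec("ssp5", list(bio1 = list(mean = 1.8),
                             bio12 = list(mean = -900)))
}

# sample presences from a niche truth, draw three-criterion pseudo-absences,
# and return the training dataset on the fine climate stack
make_benchmark_dataset <- function(land, niche, n = 130, seed = 1,
                                   use_habitat_mask = TRUE) {
  truth <- true_suitability(land$climate_fine, niche)
  occ <- thin_occurrences(sample_occurrences(truth, n, seed = seed),
                          land$dem)
  stack <- land$climate_fine
  sre_map <- classify_sre(fit_sre(occ, stack, 0.025), stack)
  pa <- sample_pseudo_absences(occ, sre_map,
                               habitat_mask = if (use_habitat_mask)
                                 habitat_cover_mask(truth),
                               study_mask = land$study, seed = seed + 1)
  extract_training_table(stack, pa)
}

# light random-forest ensemble for recovery tests
fit_light_ensemble <- function(dataset, seed, repetitions = 2) {
  runs <- run_members(dataset, "random_forest",
                      cv_config(k = 3, repetitions = repetitions, runs = 1,
                                seed = seed), ntree = 200)
  build_ensemble(runs)
}
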