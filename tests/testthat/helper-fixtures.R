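# Shared fixtures, built in code. Simulated datasets are cached per
# (n, seed, params) so expensive cohorts are generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

params_key <- function(params) paste(signif(unlist(params), 10), collapse = "_")

# labeled feature dataset from a fully simulated cohort (signals + pipeline)
cached_pipeline_dataset <- function(n, seed, params = physio_params()) {
  key <- paste("ds", n, seed, params_key(params), sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    study <- simulate_cohort(n, params = params, seed = seed)
    .fixture_cache[[key]] <- build_labeled_dataset(study)
  }
  .fixture_cache[[key]]
}

# generator configuration with identical hydrated/dehydrated distributions
null_physio_params <- function() {
  physio_params(ortho_delta_deh_mean = 14, ortho_delta_deh_sd = 8)
}

# a labeled dataset with directly constructed features (no signal pipeline):
# full crossover design, features drawn by `feature_fun(label, n_rows)`
design_dataset <- function(n_participants, feature_fun, seed = 1) {
  set.seed(seed)
  sched <- battery_schedule()
  grid <- expand.grid(session_type = c("NO_FLUID", "FLUID_REPLACED"),
                      timing = c("PRE_EXERCISE", "POST_EXERCISE"),
                      participant_id = seq_len(n_participants),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    lab <- ifelse(g$session_type == "NO_FLUID" & g$timing == "POST_EXERCISE",
                  "DEHYDRATED", "EUHYDRATED")
    data.frame(participant_id = g$participant_id,
               session_type = g$session_type, timing = g$timing,
               movement_type = sched$movement_type,
               repetition = sched$repetition,
               label = lab, stringsAsFactors = FALSE)
  }))
  f <- feature_fun(rows$label, nrow(rows))
  rows$d1 <- f[, 1L]; rows$d2 <- f[, 2L]; rows$d3 <- f[, 3L]
  class(rows) <- c("hyd_dataset", "data.frame")
  rows
}

# gaussian features whose third component carries the class signal
signal_features <- function(shift = 2) {
  function(label, n) {
    f <- matrix(rnorm(3 * n), ncol = 3)
    f[, 3] <- f[, 3] + ifelse(label == "DEHYDRATED", shift, 0)
    f
  }
}

# values of a sensor_series in [from, to)
window_ref <- function(s, from, to) s$values[s$time >= from & s$time < to]

# independent restatement of the labeling rule
hydration_label_ref <- function(session_type, timing) {
  ifelse(session_type == "NO_FLUID" & timing == "POST_EXERCISE",
         "DEHYDRATED", "EUHYDRATED")
}

table1_path <- function() {
  system.file("extdata", "table1_participants.csv", package = "hydrostatus")
}

# single-movement schedule (three 30-s toe-touch reps), cheap for IO tests
tiny_schedule <- function() {
  battery_schedule(specs = movement_specs()[movement_specs()$movement_type == "TOE_TOUCH_30S", ])
}
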