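# Shared small-world fixtures, built once per test run.

.wf_cache <- new.env()

tiny_config <- function(...) {
  args <- list(seed = 11, years = 5, coarse_rows = 2, coarse_cols = 2,
               fine_factor = 2, n_countries = 2, census_noise = 0.05)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(world_config, args)
}

# A cached pipeline run on the tiny world (computed on first use).
tiny_run <- function() {
  if (is.null(.wf_cache$run)) .wf_cache$run <- wf_pipeline(tiny_config())
  .wf_cache$run
}

# Cached zero-noise run for self-consistency checks.
tiny_run_noise0 <- function() {
  if (is.null(.wf_cache$run0)) {
    .wf_cache$run0 <- wf_pipeline(tiny_config(census_noise = 0))
  }
  .wf_cache$run0
}

# A single-cell forcing series with ET0, for engine-level tests.
cell_forcing <- function(config = tiny_config(), cell = 1) {
  key <- paste0("forcing_", config$seed, "_", cell, "_", config$years)
  if (is.null(.wf_cache[[key]])) {
    w <- generate_weather(config, cell)
    info <- wfcrop:::world_cells(config)
    info <- info[info$cell == cell, ]
    .wf_cache[[key]] <- reference_et0(w, latitude = info$lat, elevation = 100)
  }
  .wf_cache[[key]]
}

crop_row <- function(name) {
  p <- crop_parameters()
  p[p$crop == name, ]
}

policy_row <- function(name) {
  p <- irrigation_policies()
  p[p$crop == name, ]
}

# The default synthetic world (4x4 coarse grid, 3 countries, 12 years),
# cached for the acceptance checks.
default_run <- function() {
  if (is.null(.wf_cache$default)) {
    .wf_cache$default <- wf_pipeline(world_config(seed = 42))
  }
  .wf_cache$default
}

default_run_noise0 <- function() {
  if (is.null(.wf_cache$default0)) {
    .wf_cache$default0 <- wf_pipeline(world_config(seed = 42, census_noise = 0))
  }
  .wf_cache$default0
}
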