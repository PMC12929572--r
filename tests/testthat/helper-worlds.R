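# Shared synthetic worlds, generated once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .world_cache)) assign(key, force(expr), .world_cache)
  get(key, .world_cache)
}

# small noisy world with default missingness
tiny_world <- function() cached("tiny", generate_world(world_config(
  n_rows = 10, n_cols = 10, date_start = "2016-01-01",
  date_end = "2016-06-30", n_stations = 12, seed = 3)))

# noise-free, field-free, fully observed: Ta is an exact linear function
clean_world <- function() cached("clean", generate_world(world_config(
  n_rows = 10, n_cols = 10, date_start = "2016-01-01",
  date_end = "2016-12-31", n_stations = 12, noise_sd = 0, field_sd = 0,
  missing_frac_target = 0, seed = 5)))

generating_features <- function() names(default_coefficients())

# training table of a world, rows with any missing feature dropped
world_table <- function(w, features = generating_features()) {
  tab <- extract_station_values(w$predictors[features], station_table(w))
  tab[stats::complete.cases(tab[features]), ]
}
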