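#' Default run configuration
#'
#' The full configuration tree with every parameter at its default, the
#' baseline that [load_config()] overlays a user file onto. Sections:
#' `environment` (geometry and nectar dynamics), `bee` (cognitive and
#' physical parameters), `simulation` (colony size, horizon, seed) and
#' `sweep` (replication counts).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    schema_version = "1",
    environment = list(layout = "uniform", n_sites = 25L, arena_side = 500,
                       density = NULL, n_max = 20, renewal_duration = 1500),
    bee = list(alpha = 0.5, beta = 20, wm_span = 30, speed = 3,
               max_bout_distance = 3000, nest_wait = 300,
               value_basis = "standing"),
    simulation = list(n_bees = 1L, horizon = 25200, dt = 1, rng_seed = 1L),
    sweep = list(n_environments = 5L, sims_per_environment = 2L,
                 reporting_bout = NULL)
  )
}

config_ranges <- function() {
  # key -> c(min, max); NA bound = unbounded
  list(
    "environment.n_sites" = c(2, Inf),
    "environment.arena_side" = c(1e-9, Inf),
    "environment.density" = c(1e-12, Inf),
    "environment.n_max" = c(1e-9, Inf),
    "environment.renewal_duration" = c(1e-9, Inf),
    "bee.alpha" = c(0, 1),
    "bee.beta" = c(0, Inf),
    "bee.wm_span" = c(1e-9, Inf),
    "bee.speed" = c(1e-9, Inf),
    "bee.max_bout_distance" = c(1e-9, Inf),
    "bee.nest_wait" = c(1e-9, Inf),
    "simulation.n_bees" = c(1, Inf),
    "simulation.horizon" = c(1e-9, Inf),
    "simulation.dt" = c(1e-9, Inf),
    "sweep.n_environments" = c(1, Inf),
    "sweep.sims_per_environment" = c(1, Inf),
    "sweep.reporting_bout" = c(1, Inf)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, overlays it on [default_config()], rejects
#' unknown keys and checks every numeric parameter against its documented
#' range (errors name the offending key, e.g. `"bee.alpha"`). An empty file
#' yields the all-defaults configuration.
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `run_config`.
#' @seealso [echo_config()] for writing the effective configuration next to
#'   a run's outputs.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  for (sec in names(user)) {
    if (sec == "schema_version") { cfg$schema_version <- user[[sec]]; next }
    if (!sec %in% names(cfg))
      stop("unknown config section: ", sec, call. = FALSE)
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key, call. = FALSE)
      # preserve explicit nulls without dropping the list element
      cfg[[sec]][key] <- list(user[[sec]][[key]])
    }
  }
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  ranges <- config_ranges()
  for (key in names(ranges)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (is.null(val)) next
    if (key == "bee.wm_span" && identical(val, "matched")) next
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("config key ", key, " must be a finite number", call. = FALSE)
    r <- ranges[[key]]
    if (val < r[1] || val > r[2])
      stop(sprintf("config key %s = %g outside its allowed range [%g, %g]",
                   key, val, r[1], r[2]), call. = FALSE)
  }
  if (!cfg$environment$layout %in% c("uniform", "patch"))
    stop("config key environment.layout must be 'uniform' or 'patch'",
         call. = FALSE)
  if (cfg$environment$layout == "patch" && is.null(cfg$environment$density))
    stop("config key environment.density is required for patch layouts",
         call. = FALSE)
  invisible(cfg)
}

#' Write the effective configuration next to a run's outputs
#'
#' Serialises the post-default configuration to `config_echo.yaml` in
#' `out_dir`, so any result directory carries the full provenance needed to
#' reproduce it (together with the master seed it already contains).
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if missing).
#' @return The echo file path, invisibly.
#' @export
echo_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build an environment / bee parameters / simulation call from a config
#'
#' Helpers mapping a validated `run_config` onto the package's constructors:
#' `config_environment()` draws the environment, `config_params()` builds the
#' [bee_params()], and `config_simulation()` runs the whole thing.
#'
#' @param cfg a `run_config`.
#' @param rng_seed seed overriding `simulation.rng_seed` (e.g. from the
#'   command line); `NULL` keeps the config value.
#' @return See each constructor.
#' @export
config_environment <- function(cfg, rng_seed = NULL) {
  e <- cfg$environment
  seed <- if (is.null(rng_seed)) cfg$simulation$rng_seed else rng_seed
  seed <- derive_seed(seed, "config/env")
  if (e$layout == "patch") {
    generate_patch(e$n_sites, e$density, e$arena_side, rng_seed = seed,
                   max_nectar = e$n_max, renewal_duration = e$renewal_duration)
  } else {
    generate_uniform(e$n_sites, e$arena_side, rng_seed = seed,
                     max_nectar = e$n_max, renewal_duration = e$renewal_duration)
  }
}

#' @rdname config_environment
#' @export
config_params <- function(cfg) {
  b <- cfg$bee
  wm <- if (identical(b$wm_span, "matched")) cfg$environment$renewal_duration else b$wm_span
  bee_params(alpha = b$alpha, beta = b$beta, wm_span = wm,
             n_max = cfg$environment$n_max, speed = b$speed,
             max_bout_distance = b$max_bout_distance, nest_wait = b$nest_wait,
             value_basis = b$value_basis)
}

#' @rdname config_environment
#' @export
config_simulation <- function(cfg, rng_seed = NULL) {
  seed <- if (is.null(rng_seed)) cfg$simulation$rng_seed else rng_seed
  run_simulation(config_environment(cfg, rng_seed = seed), config_params(cfg),
                 n_bees = cfg$simulation$n_bees,
                 horizon = cfg$simulation$horizon, dt = cfg$simulation$dt,
                 rng_seed = derive_seed(seed, "config/sim"))
}
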