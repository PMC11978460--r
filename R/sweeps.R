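#' Specify a parameter sweep
#'
#' A sweep runs the simulator over a grid of conditions (one row of `grid`
#' per cell), with `n_environments` independent environment draws per cell
#' and `sims_per_environment` simulation replicates per environment, and
#' aggregates the similarity and foraging-success metrics at a reporting
#' bout.
#'
#' Recognised `grid` / `base` fields: `layout` ("uniform" or "patch"),
#' `n_sites`, `density` (patch layouts), `arena_side`, `n_max`,
#' `renewal_duration`, `wm_span` (seconds, or `"matched"` to tie it to the
#' renewal duration), `n_bees`, `alpha`, `beta`, `horizon`, plus any
#' [bee_params()] argument. Environment seeds depend only on the
#' environment-generating fields, so cells differing only in bee parameters
#' (e.g. a learning vs no-learning comparison) run on identical environment
#' draws with common random numbers.
#'
#' @param grid data frame of varied parameters, one row per cell.
#' @param n_environments environment draws per cell.
#' @param sims_per_environment simulation replicates per environment draw.
#' @param reporting_bout bout index at which cell summaries are taken;
#'   `NULL` (default) picks it automatically with [plateau_bout()].
#' @param base named list of shared defaults for fields not in `grid`.
#' @param rng_seed master seed for the whole sweep.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(grid, n_environments = 5L, sims_per_environment = 2L,
                       reporting_bout = NULL, base = list(), rng_seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  if (n_environments < 1L || sims_per_environment < 1L)
    stop("replication counts must be at least 1", call. = FALSE)
  if (!is.null(reporting_bout) && reporting_bout < 1L)
    stop("reporting_bout must be >= 1", call. = FALSE)
  structure(list(grid = grid, n_environments = as.integer(n_environments),
                 sims_per_environment = as.integer(sims_per_environment),
                 reporting_bout = reporting_bout, base = base,
                 rng_seed = rng_seed),
            class = "sweep_spec")
}

sweep_defaults <- function() {
  list(layout = "uniform", n_sites = 25L, density = NA_real_,
       arena_side = 500, n_max = 20, renewal_duration = 1500,
       wm_span = 30, n_bees = 1L, alpha = 0.5, beta = 20,
       horizon = 25200, speed = 3, max_bout_distance = 3000,
       nest_wait = 300, value_basis = "standing")
}

cell_config <- function(spec, cell_row) {
  cfg <- sweep_defaults()
  for (nm in names(spec$base)) cfg[[nm]] <- spec$base[[nm]]
  for (nm in names(spec$grid)) cfg[[nm]] <- spec$grid[[nm]][cell_row]
  if (identical(cfg$wm_span, "matched")) cfg$wm_span <- cfg$renewal_duration
  cfg$wm_span <- as.numeric(cfg$wm_span)
  cfg
}

# environment-label seeds depend only on the fields that shape the
# environment, so bee-parameter contrasts share environment draws
env_stream_label <- function(cfg, e) {
  paste("env", cfg$layout, cfg$n_sites, signif(cfg$density, 10),
        cfg$arena_side, cfg$n_max, cfg$renewal_duration, e, sep = "/")
}

build_cell_env <- function(cfg, seed) {
  if (cfg$layout == "patch") {
    generate_patch(cfg$n_sites, cfg$density, cfg$arena_side, rng_seed = seed,
                   max_nectar = cfg$n_max,
                   renewal_duration = cfg$renewal_duration)
  } else {
    generate_uniform(cfg$n_sites, cfg$arena_side, rng_seed = seed,
                     max_nectar = cfg$n_max,
                     renewal_duration = cfg$renewal_duration)
  }
}

#' Run a parameter sweep
#'
#' Executes every cell of a [sweep_spec()]: generates the environments, runs
#' the simulations, computes per-bout similarity (lags 1 and 2) and foraging
#' success for every bee, and summarises each cell at the reporting bout.
#' Infeasible cells (e.g. a patch larger than the arena) are recorded and
#' skipped. Fully reproducible under the spec's seed.
#'
#' @param spec a [sweep_spec()].
#' @param keep_sims keep the full `trapline_sim` objects (memory-hungry)?
#' @return An object of class `trapline_sweep`: list with `per_bout` (long
#'   data frame: one row per cell x environment x replicate x bee x bout),
#'   `summary` (one row per cell: replicate mean and sd of `si_lag1`,
#'   `si_lag2`, `success` at the reporting bout, plus replicate counts),
#'   `reporting_bout`, `failed` (indices of infeasible cells), `spec`.
#' @export
run_sweep <- function(spec, keep_sims = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  per_bout <- list(); k <- 0L
  failed <- integer(0)
  sims <- if (keep_sims) list() else NULL
  for (cell in seq_len(nrow(spec$grid))) {
    cfg <- cell_config(spec, cell)
    params <- bee_params(alpha = cfg$alpha, beta = cfg$beta,
                         wm_span = cfg$wm_span, n_max = cfg$n_max,
                         speed = cfg$speed,
                         max_bout_distance = cfg$max_bout_distance,
                         nest_wait = cfg$nest_wait,
                         value_basis = cfg$value_basis)
    ok <- TRUE
    for (e in seq_len(spec$n_environments)) {
      env_lab <- env_stream_label(cfg, e)
      env <- tryCatch(build_cell_env(cfg, derive_seed(spec$rng_seed, env_lab)),
                      error = function(err) NULL)
      if (is.null(env)) { ok <- FALSE; break }
      for (s in seq_len(spec$sims_per_environment)) {
        sim <- run_simulation(env, params, n_bees = cfg$n_bees,
                              horizon = cfg$horizon,
                              rng_seed = derive_seed(spec$rng_seed,
                                                     paste0(env_lab, "/sim/", s)),
                              record_events = FALSE)
        if (nrow(sim$bouts) == 0L) next
        m <- bout_metrics(sim)
        m$cell <- cell; m$env_draw <- e; m$replicate <- s
        k <- k + 1L
        per_bout[[k]] <- m
        if (keep_sims) sims[[length(sims) + 1L]] <- sim
      }
    }
    if (!ok) failed <- c(failed, cell)
  }
  per_bout <- if (k) do.call(rbind, per_bout) else NULL
  rb <- spec$reporting_bout
  if (is.null(rb) && !is.null(per_bout)) {
    rb <- auto_reporting_bout(per_bout)
  }
  structure(list(per_bout = per_bout,
                 summary = summarise_cells(per_bout, spec$grid, rb),
                 reporting_bout = rb, failed = failed, spec = spec,
                 sims = sims),
            class = "trapline_sweep")
}

# plateau of the per-bout mean similarity, per cell; report at the latest
# plateau reachable by most replicates of every cell
auto_reporting_bout <- function(per_bout) {
  per_cell <- split(per_bout, per_bout$cell)
  plateaus <- vapply(per_cell, function(d) {
    mu <- tapply(d$si_lag1, d$bout_index, mean, na.rm = TRUE)
    plateau_bout(as.numeric(mu))
  }, numeric(1))
  depth <- vapply(per_cell, function(d) {
    reps <- split(d$bout_index, interaction(d$env_draw, d$replicate, d$bee_id,
                                            drop = TRUE))
    stats::median(vapply(reps, max, numeric(1)))
  }, numeric(1))
  max(1L, min(max(plateaus), min(depth) - 2L))
}

summarise_cells <- function(per_bout, grid, reporting_bout) {
  if (is.null(per_bout)) return(NULL)
  at <- per_bout[per_bout$bout_index == reporting_bout, , drop = FALSE]
  # average over bees within a simulation first, then across replicates
  sim_means <- stats::aggregate(
    cbind(si_lag1, si_lag2, success) ~ cell + env_draw + replicate, data = at,
    FUN = function(z) mean(z, na.rm = TRUE), na.action = stats::na.pass)
  out <- do.call(rbind, lapply(split(sim_means, sim_means$cell), function(d) {
    data.frame(cell = d$cell[1],
               si_lag1 = mean(d$si_lag1, na.rm = TRUE),
               si_lag1_sd = stats::sd(d$si_lag1[!is.na(d$si_lag1)]),
               si_lag2 = mean(d$si_lag2, na.rm = TRUE),
               si_lag2_sd = stats::sd(d$si_lag2[!is.na(d$si_lag2)]),
               success = mean(d$success, na.rm = TRUE),
               success_sd = stats::sd(d$success[!is.na(d$success)]),
               n_replicates = nrow(d))
  }))
  out <- cbind(grid[out$cell, , drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' @export
print.trapline_sweep <- function(x, ...) {
  cat(sprintf("<trapline_sweep> %d cell(s), reporting bout %s\n",
              nrow(x$spec$grid), format(x$reporting_bout)))
  if (length(x$failed))
    cat("  infeasible cells skipped:", paste(x$failed, collapse = ", "), "\n")
  if (!is.null(x$summary)) print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot a sweep summary
#'
#' Base-graphics line plot of a cell-summary metric against a grid variable,
#' one line per level of an optional grouping variable — the layout of the
#' renewal, spacing and competition figures.
#'
#' @param x a `trapline_sweep`.
#' @param xvar name of the grid column for the x-axis.
#' @param yvar summary metric (`"si_lag1"`, `"si_lag2"` or `"success"`).
#' @param group optional grid column drawn as separate lines.
#' @param ... passed to [graphics::matplot()].
#' @return The summary data frame, invisibly.
#' @export
plot.trapline_sweep <- function(x, xvar, yvar = "si_lag1", group = NULL, ...) {
  s <- x$summary
  if (is.null(s)) stop("sweep has no summary to plot", call. = FALSE)
  if (is.null(group)) {
    graphics::plot(s[[xvar]], s[[yvar]], type = "b", xlab = xvar, ylab = yvar, ...)
  } else {
    lv <- unique(s[[group]])
    xs <- sort(unique(s[[xvar]]))
    ym <- sapply(lv, function(g)
      s[[yvar]][s[[group]] == g][order(s[[xvar]][s[[group]] == g])])
    graphics::matplot(xs, ym, type = "b", pch = 1, xlab = xvar, ylab = yvar, ...)
    graphics::legend("topleft", legend = paste(group, "=", lv),
                     col = seq_along(lv), lty = seq_along(lv), bty = "n")
  }
  invisible(s)
}

#' Earliest plateau of a per-bout metric series
#'
#' Finds the earliest index after which the (rolling-mean smoothed) series
#' changes, step to step, by less than `tolerance` in relative terms for all
#' subsequent steps. Used to automate the choice of the reporting bout,
#' which is otherwise confirmed visually.
#'
#' @param series numeric per-bout means, bout order.
#' @param tolerance maximal relative step-to-step change inside the plateau.
#' @param window rolling-mean window (1 = raw series).
#' @return Plateau start index (on the original bout scale). If the series
#'   never settles, the last index, with a warning.
#' @export
plateau_bout <- function(series, tolerance = 0.05, window = 1L) {
  series <- series[!is.na(series)]
  n <- length(series)
  if (n < 3L) stop("series must have at least 3 bouts", call. = FALSE)
  r <- if (window > 1L) {
    stats::filter(series, rep(1 / window, window), sides = 1)
  } else series
  r <- as.numeric(r)
  ok <- !is.na(r)
  rel <- abs(diff(r[ok])) / pmax(abs(r[ok][-sum(ok)]), 1e-12)
  settled <- rev(cumprod(rev(rel < tolerance))) == 1
  first <- which(settled)[1]
  if (is.na(first)) {
    warning("series did not reach a plateau; returning the last bout")
    return(n)
  }
  which(ok)[first]
}

#' Learning vs no-learning foraging-success comparison
#'
#' Pairs, over a grid of patch spacings, a learning forager against a
#' no-learning control with noisy decisions (`alpha = 0`, `beta = 2`), on
#' identical environment draws, and reports the per-spacing difference in
#' foraging success. Learners pull ahead as feeding sites grow farther
#' apart; with very close sites the two perform similarly.
#'
#' @param densities numeric vector of patch densities (sites per square
#'   metre) defining the spacing grid, high density = close sites.
#' @param n_sites sites per patch.
#' @param learner,control [bee_params()]-style lists with at least `alpha`
#'   and `beta`.
#' @inheritParams sweep_spec
#' @param ... further `base` fields passed to [sweep_spec()].
#' @return A data frame, one row per density: mean learner and control
#'   success, their difference, and the mean inter-site distance proxy for
#'   the spacing axis.
#' @export
control_comparison <- function(densities, n_sites = 10L,
                               learner = list(alpha = 0.5, beta = 20),
                               control = list(alpha = 0, beta = 2),
                               n_environments = 5L, sims_per_environment = 2L,
                               reporting_bout = NULL, rng_seed = 1L, ...) {
  grid <- expand.grid(density = densities,
                      forager = c("learner", "control"),
                      stringsAsFactors = FALSE)
  grid$alpha <- ifelse(grid$forager == "learner", learner$alpha, control$alpha)
  grid$beta <- ifelse(grid$forager == "learner", learner$beta, control$beta)
  grid$layout <- "patch"
  grid$n_sites <- n_sites
  sw <- run_sweep(sweep_spec(grid, n_environments = n_environments,
                             sims_per_environment = sims_per_environment,
                             reporting_bout = reporting_bout,
                             base = list(...), rng_seed = rng_seed))
  s <- sw$summary
  out <- do.call(rbind, lapply(split(s, s$density), function(d) {
    data.frame(density = d$density[1],
               learner_success = d$success[d$forager == "learner"],
               control_success = d$success[d$forager == "control"])
  }))
  out$advantage <- out$learner_success - out$control_success
  out$mean_distance <- vapply(out$density, function(dd)
    mean_intersite_distance(n_sites, dd, n_environments = 200,
                            rng_seed = rng_seed), numeric(1))
  out <- out[order(out$mean_distance), ]
  rownames(out) <- NULL
  out
}
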