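#' Canonical sweep specifications
#'
#' Pre-configured [sweep_spec()]s for the three experiments the simulator is
#' built around, at desk scale (a few environment draws and replicates per
#' cell; raise `n_environments` / `sims_per_environment` towards 25 x 2 for
#' full-scale replication).
#'
#' `spacing_sweep_spec()` varies the spacing and number of feeding sites of
#' a patch exploited by a single forager: repetitiveness rises with
#' inter-site distance when sites are plentiful, and the effect fades when
#' only a few sites are available.
#'
#' `renewal_sweep_spec()` crosses nectar renewal duration with the
#' working-memory span (a short 30 s span vs a span matched to the renewal
#' duration) for a single forager on 25 uniformly placed sites: a short
#' memory loses both routine and efficiency as renewal slows, a matched
#' memory keeps efficiency high and switches to alternating between two
#' routes once the span exceeds the bout cycle.
#'
#' `competition_sweep_spec()` varies colony size under fast and slow renewal
#' on 25 uniformly placed sites whose total capacity fills five crops:
#' route similarity and foraging success fall as foragers are added, the
#' more steeply the slower the renewal.
#'
#' @param densities patch densities (sites per square metre); low density =
#'   widely spaced sites.
#' @param n_sites numbers of feeding sites.
#' @param renewal_durations nectar renewal durations, seconds.
#' @param wm_spans working-memory spans: seconds, or `"matched"`.
#' @param n_bees colony sizes.
#' @param n_environments,sims_per_environment replication per cell.
#' @param reporting_bout bout at which cells are summarised.
#' @param rng_seed master seed.
#' @return A [sweep_spec()].
#' @name canonical_sweeps
NULL

#' @rdname canonical_sweeps
#' @export
spacing_sweep_spec <- function(densities = c(0.01, 0.002, 2e-4),
                               n_sites = c(5L, 25L),
                               n_environments = 5L, sims_per_environment = 2L,
                               reporting_bout = 10L, rng_seed = 1L) {
  grid <- expand.grid(density = densities, n_sites = n_sites)
  grid$layout <- "patch"
  sweep_spec(grid, n_environments = n_environments,
             sims_per_environment = sims_per_environment,
             reporting_bout = reporting_bout,
             base = list(arena_side = 1000, renewal_duration = 500,
                         wm_span = 30, n_bees = 1L, horizon = 18000),
             rng_seed = rng_seed)
}

#' @rdname canonical_sweeps
#' @export
renewal_sweep_spec <- function(renewal_durations = c(100, 500, 1000, 1500),
                               wm_spans = c("30", "matched"),
                               n_environments = 2L, sims_per_environment = 1L,
                               reporting_bout = 15L, rng_seed = 1L) {
  grid <- expand.grid(renewal_duration = renewal_durations,
                      wm_span = wm_spans, stringsAsFactors = FALSE)
  sweep_spec(grid, n_environments = n_environments,
             sims_per_environment = sims_per_environment,
             reporting_bout = reporting_bout,
             base = list(layout = "uniform", n_sites = 25L, arena_side = 500,
                         n_bees = 1L, horizon = 25200),
             rng_seed = rng_seed)
}

#' @rdname canonical_sweeps
#' @export
competition_sweep_spec <- function(n_bees = c(1L, 5L, 10L),
                                   renewal_durations = c(200, 1500),
                                   n_environments = 2L,
                                   sims_per_environment = 1L,
                                   reporting_bout = 15L, rng_seed = 1L) {
  grid <- expand.grid(n_bees = n_bees, renewal_duration = renewal_durations)
  sweep_spec(grid, n_environments = n_environments,
             sims_per_environment = sims_per_environment,
             reporting_bout = reporting_bout,
             base = list(layout = "uniform", n_sites = 25L, arena_side = 500,
                         wm_span = 30, horizon = 25200),
             rng_seed = rng_seed)
}

#' Average a sweep summary over several master seeds
#'
#' Re-runs a sweep-spec constructor under each seed and averages the cell
#' summaries, the replication pattern used when a directional effect is read
#' off a stochastic sweep.
#'
#' @param spec_fun function(`rng_seed`) returning a [sweep_spec()].
#' @param seeds integer vector of master seeds.
#' @return The first sweep's summary grid with `si_lag1`, `si_lag2` and
#'   `success` replaced by their across-seed means.
#' @export
sweep_over_seeds <- function(spec_fun, seeds) {
  sums <- lapply(seeds, function(s) run_sweep(spec_fun(s))$summary)
  out <- sums[[1]]
  for (v in c("si_lag1", "si_lag2", "success")) {
    out[[v]] <- rowMeans(sapply(sums, function(d) d[[v]]), na.rm = TRUE)
    out[[paste0(v, "_sd")]] <- apply(sapply(sums, function(d) d[[v]]), 1,
                                     stats::sd, na.rm = TRUE)
  }
  out$n_seeds <- length(seeds)
  out
}
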