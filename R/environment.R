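#' Construct a foraging environment
#'
#' An environment is a square arena of side `arena_side` metres centred on the
#' nest at the origin, holding `n` feeding sites. Each site is a renewing
#' nectar source: when (partially) emptied by a forager its nectar refills
#' linearly until it reaches the site's maximal load `max_nectar`.
#'
#' @param x,y numeric site coordinates in metres, inside
#'   `[-arena_side/2, arena_side/2]`.
#' @param arena_side side length of the square arena, metres.
#' @param max_nectar maximal nectar load per site, microlitres.
#' @param renewal_duration time for a site to refill from empty to full,
#'   seconds.
#' @param layout_kind `"uniform"`, `"patch"` or `"manual"`; recorded for
#'   provenance only.
#' @return An object of class `trapline_env`: a list with elements
#'   `sites` (data frame: `id`, `x`, `y`, `nectar`, `max_nectar`,
#'   `renewal_duration`), `arena_side`, `nest` (always `c(0, 0)`) and
#'   `layout_kind`. Site ids are contiguous integers starting at 1.
#' @seealso [generate_uniform()], [generate_patch()]
#' @export
new_environment <- function(x, y, arena_side, max_nectar = 20,
                            renewal_duration = 1500,
                            layout_kind = "manual") {
  n <- length(x)
  if (n < 2L) stop("an environment needs at least 2 feeding sites", call. = FALSE)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (!is.numeric(arena_side) || arena_side <= 0)
    stop("arena_side must be a positive length in metres", call. = FALSE)
  if (max_nectar <= 0 || renewal_duration <= 0)
    stop("max_nectar and renewal_duration must be positive", call. = FALSE)
  half <- arena_side / 2
  if (any(abs(x) > half + 1e-9) || any(abs(y) > half + 1e-9))
    stop("all site positions must lie inside the arena", call. = FALSE)
  env <- structure(
    list(
      sites = data.frame(
        id = seq_len(n),
        x = as.numeric(x), y = as.numeric(y),
        nectar = rep(as.numeric(max_nectar), n),
        max_nectar = rep(as.numeric(max_nectar), n),
        renewal_duration = rep(as.numeric(renewal_duration), n)
      ),
      arena_side = as.numeric(arena_side),
      nest = c(0, 0),
      layout_kind = layout_kind
    ),
    class = "trapline_env"
  )
  env
}

#' @export
print.trapline_env <- function(x, ...) {
  cat(sprintf(
    "<trapline_env> %d feeding sites, %s layout, arena %g x %g m\n",
    nrow(x$sites), x$layout_kind, x$arena_side, x$arena_side))
  cat(sprintf("  nectar: max %g ul per site, renewal %g s (empty -> full)\n",
              x$sites$max_nectar[1], x$sites$renewal_duration[1]))
  invisible(x)
}

#' Generate an environment with uniformly placed feeding sites
#'
#' Site coordinates are drawn independently and uniformly over the square
#' arena `[-arena_side/2, arena_side/2]^2`; the nest sits at the origin. All
#' sites start at full nectar.
#'
#' @param n_sites number of feeding sites (at least 2).
#' @param arena_side side length of the square arena, metres.
#' @param rng_seed integer seed; the same seed reproduces the same layout
#'   bit-for-bit.
#' @inheritParams new_environment
#' @return A [new_environment()] object with `layout_kind = "uniform"`.
#' @examples
#' env <- generate_uniform(25, arena_side = 500, rng_seed = 1)
#' env
#' @export
generate_uniform <- function(n_sites, arena_side, rng_seed,
                             max_nectar = 20, renewal_duration = 1500) {
  if (n_sites < 2L) stop("n_sites must be at least 2", call. = FALSE)
  if (arena_side <= 0) stop("arena_side must be positive", call. = FALSE)
  half <- arena_side / 2
  xy <- local_seed(rng_seed, {
    cbind(stats::runif(n_sites, -half, half), stats::runif(n_sites, -half, half))
  })
  new_environment(xy[, 1], xy[, 2], arena_side,
                  max_nectar = max_nectar, renewal_duration = renewal_duration,
                  layout_kind = "uniform")
}

#' Radius of a patch of feeding sites
#'
#' For `n_sites` sites at density `density` (sites per square metre) the
#' default radius is `sqrt(n_sites / (pi * density))`, i.e. the radius of the
#' disc whose area holds `n_sites` sites at that density. The alternative
#' `formula = "literal"` reads the radius directly as
#' `n_sites / (pi * density)`.
#'
#' @param n_sites number of sites in the patch.
#' @param density patch density, sites per square metre.
#' @param formula `"sqrt_density"` (default) or `"literal"`.
#' @return Patch radius in metres.
#' @export
patch_radius <- function(n_sites, density, formula = c("sqrt_density", "literal")) {
  formula <- match.arg(formula)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  switch(formula,
         sqrt_density = sqrt(n_sites / (pi * density)),
         literal = n_sites / (pi * density))
}

#' Generate an environment with feeding sites clustered in a patch
#'
#' The patch centre is drawn uniformly over the arena shrunk by `buffer` on
#' every side, so the whole patch fits inside the arena; each site is then
#' placed uniformly over the disc of radius [patch_radius()] around the
#' centre (area-uniform, via square-root radius sampling).
#'
#' @inheritParams generate_uniform
#' @param density patch density, sites per square metre.
#' @param buffer margin in metres between the patch centre and the arena
#'   edge; defaults to the patch radius, which guarantees containment.
#' @param radius_formula passed to [patch_radius()].
#' @return A [new_environment()] object with `layout_kind = "patch"`. The
#'   patch centre is stored in attribute `"patch_centre"`.
#' @examples
#' env <- generate_patch(10, density = 0.008, arena_side = 500, rng_seed = 7)
#' @export
generate_patch <- function(n_sites, density, arena_side, rng_seed,
                           buffer = NULL, max_nectar = 20,
                           renewal_duration = 1500,
                           radius_formula = c("sqrt_density", "literal")) {
  if (n_sites < 2L) stop("n_sites must be at least 2", call. = FALSE)
  r <- patch_radius(n_sites, density, match.arg(radius_formula))
  if (is.null(buffer)) buffer <- r
  half <- arena_side / 2
  if (buffer < r - 1e-9)
    warning("buffer smaller than patch radius: sites may fall outside the arena")
  if (half - buffer < 0)
    stop(sprintf("patch (radius %.3g m + buffer) does not fit inside the arena", r),
         call. = FALSE)
  pts <- local_seed(rng_seed, {
    cx <- stats::runif(1, -(half - buffer), half - buffer)
    cy <- stats::runif(1, -(half - buffer), half - buffer)
    rad <- r * sqrt(stats::runif(n_sites))
    ang <- stats::runif(n_sites, 0, 2 * pi)
    list(centre = c(cx, cy), x = cx + rad * cos(ang), y = cy + rad * sin(ang))
  })
  env <- new_environment(pts$x, pts$y, arena_side,
                         max_nectar = max_nectar,
                         renewal_duration = renewal_duration,
                         layout_kind = "patch")
  attr(env, "patch_centre") <- pts$centre
  env
}

#' Mean inter-site distance of a patch specification
#'
#' Monte-Carlo estimate of the average distance between feeding sites of a
#' patch with the given `n_sites` and `density`, averaged over
#' `n_environments` independently generated patches. This is the spacing
#' proxy used on the x-axis of spatial sweeps: the patch density parameter is
#' converted to the more interpretable "average distance between feeding
#' sites".
#'
#' @inheritParams generate_patch
#' @param n_environments number of patches to average over.
#' @param kind `"pairwise"` (default) averages all site pairs;
#'   `"nearest_neighbour"` averages each site's distance to its nearest
#'   neighbour.
#' @return Mean inter-site distance in metres.
#' @export
mean_intersite_distance <- function(n_sites, density, n_environments = 1000,
                                    rng_seed = 1, arena_side = 1e6,
                                    kind = c("pairwise", "nearest_neighbour"),
                                    radius_formula = "sqrt_density") {
  kind <- match.arg(kind)
  if (n_environments < 1L) stop("n_environments must be at least 1", call. = FALSE)
  vals <- vapply(seq_len(n_environments), function(i) {
    env <- generate_patch(n_sites, density, arena_side,
                          rng_seed = derive_seed(rng_seed, paste0("misd/", i)),
                          radius_formula = radius_formula)
    d <- stats::dist(as.matrix(env$sites[, c("x", "y")]))
    if (kind == "pairwise") {
      mean(d)
    } else {
      dm <- as.matrix(d); diag(dm) <- Inf
      mean(apply(dm, 1L, min))
    }
  }, numeric(1))
  mean(vals)
}

#' Renew a site's nectar over an elapsed interval
#'
#' Nectar refills linearly at rate `max_nectar / renewal_duration`, clipped
#' at `max_nectar`: an undisturbed site starting empty holds
#' `max_nectar * min(1, t / renewal_duration)` after `t` seconds.
#'
#' @param nectar current load(s), microlitres. Vectorised.
#' @param dt elapsed time, seconds (non-negative).
#' @param max_nectar maximal load, microlitres.
#' @param renewal_duration empty-to-full refill time, seconds.
#' @return Renewed nectar load(s), microlitres.
#' @examples
#' renew_step(0, dt = 750, max_nectar = 20, renewal_duration = 1500)  # 10
#' @export
renew_step <- function(nectar, dt, max_nectar, renewal_duration) {
  if (any(dt < 0)) stop("dt must be non-negative", call. = FALSE)
  pmin(max_nectar, nectar + max_nectar * dt / renewal_duration)
}

#' Write / read an environment as plain text
#'
#' The site table goes to `<path>.csv` (columns `id`, `x`, `y`, `max_nectar`,
#' `renewal_duration`) and the scalars (`arena_side`, `layout_kind`) to a
#' JSON sidecar `<path>.json`. [read_environment()] round-trips exactly.
#'
#' @param env a `trapline_env`.
#' @param path file path stem (without extension).
#' @return `write_environment()` returns `path` invisibly;
#'   `read_environment()` returns a `trapline_env` at full nectar.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "trapline_env"))
  utils::write.csv(env$sites[, c("id", "x", "y", "max_nectar", "renewal_duration")],
                   paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(arena_side = env$arena_side,
                            layout_kind = env$layout_kind),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  sites <- utils::read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_environment(sites$x, sites$y, meta$arena_side,
                  max_nectar = sites$max_nectar[1],
                  renewal_duration = sites$renewal_duration[1],
                  layout_kind = meta$layout_kind)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  force(expr)
}
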