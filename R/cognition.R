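#' Build the discovery-probability matrix of an environment
#'
#' The discovery probability `p_d(A, B)` approximates the chance of finding
#' location B from location A by random walk. It is proportional to
#' `1 / d(A, B)^2` and row-normalised so that, from every origin, the
#' probabilities over all other locations sum to 1. Locations are the nest
#' (row/column 1) followed by the feeding sites in id order; the diagonal is
#' zero (no self-transition).
#'
#' @param env a `trapline_env`.
#' @return A square numeric matrix of dimension `n_sites + 1` with dimnames
#'   `c("nest", <site ids>)`, zero diagonal, rows summing to 1.
#' @examples
#' env <- generate_uniform(5, 100, rng_seed = 1)
#' rowSums(build_discovery_matrix(env))  # all 1
#' @export
build_discovery_matrix <- function(env) {
  stopifnot(inherits(env, "trapline_env"))
  pos <- rbind(env$nest, as.matrix(env$sites[, c("x", "y")]))
  d <- as.matrix(stats::dist(pos))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    idx <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1, ]
    labs <- c("nest", env$sites$id)
    stop(sprintf("coincident locations: %s and %s", labs[idx[1]], labs[idx[2]]),
         call. = FALSE)
  }
  w <- 1 / d^2
  diag(w) <- 0
  pd <- w / rowSums(w)
  dimnames(pd) <- list(c("nest", env$sites$id), c("nest", env$sites$id))
  pd
}

#' Perceived value of a realised transition
#'
#' On arriving at site B from location A, the forager perceives the value
#' `v = n * p_d`, the standing nectar crop at B weighted by the discovery
#' probability of the transition: transitions to hard-to-find sites are
#' discounted.
#'
#' @param nectar standing nectar crop at the destination, microlitres.
#' @param p_d discovery probability of the transition, in `[0, 1]`.
#' @return Perceived value (microlitre-weighted probability).
#' @export
perceived_value <- function(nectar, p_d) {
  if (any(nectar < 0) || any(p_d < 0) || any(p_d > 1))
    stop("nectar must be >= 0 and p_d in [0, 1]", call. = FALSE)
  nectar * p_d
}

#' Initial expected-value table
#'
#' Expected transition values start at half the best case:
#' `Q0(A, B) = 1/2 * n_max * p_d(A, B)`, so an early reward above (below)
#' half the maximal load raises (lowers) the expectation.
#'
#' @param pd discovery matrix from [build_discovery_matrix()].
#' @param n_max maximal nectar load of a site, microlitres.
#' @return Matrix of the same shape as `pd`.
#' @export
q_init <- function(pd, n_max) {
  0.5 * n_max * pd
}

#' One Q-learning update
#'
#' `Q <- alpha * v + (1 - alpha) * Q`: a convex combination of the newly
#' perceived value and the previous expectation. `alpha = 0` ignores
#' experience (the no-learning control); `alpha = 1` replaces the
#' expectation by the latest value.
#'
#' @param q_prev previous expected value.
#' @param v_new newly perceived value.
#' @param alpha learning rate in `[0, 1]`.
#' @return Updated expected value.
#' @export
q_update <- function(q_prev, v_new, alpha) {
  if (any(alpha < 0) || any(alpha > 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  alpha * v_new + (1 - alpha) * q_prev
}

#' Softmax choice probabilities over allowed destinations
#'
#' The probability of choosing destination B from the current location is
#' `exp(beta * Q(B)) / sum(exp(beta * Q(.)))`, restricted to destinations not
#' excluded by working memory. `beta = 0` gives uniform random choice; large
#' `beta` approaches greedy choice of the highest expected value. Computed
#' with max-subtraction for numerical stability.
#'
#' @param q_row named numeric vector of expected values for the candidate
#'   destinations.
#' @param beta exploration--exploitation parameter, `>= 0`.
#' @param excluded indices or names of destinations to exclude (recently
#'   visited sites held in working memory).
#' @return Numeric vector the same length as `q_row`; excluded entries are 0,
#'   the rest sum to 1. If every destination is excluded, a zero vector with
#'   attribute `"empty" = TRUE` (the engine treats this as "return to nest").
#' @export
choice_probabilities <- function(q_row, beta, excluded = integer(0)) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  p <- numeric(length(q_row))
  names(p) <- names(q_row)
  if (is.character(excluded)) excluded <- match(excluded, names(q_row))
  allowed <- setdiff(seq_along(q_row), excluded)
  if (length(allowed) == 0L) {
    attr(p, "empty") <- TRUE
    return(p)
  }
  z <- beta * q_row[allowed]
  e <- exp(z - max(z))
  p[allowed] <- e / sum(e)
  p
}

#' Sample one destination from a choice distribution
#'
#' Categorical draw from the probabilities returned by
#' [choice_probabilities()], using the current RNG state (reproducible under
#' a fixed seed).
#'
#' @param probabilities numeric vector summing to 1.
#' @return The index of the sampled destination (named, if `probabilities`
#'   is named).
#' @export
choose_next <- function(probabilities) {
  s <- sum(probabilities)
  if (!is.finite(s) || abs(s - 1) > 1e-9 || any(probabilities < 0))
    stop("malformed probability distribution", call. = FALSE)
  u <- stats::runif(1)
  idx <- findInterval(u, cumsum(probabilities)) + 1L
  idx <- min(idx, length(probabilities))  # guard u == 1 edge
  idx
}

#' Cognitive and physical parameters of a forager
#'
#' Bundles the bee's parameters with validation. Defaults describe a
#' nectar-foraging bumblebee: crop capacity equal to five full site loads,
#' straight-line flight at constant speed, and a per-bout flight-distance
#' budget.
#'
#' @param alpha learning rate, in `[0, 1]`. Below 0.5 the bee leans on its
#'   prior expectation, above 0.5 on the latest experience.
#' @param beta softmax exploration--exploitation parameter, `>= 0`.
#' @param wm_span working-memory span, seconds: how long a visited site stays
#'   excluded from destination choices. Use
#'   `wm_span = "matched"` in sweep specs to tie it to the renewal duration.
#' @param crop_capacity crop capacity, microlitres; default five full site
#'   loads of `n_max`.
#' @param speed flight speed, metres per second.
#' @param max_bout_distance flight-distance budget per bout, metres.
#' @param nest_wait time spent in the nest between bouts, seconds.
#' @param n_max maximal site load used for the crop default, microlitres.
#' @param value_basis whether the perceived value uses the nectar standing at
#'   arrival (`"standing"`, default) or the amount actually collected
#'   (`"collected"`); the two differ only when the crop is nearly full.
#' @return A list of class `bee_params`.
#' @export
bee_params <- function(alpha = 0.5, beta = 20, wm_span = 30,
                       n_max = 20, crop_capacity = 5 * n_max,
                       speed = 3, max_bout_distance = 3000,
                       nest_wait = 300,
                       value_basis = c("standing", "collected")) {
  value_basis <- match.arg(value_basis)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  for (nm in c("wm_span", "crop_capacity", "speed", "max_bout_distance", "nest_wait")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("%s must be a positive scalar", nm), call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, wm_span = wm_span,
                 crop_capacity = crop_capacity, speed = speed,
                 max_bout_distance = max_bout_distance,
                 nest_wait = nest_wait, value_basis = value_basis),
            class = "bee_params")
}

#' @export
print.bee_params <- function(x, ...) {
  cat(sprintf(
    "<bee_params> alpha=%g beta=%g wm_span=%gs crop=%gul speed=%gm/s max_dist=%gm nest_wait=%gs\n",
    x$alpha, x$beta, x$wm_span, x$crop_capacity, x$speed,
    x$max_bout_distance, x$nest_wait))
  invisible(x)
}
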