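#' Run a multi-forager simulation
#'
#' Advances one colony of foragers through discrete time on a shared
#' environment. Each bee repeatedly leaves the nest, feeds at successive
#' sites until its crop is full, its flight-distance budget is spent, or
#' every site is inhibited by working memory, then returns to the nest and
#' waits before the next bout. Travel is straight-line at constant speed with
#' travel times rounded up to whole timesteps; feeding and decision-making
#' are instantaneous. Sites renew nectar linearly and are the only channel of
#' interaction between bees: each bee has its own expected-value table and
#' working memory. Bees arriving at the same timestep are processed in
#' randomised order.
#'
#' Every bee draws from its own RNG stream derived from `rng_seed`, so adding
#' a bee leaves the other bees' draws unchanged; tie-breaking and departure
#' staggering use a separate engine stream.
#'
#' @param env a `trapline_env`. Nectar loads are taken at their initial
#'   (full) values.
#' @param params a [bee_params()] object shared by all bees.
#' @param n_bees number of foragers, `>= 1`.
#' @param horizon simulated foraging time in seconds (default 7 h, about one
#'   foraging day). Bouts still in progress at the horizon are discarded.
#' @param dt timestep in seconds.
#' @param rng_seed integer master seed; identical seeds give identical
#'   simulations bit-for-bit.
#' @param record_events keep a per-arrival event log (time, bee, origin,
#'   destination, standing crop, collected, perceived value)?
#' @return An object of class `trapline_sim`: list with
#'   \describe{
#'     \item{bouts}{data frame of completed bouts: `bee_id`, `bout_index`,
#'       `t_start`, `t_end`, `duration`, `nectar_collected`, `distance`,
#'       `n_visits`, and list column `visit_sequence` of site ids.}
#'     \item{events}{arrival log (if recorded).}
#'     \item{q_tables}{final expected-value matrix per bee.}
#'     \item{sites}{per-site final nectar (renewed to the horizon) and total
#'       nectar collected from it.}
#'     \item{env, params, n_bees, horizon, dt, rng_seed}{inputs, echoed.}
#'   }
#' @examples
#' env <- generate_uniform(10, 300, rng_seed = 1)
#' sim <- run_simulation(env, bee_params(), n_bees = 1, horizon = 3600,
#'                       rng_seed = 1)
#' sim
#' @export
run_simulation <- function(env, params, n_bees = 1L, horizon = 25200,
                           dt = 1, rng_seed = 1L, record_events = TRUE) {
  stopifnot(inherits(env, "trapline_env"), inherits(params, "bee_params"))
  if (!is.numeric(n_bees) || n_bees < 1L)
    stop("n_bees must be at least 1", call. = FALSE)
  if (horizon <= 0 || dt <= 0)
    stop("horizon and dt must be positive", call. = FALSE)
  n_bees <- as.integer(n_bees)

  n_sites <- nrow(env$sites)
  n_max <- env$sites$max_nectar[1]
  renew_dur <- env$sites$renewal_duration[1]
  pd <- build_discovery_matrix(env)              # (n_sites+1)^2, row 1 = nest
  q0 <- q_init(pd, n_max)
  pos <- rbind(env$nest, as.matrix(env$sites[, c("x", "y")]))
  dmat <- as.matrix(stats::dist(pos))
  tmat <- ceiling(dmat / (params$speed * dt)) * dt  # travel times, whole steps
  site_cols <- seq_len(n_sites) + 1L             # destination columns (no nest)

  labels <- c("engine", paste0("bee/", seq_len(n_bees)))
  streams <- rng_streams(rng_seed, labels)

  # shared site state: nectar level at last_update, lazily renewed
  level <- env$sites$nectar
  last_update <- numeric(n_sites)
  collected_tot <- numeric(n_sites)
  standing <- function(j, t) {
    renew_step(level[j], t - last_update[j], n_max, renew_dur)
  }

  # per-bee state
  bees <- lapply(seq_len(n_bees), function(i) {
    list(q = q0, loc = 1L, crop = 0, dist = 0, bout = 1L,
         t_start = NA_real_, visits = integer(0),
         last_visit = rep(-Inf, n_sites),
         phase = "depart", next_time = 0, origin = NA_integer_)
  })
  # staggered departures in randomised order break initial symmetry
  stagger <- with_stream(streams, "engine", sample.int(n_bees))
  for (i in seq_len(n_bees)) bees[[i]]$next_time <- (stagger[i] - 1L) * dt

  bouts <- list(); n_bout_rec <- 0L
  events <- list(); n_ev <- 0L

  wm_excluded <- function(bee, t) {
    which(t - bee$last_visit < params$wm_span)
  }

  # choose a destination site (column index into q) or NA if all inhibited
  pick_destination <- function(i, t) {
    bee <- bees[[i]]
    excl <- wm_excluded(bee, t)
    pr <- choice_probabilities(bee$q[bee$loc, site_cols], params$beta,
                               excluded = excl)
    if (isTRUE(attr(pr, "empty"))) return(NA_integer_)
    with_stream(streams, paste0("bee/", i), choose_next(pr)) + 1L
  }

  start_transit <- function(i, dest, t) {
    bees[[i]]$origin <<- bees[[i]]$loc
    bees[[i]]$dist <<- bees[[i]]$dist + dmat[bees[[i]]$loc, dest]
    bees[[i]]$loc <<- dest
    bees[[i]]$phase <<- if (dest == 1L) "return" else "arrive"
    bees[[i]]$next_time <<- t + tmat[bees[[i]]$origin, dest]
  }

  process_event <- function(i, t) {
    bee <- bees[[i]]
    if (bee$phase == "depart") {
      dest <- pick_destination(i, t)
      if (is.na(dest)) {              # every site inhibited: try again next step
        bees[[i]]$next_time <<- t + dt
        return(invisible())
      }
      bees[[i]]$t_start <<- t
      bees[[i]]$crop <<- 0
      bees[[i]]$dist <<- 0
      bees[[i]]$visits <<- integer(0)
      start_transit(i, dest, t)
    } else if (bee$phase == "arrive") {
      j <- bee$loc - 1L               # site index
      n_now <- standing(j, t)
      take <- min(n_now, params$crop_capacity - bee$crop)
      level[j] <<- n_now - take
      last_update[j] <<- t
      collected_tot[j] <<- collected_tot[j] + take
      v <- perceived_value(if (params$value_basis == "standing") n_now else take,
                           pd[bee$origin, bee$loc])
      bees[[i]]$q[bee$origin, bee$loc] <<-
        q_update(bee$q[bee$origin, bee$loc], v, params$alpha)
      bees[[i]]$crop <<- bee$crop + take
      bees[[i]]$last_visit[j] <<- t
      bees[[i]]$visits <<- c(bee$visits, j)
      if (record_events) {
        n_ev <<- n_ev + 1L
        events[[n_ev]] <<- list(time = t, bee_id = i, from = bee$origin - 1L,
                                to = j, standing = n_now, collected = take,
                                value = v)
      }
      bee <- bees[[i]]
      crop_full <- bee$crop >= params$crop_capacity - 1e-9
      dist_out <- bee$dist >= params$max_bout_distance
      dest <- if (crop_full || dist_out) NA_integer_ else pick_destination(i, t)
      if (is.na(dest)) start_transit(i, 1L, t) else start_transit(i, dest, t)
    } else {                          # "return": arrival at the nest
      n_bout_rec <<- n_bout_rec + 1L
      bouts[[n_bout_rec]] <<- list(
        bee_id = i, bout_index = bee$bout, t_start = bee$t_start, t_end = t,
        duration = t - bee$t_start, nectar_collected = bee$crop,
        distance = bee$dist, visit_sequence = bee$visits)
      bees[[i]]$bout <<- bee$bout + 1L
      bees[[i]]$phase <<- "depart"
      bees[[i]]$next_time <<- t + params$nest_wait
    }
    invisible()
  }

  repeat {
    times <- vapply(bees, `[[`, numeric(1), "next_time")
    t <- min(times)
    if (t > horizon) break
    ready <- which(times <= t + 1e-9)
    if (length(ready) > 1L) {         # randomise feeding order within a timestep
      ready <- ready[with_stream(streams, "engine", sample.int(length(ready)))]
    }
    for (i in ready) process_event(i, t)
  }

  # renew all sites up to the horizon for the final snapshot
  final_nectar <- renew_step(level, horizon - last_update, n_max, renew_dur)

  bouts_df <- if (n_bout_rec) {
    df <- do.call(rbind, lapply(bouts, function(b)
      data.frame(bee_id = b$bee_id, bout_index = b$bout_index,
                 t_start = b$t_start, t_end = b$t_end, duration = b$duration,
                 nectar_collected = b$nectar_collected, distance = b$distance,
                 n_visits = length(b$visit_sequence))))
    df$visit_sequence <- I(lapply(bouts, `[[`, "visit_sequence"))
    df
  } else {
    data.frame(bee_id = integer(0), bout_index = integer(0),
               t_start = numeric(0), t_end = numeric(0), duration = numeric(0),
               nectar_collected = numeric(0), distance = numeric(0),
               n_visits = integer(0))
  }
  events_df <- if (record_events && n_ev) {
    do.call(rbind, lapply(events, as.data.frame))
  } else NULL

  structure(list(
    bouts = bouts_df, events = events_df,
    q_tables = lapply(bees, `[[`, "q"),
    sites = data.frame(id = env$sites$id, final_nectar = final_nectar,
                       collected = collected_tot),
    env = env, params = params, n_bees = n_bees, horizon = horizon,
    dt = dt, rng_seed = rng_seed
  ), class = "trapline_sim")
}

#' @export
print.trapline_sim <- function(x, ...) {
  cat(sprintf("<trapline_sim> %d bee(s), %d site(s), horizon %gs, seed %s\n",
              x$n_bees, nrow(x$env$sites), x$horizon, format(x$rng_seed)))
  cat(sprintf("  %d completed bouts, %.1f ul collected in total\n",
              nrow(x$bouts), sum(x$bouts$nectar_collected)))
  invisible(x)
}

#' @export
summary.trapline_sim <- function(object, ...) {
  m <- bout_metrics(object)
  agg <- stats::aggregate(cbind(si_lag1, si_lag2, success) ~ bee_id, data = m,
                          FUN = function(z) mean(z, na.rm = TRUE),
                          na.action = stats::na.pass)
  cat(sprintf("Simulation of %d bee(s) over %g s (%d completed bouts)\n",
              object$n_bees, object$horizon, nrow(object$bouts)))
  cat("Per-bee means over bouts:\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' Write completed bouts to CSV
#'
#' Flattens the visit-sequence list column to a dash-delimited id string so
#' the table round-trips through plain text.
#'
#' @param sim a `trapline_sim`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(sim, path) {
  df <- sim$bouts
  df$visit_sequence <- vapply(df$visit_sequence, paste, character(1),
                              collapse = "-")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bouts
#' @export
read_bouts <- function(path) {
  df <- utils::read.csv(path)
  df$visit_sequence <- I(lapply(strsplit(as.character(df$visit_sequence), "-"),
                                as.integer))
  df
}
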