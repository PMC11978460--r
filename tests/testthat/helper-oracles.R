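# Independent brute-force oracle for the sequence-similarity index.
# Marks position i of `a` iff some window of length n starting at k <= i
# covers i and that window, compared element by element, occurs anywhere in
# `b` (and vice versa). Deliberately naive nested loops, sharing no code
# with similarity_index().
si_oracle <- function(a, b, window = 3L) {
  p <- length(a); q <- length(b)
  if (max(p, q) == 0L) return(NA_real_)
  windows_of <- function(x) {
    k <- length(x) - window + 1L
    if (k < 1L) return(list())
    lapply(seq_len(k), function(i) x[i:(i + window - 1L)])
  }
  occurs_in <- function(w, ws) {
    for (v in ws) if (all(v == w)) return(TRUE)
    FALSE
  }
  wa <- windows_of(a); wb <- windows_of(b)
  mark <- function(x, wx, other_ws) {
    m <- logical(length(x))
    for (k in seq_along(wx)) {
      if (occurs_in(wx[[k]], other_ws)) m[k:(k + window - 1L)] <- TRUE
    }
    m
  }
  s_ab <- sum(mark(a, wa, wb)) + sum(mark(b, wb, wa))
  s_ab / (2 * max(p, q))
}

# a tiny hand-positioned environment: five sites on a ring around the nest
ring_env <- function(n_sites = 5, radius = 50, arena_side = 200,
                     max_nectar = 20, renewal_duration = 100) {
  th <- 2 * pi * seq_len(n_sites) / n_sites
  new_environment(radius * cos(th), radius * sin(th), arena_side,
                  max_nectar = max_nectar,
                  renewal_duration = renewal_duration)
}

# replay a simulation's arrival events against the incremental renewal rule
# and return the per-site final nectar at the horizon
replay_final_nectar <- function(sim) {
  env <- sim$env
  n_max <- env$sites$max_nectar[1]
  rd <- env$sites$renewal_duration[1]
  lvl <- env$sites$nectar
  last <- numeric(nrow(env$sites))
  ev <- sim$events[order(sim$events$time), ]
  for (r in seq_len(nrow(ev))) {
    j <- ev$to[r]; t <- ev$time[r]
    lvl[j] <- renew_step(lvl[j], t - last[j], n_max, rd)
    stopifnot(abs(lvl[j] - ev$standing[r]) < 1e-9)
    lvl[j] <- lvl[j] - ev$collected[r]
    last[j] <- t
  }
  renew_step(lvl, sim$horizon - last, n_max, rd)
}
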