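#' Similarity index between two visit sequences
#'
#' Quantifies how much two foraging bouts share smaller route fragments. Both
#' sequences (feeding-site ids in visit order, nest visits excluded) are
#' decomposed into all contiguous subsequences of length `window` with a
#' sliding window. Every visitation (sequence position) of either bout that
#' lies inside at least one subsequence occurring in *both* bouts is marked;
#' the marked count `S_ab` across both bouts, normalised by twice the longer
#' bout length `l_ab = max(p, q)`, gives
#' `SI = S_ab / (2 * l_ab)`, which is 1 for identical bouts and 0 for bouts
#' sharing no window-length subsequence.
#'
#' A bout shorter than the window contributes no subsequences, so `SI = 0`
#' whenever at least one bout is non-empty but no fragment is shared; if both
#' bouts are empty the index is undefined and `NA` is returned.
#'
#' @param a,b integer vectors of visited site ids, in visit order, repeats
#'   allowed, nest entries already stripped.
#' @param window subsequence length, default 3.
#' @return A list of class `similarity_result`: `si` in `[0, 1]` (or `NA`),
#'   `shared_visit_count` (`S_ab`), `normalizer` (`l_ab`), `window`.
#' @examples
#' similarity_index(1:5, 1:5)$si           # 1
#' similarity_index(1:5, 6:10)$si          # 0
#' similarity_index(c(1, 2, 3, 4), c(1, 2, 3, 5))$si  # 0.75
#' @export
similarity_index <- function(a, b, window = 3L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  p <- length(a); q <- length(b)
  l_ab <- max(p, q)
  if (l_ab == 0L) {
    return(structure(list(si = NA_real_, shared_visit_count = 0L,
                          normalizer = 0L, window = as.integer(window)),
                     class = "similarity_result"))
  }
  s_ab <- 0L
  if (p >= window && q >= window) {
    wa <- window_keys(a, window)
    wb <- window_keys(b, window)
    shared <- intersect(wa, wb)
    if (length(shared)) {
      s_ab <- sum(covered_positions(wa %in% shared, p, window)) +
        sum(covered_positions(wb %in% shared, q, window))
    }
  }
  structure(list(si = s_ab / (2 * l_ab), shared_visit_count = as.integer(s_ab),
                 normalizer = as.integer(l_ab), window = as.integer(window)),
            class = "similarity_result")
}

# string keys of all length-`window` sliding windows of x
window_keys <- function(x, window) {
  k <- length(x) - window + 1L
  vapply(seq_len(k),
         function(i) paste(x[i:(i + window - 1L)], collapse = ","),
         character(1))
}

# logical vector over positions 1..n: position covered by any window whose
# start index is flagged in `hit`
covered_positions <- function(hit, n, window) {
  cov <- logical(n)
  for (i in which(hit)) cov[i:(i + window - 1L)] <- TRUE
  cov
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> SI = %s (S_ab = %d, l_ab = %d, window = %d)\n",
              format(x$si), x$shared_visit_count, x$normalizer, x$window))
  invisible(x)
}

#' Per-bout foraging success
#'
#' Nectar collected per unit time over one foraging bout, in microlitres per
#' second.
#'
#' @param nectar_collected microlitres collected during the bout.
#' @param bout_duration bout duration in seconds (nest departure to nest
#'   return), strictly positive.
#' @return Rate in microlitres per second. Vectorised.
#' @export
foraging_success <- function(nectar_collected, bout_duration) {
  if (any(bout_duration <= 0)) stop("bout_duration must be positive", call. = FALSE)
  nectar_collected / bout_duration
}

#' Similarity series over one bee's bouts
#'
#' Similarity index between bout `k` and bout `k + lag` for every valid `k`.
#' `lag = 1` gives the consecutive-bout similarity; `lag = 2` the
#' every-other-bout similarity, which exceeds the lag-1 value when the bee
#' alternates between two routes.
#'
#' @param sequences list of integer visit sequences, one per bout, in bout
#'   order.
#' @param lag positive integer bout offset.
#' @param window subsequence length passed to [similarity_index()].
#' @return Numeric vector of length `max(0, length(sequences) - lag)`; entry
#'   `k` compares bouts `k` and `k + lag`.
#' @export
similarity_series <- function(sequences, lag = 1L, window = 3L) {
  if (lag < 1L) stop("lag must be >= 1", call. = FALSE)
  n <- length(sequences)
  if (n <= lag) return(numeric(0))
  vapply(seq_len(n - lag), function(k) {
    similarity_index(sequences[[k]], sequences[[k + lag]], window = window)$si
  }, numeric(1))
}

#' Per-bout metrics table from a simulation result
#'
#' Computes, for every bee and bout, the lag-1 and lag-2 similarity indices
#' and the foraging success, in a long-format data frame.
#'
#' @param sim a `trapline_sim` from [run_simulation()].
#' @param window subsequence length for the similarity index.
#' @return Data frame with columns `bee_id`, `bout_index`, `si_lag1`,
#'   `si_lag2`, `success` (`si_lagX` is `NA` for bouts without a partner
#'   bout).
#' @export
bout_metrics <- function(sim, window = 3L) {
  stopifnot(inherits(sim, "trapline_sim"))
  res <- lapply(split(sim$bouts, sim$bouts$bee_id), function(bb) {
    bb <- bb[order(bb$bout_index), ]
    seqs <- lapply(bb$visit_sequence, identity)
    n <- nrow(bb)
    s1 <- c(similarity_series(seqs, 1L, window), NA_real_)
    s2 <- c(similarity_series(seqs, 2L, window), rep(NA_real_, min(2L, n)))
    data.frame(bee_id = bb$bee_id, bout_index = bb$bout_index,
               si_lag1 = s1[seq_len(n)], si_lag2 = s2[seq_len(n)],
               success = foraging_success(bb$nectar_collected, bb$duration))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
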