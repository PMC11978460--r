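#' Derive a reproducible child seed from a master seed and a stream label
#'
#' All randomness in the package flows through seeds derived from a single
#' master seed, one per named stream (per bee, per environment draw, per
#' simulation replicate). The derivation is a 32-bit multiplicative string
#' hash of `"<master_seed>:<label>"`, reduced modulo 2^31 - 1, so child seeds
#' are valid R integer seeds, stable across sessions and platforms, and
#' collision-resistant across distinct labels.
#'
#' @param master_seed single integer master seed.
#' @param stream_label character scalar naming the stream, e.g. `"bee/3"` or
#'   `"env/12/sim/1"`.
#' @return A single integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(42, "bee/1")
#' derive_seed(42, "bee/2")
#' @export
derive_seed <- function(master_seed, stream_label) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            length(stream_label) == 1L, is.character(stream_label))
  p <- 2147483647  # 2^31 - 1, Mersenne prime
  bytes <- utf8ToInt(paste0(format(master_seed, scientific = FALSE),
                            ":", stream_label))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% p
  # avoid seed 0 (and p itself cannot occur after %% p)
  as.integer(h %% (p - 1L)) + 1L
}

# A set of independent RNG streams multiplexed over R's single global RNG.
# Each stream owns a saved .Random.seed vector; drawing from a stream swaps
# its state in, evaluates, and swaps the advanced state back out, so draws on
# one stream never perturb another.
rng_streams <- function(master_seed, labels) {
  streams <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (lab in labels) {
    set.seed(derive_seed(master_seed, lab))
    assign(lab, get(".Random.seed", globalenv()), envir = streams)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  streams
}

# Evaluate `expr` with the named stream's RNG state active, then save the
# advanced state back into the stream.
with_stream <- function(streams, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(label, envir = streams), envir = globalenv())
  on.exit({
    assign(label, get(".Random.seed", globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
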