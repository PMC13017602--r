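## Counter-based random substreams.
##
## Strategies must be compared on identical life histories (common random
## numbers): natural-history randomness is a fixed function of the individual,
## and screening randomness is a fixed function of (individual, event key), so
## that any two strategies consume identical uniforms for every event they
## share and diverge only after their schedules diverge.  A counter-based
## generator gives this directly: u = hash(seed, id, stream, index), with no
## global RNG state to keep in sync.
##
## The mixer is the 32-bit murmur3 finalizer, computed exactly in doubles
## (all intermediates < 2^53).  Low cost, full avalanche, and adequate
## equidistribution for Monte-Carlo use.

.M32 <- 4294967296 # 2^32

## xor of two non-negative numbers < 2^32, via 16-bit halves
.xor32 <- function(a, b) {
  ah <- a %/% 65536L
  al <- a - ah * 65536
  bh <- b %/% 65536L
  bl <- b - bh * 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

## (x * m) mod 2^32, exact for x < 2^32, m < 2^32
.mul32 <- function(x, m) {
  xh <- x %/% 65536
  xl <- x - xh * 65536
  (((xh * m) %% 65536) * 65536 + xl * m) %% .M32
}

## murmur3 fmix32
.fmix32 <- function(h) {
  h <- .xor32(h, h %/% 65536)
  h <- .mul32(h, 2246822507) # 0x85ebca6b
  h <- .xor32(h, h %/% 8192)
  h <- .mul32(h, 3266489909) # 0xc2b2ae35
  .xor32(h, h %/% 65536)
}

## Named streams used across the engine.  Values are arbitrary but frozen:
## changing them changes every simulated trajectory.
.streams <- c(
  sex = 1, bmi = 2, smoking = 3, alcohol = 4, frailty = 5, oc_death = 6,
  n_lesions = 10, onset = 11, dwell = 12, location = 13, clin_vs_prog = 14,
  cure = 15, survival = 16, progressive = 17,
  fit = 20, fit_effect = 21, detect = 22, complication = 23,
  compl_fatal = 24, adherence = 25, stop_age = 26, arm5050 = 27
)

#' Deterministic uniform draws from a keyed substream
#'
#' Returns `runif`-like deviates that are a pure function of
#' `(seed, id, stream, index)`.  Used everywhere the engine needs
#' reproducible, strategy-invariant randomness (common random numbers).
#'
#' @param seed integer master seed.
#' @param id integer vector of individual (or lesion) identifiers.
#' @param stream stream name (one of the engine's named streams) or an
#'   integer stream code.
#' @param index integer vector of within-stream event indices (for example a
#'   test age, or a lesion transition number). Recycled against `id`.
#' @return numeric vector of uniforms in (0, 1).
#' @examples
#' substream_unif(1, 0:4, "fit", 50)
#' @export
substream_unif <- function(seed, id, stream, index = 0L) {
  if (is.character(stream)) {
    code <- unname(.streams[stream])
    if (is.na(code)) stop("unknown stream: ", stream)
  } else {
    code <- stream
  }
  n <- max(length(id), length(index))
  id <- rep_len(as.numeric(id), n) %% .M32
  index <- rep_len(as.numeric(index), n) %% .M32
  h <- .fmix32((as.numeric(seed) %% .M32 + .mul32(id, 2654435761)) %% .M32)
  h <- .fmix32((h + .mul32(rep_len(as.numeric(code), n) %% .M32, 40503)) %% .M32)
  h <- .fmix32((h + .mul32(index, 69069)) %% .M32)
  (h + 0.5) / .M32
}

## 32-bit content fingerprint of an R object (order-sensitive), used to tie
## cohorts and run manifests to the exact parameter set that produced them.
params_fingerprint <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  v <- as.numeric(raw)
  h <- 2166136261
  ## fold bytes in blocks to keep this O(n) in fast vector ops
  block <- 65536L
  for (i in seq(1L, length(v), by = block)) {
    chunk <- v[i:min(i + block - 1L, length(v))]
    mixed <- .fmix32((chunk * 16777619 + seq_along(chunk)) %% .M32)
    h <- .fmix32((h + sum(mixed %% 65536) + sum(mixed %/% 65536)) %% .M32)
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
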