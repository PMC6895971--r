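#' Convert 1-based inclusive coordinates to 0-based half-open (BED)
#'
#' All genomic coordinates inside the package are 1-based inclusive (the PLINK
#' convention). Every exported BED interval goes through this single function,
#' so the off-by-one convention lives in one place.
#'
#' @param start,end integer vectors, 1-based inclusive.
#' @return a two-column matrix with BED `start` (0-based) and `end` (exclusive).
#' @export
to_bed <- function(start, end) {
  stopifnot(all(end >= start))
  cbind(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' Convert 0-based half-open (BED) coordinates to 1-based inclusive
#'
#' @param start,end numeric vectors in BED convention.
#' @return a two-column matrix of 1-based inclusive `start`, `end`.
#' @export
from_bed <- function(start, end) {
  stopifnot(all(end > start))
  cbind(start = as.numeric(start) + 1, end = as.numeric(end))
}

## internal: deterministic sub-seed derivation (keeps values < 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483111L
}
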