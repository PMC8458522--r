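#' Canonical chromosome order
#'
#' The chromosome universe used throughout the package: the 22 autosomes in
#' numeric order followed by "X". Y and the mitochondrial genome are outside
#' the analysis scope and are rejected by the readers.
#'
#' @return Character vector of length 23.
#' @export
cslv_chromosomes <- function() c(as.character(1:22), "X")

# Deterministic per-replicate seed derived from a master seed and an index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
mix_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((abs(seed) %% 65521) * 30269 + (abs(index) %% 65521) * 911 + 1) %% 2147483647L
}

# Run code under a temporary RNG state.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}

# Partition n items into k contiguous blocks whose sizes differ by at most
# one, larger blocks first (remainder-to-front). Returns integer sizes.
block_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep.int(base, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  as.integer(sizes)
}

# Validate a chromosome label vector against the fixed universe.
check_chromosomes <- function(chrom, what = "chromosome") {
  bad <- setdiff(unique(chrom), cslv_chromosomes())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown %s label(s): %s (allowed: 1..22, X)",
      what, paste(bad, collapse = ", ")
    ), class = "cslvr_format_error")
  }
  invisible(chrom)
}
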