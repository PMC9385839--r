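# Internal utilities: random substreams, hashing, sequence helpers.

#' Derive a deterministic substream seed from a base seed and labels
#'
#' Each (seed, label...) combination maps to its own 31-bit seed, so every
#' species, protocol arm and replicate consumes an independent random stream:
#' adding a species or a replicate never perturbs the output of any other.
#'
#' @param seed Integer base seed.
#' @param ... Character or numeric labels identifying the substream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "annotation", "host")
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)),
                  collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Run code under a label-derived substream, restoring RNG state afterwards.
with_substream <- function(seed, ..., code) {
  withr::with_seed(substream_seed(seed, ...), code)
}

# Stable short hash of an R object (polynomial hash over its serialization).
# Used to stamp run outputs with the configuration they came from.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Uniform random DNA string of length n.
random_dna <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# Vectorised reverse complement of plain character sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%missing%` <- function(x, default) if (is.null(x)) default else x
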