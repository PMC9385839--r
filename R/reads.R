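# Paired-end read simulation with ground-truth provenance.

#' Simulate paired-end reads from a transcript pool
#'
#' Draws `n_pairs` read pairs multinomially by post-protocol abundance,
#' samples an insert-size fragment within each source transcript, and emits
#' 75 bp-style mates in FR orientation with per-base Phred qualities and
#' uniform substitution errors. Ground truth (source species, transcript and
#' molecule class of every pair) is recorded alongside the reads.
#'
#' Strandedness follows dUTP stranded library chemistry by default
#' (`orientation = "stranded_reverse"`): mate 1 is antisense to the source
#' transcript and mate 2 sense, which is what `strandedness = "reverse"`
#' counting expects downstream. `"stranded_forward"` swaps the mates.
#'
#' Transcripts shorter than `read_length` cannot yield a valid fragment and
#' are excluded from sampling; it is an error if no transcript is long
#' enough. Fragment lengths are clamped to `[read_length, transcript length]`.
#'
#' @param pool A post-protocol [transcript pool][build_transcript_pool()].
#' @param annotation The matching [holobiont annotation][generate_annotation()].
#' @param n_pairs Number of read pairs to draw.
#' @param read_length Mate length in bp (default 75).
#' @param error_rate Per-base substitution probability.
#' @param insert_mean,insert_sd Normal fragment-length model in bp.
#' @param quality_mean,quality_sd Normal per-base Phred quality model,
#'   truncated to `[2, 40]`.
#' @param orientation `"stranded_reverse"` (dUTP, default) or
#'   `"stranded_forward"`.
#' @param seed Integer seed; identical seeds give bit-identical read sets.
#' @return A `read_set`: list with `pairs` (tibble: pair_id, mate1, mate2,
#'   qual1, qual2), `truth` (tibble: pair_id, species_id, source_id,
#'   molecule_class) and `read_length`.
#' @export
generate_reads <- function(pool, annotation, n_pairs,
                           read_length = 75,
                           error_rate = 0.002,
                           insert_mean = 250, insert_sd = 40,
                           quality_mean = 35, quality_sd = 5,
                           orientation = c("stranded_reverse",
                                           "stranded_forward"),
                           seed = 1) {
  orientation <- match.arg(orientation)
  active <- pool[pool$relative_abundance > 0, ]
  if (nrow(active) == 0) abort("transcript pool is empty")
  txs <- transcript_sequences(annotation, active$source_id)
  txlen <- nchar(txs)
  long_enough <- txlen >= read_length
  if (!any(long_enough)) {
    abort("no transcript is at least one read length long")
  }
  active <- active[long_enough, ]
  txs <- unname(txs[long_enough])
  txlen <- txlen[long_enough]

  withr::with_seed(seed, {
    idx <- sample.int(nrow(active), n_pairs, replace = TRUE,
                      prob = active$relative_abundance)
    len_i <- txlen[idx]
    frag <- pmin(len_i, pmax(read_length,
                             round(rnorm(n_pairs, insert_mean, insert_sd))))
    start <- 1L + floor(runif(n_pairs) * (len_i - frag + 1))
    sense_start <- substring(txs[idx], start, start + read_length - 1L)
    sense_end <- revcomp(substring(txs[idx], start + frag - read_length,
                                   start + frag - 1L))
    if (orientation == "stranded_reverse") {
      mate1 <- sense_end
      mate2 <- sense_start
    } else {
      mate1 <- sense_start
      mate2 <- sense_end
    }
    if (error_rate > 0) {
      mate1 <- inject_substitutions(mate1, error_rate)
      mate2 <- inject_substitutions(mate2, error_rate)
    }
    qual1 <- random_qualities(n_pairs, read_length, quality_mean, quality_sd)
    qual2 <- random_qualities(n_pairs, read_length, quality_mean, quality_sd)
    pair_id <- sprintf("pair%07d", seq_len(n_pairs))
    new_read_set(
      pairs = tibble(pair_id = pair_id, mate1 = mate1, mate2 = mate2,
                     qual1 = qual1, qual2 = qual2),
      truth = tibble(pair_id = pair_id,
                     species_id = active$species_id[idx],
                     source_id = active$source_id[idx],
                     molecule_class = active$molecule_class[idx]),
      read_length = read_length
    )
  })
}

# Uniform substitution errors; each erroneous base becomes one of the three
# other bases with equal probability.
inject_substitutions <- function(seqs, rate) {
  len <- nchar(seqs)
  n_err <- rbinom(length(seqs), len, rate)
  which_err <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in which_err) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

# n quality strings of given length, Phred+33, truncated normal model.
random_qualities <- function(n, len, mean, sd) {
  q <- pmin(40L, pmax(2L, as.integer(round(rnorm(n * len, mean, sd)))))
  big <- rawToChar(as.raw(q + 33L))
  starts <- seq.int(1L, by = len, length.out = n)
  substring(big, starts, starts + len - 1L)
}

new_read_set <- function(pairs, truth, read_length) {
  stopifnot(all(nchar(pairs$mate1) == nchar(pairs$qual1)),
            all(nchar(pairs$mate2) == nchar(pairs$qual2)),
            all(truth$pair_id %in% pairs$pair_id))
  structure(list(pairs = pairs, truth = truth, read_length = read_length),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set>", nrow(x$pairs), "pairs,",
      "read length", x$read_length, "bp\n")
  if (nrow(x$truth)) {
    tab <- table(x$truth$species_id)
    cat("  truth by species:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of read pairs in a read set
#' @param x A `read_set`.
#' @return Integer pair count.
#' @export
n_pairs <- function(x) nrow(x$pairs)
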