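# 2-bit k-mer encoding and the competitive genome index.

# ASCII lookup: A/C/G/T -> 0..3, anything else NA.
base_lookup <- local({
  x <- rep(NA_integer_, 256)
  x[utf8ToInt("A") + 1L] <- 0L
  x[utf8ToInt("C") + 1L] <- 1L
  x[utf8ToInt("G") + 1L] <- 2L
  x[utf8ToInt("T") + 1L] <- 3L
  x
})

# All k-mers of a character vector of sequences, 2-bit packed into doubles
# (exact for k <= 26). Returns data.table(seq_idx, pos, code); positions are
# 1-based within each sequence; windows containing non-ACGT bases or spanning
# sequence boundaries are dropped.
encode_kmers <- function(seqs, k) {
  lens <- nchar(seqs)
  total <- sum(lens)
  empty <- data.table(seq_idx = integer(), pos = integer(), code = numeric())
  if (total < k) return(empty)
  b <- base_lookup[as.integer(charToRaw(paste(seqs, collapse = ""))) + 1L]
  bad <- is.na(b)
  if (any(bad)) b[bad] <- 0L
  nv <- total - k + 1L
  acc <- numeric(nv)
  pw <- 4^((k - 1):0)
  for (j in seq_len(k)) {
    acc <- acc + b[j:(j + nv - 1L)] * pw[j]
  }
  seq_idx_all <- rep.int(seq_along(seqs), lens)
  offsets <- cumsum(c(0L, lens))
  starts <- seq_len(nv)
  sidx <- seq_idx_all[starts]
  valid <- seq_idx_all[starts + k - 1L] == sidx
  if (any(bad)) {
    csb <- cumsum(bad)
    valid <- valid & (csb[starts + k - 1L] - csb[starts] + bad[starts]) == 0L
  }
  data.table(seq_idx = sidx[valid],
             pos = (starts - offsets[sidx])[valid],
             code = acc[valid])
}

#' Build a competitive k-mer index over all holobiont genomes
#'
#' Indexes every k-mer of both strands of every scaffold, recording its
#' species, scaffold, 1-based forward-strand start position and strand.
#' Minus-strand entries store the reverse-complement k-mer mapped back to
#' forward coordinates. Lookup is a keyed binary-search join, effectively
#' constant time per query k-mer. This index plays the role a spliced aligner
#' index plays for real data: synthetic genes are intron-free, and genome
#' -level assignment is all the downstream metrics consume.
#'
#' @param annotation A [holobiont annotation][generate_annotation()].
#' @param k K-mer length; must lie in `[11, 26]` (k-mers are 2-bit packed
#'   into doubles, exact up to `4^26`).
#' @return A `genome_index` object.
#' @export
build_index <- function(annotation, k = 21) {
  if (k < 11 || k > 26) abort("k must lie in [11, 26]")
  genomes <- annotation$genomes
  if (min(nchar(genomes)) < k) abort("k is longer than the shortest scaffold")
  sp <- scaffold_species(annotation)

  fwd <- encode_kmers(unname(genomes), k)
  fwd[, `:=`(scaffold = names(genomes)[seq_idx], strand = "+")]
  rev <- encode_kmers(revcomp(unname(genomes)), k)
  lens <- nchar(genomes)
  rev[, `:=`(scaffold = names(genomes)[seq_idx],
             pos = lens[seq_idx] - pos - k + 2L,
             strand = "-")]
  dt <- rbindlist(list(fwd, rev))[, seq_idx := NULL]
  dt[, species_id := unname(sp[scaffold])]
  setkey(dt, code)
  structure(list(dt = dt, k = as.integer(k),
                 scaffolds = tibble(scaffold = names(genomes),
                                    species_id = unname(sp[names(genomes)]),
                                    length = unname(lens))),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> k =", x$k, "|", nrow(x$dt), "indexed positions over",
      nrow(x$scaffolds), "scaffolds\n")
  invisible(x)
}

#' Look up k-mers in a genome index
#'
#' @param index A [genome_index][build_index()].
#' @param kmers Character vector of k-mers (each of length `index$k`).
#' @return Tibble of locations (`kmer`, `species_id`, `scaffold`, `pos`,
#'   `strand`); zero rows for k-mers absent from every genome.
#' @export
index_lookup <- function(index, kmers) {
  stopifnot(all(nchar(kmers) == index$k))
  q <- encode_kmers(kmers, index$k)
  hits <- index$dt[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  tibble(kmer = kmers[hits$seq_idx],
         species_id = hits$species_id,
         scaffold = hits$scaffold,
         pos = hits$pos,
         strand = hits$strand)
}
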