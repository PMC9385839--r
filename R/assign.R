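# Competitive assignment of read pairs across all holobiont genomes.

#' Competitively assign read pairs to holobiont genomes
#'
#' For every mate, k-mer seeds at a fixed stride are looked up in the
#' [genome index][build_index()]. Seed hits on the same scaffold, strand and
#' alignment diagonal are chained; a species supports a pair when both mates
#' have at least `min_seed_hits` colinear hits on one scaffold, on opposite
#' strands (FR orientation), within `insert_bound` bp of each other. A pair
#' is `assigned` when exactly one species supports it, `ambiguous_genome`
#' when two or more do (ties in seed support are never resolved by score:
#' reads compatible with more than one genome are discarded, mirroring
#' competitive mapping against all partner genomes jointly), and `unaligned`
#' when none does. For assigned pairs `best_locus` spans the supporting seed
#' hits and `strand` is the aligned strand of mate 1.
#'
#' @param reads A (typically trimmed) [read_set][generate_reads()].
#' @param index A [genome_index][build_index()].
#' @param stride Distance in bp between successive seed start positions.
#' @param min_seed_hits Minimum colinear seed hits per mate for support.
#'   Raising it only ever makes assignment stricter.
#' @param insert_bound Maximum distance in bp between the mates' alignment
#'   diagonals (an insert-size sanity bound).
#' @return A `pair_assignments` tibble: `pair_id`, `status`
#'   (`assigned`/`unaligned`/`ambiguous_genome`), `species_id`, `scaffold`,
#'   `start`, `end`, `strand` (locus fields are `NA` unless assigned).
#' @export
assign_pairs <- function(reads, index, stride = 7, min_seed_hits = 2,
                         insert_bound = 1000) {
  stopifnot(inherits(index, "genome_index"))
  pairs <- reads$pairs
  out <- tibble(pair_id = pairs$pair_id,
                status = "unaligned",
                species_id = NA_character_,
                scaffold = NA_character_,
                start = NA_integer_, end = NA_integer_,
                strand = NA_character_)
  if (nrow(pairs) == 0) return(new_pair_assignments(out))
  k <- index$k

  seed_table <- function(seqs, mate_no) {
    km <- encode_kmers(seqs, k)
    km <- km[(pos - 1L) %% stride == 0L]
    km[, mate_no := mate_no]
    km
  }
  seeds <- rbindlist(list(seed_table(pairs$mate1, 1L),
                          seed_table(pairs$mate2, 2L)))
  data.table::setnames(seeds, c("seq_idx", "pos"), c("pair_idx", "off"))
  hits <- index$dt[seeds, on = "code", nomatch = NULL,
                   allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(new_pair_assignments(out))
  # alignment diagonal: constant across colinear exact seed hits
  hits[, diag_ := fifelse(strand == "+", pos - off, pos + off)]
  grp <- hits[, list(nhit = data.table::uniqueN(off),
                     lo = min(pos), hi = max(pos) + k - 1L),
              by = list(pair_idx, mate_no, species_id, scaffold, strand,
                        diag_)]
  grp <- grp[nhit >= min_seed_hits]
  m1 <- grp[mate_no == 1L,
            list(pair_idx, species_id, scaffold, s1 = strand, d1 = diag_,
                 n1 = nhit, lo1 = lo, hi1 = hi)]
  m2 <- grp[mate_no == 2L,
            list(pair_idx, species_id, scaffold, s2 = strand, d2 = diag_,
                 n2 = nhit, lo2 = lo, hi2 = hi)]
  cand <- m1[m2, on = c("pair_idx", "species_id", "scaffold"),
             nomatch = NULL, allow.cartesian = TRUE]
  cand <- cand[s1 != s2 & abs(d1 - d2) <= insert_bound]
  if (nrow(cand) == 0) return(new_pair_assignments(out))

  support <- unique(cand[, list(pair_idx, species_id)])
  nsupp <- support[, list(n_species = .N), by = pair_idx]
  ambiguous <- nsupp[n_species >= 2L]$pair_idx
  assigned <- nsupp[n_species == 1L]$pair_idx
  out$status[ambiguous] <- "ambiguous_genome"

  if (length(assigned)) {
    best <- cand[pair_idx %in% assigned]
    setorder(best, pair_idx, -n1, -n2, scaffold, d1, d2)
    best <- best[, .SD[1L], by = pair_idx]
    out$status[best$pair_idx] <- "assigned"
    out$species_id[best$pair_idx] <- best$species_id
    out$scaffold[best$pair_idx] <- best$scaffold
    out$start[best$pair_idx] <- as.integer(pmin(best$lo1, best$lo2))
    out$end[best$pair_idx] <- as.integer(pmax(best$hi1, best$hi2))
    out$strand[best$pair_idx] <- best$s1
  }
  new_pair_assignments(out)
}

new_pair_assignments <- function(x) {
  stopifnot(all(x$status %in% c("assigned", "unaligned", "ambiguous_genome")),
            all(is.na(x$species_id) == (x$status != "assigned")))
  class(x) <- c("pair_assignments", class(tibble()))
  x
}

#' Tally assignment statuses
#'
#' @param assignments A [pair_assignments][assign_pairs()] tibble.
#' @return Tibble with one row per status (`assigned`, `unaligned`,
#'   `ambiguous_genome`) and the number of pairs in each.
#' @export
assignment_summary <- function(assignments) {
  tibble(status = c("assigned", "unaligned", "ambiguous_genome")) |>
    left_join(count(as_tibble(assignments), .data$status, name = "n_pairs"),
              by = "status") |>
    mutate(n_pairs = coalesce(.data$n_pairs, 0L))
}
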