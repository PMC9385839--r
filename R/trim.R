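# Quality trimming of read pairs (headcrop + sliding window + min length).

#' Trimming parameters
#'
#' Defaults reproduce a common Trimmomatic recipe for 75 bp reads: crop the
#' first 10 bp of each mate, scan 5'→3' with a 4 bp window and truncate the
#' read at the start of the first window whose mean Phred quality falls below
#' 20, then discard any pair in which either mate ends up shorter than 60 bp.
#'
#' @param headcrop Bases removed from the 5' end of each mate.
#' @param window Sliding-window width in bp (>= 1).
#' @param mean_quality_threshold Mean Phred quality below which a window
#'   triggers truncation.
#' @param min_length Minimum surviving mate length in bp; shorter mates drop
#'   the whole pair.
#' @param step_order Order in which the steps are applied.
#' @return A `trim_params` list.
#' @export
#' @examples
#' trim_params()                              # 10 / 4:20 / 60 recipe
#' trim_params(headcrop = 7, mean_quality_threshold = 15)
trim_params <- function(headcrop = 10,
                        window = 4,
                        mean_quality_threshold = 20,
                        min_length = 60,
                        step_order = c("headcrop", "slidingwindow",
                                       "minlen")) {
  stopifnot(headcrop >= 0, window >= 1, min_length >= 1,
            all(step_order %in% c("headcrop", "slidingwindow", "minlen")))
  structure(list(headcrop = as.integer(headcrop),
                 window = as.integer(window),
                 mean_quality_threshold = mean_quality_threshold,
                 min_length = as.integer(min_length),
                 step_order = step_order),
            class = "trim_params")
}

#' Quality-trim read pairs
#'
#' Applies the configured steps, in order, to each mate independently:
#' `headcrop` removes leading bases; `slidingwindow` scans 5'→3' and
#' truncates the read immediately before the first window whose mean Phred
#' quality is below the threshold (a mate shorter than the window is treated
#' as failing entirely and truncated to length zero); `minlen` flags pairs in
#' which either mate is below the minimum length. Flagged pairs are removed
#' whole — pairs are kept intact or dropped entirely, never orphaned — and
#' the ground-truth table is filtered to the survivors. Trimming is
#' idempotent: re-trimming a trimmed set changes nothing.
#'
#' @param reads A [read_set][generate_reads()].
#' @param params A [trim_params()] object.
#' @return The trimmed `read_set`.
#' @export
trim_pairs <- function(reads, params = trim_params()) {
  pairs <- reads$pairs
  if (nrow(pairs) == 0) return(reads)
  m1 <- list(seq = pairs$mate1, qual = pairs$qual1)
  m2 <- list(seq = pairs$mate2, qual = pairs$qual2)
  drop <- logical(nrow(pairs))

  apply_step <- function(mate, step) {
    switch(step,
      headcrop = {
        mate$seq <- substring(mate$seq, params$headcrop + 1L)
        mate$qual <- substring(mate$qual, params$headcrop + 1L)
        mate
      },
      slidingwindow = {
        keep <- sliding_keep_length(mate$qual, params$window,
                                    params$mean_quality_threshold)
        mate$seq <- substring(mate$seq, 1L, keep)
        mate$qual <- substring(mate$qual, 1L, keep)
        mate
      },
      minlen = mate
    )
  }

  for (step in params$step_order) {
    if (step == "minlen") {
      drop <- drop | nchar(m1$seq) < params$min_length |
        nchar(m2$seq) < params$min_length
    } else {
      m1 <- apply_step(m1, step)
      m2 <- apply_step(m2, step)
    }
  }

  keep <- !drop
  out_pairs <- tibble(pair_id = pairs$pair_id[keep],
                      mate1 = m1$seq[keep], mate2 = m2$seq[keep],
                      qual1 = m1$qual[keep], qual2 = m2$qual[keep])
  truth <- reads$truth[reads$truth$pair_id %in% out_pairs$pair_id, ]
  new_read_set(out_pairs, truth, reads$read_length)
}

# Surviving length of each read under the sliding-window rule: the read is
# truncated at the start of the first window (5'->3') whose mean quality is
# below the threshold. Reads shorter than the window fail outright (length 0).
sliding_keep_length <- function(quals, window, threshold) {
  lens <- nchar(quals)
  out <- lens
  out[lens < window] <- 0L
  idx <- which(lens >= window)
  if (!length(idx)) return(out)
  q <- as.integer(charToRaw(paste(quals[idx], collapse = ""))) - 33L
  dt <- data.table(read = rep.int(seq_along(idx), lens[idx]), q = q)
  dt[, pos := rowid(read)]
  dt[, cs := cumsum(q), by = read]
  w <- as.integer(window)
  dt[, ws := data.table::shift(cs, n = w - 1L, type = "lead") - cs + q,
     by = read]
  # rows are in ascending pos order within each read, so pos[1L] is the
  # first failing window start
  fails <- dt[!is.na(ws) & ws / w < threshold, list(first = pos[1L]),
              by = read]
  if (nrow(fails)) out[idx[fails$read]] <- fails$first - 1L
  out
}
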