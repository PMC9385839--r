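# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Sliding-window trimming of a single read: loop over every window.
oracle_trim_read <- function(seq, qual, headcrop, window, threshold,
                             order = c("headcrop", "slidingwindow")) {
  for (step in order) {
    if (step == "headcrop") {
      seq <- substring(seq, headcrop + 1)
      qual <- substring(qual, headcrop + 1)
    } else if (step == "slidingwindow") {
      q <- as.integer(charToRaw(qual)) - 33L
      len <- length(q)
      if (len < window) {
        seq <- ""
        qual <- ""
        next
      }
      cut <- len
      for (i in seq_len(len - window + 1)) {
        if (mean(q[i:(i + window - 1)]) < threshold) {
          cut <- i - 1
          break
        }
      }
      seq <- substring(seq, 1, cut)
      qual <- substring(qual, 1, cut)
    }
  }
  list(seq = seq, qual = qual)
}

# Average ranks computed by definition (mean position among sorted values).
oracle_rank_avg <- function(v) {
  s <- sort(v)
  vapply(v, function(z) mean(which(s == z)), numeric(1))
}

# Spearman rho as Pearson correlation of average ranks, by the closed form.
oracle_spearman <- function(x, y) {
  rx <- oracle_rank_avg(x)
  ry <- oracle_rank_avg(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Quadratic interval-overlap counting with the strand rule; classifies each
# locus as (gene hit, ambiguous, or no feature) by scanning every gene.
oracle_count_loci <- function(loci, genes, strandedness = "reverse") {
  counted <- integer(0)
  ambiguous <- 0L
  none <- 0L
  gene_counts <- setNames(integer(nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(loci))) {
    hits <- character(0)
    for (j in seq_len(nrow(genes))) {
      overlap <- loci$start[i] <= genes$end[j] &&
        loci$end[i] >= genes$start[j]
      compat <- switch(strandedness,
                       reverse = genes$strand[j] != loci$strand[i],
                       forward = genes$strand[j] == loci$strand[i],
                       none = TRUE)
      if (overlap && compat) hits <- c(hits, genes$gene_id[j])
    }
    if (length(hits) == 1) {
      gene_counts[hits] <- gene_counts[hits] + 1L
    } else if (length(hits) >= 2) {
      ambiguous <- ambiguous + 1L
    } else {
      none <- none + 1L
    }
  }
  list(gene_counts = gene_counts, ambiguous = ambiguous, none = none)
}

# Term-by-term scan for the expressed-GO percentage.
oracle_expressed_go_percent <- function(go_pairs, expressed) {
  terms <- unique(go_pairs$go_id)
  hit <- 0L
  for (term in terms) {
    members <- go_pairs$gene_id[go_pairs$go_id == term]
    if (any(members %in% expressed)) hit <- hit + 1L
  }
  100 * hit / length(terms)
}

# Full sort of all absolute differences, then truncation.
oracle_top_go <- function(go_ids, mean_a, mean_b, n) {
  d <- abs(mean_a - mean_b)
  ord <- order(-d, go_ids)
  head(go_ids[ord], n)
}

# Two-sample t statistic from the textbook closed forms.
oracle_t_statistic <- function(a, b, var_equal = FALSE) {
  na <- length(a)
  nb <- length(b)
  if (var_equal) {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    (mean(a) - mean(b)) / sqrt(var(a) / na + var(b) / nb)
  }
}

# Random quality string helper for trimming tests.
random_qual_string <- function(len, lo = 2, hi = 40) {
  rawToChar(as.raw(sample(lo:hi, len, replace = TRUE) + 33L))
}
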