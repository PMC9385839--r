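# Synthetic holobiont genomes, gene models and GO annotation.

#' Generate genomes, gene models and GO annotation for a holobiont
#'
#' Lays out, for every species, `n_genes` non-overlapping intron-free CDS on
#' random strands with uniform random lengths, plus rRNA loci, separated by
#' intergenic spacers on a single scaffold, and fills the scaffold with
#' uniform random DNA. A per-species GO vocabulary is generated and each gene
#' is annotated with 0 or more terms; every generated term is guaranteed to
#' annotate at least one gene. All coordinates are 1-based and inclusive, the
#' native convention of the Bioconductor interval stack, so GFF3 emission
#' needs no conversion.
#'
#' Each species draws from its own random substream keyed by
#' `(seed, "annotation", species_id)`, so adding a species to the holobiont
#' leaves the others' genomes bit-identical.
#'
#' @param specs Species specification tibble (see [species_spec()]).
#' @param seed Integer seed; the same seed reproduces the annotation exactly.
#' @param n_rrna Number of rRNA loci per species.
#' @param rrna_lengths Lengths (bp) of the rRNA loci, recycled to `n_rrna`.
#' @param spacer_range Min/max intergenic spacer length in bp.
#' @param max_go_per_gene Maximum number of GO terms per gene.
#' @param genes_per_go_term Target ratio of genes to GO vocabulary size.
#' @return A `holobiont_annotation` object: a list with elements
#'   `species` (the specs), `genomes` (named character, one scaffold per
#'   species), `features` (tibble: species_id, feature_id, type, scaffold,
#'   start, end, strand) and `go_map` (tibble: species_id, gene_id, go_id).
#' @export
#' @examples
#' ann <- generate_annotation(species_spec("s", 5), seed = 1)
#' ann$features
generate_annotation <- function(specs,
                                seed = 1,
                                n_rrna = 2,
                                rrna_lengths = c(1500, 2900),
                                spacer_range = c(100, 300),
                                max_go_per_gene = 4,
                                genes_per_go_term = 2.5) {
  validate_species_specs(specs)
  rrna_lengths <- rep_len(rrna_lengths, n_rrna)

  per_species <- purrr::pmap(specs, function(species_id, n_genes,
                                             gene_length_min, gene_length_max,
                                             ...) {
    with_substream(seed, "annotation", species_id, code = {
      scaffold <- paste0(species_id, "_scaffold")
      gene_len <- sample(gene_length_min:gene_length_max, n_genes,
                         replace = TRUE)
      feat <- tibble(
        species_id = species_id,
        feature_id = c(sprintf("%s_g%04d", species_id, seq_len(n_genes)),
                       sprintf("%s_rrna%d", species_id, seq_len(n_rrna))),
        type = rep(c("CDS", "rRNA"), c(n_genes, n_rrna)),
        length = c(gene_len, as.integer(rrna_lengths))
      )
      feat <- feat[sample.int(nrow(feat)), ]
      spacer <- sample(spacer_range[1]:spacer_range[2], nrow(feat) + 1,
                       replace = TRUE)
      feat$start <- cumsum(spacer[-length(spacer)]) +
        cumsum(c(0L, feat$length[-nrow(feat)])) + 1L
      feat$end <- feat$start + feat$length - 1L
      feat$strand <- sample(c("+", "-"), nrow(feat), replace = TRUE)
      feat$scaffold <- scaffold
      genome_len <- feat$end[nrow(feat)] + spacer[length(spacer)]
      genome <- random_dna(genome_len)

      n_go <- max(3L, ceiling(n_genes / genes_per_go_term))
      go_ids <- sprintf("GO:%07d", seq_len(n_go))
      # skewed term sizes: low-index terms annotate many genes, like real
      # high-level GO categories
      term_w <- 1 / seq_len(n_go)^0.7
      gene_ids <- feat$feature_id[feat$type == "CDS"]
      n_terms <- sample(0:max_go_per_gene, n_genes, replace = TRUE,
                        prob = c(0.15, 0.35, 0.25, 0.15, 0.10)[
                          seq_len(max_go_per_gene + 1)])
      n_terms <- pmin(n_terms, n_go)
      go_map <- tibble(
        species_id = species_id,
        gene_id = rep(gene_ids, n_terms),
        go_id = go_ids[unlist(purrr::map(n_terms, function(k) {
          sample.int(n_go, min(k, n_go), prob = term_w)
        }))]
      )
      orphan <- setdiff(go_ids, go_map$go_id)
      if (length(orphan)) {
        go_map <- bind_rows(go_map, tibble(
          species_id = species_id,
          gene_id = sample(gene_ids, length(orphan), replace = TRUE),
          go_id = orphan
        ))
      }
      list(genome = setNames(genome, scaffold),
           features = feat[, c("species_id", "feature_id", "type", "scaffold",
                               "start", "end", "strand", "length")],
           go_map = arrange(distinct(go_map), .data$gene_id, .data$go_id))
    })
  })

  structure(
    list(
      species = specs,
      genomes = unlist(purrr::map(per_species, "genome")),
      features = purrr::list_rbind(purrr::map(per_species, "features")),
      go_map = purrr::list_rbind(purrr::map(per_species, "go_map"))
    ),
    class = "holobiont_annotation"
  )
}

#' @export
print.holobiont_annotation <- function(x, ...) {
  cat("<holobiont_annotation>\n")
  cat("  species:", paste(x$species$species_id, collapse = ", "), "\n")
  cat("  genome sizes:",
      paste(format(nchar(x$genomes), big.mark = ","), collapse = ", "), "bp\n")
  cat("  features:", sum(x$features$type == "CDS"), "CDS,",
      sum(x$features$type == "rRNA"), "rRNA\n")
  cat("  GO annotations:", nrow(x$go_map), "gene-term links,",
      length(unique(x$go_map$go_id)), "terms\n")
  invisible(x)
}

#' Extract strand-aware transcript sequences
#'
#' Returns the spliced-out (here intron-free) transcript sequence of every
#' CDS and rRNA feature, reverse-complemented for minus-strand features.
#'
#' @param annotation A `holobiont_annotation`.
#' @param feature_ids Optional subset of feature ids.
#' @return Named character vector of sequences.
#' @export
transcript_sequences <- function(annotation, feature_ids = NULL) {
  feat <- annotation$features
  if (!is.null(feature_ids)) {
    feat <- feat[match(feature_ids, feat$feature_id), ]
    if (anyNA(feat$feature_id)) abort("unknown feature ids requested")
  }
  seqs <- substring(annotation$genomes[feat$scaffold], feat$start, feat$end)
  neg <- feat$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  setNames(seqs, feat$feature_id)
}

# Map scaffolds to species ids.
scaffold_species <- function(annotation) {
  feat <- distinct(annotation$features, .data$scaffold, .data$species_id)
  setNames(feat$species_id, feat$scaffold)
}
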