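# Species specifications for the synthetic holobiont.

#' Describe one species of a synthetic holobiont
#'
#' A species specification captures everything the simulator needs to know
#' about one partner of the holobiont: how many genes it has, how variable
#' their expression is, how much of its raw transcript pool is ribosomal RNA,
#' and how its mRNA behaves under oligo(dT) poly(A) capture. Eukaryotic host
#' mRNA carries long, stable poly(A) tails and is captured essentially
#' completely (`polya_capture_model = "stable_eukaryote"`); bacterial mRNA is
#' only transiently polyadenylated en route to degradation, so each gene's
#' transcripts are captured with a gene-dependent probability drawn from a
#' Beta distribution with mean `polya_mean_capture` and concentration
#' `polya_capture_concentration` (`polya_capture_model = "transient_bacterial"`).
#'
#' @param species_id Short label, unique within the holobiont.
#' @param n_genes Number of protein-coding genes (>= 1).
#' @param gene_length_range Length-two numeric, min/max CDS length in bp.
#' @param expressed_fraction Fraction of genes with non-zero expression, in
#'   `[0, 1]`. The simulator expresses exactly
#'   `round(expressed_fraction * n_genes)` genes.
#' @param expression_dispersion Standard deviation of log-normal expression
#'   on the natural-log scale.
#' @param rrna_transcript_fraction Fraction of the species' raw transcript
#'   pool (by molecule weight) that is rRNA, in `[0, 1)`.
#' @param polya_capture_model `"stable_eukaryote"` or `"transient_bacterial"`.
#' @param polya_mean_capture Mean per-gene probability that a transcript is
#'   retained by poly(A) pulldown, in `(0, 1]`.
#' @param polya_capture_concentration Beta concentration for gene-dependent
#'   bacterial capture (ignored for the stable eukaryote model).
#' @param pool_weight Relative total RNA mass this species contributes to the
#'   holobiont transcript pool before any bacterial cell enrichment.
#' @return A one-row tibble; combine species with [dplyr::bind_rows()].
#' @seealso [default_holobiont_specs()], [generate_annotation()]
#' @export
#' @examples
#' species_spec("sym1", n_genes = 50, pool_weight = 0.02)
species_spec <- function(species_id,
                         n_genes,
                         gene_length_range = c(300, 900),
                         expressed_fraction = 0.9,
                         expression_dispersion = 1.2,
                         rrna_transcript_fraction = 0.95,
                         polya_capture_model = c("transient_bacterial",
                                                 "stable_eukaryote"),
                         polya_mean_capture = 0.2,
                         polya_capture_concentration = 2,
                         pool_weight = 1) {
  polya_capture_model <- match.arg(polya_capture_model)
  spec <- tibble(
    species_id = as.character(species_id),
    n_genes = as.integer(n_genes),
    gene_length_min = as.integer(gene_length_range[1]),
    gene_length_max = as.integer(gene_length_range[2]),
    expressed_fraction = as.double(expressed_fraction),
    expression_dispersion = as.double(expression_dispersion),
    rrna_transcript_fraction = as.double(rrna_transcript_fraction),
    polya_capture_model = polya_capture_model,
    polya_mean_capture = as.double(polya_mean_capture),
    polya_capture_concentration = as.double(polya_capture_concentration),
    pool_weight = as.double(pool_weight)
  )
  validate_species_specs(spec)
  spec
}

validate_species_specs <- function(specs) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1)
  if (anyDuplicated(specs$species_id)) {
    abort("species ids must be distinct")
  }
  with(specs, {
    if (any(n_genes < 1)) abort("n_genes must be >= 1")
    if (any(gene_length_min < 1 | gene_length_max < gene_length_min)) {
      abort("gene_length_range must satisfy 1 <= min <= max")
    }
    if (any(expressed_fraction < 0 | expressed_fraction > 1)) {
      abort("expressed_fraction must lie in [0, 1]")
    }
    if (any(rrna_transcript_fraction < 0 | rrna_transcript_fraction >= 1)) {
      abort("rrna_transcript_fraction must lie in [0, 1)")
    }
    if (any(polya_mean_capture <= 0 | polya_mean_capture > 1)) {
      abort("polya_mean_capture must lie in (0, 1]")
    }
    if (any(pool_weight <= 0)) abort("pool_weight must be positive")
  })
  invisible(specs)
}

#' Default holobiont: one host plus three bacterial symbionts
#'
#' The default study system mirrors a sponge-like holobiont: a eukaryotic
#' host whose transcript mass dominates the pool, and three proteobacteria-like
#' symbionts of decreasing abundance. Host mRNA is stably polyadenylated
#' (capture probability 1 under poly(A) pulldown); symbiont mRNA is captured
#' with gene-dependent probability of mean 0.2. Both pools are dominated by
#' rRNA before any depletion (85% of host RNA, 95% of bacterial RNA).
#'
#' @param n_host_genes,n_symbiont_genes Gene counts for the host and for each
#'   symbiont. The defaults keep a desk-scale experiment fast while leaving
#'   enough genes for stable coverage percentages.
#' @return A four-row species specification tibble.
#' @export
#' @examples
#' default_holobiont_specs()
default_holobiont_specs <- function(n_host_genes = 600,
                                    n_symbiont_genes = 300) {
  bind_rows(
    species_spec("host", n_host_genes,
                 gene_length_range = c(500, 2000),
                 expressed_fraction = 0.55,
                 expression_dispersion = 1.5,
                 rrna_transcript_fraction = 0.85,
                 polya_capture_model = "stable_eukaryote",
                 polya_mean_capture = 1,
                 pool_weight = 1),
    species_spec("sym1", n_symbiont_genes, pool_weight = 0.02),
    species_spec("sym2", n_symbiont_genes, pool_weight = 0.006),
    species_spec("sym3", n_symbiont_genes, pool_weight = 0.004)
  )
}
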