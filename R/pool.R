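# Transcript pools and library-preparation protocol transforms.

#' Build the holobiont transcript pool
#'
#' Materialises the abundance and polyadenylation model of the simulator.
#' Per species: exactly `round(expressed_fraction * n_genes)` genes receive
#' positive log-normal molar abundances (the rest are silent with abundance
#' zero); mRNA abundances are scaled so the species' mRNA totals
#' `pool_weight * (1 - rrna_transcript_fraction)` and its rRNA loci share
#' `pool_weight * rrna_transcript_fraction` equally, making rRNA dominate the
#' raw pool as it does in total RNA. Poly(A)-capture probabilities are
#' `polya_mean_capture` (default 1) for every stable-eukaryote mRNA, drawn
#' per gene from `Beta(mc, (1 - m)c)` with mean `m = polya_mean_capture` and
#' concentration `c = polya_capture_concentration` for transient-bacterial
#' mRNA, and 0 for all rRNA (rRNA is not polyadenylated).
#'
#' @param annotation A [holobiont annotation][generate_annotation()].
#' @param seed Integer seed; per-species substreams keyed by
#'   `(seed, "pool", species_id)`.
#' @param specs Species specifications; defaults to those stored in the
#'   annotation.
#' @return A `transcript_pool` tibble with columns `species_id`, `source_id`,
#'   `molecule_class` (`"mRNA"`/`"rRNA"`), `relative_abundance` and
#'   `polya_capture_prob`.
#' @export
#' @examples
#' ann <- generate_annotation(species_spec("s", 10), seed = 1)
#' build_transcript_pool(ann, seed = 1)
build_transcript_pool <- function(annotation, seed = 1,
                                  specs = annotation$species) {
  validate_species_specs(specs)
  if (!all(specs$species_id %in% annotation$features$species_id)) {
    abort("specs reference species absent from the annotation")
  }
  pool <- purrr::pmap(specs, function(species_id, n_genes, expressed_fraction,
                                      expression_dispersion,
                                      rrna_transcript_fraction,
                                      polya_capture_model, polya_mean_capture,
                                      polya_capture_concentration, pool_weight,
                                      ...) {
    feat <- annotation$features[annotation$features$species_id == species_id, ]
    genes <- feat$feature_id[feat$type == "CDS"]
    rrna <- feat$feature_id[feat$type == "rRNA"]
    with_substream(seed, "pool", species_id, code = {
      n_expr <- round(expressed_fraction * length(genes))
      expressed <- sample(genes, n_expr)
      ab <- setNames(numeric(length(genes)), genes)
      if (n_expr > 0) {
        raw <- rlnorm(n_expr, meanlog = 0, sdlog = expression_dispersion)
        ab[expressed] <- raw / sum(raw) *
          pool_weight * (1 - rrna_transcript_fraction)
      }
      capture <- if (polya_capture_model == "stable_eukaryote") {
        rep(polya_mean_capture, length(genes))
      } else {
        m <- polya_mean_capture
        cc <- polya_capture_concentration
        rbeta(length(genes), m * cc, (1 - m) * cc)
      }
      bind_rows(
        tibble(species_id = species_id, source_id = genes,
               molecule_class = "mRNA", relative_abundance = unname(ab),
               polya_capture_prob = capture),
        tibble(species_id = species_id, source_id = rrna,
               molecule_class = "rRNA",
               relative_abundance =
                 pool_weight * rrna_transcript_fraction / length(rrna),
               polya_capture_prob = 0)
      )
    })
  })
  new_transcript_pool(purrr::list_rbind(pool))
}

new_transcript_pool <- function(x) {
  stopifnot(all(c("species_id", "source_id", "molecule_class",
                  "relative_abundance", "polya_capture_prob") %in% names(x)))
  if (any(x$relative_abundance < 0)) abort("abundances must be nonnegative")
  class(x) <- c("transcript_pool", class(tibble()))
  x
}

#' Library-preparation protocol parameters
#'
#' @param protocol One of `"none"`, `"polyA_capture"` (oligo(dT) pulldown) or
#'   `"rrna_depletion"` (subtractive rRNA removal).
#' @param rrna_depletion_efficiency Fraction of rRNA molecules removed when
#'   `protocol = "rrna_depletion"`, in `[0, 1]`. The default 0.95 reflects a
#'   high- but not perfectly-efficient commercial depletion kit.
#' @return A `protocol_params` list.
#' @export
#' @examples
#' protocol_params("rrna_depletion", 0.95)
protocol_params <- function(protocol = c("none", "polyA_capture",
                                         "rrna_depletion"),
                            rrna_depletion_efficiency = 0.95) {
  protocol <- match.arg(protocol)
  if (rrna_depletion_efficiency < 0 || rrna_depletion_efficiency > 1) {
    abort("rrna_depletion_efficiency must lie in [0, 1]")
  }
  structure(list(protocol = protocol,
                 rrna_depletion_efficiency = rrna_depletion_efficiency),
            class = "protocol_params")
}

#' Apply a library-preparation protocol to a transcript pool
#'
#' `polyA_capture` multiplies every entry's abundance by its poly(A)-capture
#' probability, so non-polyadenylated rRNA vanishes and bacterial mRNA is
#' thinned gene-dependently. `rrna_depletion` multiplies rRNA abundances by
#' `1 - efficiency` and leaves mRNA untouched. `none` is the identity.
#' Protocols only ever remove material: total pool weight never increases.
#'
#' @param pool A `transcript_pool`.
#' @param params A [protocol_params()] object.
#' @return The transformed `transcript_pool`.
#' @export
#' @examples
#' ann <- generate_annotation(species_spec("s", 10), seed = 1)
#' pool <- build_transcript_pool(ann, seed = 1)
#' apply_protocol(pool, protocol_params("rrna_depletion"))
apply_protocol <- function(pool, params) {
  stopifnot(inherits(params, "protocol_params"))
  out <- switch(
    params$protocol,
    none = pool,
    polyA_capture = mutate(
      pool,
      relative_abundance = .data$relative_abundance * .data$polya_capture_prob
    ),
    rrna_depletion = mutate(
      pool,
      relative_abundance = .data$relative_abundance *
        ifelse(.data$molecule_class == "rRNA",
               1 - params$rrna_depletion_efficiency, 1)
    )
  )
  if (sum(out$relative_abundance) <= 0) {
    abort("protocol removed all material: resulting pool is empty")
  }
  new_transcript_pool(as_tibble(out))
}

#' Model physical bacterial cell enrichment
#'
#' Multiplies the pool weight of every transient-bacterial species by
#' `factor`, emulating the centrifugation/filtration enrichment of symbiont
#' cells performed before RNA extraction.
#'
#' @param pool A `transcript_pool`.
#' @param specs Species specifications (to identify bacterial species).
#' @param factor Enrichment multiplier (`1` = unenriched).
#' @return The enriched `transcript_pool`.
#' @export
enrich_bacteria <- function(pool, specs, factor = 50) {
  bacterial <- specs$species_id[specs$polya_capture_model ==
                                  "transient_bacterial"]
  new_transcript_pool(mutate(
    pool,
    relative_abundance = .data$relative_abundance *
      ifelse(.data$species_id %in% bacterial, factor, 1)
  ))
}
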