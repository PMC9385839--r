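# GO-term representation statistics.
#
# GO terms are treated as flat labels: terms are counted exactly as
# annotated, with no ontology-graph ancestor propagation, matching how
# directly-assigned annotation exports are tallied in practice.

#' Genes expressed in a sample
#'
#' @param table A [gene_count_table()].
#' @param species_id Species of interest.
#' @param threshold Minimum read-pair count for a gene to count as
#'   expressed (default 1; the boundary is inclusive).
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(table, species_id, threshold = 1) {
  stopifnot(inherits(table, "gene_count_table"))
  cc <- table$counts
  if (!species_id %in% cc$species_id) abort("species absent from count table")
  cc$gene_id[cc$species_id == species_id & cc$count >= threshold]
}

#' Percentage of a species' GO terms that are expressed
#'
#' A GO term is expressed when at least one of its member genes is expressed
#' at the threshold. The percentage is over all GO terms annotated for the
#' species.
#'
#' @param table A [gene_count_table()].
#' @param go_map Tibble `species_id`, `gene_id`, `go_id` (see
#'   [generate_annotation()]).
#' @param species_id Species of interest.
#' @param threshold Expression threshold in read pairs.
#' @return Percentage in `[0, 100]`.
#' @export
expressed_go_percent <- function(table, go_map, species_id, threshold = 1) {
  gm <- distinct(go_map[go_map$species_id == species_id,
                        c("gene_id", "go_id")])
  if (nrow(gm) == 0) abort("species absent from GO map")
  expressed <- expressed_genes(table, species_id, threshold)
  n_terms <- length(unique(gm$go_id))
  n_expr <- length(unique(gm$go_id[gm$gene_id %in% expressed]))
  100 * n_expr / n_terms
}

#' Per-GO expression profile of a replicated dataset
#'
#' For each GO term of the species, the number and proportion of its member
#' genes expressed, computed per replicate and then arithmetically averaged
#' over replicates; the dataset-level expressed-GO percentage is averaged
#' likewise. Counts and proportions are averaged independently.
#'
#' @param tables List of replicate [gene_count_table()]s (>= 1) over the
#'   same gene universe.
#' @param go_map GO annotation tibble (`species_id`, `gene_id`, `go_id`).
#' @param species_id Species of interest.
#' @param threshold Expression threshold in read pairs.
#' @param label Dataset label (e.g. the protocol arm).
#' @return A `go_profile` tibble (`go_id`, `n_genes`, `mean_expressed_count`,
#'   `mean_expressed_prop`) with attributes `species_id`, `label`,
#'   `n_replicates` and `expressed_go_percent`.
#' @export
go_profile <- function(tables, go_map, species_id, threshold = 1,
                       label = "dataset") {
  if (length(tables) < 1) abort("need at least one replicate")
  gm <- distinct(go_map[go_map$species_id == species_id,
                        c("gene_id", "go_id")])
  if (nrow(gm) == 0) abort("species absent from GO map")
  universes <- purrr::map(tables, function(t) {
    sort(t$counts$gene_id[t$counts$species_id == species_id])
  })
  if (!all(vapply(universes, identical, logical(1), y = universes[[1]]))) {
    abort("replicate gene universes disagree")
  }
  term_sizes <- gm |> count(.data$go_id, name = "n_genes")

  per_rep <- purrr::map(tables, function(t) {
    expressed <- expressed_genes(t, species_id, threshold)
    gm |>
      group_by(.data$go_id) |>
      summarise(expressed_count = sum(.data$gene_id %in% expressed),
                .groups = "drop")
  })
  counts_mat <- do.call(cbind, purrr::map(per_rep, "expressed_count"))
  prof <- term_sizes |>
    mutate(mean_expressed_count = rowMeans(counts_mat),
           mean_expressed_prop = rowMeans(counts_mat / .data$n_genes)) |>
    arrange(.data$go_id)

  ego <- mean(map_dbl(tables, expressed_go_percent, go_map = go_map,
                      species_id = species_id, threshold = threshold))
  structure(prof,
            class = c("go_profile", class(tibble())),
            species_id = species_id, label = label,
            n_replicates = length(tables),
            expressed_go_percent = ego)
}

#' Most differentially represented GO terms between two datasets
#'
#' Ranks GO terms by the absolute difference in mean expressed-gene number
#' between two [go_profile()]s and returns the `n` largest, sorted by
#' decreasing difference with ties broken lexicographically by GO id
#' (deterministic). `n` is capped at the size of the GO universe.
#'
#' @param profile_a,profile_b [go_profile()]s over the same species and GO
#'   universe.
#' @param n Number of terms to return (conventionally 30).
#' @return A `differential_go` tibble: `go_id`, `mean_a`, `mean_b`,
#'   `abs_diff`.
#' @export
top_differential_go <- function(profile_a, profile_b, n = 30) {
  if (!identical(attr(profile_a, "species_id"),
                 attr(profile_b, "species_id"))) {
    abort("profiles compare different species")
  }
  if (!identical(profile_a$go_id, profile_b$go_id)) {
    abort("profiles have mismatched GO universes")
  }
  out <- tibble(
    go_id = profile_a$go_id,
    mean_a = profile_a$mean_expressed_count,
    mean_b = profile_b$mean_expressed_count
  ) |>
    mutate(abs_diff = abs(.data$mean_a - .data$mean_b)) |>
    arrange(desc(.data$abs_diff), .data$go_id) |>
    head(n = min(n, nrow(profile_a)))
  structure(out, class = c("differential_go", class(tibble())),
            labels = c(attr(profile_a, "label"), attr(profile_b, "label")),
            species_id = attr(profile_a, "species_id"))
}
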