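# Shared fixtures, built in code. The full default experiment is expensive
# (seven samples at 1e5 pairs), so it is computed once per test run and
# cached for every test that inspects it.

.holosim_cache <- new.env(parent = emptyenv())

default_experiment_report <- function() {
  if (is.null(.holosim_cache$report)) {
    .holosim_cache$report <- run_experiment(experiment_config(seed = 101))
  }
  .holosim_cache$report
}

tiny_specs <- function() {
  dplyr::bind_rows(
    species_spec("host", 20, gene_length_range = c(300, 600),
                 expressed_fraction = 0.5, expression_dispersion = 1,
                 rrna_transcript_fraction = 0.8,
                 polya_capture_model = "stable_eukaryote",
                 polya_mean_capture = 1, pool_weight = 1),
    species_spec("sym1", 15, pool_weight = 0.1)
  )
}

tiny_annotation <- function(seed = 42) generate_annotation(tiny_specs(),
                                                           seed = seed)

# Hand-built count table over an explicit gene universe.
manual_count_table <- function(counts, sample_id = "s") {
  gene_count_table(tibble::tibble(
    species_id = counts$species_id,
    gene_id = counts$gene_id,
    count = counts$count
  ), sample_id = sample_id)
}

# A read set built directly from explicit mate sequences/qualities.
manual_read_set <- function(mate1, mate2, qual1 = NULL, qual2 = NULL,
                            truth = NULL) {
  n <- length(mate1)
  q40 <- function(s) vapply(nchar(s), function(l)
    strrep(rawToChar(as.raw(40 + 33)), l), character(1))
  pairs <- tibble::tibble(
    pair_id = sprintf("p%03d", seq_len(n)),
    mate1 = mate1, mate2 = mate2,
    qual1 = qual1 %||% q40(mate1),
    qual2 = qual2 %||% q40(mate2)
  )
  if (is.null(truth)) {
    truth <- tibble::tibble(pair_id = pairs$pair_id,
                            species_id = NA_character_,
                            source_id = NA_character_,
                            molecule_class = NA_character_)
  }
  holosim:::new_read_set(pairs, truth, read_length = max(nchar(mate1)))
}

`%||%` <- rlang::`%||%`
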