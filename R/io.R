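# Plain-text fixture IO: FASTA, GFF3, GO map TSV, paired FASTQ, truth TSV.

#' Write a holobiont annotation (and optionally reads) to standard files
#'
#' Emits `genomes.fasta` (one record per scaffold), `features.gff3`
#' (feature types `CDS` and `rRNA`, attribute `ID=<feature_id>`, 1-based
#' inclusive coordinates), `species.tsv` (the species specifications),
#' `go_map.tsv` (`species_id`, `gene_id`, semicolon-joined GO ids) and, when
#' a read set is given, Phred+33 FASTQ mates `reads_1.fastq`/`reads_2.fastq`
#' plus `truth.tsv`. Everything round-trips losslessly through
#' [read_fixture()].
#'
#' @param annotation A [holobiont annotation][generate_annotation()].
#' @param dir Output directory (created if needed).
#' @param reads Optional `read_set`.
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(annotation, dir, reads = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genomes = file.path(dir, "genomes.fasta"),
    features = file.path(dir, "features.gff3"),
    species = file.path(dir, "species.tsv"),
    go_map = file.path(dir, "go_map.tsv")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(annotation$genomes), paths[["genomes"]])

  feat <- annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = feat$scaffold,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end),
    strand = feat$strand
  )
  S4Vectors::mcols(gr)$source <- "holosim"
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$ID <- feat$feature_id
  # intron-free CDS all start in frame 0
  S4Vectors::mcols(gr)$phase <- ifelse(feat$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, paths[["features"]], format = "gff3")

  readr::write_tsv(annotation$species, paths[["species"]])
  go <- annotation$go_map |>
    group_by(.data$species_id, .data$gene_id) |>
    summarise(go_ids = paste(sort(.data$go_id), collapse = ";"),
              .groups = "drop")
  readr::write_tsv(go, paths[["go_map"]])

  if (!is.null(reads)) {
    paths <- c(paths,
               reads_1 = file.path(dir, "reads_1.fastq"),
               reads_2 = file.path(dir, "reads_2.fastq"),
               truth = file.path(dir, "truth.tsv"))
    write_fastq_mate(reads$pairs$pair_id, reads$pairs$mate1,
                     reads$pairs$qual1, paths[["reads_1"]])
    write_fastq_mate(reads$pairs$pair_id, reads$pairs$mate2,
                     reads$pairs$qual2, paths[["reads_2"]])
    readr::write_tsv(reads$truth, paths[["truth"]])
  }
  invisible(paths)
}

write_fastq_mate <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
}

#' Read a fixture directory back into annotation and reads
#'
#' @param dir Directory produced by [write_fixture()].
#' @return List with `annotation` (a `holobiont_annotation`) and, when FASTQ
#'   files are present, `reads` (a `read_set`).
#' @export
read_fixture <- function(dir) {
  specs <- readr::read_tsv(file.path(dir, "species.tsv"),
                           show_col_types = FALSE) |>
    mutate(across(c("n_genes", "gene_length_min", "gene_length_max"),
                  as.integer))
  genomes <- Biostrings::readDNAStringSet(file.path(dir, "genomes.fasta"))
  gff <- rtracklayer::import(file.path(dir, "features.gff3"))
  feat <- tibble(
    feature_id = S4Vectors::mcols(gff)$ID,
    type = as.character(S4Vectors::mcols(gff)$type),
    scaffold = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff))
  )
  feat$species_id <- specs$species_id[
    match(feat$scaffold, paste0(specs$species_id, "_scaffold"))]
  if (anyNA(feat$species_id)) {
    # fall back: species id is the scaffold name up to the last "_scaffold"
    feat$species_id <- sub("_scaffold$", "", feat$scaffold)
  }
  feat$length <- feat$end - feat$start + 1L
  feat <- feat[, c("species_id", "feature_id", "type", "scaffold",
                   "start", "end", "strand", "length")]

  go_raw <- readr::read_tsv(file.path(dir, "go_map.tsv"),
                            show_col_types = FALSE)
  go_map <- go_raw |>
    mutate(go_id = strsplit(.data$go_ids, ";", fixed = TRUE)) |>
    tidyr::unnest("go_id") |>
    select("species_id", "gene_id", "go_id") |>
    arrange(.data$species_id, .data$gene_id, .data$go_id)

  ann <- structure(
    list(species = validate_species_specs(specs),
         genomes = setNames(as.character(genomes), names(genomes)),
         features = feat,
         go_map = as_tibble(go_map)),
    class = "holobiont_annotation"
  )

  out <- list(annotation = ann)
  fq1 <- file.path(dir, "reads_1.fastq")
  if (file.exists(fq1)) {
    m1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fq1))
    m2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
      file.path(dir, "reads_2.fastq")))
    truth_path <- file.path(dir, "truth.tsv")
    truth <- if (file.exists(truth_path)) {
      readr::read_tsv(truth_path, show_col_types = FALSE)
    } else {
      tibble(pair_id = character(), species_id = character(),
             source_id = character(), molecule_class = character())
    }
    out$reads <- new_read_set(
      pairs = tibble(
        pair_id = names(m1),
        mate1 = as.character(m1),
        mate2 = as.character(m2),
        qual1 = as.character(Biostrings::quality(m1)),
        qual2 = as.character(Biostrings::quality(m2))
      ),
      truth = truth,
      read_length = max(nchar(as.character(m1)))
    )
  }
  out
}
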