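# Builds assignments by hand to probe the union-overlap counting rules.

manual_annotation <- function(genes) {
  structure(list(
    species = species_spec("s", nrow(genes)),
    genomes = c(s_scaffold = strrep("A", 10000)),
    features = tibble::tibble(
      species_id = "s", feature_id = genes$gene_id, type = "CDS",
      scaffold = "s_scaffold", start = genes$start, end = genes$end,
      strand = genes$strand, length = genes$end - genes$start + 1L
    ),
    go_map = tibble::tibble(species_id = character(), gene_id = character(),
                            go_id = character())
  ), class = "holobiont_annotation")
}

manual_assignments <- function(loci) {
  holosim:::new_pair_assignments(tibble::tibble(
    pair_id = sprintf("p%03d", seq_len(nrow(loci))),
    status = "assigned",
    species_id = "s",
    scaffold = "s_scaffold",
    start = loci$start, end = loci$end, strand = loci$strand
  ))
}

test_that("single-gene overlaps count once, with the reverse strand rule", {
  ann <- manual_annotation(tibble::tibble(
    gene_id = c("g1", "g2"), start = c(100L, 600L), end = c(400L, 900L),
    strand = c("+", "-")))
  # mate1 aligned "-" against a "+" gene: compatible under reverse
  asg <- manual_assignments(tibble::tibble(
    start = c(150L, 650L), end = c(350L, 850L), strand = c("-", "-")))
  tab <- count_genes(asg, ann, strandedness = "reverse")
  expect_equal(tab$counts$count[tab$counts$gene_id == "g1"], 1L)
  expect_equal(tab$counts$count[tab$counts$gene_id == "g2"], 0L)
  expect_equal(tab$stats$no_feature_pairs, 1L)

  fwd <- count_genes(asg, ann, strandedness = "forward")
  expect_equal(fwd$counts$count[fwd$counts$gene_id == "g2"], 1L)
  none <- count_genes(asg, ann, strandedness = "none")
  expect_equal(sum(none$counts$count), 2L)
})

test_that("a pair spanning two genes is feature-ambiguous, not counted", {
  ann <- manual_annotation(tibble::tibble(
    gene_id = c("g1", "g2"), start = c(100L, 350L), end = c(400L, 700L),
    strand = c("+", "+")))
  asg <- manual_assignments(tibble::tibble(start = 300L, end = 500L,
                                           strand = "-"))
  tab <- count_genes(asg, ann)
  expect_equal(sum(tab$counts$count), 0L)
  expect_equal(tab$stats$ambiguous_feature_pairs, 1L)
  expect_equal(tab$stats$no_feature_pairs, 0L)
})

test_that("counting matches a quadratic overlap oracle on random layouts", {
  withr::local_seed(41)
  for (rep in 1:60) {
    n_genes <- sample(2:8, 1)
    starts <- sort(sample(seq(50, 5000, by = 10), n_genes))
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", seq_len(n_genes)),
      start = starts,
      end = starts + sample(50:600, n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    n_loci <- sample(5:25, 1)
    lstart <- sample(1:5500, n_loci, replace = TRUE)
    loci <- tibble::tibble(start = lstart,
                           end = lstart + sample(50:300, n_loci,
                                                 replace = TRUE),
                           strand = sample(c("+", "-"), n_loci,
                                           replace = TRUE))
    ann <- manual_annotation(genes)
    tab <- count_genes(manual_assignments(loci), ann,
                       strandedness = "reverse")
    want <- oracle_count_loci(loci, genes, "reverse")
    expect_equal(setNames(tab$counts$count, tab$counts$gene_id)[
      names(want$gene_counts)], want$gene_counts)
    expect_equal(tab$stats$ambiguous_feature_pairs, want$ambiguous)
    expect_equal(tab$stats$no_feature_pairs, want$none)
  }
})

test_that("unknown species in assignments is a hard error", {
  ann <- manual_annotation(tibble::tibble(gene_id = "g1", start = 10L,
                                          end = 50L, strand = "+"))
  asg <- holosim:::new_pair_assignments(tibble::tibble(
    pair_id = "p1", status = "assigned", species_id = "ghost",
    scaffold = "x", start = 1L, end = 10L, strand = "+"))
  expect_error(count_genes(asg, ann), "ghost")
})

test_that("count tables validate their own invariants", {
  expect_error(gene_count_table(tibble::tibble(
    species_id = "s", gene_id = c("g1", "g1"), count = c(1L, 2L)), "x"),
    "duplicated")
  expect_error(gene_count_table(tibble::tibble(
    species_id = "s", gene_id = "g1", count = -1L), "x"), "nonnegative")
})
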