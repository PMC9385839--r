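mk_table <- function(counts, id = "s1") manual_count_table(tibble::tibble(
  species_id = "s", gene_id = names(counts), count = as.integer(counts)),
  sample_id = id)

mk_go <- function(...) {
  pairs <- list(...)
  tibble::tibble(
    species_id = "s",
    gene_id = unlist(pairs, use.names = FALSE),
    go_id = rep(names(pairs), lengths(pairs))
  )
}

test_that("expressed gene sets respect the inclusive threshold", {
  tab <- mk_table(c(g1 = 1, g2 = 0))
  expect_setequal(expressed_genes(tab, "s"), "g1")
  expect_length(expressed_genes(mk_table(c(g1 = 0, g2 = 0)), "s"), 0)
  tab5 <- mk_table(c(g1 = 5, g2 = 4))
  expect_setequal(expressed_genes(tab5, "s", threshold = 5), "g1")
})

test_that("expressed GO percentage counts terms with any expressed member", {
  go <- mk_go("GO:A" = c("g1", "g2"), "GO:B" = "g3")
  tab <- mk_table(c(g1 = 2, g2 = 0, g3 = 0))
  expect_equal(expressed_go_percent(tab, go, "s"), 50)
  all_on <- mk_table(c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(expressed_go_percent(all_on, go, "s"), 100)
})

test_that("random bipartite annotations match the term-by-term oracle", {
  withr::local_seed(61)
  for (rep in 1:50) {
    n_genes <- sample(4:25, 1)
    genes <- sprintf("g%02d", seq_len(n_genes))
    n_terms <- sample(2:10, 1)
    go <- tibble::tibble(
      species_id = "s",
      go_id = rep(sprintf("GO:%03d", seq_len(n_terms)),
                  each = 3),
      gene_id = sample(genes, 3 * n_terms, replace = TRUE)
    )
    counts <- setNames(rpois(n_genes, 0.8), genes)
    tab <- mk_table(counts)
    expect_equal(
      expressed_go_percent(tab, go, "s"),
      oracle_expressed_go_percent(go, names(counts)[counts >= 1]))
  }
})

test_that("profiles average counts and proportions over replicates", {
  go <- mk_go("GO:A" = c("g1", "g2"), "GO:B" = "g3")
  r1 <- mk_table(c(g1 = 2, g2 = 3, g3 = 0), "r1")
  prof_same <- go_profile(list(r1, r1), go, "s", label = "d")
  expect_equal(prof_same$mean_expressed_count,
               c(2, 0)[match(prof_same$go_id, c("GO:A", "GO:B"))])

  r2 <- mk_table(c(g1 = 0, g2 = 0, g3 = 0), "r2")
  prof <- go_profile(list(r1, r2), go, "s")
  expect_equal(prof$mean_expressed_count[prof$go_id == "GO:A"], 1)
  expect_equal(prof$mean_expressed_prop[prof$go_id == "GO:A"], 0.5)
  expect_equal(attr(prof, "expressed_go_percent"), mean(c(50, 0)))

  # per-replicate oracle on three random replicates
  withr::local_seed(62)
  genes <- sprintf("g%02d", 1:12)
  go_r <- tibble::tibble(
    species_id = "s",
    go_id = rep(sprintf("GO:%03d", 1:5), each = 4),
    gene_id = sample(genes, 20, replace = TRUE))
  reps <- lapply(1:3, function(i) mk_table(setNames(rpois(12, 1), genes),
                                           paste0("r", i)))
  prof <- go_profile(reps, go_r, "s")
  for (term in prof$go_id) {
    members <- unique(go_r$gene_id[go_r$go_id == term])
    per_rep <- vapply(reps, function(t) {
      length(intersect(members, expressed_genes(t, "s")))
    }, numeric(1))
    expect_equal(prof$mean_expressed_count[prof$go_id == term],
                 mean(per_rep))
  }
})

test_that("differential GO ranking is by difference then GO id", {
  go <- mk_go("GO:X" = c("g1", "g2"), "GO:Y" = "g3")
  mk_prof <- function(counts, label) {
    go_profile(list(mk_table(counts)), go, "s", label = label)
  }
  a <- mk_prof(c(g1 = 4, g2 = 9, g3 = 2), "a")   # GO:X 2 expressed, GO:Y 1
  b <- mk_prof(c(g1 = 1, g2 = 0, g3 = 5), "b")   # GO:X 1 expressed, GO:Y 1
  top <- top_differential_go(a, b, n = 1)
  expect_equal(top$go_id, "GO:X")
  expect_equal(top$abs_diff, 1)

  tied <- top_differential_go(a, a, n = 2)
  expect_equal(tied$go_id, c("GO:X", "GO:Y"))  # lexical order on ties
  expect_equal(tied$abs_diff, c(0, 0))
})

test_that("top-N equals a full-sort oracle on random profiles", {
  withr::local_seed(63)
  for (rep in 1:40) {
    n_terms <- sample(10:60, 1)
    ids <- sprintf("GO:%04d", sample(1e4, n_terms))
    a_means <- round(runif(n_terms, 0, 20), 1)
    b_means <- round(runif(n_terms, 0, 20), 1)
    prof <- function(m, lab) structure(
      tibble::tibble(go_id = sort(ids), n_genes = 5L,
                     mean_expressed_count = m[order(ids)],
                     mean_expressed_prop = 0.5),
      class = c("go_profile", class(tibble::tibble())),
      species_id = "s", label = lab, n_replicates = 1,
      expressed_go_percent = 50)
    top <- top_differential_go(prof(a_means, "a"), prof(b_means, "b"),
                               n = 30)
    want <- oracle_top_go(sort(ids), a_means[order(ids)],
                          b_means[order(ids)], 30)
    expect_identical(top$go_id, want)
  }
})

test_that("adding reads never silences an expressed GO term", {
  go <- mk_go("GO:A" = c("g1", "g2"), "GO:B" = c("g2", "g3"),
              "GO:C" = "g4")
  base <- c(g1 = 0, g2 = 1, g3 = 0, g4 = 0)
  p0 <- expressed_go_percent(mk_table(base), go, "s")
  withr::local_seed(64)
  for (rep in 1:20) {
    more <- base + rpois(4, 1)
    expect_gte(expressed_go_percent(mk_table(more), go, "s"), p0)
  }
})
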