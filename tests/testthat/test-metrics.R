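test_that("taxonomic distribution is plain percentage arithmetic", {
  asg <- holosim:::new_pair_assignments(tibble::tibble(
    pair_id = sprintf("p%03d", 1:100),
    status = "assigned",
    species_id = rep(c("A", "B", "C", "D"), c(77, 19, 3, 1)),
    scaffold = "x", start = 1L, end = 2L, strand = "+"
  ))
  td <- taxonomic_distribution(asg)
  expect_equal(setNames(td$percent, td$species_id),
               c(A = 77, B = 19, C = 3, D = 1))
  expect_equal(sum(td$percent), 100)

  single <- holosim:::new_pair_assignments(tibble::tibble(
    pair_id = "p1", status = "assigned", species_id = "A",
    scaffold = "x", start = 1L, end = 2L, strand = "+"))
  expect_equal(taxonomic_distribution(single)$percent, 100)

  nothing <- holosim:::new_pair_assignments(tibble::tibble(
    pair_id = "p1", status = "unaligned", species_id = NA_character_,
    scaffold = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_))
  expect_error(taxonomic_distribution(nothing), "no assigned")
})

test_that("gene coverage divides expressed genes by all annotated genes", {
  tab <- manual_count_table(tibble::tibble(
    species_id = "s", gene_id = c("g1", "g2", "g3"), count = c(5L, 1L, 0L)))
  cov <- gene_coverage(tab, thresholds = c(1, 5))
  expect_equal(cov$coverage[cov$threshold == 1], 100 * 2 / 3)
  expect_equal(cov$coverage[cov$threshold == 5], 100 * 1 / 3)
  expect_error(gene_coverage(tab, thresholds = 0), ">= 1")
})

test_that("coverage is non-increasing in the threshold on random tables", {
  withr::local_seed(55)
  for (rep in 1:20) {
    n <- sample(10:100, 1)
    tab <- manual_count_table(tibble::tibble(
      species_id = "s", gene_id = sprintf("g%03d", 1:n),
      count = rpois(n, sample(c(0.5, 2, 10), 1))))
    cov <- gene_coverage(tab, thresholds = 1:10)
    expect_true(all(diff(cov$coverage[order(cov$threshold)]) <= 1e-12))
  }
})

test_that("depth summaries use expressed genes and the midpoint median", {
  tab <- manual_count_table(tibble::tibble(
    species_id = "s", gene_id = sprintf("g%d", 1:5),
    count = c(3L, 7L, 11L, 0L, 0L)))
  d <- depth_stats(tab)
  expect_equal(d$median, 7)
  expect_equal(d$n_expressed, 3)

  even <- manual_count_table(tibble::tibble(
    species_id = "s", gene_id = c("g1", "g2"), count = c(2L, 4L)))
  expect_equal(depth_stats(even)$median, 3)

  # sort-based oracle on random tables
  withr::local_seed(56)
  for (rep in 1:30) {
    counts <- rpois(sample(5:50, 1), 6)
    tab <- manual_count_table(tibble::tibble(
      species_id = "s", gene_id = sprintf("g%03d", seq_along(counts)),
      count = counts))
    d <- depth_stats(tab)
    expr <- sort(counts[counts >= 1])
    n <- length(expr)
    want_med <- if (n %% 2 == 1) expr[(n + 1) / 2] else
      (expr[n / 2] + expr[n / 2 + 1]) / 2
    expect_equal(d$median, want_med)
    expect_equal(d$mean, mean(expr))
  }
})

test_that("replicate Spearman matches the rank-then-Pearson oracle", {
  mk <- function(counts, id) manual_count_table(tibble::tibble(
    species_id = "s", gene_id = sprintf("g%03d", seq_along(counts)),
    count = as.integer(counts)), sample_id = id)

  t1 <- mk(c(5, 3, 8, 1), "a")
  expect_equal(unname(spearman_replicates(list(t1, t1), "s")[1, 2]), 1)

  m <- spearman_replicates(list(mk(c(0, 1, 3, 8), "a"),
                                mk(c(8, 3, 1, 0), "b")), "s")
  expect_equal(unname(m[1, 2]), -1)

  withr::local_seed(57)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    x <- rpois(n, 3)  # plenty of ties
    y <- rpois(n, 3)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    m <- spearman_replicates(list(mk(x, "a"), mk(y, "b")), "s")
    expect_equal(unname(m[1, 2]), oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("constant replicate vectors are flagged, not silent NaN", {
  mk <- function(counts, id) manual_count_table(tibble::tibble(
    species_id = "s", gene_id = sprintf("g%03d", seq_along(counts)),
    count = as.integer(counts)), sample_id = id)
  expect_warning(
    m <- spearman_replicates(list(mk(c(2, 2, 2), "a"), mk(c(1, 2, 3), "b")),
                             "s"),
    "constant")
  expect_true(is.na(m[1, 2]))
  expect_equal(diag(m), c(a = 1, b = 1))
})

test_that("method comparisons match the closed-form t statistic", {
  same <- compare_methods(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$p_value, 1)

  degen <- compare_methods(c(10, 10, 10), c(0, 0, 0),
                           alternative = "greater")
  expect_equal(degen$p_value, 0)
  expect_equal(degen$statistic, Inf)
  degen_eq <- compare_methods(c(5, 5), c(5, 5))
  expect_equal(degen_eq$p_value, 1)
  expect_equal(degen_eq$statistic, 0)

  withr::local_seed(58)
  for (rep in 1:40) {
    a <- rnorm(sample(3:6, 1), 10, 2)
    b <- rnorm(sample(3:6, 1), 8, 3)
    for (ve in c(TRUE, FALSE)) {
      cmp <- compare_methods(a, b, var_equal = ve)
      expect_equal(cmp$statistic, oracle_t_statistic(a, b, ve),
                   tolerance = 1e-10)
    }
  }
  expect_error(compare_methods(1, c(1, 2)), "two replicates")
})

test_that("comparison objects tidy and glance like broom fits", {
  cmp <- compare_methods(c(89.2, 90.1, 89.8), c(70.3, 69.5, 70.4),
                         alternative = "greater", metric = "coverage",
                         labels = c("rrna", "polya"))
  td <- tidy(cmp)
  expect_equal(nrow(td), 6)
  expect_setequal(unique(td$label), c("rrna", "polya"))
  g <- glance(cmp)
  expect_equal(nrow(g), 1)
  expect_equal(g$kind, "one_tailed_t")
  expect_lt(g$p_value, 0.001)
  expect_equal(g$mean_a, mean(c(89.2, 90.1, 89.8)))
  expect_equal(g$sd_a, sd(c(89.2, 90.1, 89.8)))
})
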