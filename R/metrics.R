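# Evaluation metrics: taxonomic distribution, coverage, depth, correlation,
# and between-method t-tests.

#' Taxonomic distribution of assigned read pairs
#'
#' Percentage of assigned pairs attributed to each species, after the
#' genome-ambiguous discard.
#'
#' @param x A [pair_assignments][assign_pairs()] tibble or a
#'   [gene_count_table()] produced by [count_genes()].
#' @return A `taxonomic_distribution` tibble: `species_id`, `n_pairs`,
#'   `percent` (summing to 100).
#' @export
taxonomic_distribution <- function(x) {
  by_species <- if (inherits(x, "gene_count_table")) {
    x$stats$assigned_by_species %||%
      abort("count table carries no assignment tallies")
  } else {
    as_tibble(x) |>
      filter(.data$status == "assigned") |>
      count(.data$species_id, name = "n_pairs")
  }
  total <- sum(by_species$n_pairs)
  if (total == 0) abort("no assigned pairs")
  out <- by_species |>
    mutate(percent = 100 * .data$n_pairs / total) |>
    arrange(desc(.data$percent))
  class(out) <- c("taxonomic_distribution", class(tibble()))
  out
}

#' Gene coverage at read-pair thresholds
#'
#' Coverage is the percentage of a species' annotated genes with at least
#' `threshold` read pairs: expressed gene number divided by total gene
#' number. The denominator is *all* annotated genes, including
#' never-expressed ones. Coverage is non-increasing in the threshold.
#'
#' @param table A [gene_count_table()].
#' @param thresholds Integer read-pair thresholds (>= 1); the conventional
#'   pair is `c(1, 5)` (detection, and the usual pre-filter for differential
#'   expression).
#' @param species_id Optional species filter.
#' @return A `gene_coverage` tibble: `sample_id`, `species_id`, `threshold`,
#'   `n_expressed`, `n_genes`, `coverage` (percent).
#' @export
gene_coverage <- function(table, thresholds = c(1, 5), species_id = NULL) {
  stopifnot(inherits(table, "gene_count_table"))
  if (any(thresholds < 1)) abort("thresholds must be >= 1")
  counts <- table$counts
  if (!is.null(species_id)) {
    if (!all(species_id %in% counts$species_id)) {
      abort("species absent from count table")
    }
    counts <- counts[counts$species_id %in% species_id, ]
  }
  out <- tidyr::crossing(distinct(counts, .data$species_id),
                         threshold = as.integer(thresholds)) |>
    left_join(counts, by = "species_id", relationship = "many-to-many") |>
    group_by(.data$species_id, .data$threshold) |>
    summarise(n_expressed = sum(.data$count >= .data$threshold[1]),
              n_genes = n(),
              .groups = "drop") |>
    mutate(coverage = 100 * .data$n_expressed / .data$n_genes,
           sample_id = table$sample_id, .before = 1)
  class(out) <- c("gene_coverage", class(tibble()))
  out
}

#' Gene-depth summary statistics
#'
#' Summaries of per-gene read-pair counts. By default only expressed genes
#' (count >= 1) enter the summary, matching depth boxplots of mapped genes;
#' `include_zeros = TRUE` summarises all genes. The median uses the midpoint
#' rule for even sample sizes; quartiles are type-7.
#'
#' @param table A [gene_count_table()].
#' @param species_id Optional species filter; if a requested species has no
#'   expressed genes this is an error.
#' @param include_zeros Include silent genes in the summary?
#' @return A `depth_report` tibble: `sample_id`, `species_id`, `n_expressed`,
#'   `mean`, `q1`, `median`, `q3`.
#' @export
depth_stats <- function(table, species_id = NULL, include_zeros = FALSE) {
  stopifnot(inherits(table, "gene_count_table"))
  counts <- table$counts
  if (!is.null(species_id)) {
    if (!all(species_id %in% counts$species_id)) {
      abort("species absent from count table")
    }
    counts <- counts[counts$species_id %in% species_id, ]
  }
  out <- counts |>
    group_by(.data$species_id) |>
    summarise(n_expressed = sum(.data$count >= 1L),
              depth = list(if (include_zeros) .data$count
                           else .data$count[.data$count >= 1L]),
              .groups = "drop") |>
    mutate(mean = map_dbl(.data$depth, ~ if (length(.x)) mean(.x) else NA_real_),
           q1 = map_dbl(.data$depth,
                        ~ if (length(.x)) unname(quantile(.x, 0.25))
                          else NA_real_),
           median = map_dbl(.data$depth,
                            ~ if (length(.x)) median(.x) else NA_real_),
           q3 = map_dbl(.data$depth,
                        ~ if (length(.x)) unname(quantile(.x, 0.75))
                          else NA_real_),
           sample_id = table$sample_id, .before = 1) |>
    select(-"depth")
  if (!is.null(species_id) && anyNA(out$median) && !include_zeros) {
    abort("requested species has no expressed genes")
  }
  class(out) <- c("depth_report", class(tibble()))
  out
}

#' Spearman correlation between replicate count tables
#'
#' Rank correlation of per-gene counts between every pair of samples,
#' computed over the full gene vector *including zeros*; ties receive
#' average ranks. A constant count vector makes rank correlation undefined:
#' such samples are flagged with a warning and their correlations set `NA`
#' rather than silently propagating `NaN`.
#'
#' @param tables List of [gene_count_table()]s over an identical gene
#'   universe (>= 2).
#' @param species_id Species whose genes to correlate.
#' @return A symmetric correlation matrix with unit diagonal, sample ids as
#'   dimnames (class `spearman_matrix`).
#' @export
spearman_replicates <- function(tables, species_id) {
  if (length(tables) < 2) abort("need at least two samples")
  vecs <- purrr::map(tables, function(t) {
    stopifnot(inherits(t, "gene_count_table"))
    cc <- t$counts[t$counts$species_id == species_id, ]
    setNames(cc$count, cc$gene_id)[order(cc$gene_id)]
  })
  universe <- names(vecs[[1]])
  if (length(universe) == 0) abort("species absent from count tables")
  same <- vapply(vecs, function(v) identical(names(v), universe), logical(1))
  if (!all(same)) abort("replicate gene universes disagree")
  ids <- map_chr(tables, "sample_id")
  mat <- do.call(cbind, purrr::map(vecs, unname))
  colnames(mat) <- ids
  constant <- apply(mat, 2, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(cor(mat, method = "spearman"))
  if (any(constant)) {
    warn(paste("constant count vector(s), correlation undefined for:",
               paste(ids[constant], collapse = ", ")))
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
  }
  diag(rho) <- 1
  structure(rho, class = c("spearman_matrix", "matrix", "array"),
            species_id = species_id)
}

#' Compare a metric between two library-preparation methods
#'
#' Two-sample t-test over replicate values of a metric (coverage, expressed
#' GO percent, ...), reporting each group as mean (+/- sd) in the style
#' conventional for triplicate RNA-Seq summaries. The default is Welch's
#' unequal-variance test; `var_equal = TRUE` pools variances.
#' `alternative = "greater"` tests whether method A exceeds method B
#' (one-tailed).
#'
#' If both groups are exactly constant the t statistic is degenerate; the
#' documented rule is `p = 1` (statistic 0) when the group means are equal
#' and `p = 0` (infinite statistic) when they differ.
#'
#' @param values_a,values_b Numeric replicate values (>= 2 each).
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @param var_equal Pool variances instead of Welch's approximation?
#' @param metric Name of the compared metric.
#' @param labels Length-2 method labels.
#' @return A `method_comparison` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
#' @examples
#' cmp <- compare_methods(c(89.2, 90.1, 89.8), c(70.3, 69.5, 70.4),
#'                        alternative = "greater", metric = "coverage")
#' glance(cmp)
compare_methods <- function(values_a, values_b,
                            alternative = c("two_sided", "greater", "less"),
                            var_equal = FALSE,
                            metric = "metric",
                            labels = c("A", "B")) {
  alternative <- match.arg(alternative)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("need at least two replicates per group")
  }
  degenerate <- sd(values_a) == 0 && sd(values_b) == 0
  if (degenerate) {
    delta <- mean(values_a) - mean(values_b)
    statistic <- if (delta == 0) 0 else sign(delta) * Inf
    p_value <- switch(alternative,
      two_sided = as.numeric(delta == 0),
      greater = if (delta > 0) 0 else 1,
      less = if (delta < 0) 0 else 1
    )
    df <- NA_real_
  } else {
    tt <- t.test(values_a, values_b,
                 alternative = sub("two_sided", "two.sided", alternative),
                 var.equal = var_equal)
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
    df <- unname(tt$parameter)
  }
  structure(
    list(
      metric = metric,
      labels = labels,
      values = setNames(list(values_a, values_b), labels),
      summary = tibble(
        label = labels,
        n = c(length(values_a), length(values_b)),
        mean = c(mean(values_a), mean(values_b)),
        sd = c(sd(values_a), sd(values_b)),
        sem = c(sd(values_a) / sqrt(length(values_a)),
                sd(values_b) / sqrt(length(values_b)))
      ),
      kind = if (alternative == "two_sided") "two_tailed_t" else
        "one_tailed_t",
      alternative = alternative,
      var_equal = var_equal,
      statistic = statistic,
      df = df,
      p_value = p_value
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<method_comparison> %s\n", x$metric))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.4g (+/- %.4g), n = %d\n",
                s$label[i], s$mean[i], s$sd[i], s$n[i]))
  }
  cat(sprintf("  %s (%s): t = %.4g, p = %.3g\n", x$kind, x$alternative,
              x$statistic, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a method comparison into one row per replicate value
#' @param x A [compare_methods()] result.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `label`, `replicate`, `value`.
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) {
  purrr::imap(x$values, function(v, lab) {
    tibble(metric = x$metric, label = lab,
           replicate = seq_along(v), value = v)
  }) |> purrr::list_rbind()
}

#' One-row summary of a method comparison
#' @param x A [compare_methods()] result.
#' @param ... Unused.
#' @return A one-row tibble with group means/sds and the test result.
#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  s <- x$summary
  tibble(metric = x$metric,
         label_a = s$label[1], mean_a = s$mean[1], sd_a = s$sd[1],
         label_b = s$label[2], mean_b = s$mean[2], sd_b = s$sd[2],
         kind = x$kind, alternative = x$alternative,
         statistic = x$statistic, df = x$df, p_value = x$p_value)
}
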