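# End-to-end experiment orchestration: simulate -> trim -> assign -> count
# -> metrics -> GO, over several protocol arms with replicates.

#' Configure a library-preparation comparison experiment
#'
#' The default design mirrors the canonical three-way comparison: three
#' bacterial-enriched rRNA-depleted replicates, three bacterial-enriched
#' poly(A)-capture replicates, and one unenriched, unreplicated poly(A)
#' library.
#'
#' @param species Species specification tibble
#'   (default [default_holobiont_specs()]).
#' @param arms Tibble with columns `label`, `protocol`
#'   (`"polyA_capture"`/`"rrna_depletion"`/`"none"`),
#'   `rrna_depletion_efficiency`, `n_replicates`, `n_pairs`, `enrichment`
#'   (bacterial enrichment factor).
#' @param trim [trim_params()] for all samples.
#' @param k,stride,min_seed_hits,insert_bound Assignment parameters, see
#'   [build_index()] and [assign_pairs()].
#' @param strandedness Counting strand rule, see [count_genes()].
#' @param thresholds Coverage thresholds in read pairs.
#' @param go_threshold Expression threshold for GO statistics.
#' @param top_n Size of the differential-GO table.
#' @param read_length,error_rate,insert_mean,insert_sd Read simulation
#'   parameters, see [generate_reads()].
#' @param seed Master seed; every stage derives disjoint substreams from it.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(species = default_holobiont_specs(),
                              arms = default_arms(),
                              trim = trim_params(),
                              k = 21, stride = 7, min_seed_hits = 2,
                              insert_bound = 1000,
                              strandedness = "reverse",
                              thresholds = c(1, 5),
                              go_threshold = 1,
                              top_n = 30,
                              read_length = 75,
                              error_rate = 0.002,
                              insert_mean = 250, insert_sd = 40,
                              seed = 1) {
  validate_species_specs(species)
  arms <- as_tibble(arms)
  needed <- c("label", "protocol", "rrna_depletion_efficiency",
              "n_replicates", "n_pairs", "enrichment")
  if (!all(needed %in% names(arms))) {
    abort(paste("arms must have columns:", paste(needed, collapse = ", ")))
  }
  if (nrow(arms) < 1 || anyDuplicated(arms$label)) {
    abort("need at least one arm with distinct labels")
  }
  if (any(arms$n_replicates < 1)) abort("replicate counts must be >= 1")
  if (length(thresholds) < 1) abort("thresholds must be non-empty")
  structure(
    list(species = species, arms = arms, trim = trim,
         k = k, stride = stride, min_seed_hits = min_seed_hits,
         insert_bound = insert_bound, strandedness = strandedness,
         thresholds = as.integer(thresholds), go_threshold = go_threshold,
         top_n = top_n, read_length = read_length, error_rate = error_rate,
         insert_mean = insert_mean, insert_sd = insert_sd,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Default protocol arms (3x rRNA-depleted, 3x poly(A), 1x unenriched poly(A))
#'
#' @param n_pairs Read pairs per sample.
#' @param enrichment Bacterial enrichment factor for the enriched arms.
#' @return Arms tibble for [experiment_config()].
#' @export
default_arms <- function(n_pairs = 1e5, enrichment = 50) {
  tibble(
    label = c("rrna_dep", "polya", "polya_unenriched"),
    protocol = c("rrna_depletion", "polyA_capture", "polyA_capture"),
    rrna_depletion_efficiency = c(0.95, NA, NA),
    n_replicates = c(3L, 3L, 1L),
    n_pairs = as.integer(n_pairs),
    enrichment = c(enrichment, enrichment, 1)
  )
}

#' Run a full library-preparation comparison experiment
#'
#' Executes every stage for every arm and replicate: transcript-pool
#' construction, bacterial enrichment, protocol transform, read simulation,
#' quality trimming, competitive genome assignment, strand-aware gene
#' counting, and then the cross-sample metrics (taxonomic distribution,
#' coverage, depth, Spearman replicate correlation, between-arm t-tests) and
#' GO statistics (expressed-GO percent, per-GO profiles, top differential GO
#' tables for every arm pair). Arms with a single replicate are reported
#' without test statistics. Every replicate consumes a substream derived
#' from `(seed, "reads", arm, replicate)`, so runs are fully deterministic
#' and adding a replicate to one arm leaves all other samples bit-identical.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional run directory; when given, all tables are written
#'   as TSV (first line a `# config <hash>` header) plus a JSON manifest. An
#'   existing directory stamped with a different config hash is refused
#'   unless `force = TRUE`.
#' @param force Overwrite a mismatched run directory?
#' @param quiet Suppress progress messages?
#' @return A `run_report` (list) with the config, per-sample stage tallies,
#'   count tables, every metric tibble, the comparison objects and GO
#'   results.
#' @export
run_experiment <- function(config, out_dir = NULL, force = FALSE,
                           quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(unclass(config))
  say <- function(...) if (!quiet) inform(paste0(...))

  say("generating annotation and transcript pool")
  annotation <- generate_annotation(config$species, seed = config$seed)
  pool <- build_transcript_pool(annotation, seed = config$seed)
  index <- build_index(annotation, k = config$k)

  samples <- tibble()
  tables <- list()
  arm_of <- character()

  for (ai in seq_len(nrow(config$arms))) {
    arm_row <- config$arms[ai, ]
    arm_pool <- enrich_bacteria(pool, config$species, arm_row$enrichment)
    params <- protocol_params(
      arm_row$protocol,
      rrna_depletion_efficiency =
        ifelse(is.na(arm_row$rrna_depletion_efficiency), 0.95,
               arm_row$rrna_depletion_efficiency))
    arm_pool <- apply_protocol(arm_pool, params)
    for (r in seq_len(arm_row$n_replicates)) {
      sample_id <- sprintf("%s_r%d", arm_row$label, r)
      say("simulating and processing ", sample_id)
      reads <- generate_reads(
        arm_pool, annotation, n_pairs = arm_row$n_pairs,
        read_length = config$read_length, error_rate = config$error_rate,
        insert_mean = config$insert_mean, insert_sd = config$insert_sd,
        seed = substream_seed(config$seed, "reads", arm_row$label, r))
      trimmed <- trim_pairs(reads, config$trim)
      asg <- assign_pairs(trimmed, index, stride = config$stride,
                          min_seed_hits = config$min_seed_hits,
                          insert_bound = config$insert_bound)
      tab <- count_genes(asg, annotation, strandedness = config$strandedness,
                         sample_id = sample_id)
      tables[[sample_id]] <- tab
      arm_of[sample_id] <- arm_row$label
      samples <- bind_rows(samples, tibble(
        sample_id = sample_id, arm = arm_row$label, replicate = r,
        protocol = arm_row$protocol,
        pairs_raw = n_pairs(reads), pairs_trimmed = n_pairs(trimmed),
        assigned = tab$stats$assigned, unaligned = tab$stats$unaligned,
        ambiguous_genome = tab$stats$ambiguous_genome,
        counted = tab$stats$counted_pairs,
        ambiguous_feature = tab$stats$ambiguous_feature_pairs,
        no_feature = tab$stats$no_feature_pairs
      ))
    }
  }

  say("computing metrics")
  add_arm <- function(df) {
    mutate(df, arm = unname(arm_of[.data$sample_id]), .after = "sample_id")
  }
  taxdist <- purrr::map(tables, function(t) {
    mutate(as_tibble(taxonomic_distribution(t)), sample_id = t$sample_id,
           .before = 1)
  }) |> purrr::list_rbind() |> add_arm()
  coverage <- purrr::map(tables, gene_coverage,
                         thresholds = config$thresholds) |>
    purrr::map(as_tibble) |> purrr::list_rbind() |> add_arm()
  depth <- purrr::map(tables, depth_stats) |>
    purrr::map(as_tibble) |> purrr::list_rbind() |> add_arm()

  species_ids <- config$species$species_id
  replicated_arms <- config$arms$label[config$arms$n_replicates >= 2]
  spearman <- purrr::map(replicated_arms, function(a) {
    reps <- tables[names(arm_of)[arm_of == a]]
    purrr::map(species_ids, function(sp) {
      m <- spearman_replicates(reps, sp)
      as_tibble(as.data.frame.table(as.table(unclass(m)),
                                    responseName = "rho")) |>
        mutate(arm = a, species_id = sp,
               sample_a = as.character(.data$Var1),
               sample_b = as.character(.data$Var2), .keep = "unused") |>
        filter(.data$sample_a < .data$sample_b) |>
        select("arm", "species_id", "sample_a", "sample_b", "rho")
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  # between-arm tests on coverage, for every pair of replicated arms:
  # one-tailed (first arm greater) for bacterial species, two-tailed for the
  # host, matching how symbiont gains vs host parity are conventionally
  # tested
  bacterial <- config$species$species_id[
    config$species$polya_capture_model == "transient_bacterial"]
  comparisons <- list()
  if (length(replicated_arms) >= 2) {
    arm_pairs <- utils::combn(replicated_arms, 2, simplify = FALSE)
    for (ap in arm_pairs) {
      for (sp in species_ids) {
        for (t in config$thresholds) {
          va <- coverage$coverage[coverage$arm == ap[1] &
                                    coverage$species_id == sp &
                                    coverage$threshold == t]
          vb <- coverage$coverage[coverage$arm == ap[2] &
                                    coverage$species_id == sp &
                                    coverage$threshold == t]
          cmp <- compare_methods(
            va, vb,
            alternative = if (sp %in% bacterial) "greater" else "two_sided",
            metric = sprintf("coverage_t%d_%s", t, sp),
            labels = ap)
          comparisons[[cmp$metric]] <- cmp
        }
      }
    }
  }

  say("computing GO statistics")
  go_percent <- purrr::map(tables, function(t) {
    tibble(sample_id = t$sample_id,
           species_id = species_ids,
           expressed_go_percent = map_dbl(
             species_ids, function(sp)
               expressed_go_percent(t, annotation$go_map, sp,
                                    threshold = config$go_threshold)))
  }) |> purrr::list_rbind() |> add_arm()

  go_profiles <- list()
  for (a in config$arms$label) {
    reps <- tables[names(arm_of)[arm_of == a]]
    go_profiles[[a]] <- purrr::map(
      setNames(species_ids, species_ids),
      function(sp) go_profile(reps, annotation$go_map, sp,
                              threshold = config$go_threshold, label = a))
  }
  if (length(replicated_arms) >= 2) {
    for (ap in utils::combn(replicated_arms, 2, simplify = FALSE)) {
      for (sp in species_ids) {
        vals_a <- map_dbl(tables[names(arm_of)[arm_of == ap[1]]],
                          expressed_go_percent, go_map = annotation$go_map,
                          species_id = sp, threshold = config$go_threshold)
        vals_b <- map_dbl(tables[names(arm_of)[arm_of == ap[2]]],
                          expressed_go_percent, go_map = annotation$go_map,
                          species_id = sp, threshold = config$go_threshold)
        cmp <- compare_methods(
          vals_a, vals_b,
          alternative = if (sp %in% bacterial) "greater" else "two_sided",
          metric = sprintf("expressed_go_percent_%s", sp),
          labels = ap)
        comparisons[[cmp$metric]] <- cmp
      }
    }
  }

  top_go <- list()
  all_arm_pairs <- if (nrow(config$arms) >= 2) {
    utils::combn(config$arms$label, 2, simplify = FALSE)
  } else list()
  for (ap in all_arm_pairs) {
    key <- paste(ap, collapse = "_vs_")
    top_go[[key]] <- purrr::map(
      setNames(species_ids, species_ids),
      function(sp) top_differential_go(go_profiles[[ap[1]]][[sp]],
                                       go_profiles[[ap[2]]][[sp]],
                                       n = config$top_n))
  }

  report <- structure(
    list(config = config, config_hash = hash, annotation = annotation,
         samples = samples, tables = tables, taxonomic = taxdist,
         coverage = coverage, depth = depth, spearman = spearman,
         comparisons = comparisons, go_percent = go_percent,
         go_profiles = go_profiles, top_go = top_go),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_run_report(report, out_dir, force = force)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", nrow(x$samples), "samples over",
      nrow(x$config$arms), "arms | config", x$config_hash, "\n")
  print(x$samples, n = Inf)
  invisible(x)
}

# --- persistence ------------------------------------------------------------

write_hashed_tsv <- function(df, path, hash) {
  writeLines(paste0("# config ", hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
}

#' Persist a run report as TSV tables plus a JSON manifest
#'
#' Every TSV carries the config hash in a `#` header line; the manifest
#' records the hash, seed and per-sample stage tallies. Re-running into a
#' directory stamped with a different hash is refused unless `force = TRUE`.
#'
#' @param report A [run_experiment()] result.
#' @param out_dir Output directory.
#' @param force Overwrite a mismatched run directory?
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(report, out_dir, force = FALSE) {
  manifest_path <- file.path(out_dir, "run_manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_hash, report$config_hash) && !force) {
      abort(paste0("output directory holds a run with config ",
                   old$config_hash, " != ", report$config_hash,
                   "; use force = TRUE to overwrite"))
    }
  }
  dir.create(file.path(out_dir, "counts"), showWarnings = FALSE,
             recursive = TRUE)
  hash <- report$config_hash
  paths <- c()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_hashed_tsv(df, p, hash)
    paths <<- c(paths, p)
  }
  put(report$samples, "samples.tsv")
  put(report$taxonomic, "taxonomic_distribution.tsv")
  put(report$coverage, "coverage.tsv")
  put(report$depth, "depth.tsv")
  if (nrow(report$spearman %||% tibble())) put(report$spearman,
                                               "spearman.tsv")
  if (length(report$comparisons)) {
    put(purrr::map(report$comparisons, glance) |> purrr::list_rbind(),
        "comparisons.tsv")
  }
  put(report$go_percent, "go_percent.tsv")
  go_prof_tbl <- purrr::imap(report$go_profiles, function(by_sp, a) {
    purrr::imap(by_sp, function(p, sp) {
      mutate(as_tibble(p), arm = a, species_id = sp, .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  put(go_prof_tbl, "go_profiles.tsv")
  top_go_tbl <- purrr::imap(report$top_go, function(by_sp, key) {
    purrr::imap(by_sp, function(p, sp) {
      mutate(as_tibble(p), comparison = key, species_id = sp,
             rank = dplyr::row_number(), .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  put(top_go_tbl, "top_go.tsv")
  for (t in report$tables) {
    put(as_tibble(t), file.path("counts", paste0(t$sample_id, ".tsv")))
  }
  manifest <- list(
    config_hash = hash,
    seed = report$config$seed,
    package_version = as.character(utils::packageVersion("holosim")),
    samples = report$samples
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, manifest_path))
}

# --- real-data entry point --------------------------------------------------

#' Import externally quantified per-gene counts
#'
#' Entry point for real data quantified outside the simulator: a TSV of
#' `sample_id`, `species_id`, `gene_id`, `count` is validated against the
#' annotation and expanded to full count tables (missing genes become
#' zeros), after which every metric and GO stage runs identically to the
#' simulated path. Unknown species or gene ids are reported exhaustively;
#' duplicated `(sample_id, species_id, gene_id)` rows are an error, never
#' silently summed.
#'
#' @param path TSV file (optionally with `#` comment headers).
#' @param annotation A [holobiont annotation][generate_annotation()] (or one
#'   read by [read_fixture()]).
#' @return Named list of [gene_count_table()]s, one per sample.
#' @export
import_counts <- function(path, annotation) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  needed <- c("sample_id", "species_id", "gene_id", "count")
  if (!all(needed %in% names(df))) {
    abort(paste("count TSV must have columns:",
                paste(needed, collapse = ", ")))
  }
  cds <- annotation$features |> filter(.data$type == "CDS")
  bad_sp <- setdiff(unique(df$species_id), unique(cds$species_id))
  if (length(bad_sp)) {
    abort(paste0("unknown species ids: ", paste(sort(bad_sp),
                                                collapse = ", ")))
  }
  bad_gene <- setdiff(unique(df$gene_id), cds$feature_id)
  if (length(bad_gene)) {
    abort(paste0("unknown gene ids: ", paste(sort(bad_gene),
                                             collapse = ", ")))
  }
  dup <- df |> count(.data$sample_id, .data$species_id, .data$gene_id) |>
    filter(n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicated (sample, species, gene) rows: ",
                 paste(sprintf("%s/%s", dup$sample_id, dup$gene_id),
                       collapse = ", ")))
  }
  full <- tibble(species_id = cds$species_id, gene_id = cds$feature_id)
  samples <- unique(df$sample_id)
  setNames(purrr::map(samples, function(s) {
    d <- df[df$sample_id == s, c("species_id", "gene_id", "count")]
    counts <- full |>
      left_join(d, by = c("species_id", "gene_id")) |>
      mutate(count = as.integer(coalesce(.data$count, 0L))) |>
      arrange(.data$species_id, .data$gene_id)
    gene_count_table(counts, sample_id = s)
  }), samples)
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors [experiment_config()]: top-level scalar parameters, a
#' `species` list of [species_spec()] argument sets, `arms` as a list of
#' records, and optionally `trim` with [trim_params()] fields.
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  species <- if (is.null(y$species)) default_holobiont_specs() else {
    purrr::map(y$species, function(s) {
      s$gene_length_range <- unlist(s$gene_length_range %||% c(300, 900))
      do.call(species_spec, s)
    }) |> purrr::list_rbind()
  }
  arms <- if (is.null(y$arms)) default_arms() else {
    purrr::map(y$arms, function(a) {
      tibble(label = a$label, protocol = a$protocol,
             rrna_depletion_efficiency =
               a$rrna_depletion_efficiency %||% NA_real_,
             n_replicates = as.integer(a$n_replicates %||% 1L),
             n_pairs = as.integer(a$n_pairs %||% 1e5),
             enrichment = a$enrichment %||% 1)
    }) |> purrr::list_rbind()
  }
  trim <- do.call(trim_params, y$trim %||% list())
  extra <- y[setdiff(names(y), c("species", "arms", "trim"))]
  do.call(experiment_config,
          c(list(species = species, arms = arms, trim = trim), extra))
}
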