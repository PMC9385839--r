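test_that("expressed fraction is exact and capture models behave", {
  spec <- species_spec("s", 10, expressed_fraction = 0.5)
  ann <- generate_annotation(spec, seed = 2)
  pool <- build_transcript_pool(ann, seed = 2)
  mrna <- pool[pool$molecule_class == "mRNA", ]
  expect_equal(sum(mrna$relative_abundance > 0), 5)

  host <- species_spec("h", 10, polya_capture_model = "stable_eukaryote",
                       polya_mean_capture = 1)
  hann <- generate_annotation(host, seed = 2)
  hpool <- build_transcript_pool(hann, seed = 2)
  expect_true(all(hpool$polya_capture_prob[
    hpool$molecule_class == "mRNA"] == 1))
  expect_true(all(hpool$polya_capture_prob[
    hpool$molecule_class == "rRNA"] == 0))
})

test_that("gene-dependent bacterial capture has the configured mean", {
  # law of large numbers on the Beta(mean * c, (1 - mean) * c) draw
  spec <- species_spec("b", 1e4, gene_length_range = c(60, 80),
                       polya_mean_capture = 0.2,
                       polya_capture_concentration = 2)
  ann <- generate_annotation(spec, seed = 5)
  pool <- build_transcript_pool(ann, seed = 5)
  cap <- pool$polya_capture_prob[pool$molecule_class == "mRNA"]
  expect_length(cap, 1e4)
  expect_lt(abs(mean(cap) - 0.2), 0.02)
  expect_true(all(cap >= 0 & cap <= 1))
})

test_that("rRNA receives the configured share of the species pool", {
  spec <- species_spec("s", 30, rrna_transcript_fraction = 0.9,
                       pool_weight = 2)
  ann <- generate_annotation(spec, seed = 3)
  pool <- build_transcript_pool(ann, seed = 3)
  rr <- sum(pool$relative_abundance[pool$molecule_class == "rRNA"])
  tot <- sum(pool$relative_abundance)
  expect_equal(rr / tot, 0.9, tolerance = 1e-12)
  expect_equal(tot, 2, tolerance = 1e-12)
})

test_that("protocol transforms multiply abundances as specified", {
  pool <- holosim:::new_transcript_pool(tibble::tibble(
    species_id = c("b", "b"),
    source_id = c("g1", "r1"),
    molecule_class = c("mRNA", "rRNA"),
    relative_abundance = c(10, 100),
    polya_capture_prob = c(0.2, 0)
  ))
  polya <- apply_protocol(pool, protocol_params("polyA_capture"))
  expect_equal(polya$relative_abundance, c(2, 0))

  dep <- apply_protocol(pool, protocol_params("rrna_depletion", 0.95))
  expect_equal(dep$relative_abundance, c(10, 5))

  none <- apply_protocol(pool, protocol_params("none"))
  expect_equal(none$relative_abundance, pool$relative_abundance)
})

test_that("an all-zero post-protocol pool is an explicit error", {
  pool <- holosim:::new_transcript_pool(tibble::tibble(
    species_id = "b", source_id = "r1", molecule_class = "rRNA",
    relative_abundance = 50, polya_capture_prob = 0
  ))
  expect_error(apply_protocol(pool, protocol_params("polyA_capture")),
               "empty")
})

test_that("protocols never create abundance and poly(A) scaling is exact", {
  specs <- tiny_specs()
  ann <- generate_annotation(specs, seed = 8)
  pool <- build_transcript_pool(ann, seed = 8)
  for (p in list(protocol_params("polyA_capture"),
                 protocol_params("rrna_depletion", 0.5),
                 protocol_params("none"))) {
    out <- apply_protocol(pool, p)
    expect_lte(sum(out$relative_abundance), sum(pool$relative_abundance))
  }
  # bacterial mRNA total is scaled by its abundance-weighted mean capture
  out <- apply_protocol(pool, protocol_params("polyA_capture"))
  b_in <- pool[pool$species_id == "sym1" & pool$molecule_class == "mRNA", ]
  b_out <- out[out$species_id == "sym1" & out$molecule_class == "mRNA", ]
  wmean <- sum(b_in$relative_abundance * b_in$polya_capture_prob) /
    sum(b_in$relative_abundance)
  expect_equal(sum(b_out$relative_abundance),
               sum(b_in$relative_abundance) * wmean, tolerance = 1e-12)
  expect_lte(wmean, 1)
})

test_that("bacterial enrichment scales only bacterial species", {
  specs <- tiny_specs()
  ann <- generate_annotation(specs, seed = 8)
  pool <- build_transcript_pool(ann, seed = 8)
  enr <- enrich_bacteria(pool, specs, factor = 50)
  expect_equal(enr$relative_abundance[enr$species_id == "sym1"],
               50 * pool$relative_abundance[pool$species_id == "sym1"])
  expect_equal(enr$relative_abundance[enr$species_id == "host"],
               pool$relative_abundance[pool$species_id == "host"])
})
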