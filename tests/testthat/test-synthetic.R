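test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 7, n_genes = 5)
  a <- generate_genome_annotation(cfg)
  b <- generate_genome_annotation(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$models, b$models)
  expect_identical(a$truth, b$truth)
})

test_that("emitted files are standards-conformant and round-trip", {
  cfg <- synthetic_config(seed = 8, n_genes = 4)
  fa <- tempfile(fileext = ".fa")
  gtf <- tempfile(fileext = ".gtf")
  syn <- generate_genome_annotation(cfg, fasta_path = fa, gtf_path = gtf)
  g2 <- as_genome(fa)
  expect_identical(unname(g2), unname(syn$genome))
  m2 <- load_annotation(gtf, "gtf")
  expect_equal(m2$start, syn$models$start)
  expect_equal(m2$end, syn$models$end)
  expect_equal(m2$transcript_id, syn$models$transcript_id)
})

test_that("classification round-trip recovers planted categories", {
  syn <- generate_genome_annotation(synthetic_config(seed = 9,
                                                     n_genes = 12))
  sites <- classify_splice_sites(syn$models)
  key_t <- paste(syn$truth$seqname, syn$truth$strand, syn$truth$side,
                 syn$truth$junction_pos, syn$truth$category)
  key_c <- paste(sites$seqname, sites$strand, sites$side,
                 sites$junction_pos, sites$category)
  expect_gte(mean(key_t %in% key_c), 0.99)
  expect_gte(mean(key_c %in% key_t), 0.99)
})

test_that("real junctions carry the GT/AG consensus in their windows", {
  syn <- generate_genome_annotation(synthetic_config(seed = 10,
                                                     n_genes = 6))
  sites <- classify_splice_sites(syn$models)
  w <- extract_windows(syn$genome, sites, flank = 70)
  don <- w[w$side == "donor", ]
  acc <- w[w$side == "acceptor", ]
  expect_true(all(substr(don$sequence, 71, 72) == "GT"))
  expect_true(all(substr(acc$sequence, 70, 71) == "AG"))
})

test_that("window cohorts hit the planted GC world", {
  cfg <- synthetic_config(seed = 11)
  co <- generate_windows_cohort(cfg, n_per_category = 300)
  agg <- tapply(co$gc_fraction, co$category, mean)
  expect_gt(agg[["alternative"]], agg[["constitutive"]])
  expect_gt(agg[["constitutive"]], agg[["skipped"]])
  # planted mean recovered within 3 standard errors
  alt <- co$gc_fraction[co$category == "alternative"]
  se <- sd(alt) / sqrt(length(alt))
  expect_lt(abs(mean(alt) - 0.52), 3 * se)
  # sd = 0: every window exactly at the rounded target count
  cfg0 <- synthetic_config(seed = 12, gc_sd = 0)
  co0 <- generate_windows_cohort(cfg0, n_per_category = 20)
  expect_true(all(co0$gc_number == round(co0$gc_target * 141)))
  # determinism
  expect_identical(generate_windows_cohort(cfg, n_per_category = 50),
                   generate_windows_cohort(cfg, n_per_category = 50))
})

test_that("tissue tables are threshold-clear and exactly recoverable", {
  cfg <- synthetic_config(seed = 13, fraction_tissue_specific = 0.25)
  tt <- generate_tissue_table(cfg, n_events = 300)
  cls <- classify_tissue_specific(tt$events)
  merged <- merge(cls, tt$truth, by = "event_id")
  expect_true(all((merged$class == "tissue_specific") ==
                    merged$tissue_specific))
  expect_false(any(merged$class == "unclassified"))
  # extremes
  none <- generate_tissue_table(
    synthetic_config(seed = 14, fraction_tissue_specific = 0),
    n_events = 50)
  expect_equal(sum(classify_tissue_specific(none$events)$class ==
                     "tissue_specific"), 0)
  all_spec <- generate_tissue_table(
    synthetic_config(seed = 15, fraction_tissue_specific = 1),
    n_events = 50)
  expect_equal(sum(classify_tissue_specific(all_spec$events)$class ==
                     "tissue_specific"), 50)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(gc_means = c(alternative = 1.2)))
  expect_error(generate_genome_annotation(
    synthetic_config(seed = 1, flank = 200L)), "infeasible")
})
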