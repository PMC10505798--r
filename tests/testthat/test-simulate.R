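# Synthetic panel generator: determinism, self-consistency, degenerate
# configurations, and the study-mimic suite.

test_that("the same configuration yields byte-identical files", {
  cfg <- small_cfg(seed = 123)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  b1 <- simulate_panel(cfg, out_dir = d1)
  b2 <- simulate_panel(cfg, out_dir = d2)
  for (f in names(b1$files)) {
    expect_identical(unname(tools::md5sum(b1$files[[f]])[[1]]),
                     unname(tools::md5sum(b2$files[[f]])[[1]]),
                     info = f)
  }
  b3 <- simulate_panel(small_cfg(seed = 124))
  expect_false(identical(b1$ref_region, b3$ref_region))
})

test_that("a zero-variant configuration yields a monomorphic panel", {
  cfg <- panel_config(seed = 9, n_accessions = 30, gene_length = 600,
                      upstream_len = 300, downstream_len = 200,
                      n_functional_variants = 0L, n_silent_variants = 0L,
                      elite_spec = list(n_defining = 0L, regions = "exon"),
                      rare_haplotype_sizes = integer())
  b <- simulate_panel(cfg)
  expect_equal(nrow(b$variants), 0L)
  asn <- classify_haplotypes(b$variants, b$geno, b$panel,
                             b$truth$reference_accession,
                             sequenced = b$truth$sequenced)
  expect_equal(asn$groups$group, "HapA")
  expect_equal(asn$haplotypes$haplotype, "HapA-1")
})

test_that("panel truth is self-consistent with the emitted sequences", {
  b <- simulate_panel(small_cfg(seed = 55))
  for (acc in sample(b$panel$accession_id, 6)) {
    carried <- b$variants[b$geno[, acc] == "1", , drop = FALSE]
    expect_identical(apply_variants(b$ref_region, carried),
                     unname(b$sequences[[acc]]))
  }
})

test_that("infeasible configurations error", {
  cfg <- panel_config(seed = 2, n_accessions = 12,
                      rare_haplotype_sizes = c(4L, 4L, 4L))
  expect_error(simulate_panel(cfg), "infeasible")
})

test_that("pipeline recovers the planted structure on random panels", {
  # the full 200-seed battery runs with the acceptance checks; this is a
  # quick regression sample
  ok <- 0L
  for (seed in 1:15) {
    b <- simulate_panel(small_cfg(seed = 1000 + seed))
    if (recovery_ok(b)) ok <- ok + 1L
  }
  expect_equal(ok, 15L)
})

suite <- paper_mimic_suite()

test_that("the mimic suite reproduces the per-gene qualitative structure", {
  expect_named(suite, c("SKC1like", "GS3like", "HAK21like", "PAO3like",
                        "RST1like"))
  # GS3-like: the elite-defining variant is a premature stop
  gv <- suite$GS3like$variants
  expect_equal(gv$effect[gv$variant_id == "gs3_e1637"], "premature_stop")
  # HAK21-like: two elite groups plus promoter indels of 391 and 17 bp
  hv <- suite$HAK21like$variants
  expect_equal(nchar(hv$alt[hv$variant_id == "hak21_ins391"]), 391L)
  expect_equal(nchar(hv$ref[hv$variant_id == "hak21_del17"]), 17L)
  expect_equal(length(unique(suite$HAK21like$truth$labels$group[
    grepl("elite", suite$HAK21like$truth$labels$group)])), 2L)
  # RST1-like: 514-bp promoter indel analog
  rv <- suite$RST1like$variants
  expect_equal(nchar(rv$ref[rv$variant_id == "rst1_del514"]), 514L)
  expect_equal(rv$region[rv$variant_id == "rst1_del514"], "5'UTR")
})

test_that("mimic panels classify into the planted groups with elite flags", {
  for (nm in c("SKC1like", "PAO3like")) {
    p <- suite[[nm]]
    asn <- classify_haplotypes(p$variants, p$geno, p$panel,
                               p$truth$reference_accession,
                               sequenced = p$truth$sequenced)
    asn <- mark_elite(asn, p$truth$elite_definition)
    expect_equal(nrow(asn$groups),
                 length(unique(p$truth$labels$group)), info = nm)
    elite_accs <- asn$assignment$accession_id[
      asn$assignment$group %in% asn$groups$group[asn$groups$elite]]
    expected <- p$truth$labels$accession_id[
      p$truth$labels$group %in% grep("elite", unique(p$truth$labels$group),
                                     value = TRUE)]
    expect_setequal(elite_accs, expected)
  }
})

test_that("unique-variant counts match the published per-gene counts", {
  for (spec in list(list("PAO3like", 2L), list("GS3like", 1L))) {
    p <- suite[[spec[[1]]]]
    asn <- classify_haplotypes(p$variants, p$geno, p$panel,
                               p$truth$reference_accession,
                               sequenced = p$truth$sequenced)
    asn <- mark_elite(asn, p$truth$elite_definition)
    uq <- find_unique_variants(asn, asn$groups$group[asn$groups$elite])
    expect_equal(nrow(uq), spec[[2]], info = spec[[1]])
    expect_setequal(uq$variant_id, p$truth$unique_elite)
  }
})
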