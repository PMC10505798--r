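# CAPS / dCAPS / Indel marker design.

snp_row <- function(p, ref, alt, id = "snp") {
  data.frame(variant_id = id, atg_pos = p, region_pos = p,
             genomic_pos = NA_integer_, ref = ref, alt = alt,
             vclass = "SNP", stringsAsFactors = FALSE)
}

test_that("find_caps keeps enzymes whose site is completed by one allele", {
  # C->A where the A completes CTGCAG in the alt context only
  ctx <- paste0("TTTTTTTTTT", "CTGCCG", "TTTTTTTTTT")
  hit <- find_caps(ctx, 15L, "C", "A")
  expect_equal(hit$name, "PstI")
  expect_equal(hit$cut_allele, "alt")
  # neither allele completes a site
  none <- find_caps(paste(rep("T", 30), collapse = ""), 15L, "T", "A")
  expect_equal(nrow(none), 0L)
  # degenerate site present in both alleles is excluded: CCWGG with the
  # SNP at the W position matches for both A and T
  ctx2 <- paste0("AAAAAAAAAA", "CCAGG", "AAAAAAAAAA")
  both <- find_caps(ctx2, 13L, "A", "T")
  expect_false("EcoRII" %in% both$name)
})

test_that("designed CAPS markers discriminate and conserve fragment sums", {
  set.seed(41)
  tmpl <- rdna(1200)
  p <- 600L
  substr(tmpl, p - 4L, p + 1L) <- "CTGCCG"   # alt A at motif pos 5 -> CTGCAG
  v <- snp_row(p, "C", "A")
  m <- design_caps(tmpl, v, elite_allele = "alt")
  expect_s3_class(m, "marker_spec")
  expect_equal(m$enzyme$name, "PstI")
  expect_false(identical(sort(m$elite_bands), sort(m$other_bands)))
  expect_equal(sum(m$elite_bands), sum(m$other_bands))
  expect_true(m$amplicon_len >= 300 && m$amplicon_len <= 800)
})

test_that("dCAPS design creates a site in exactly one allele via one mismatch", {
  set.seed(42)
  # toy from first principles: template 5'...GACTT[T/C]C...; one primer
  # mismatch C->A turns the window into GAATT + allele + C, so the T
  # allele completes GAATTC and the C allele does not
  tmpl2 <- rdna(700)
  p <- 350L
  substr(tmpl2, p - 5L, p + 1L) <- "GACTTTC"  # ref allele T at p
  v2 <- snp_row(p, "T", "C")
  m <- design_dcaps(tmpl2, v2, elite_allele = "ref",
                    enzymes = default_enzymes()[1, ])
  expect_s3_class(m, "marker_spec")
  expect_equal(m$enzyme$name, "EcoRI")
  expect_equal(length(m$forward$mismatch_positions) +
               length(m$reverse$mismatch_positions), 1L)
  expect_true(grepl("[acgt]", paste0(m$forward$seq, m$reverse$seq)))
  # soundness: re-scan both primer-modified amplicons
  parts <- list(forward = m$forward, reverse = m$reverse, variant = v2)
  amp_ref <- haplomarker:::allele_amplicon(tmpl2, parts, "ref")
  amp_alt <- haplomarker:::allele_amplicon(tmpl2, parts, "alt")
  n_ref <- nrow(scan_restriction_sites(amp_ref, m$enzyme))
  n_alt <- nrow(scan_restriction_sites(amp_alt, m$enzyme))
  expect_equal(abs(n_ref - n_alt), 1L)
  # the diagnostic small fragment equals the mismatch primer length
  cut_bands <- if (n_ref > n_alt) if (m$elite_allele == "ref") m$elite_bands
                                  else m$other_bands
               else if (m$elite_allele == "alt") m$elite_bands else m$other_bands
  mm_primer <- if (length(m$forward$mismatch_positions)) m$forward else m$reverse
  expect_equal(min(cut_bands), nchar(mm_primer$seq))
})

test_that("dCAPS reports infeasibility when every placement needs > k mismatches", {
  set.seed(43)
  tmpl <- paste(rep("AT", 400), collapse = "")
  v <- snp_row(401L, "T", "G")
  d <- design_dcaps(tmpl, v, enzymes = default_enzymes()[4, , drop = FALSE],
                    k = 1L, diagnostics = TRUE)
  expect_null(d$marker)
  expect_match(d$diagnostics[["PstI"]], "no admissible placement")
})

test_that("indel marker bands differ exactly by the indel size, by size class", {
  set.seed(44)
  tmpl <- rdna(2500)
  # 17-bp deletion: 100-300 bp amplicon class
  v17 <- data.frame(variant_id = "d17", atg_pos = 1200L, region_pos = 1200L,
                    genomic_pos = NA, ref = substr(tmpl, 1200, 1216),
                    alt = "", vclass = "deletion", stringsAsFactors = FALSE)
  m17 <- design_indel_marker(tmpl, v17, elite_allele = "alt")
  expect_equal(sort(c(m17$elite_bands, m17$other_bands), decreasing = TRUE)[1] -
               sort(c(m17$elite_bands, m17$other_bands), decreasing = TRUE)[2],
               -17L * -1L)
  expect_true(m17$other_bands >= 100 && m17$other_bands <= 300)
  expect_equal(m17$other_bands - m17$elite_bands, 17L)
  # 391-bp insertion: 400-1000 bp class on the long allele
  v391 <- data.frame(variant_id = "i391", atg_pos = 600L, region_pos = 600L,
                     genomic_pos = NA, ref = "", alt = rdna(391),
                     vclass = "insertion", stringsAsFactors = FALSE)
  m391 <- design_indel_marker(tmpl, v391, elite_allele = "alt")
  expect_equal(m391$elite_bands - m391$other_bands, 391L)
  expect_true(m391$elite_bands >= 400 && m391$elite_bands <= 1000)
  # sizes outside the classes are rejected unless forced
  v3 <- data.frame(variant_id = "d3", atg_pos = 900L, region_pos = 900L,
                   genomic_pos = NA, ref = substr(tmpl, 900, 902), alt = "",
                   vclass = "deletion", stringsAsFactors = FALSE)
  expect_error(design_indel_marker(tmpl, v3), "outside the marker size classes")
  v45 <- data.frame(variant_id = "d45", atg_pos = 1800L, region_pos = 1800L,
                    genomic_pos = NA, ref = substr(tmpl, 1800, 1844), alt = "",
                    vclass = "deletion", stringsAsFactors = FALSE)
  expect_error(design_indel_marker(tmpl, v45), "outside the marker size classes")
  expect_s3_class(design_indel_marker(tmpl, v45, force = TRUE), "marker_spec")
})

test_that("primer pairs satisfy the published length rule and the constraints", {
  set.seed(45)
  tmpl <- rdna(500)
  pr <- design_primer_pair(tmpl, must_span = c(240, 260),
                           product_range = c(100, 300))
  expect_true(pr$product_len >= 100 && pr$product_len <= 300)
  expect_true(pr$forward$template_start <= 240 &&
              pr$reverse$template_end >= 260)
  for (p in list(pr$forward, pr$reverse)) {
    expect_true(nchar(p$seq) >= 18 && nchar(p$seq) <= 24)
    expect_true(tm_wallace(p$seq) >= 52 && tm_wallace(p$seq) <= 62)
  }
  expect_lte(abs(tm_wallace(pr$forward$seq) - tm_wallace(pr$reverse$seq)), 5)
  # a product window too small to hold primers is infeasible
  expect_error(design_primer_pair(tmpl, c(240, 260), c(10, 20)),
               "cannot hold|no admissible")
  # verify the pair by virtual PCR on a marker shell
  m <- haplomarker:::new_marker_spec("t", "g", "Indel",
    snp_row(250L, substr(tmpl, 250, 250),
            setdiff(c("A","C","G","T"), substr(tmpl, 250, 250))[1]),
    pr$forward, pr$reverse, NULL, pr$product_len, pr$product_len + 17L, "alt")
  amp <- virtual_pcr(tmpl, m)
  expect_equal(nchar(amp), pr$product_len)
})

test_that("all published primers satisfy the 18-24 nt length rule", {
  df <- read_marker_table(published_marker_table())
  v <- validate_marker_table(df)
  expect_true(all(v$primer_len_ok))
})

test_that("design_marker follows the priority rules", {
  set.seed(46)
  tmpl <- rdna(1500)
  substr(tmpl, 746, 751) <- "CTGCCG"
  v <- snp_row(750L, "C", "A")
  m <- design_marker(tmpl, v)
  expect_equal(m$mtype, "CAPS")   # natural site available -> CAPS first
})
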