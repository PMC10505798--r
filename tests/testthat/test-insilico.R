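# In-silico PCR, digestion, gel model and genotype calling.

test_that("gel resolvability thresholds behave as modelled", {
  expect_true(resolvable(179, 162, "PAGE"))    # 17-bp indel difference
  expect_false(resolvable(423, 423, "agarose"))
  expect_false(resolvable(300, 296, "agarose"))  # under the 20-bp floor
  expect_true(resolvable(300, 330, "agarose"))
  expect_false(resolvable(200, 203, "PAGE"))   # under the 4-bp floor
  expect_true(resolvable(400, 410, "PAGE"))
  # symmetry
  expect_equal(resolvable(162, 179, "PAGE"), resolvable(179, 162, "PAGE"))
  expect_equal(gel_class(299), "PAGE")
  expect_equal(gel_class(300), "agarose")
})

test_that("virtual PCR amplifies between primer 5' ends and needs both sites", {
  set.seed(50)
  tmpl <- rdna(600)
  f <- haplomarker:::new_primer(substr(tmpl, 101, 120), 101, 120, "F")
  r_foot <- substr(tmpl, 231, 250)
  r <- haplomarker:::new_primer(revcomp(r_foot), 231, 250, "R")
  m <- list(name = "t", forward = f, reverse = r, enzyme = NULL,
            mtype = "Indel")
  amp <- virtual_pcr(tmpl, m)
  expect_equal(nchar(amp), 150L)
  expect_equal(amp, substr(tmpl, 101, 250))
  # template lacking the reverse site
  broken <- paste0(substr(tmpl, 1, 230), rdna(100))
  expect_null(virtual_pcr(broken, m))
})

test_that("designed primer mismatches are tolerated and written into the amplicon", {
  set.seed(51)
  tmpl <- rdna(400)
  fs <- substr(tmpl, 51, 70)
  mm <- haplomarker:::chars(fs)
  mm[17] <- tolower(setdiff(c("A","C","G","T"), mm[17])[1])
  f <- haplomarker:::new_primer(paste(mm, collapse = ""), 51, 70, "F",
                                mismatch_positions = 17L)
  r <- haplomarker:::new_primer(revcomp(substr(tmpl, 181, 200)), 181, 200, "R")
  m <- list(name = "t", forward = f, reverse = r, enzyme = NULL, mtype = "dCAPS")
  amp <- virtual_pcr(tmpl, m)
  expect_false(is.null(amp))
  expect_equal(substr(amp, 17, 17), toupper(mm[17]))
})

test_that("non-specific primer pairs raise an error naming the loci", {
  set.seed(52)
  tmpl <- paste0(rdna(100), "GAGGATCCGTTAACGGCTAG", rdna(100),
                 "GAGGATCCGTTAACGGCTAG", rdna(100))
  f <- haplomarker:::new_primer("GAGGATCCGTTAACGGCTAG", 101, 120, "F")
  rfoot <- substr(tmpl, 301, 320)
  r <- haplomarker:::new_primer(revcomp(rfoot), 301, 320, "R")
  m <- list(name = "t", forward = f, reverse = r, enzyme = NULL, mtype = "Indel")
  expect_error(virtual_pcr(tmpl, m), "non-specific")
})

test_that("genotype calls follow the band patterns, with sensible fallbacks", {
  set.seed(53)
  tmpl <- rdna(1200)
  p <- 600L
  substr(tmpl, p - 4L, p + 1L) <- "CTGCCG"   # alt A at motif pos 5 -> CTGCAG
  v <- data.frame(variant_id = "s", atg_pos = p, region_pos = p,
                  genomic_pos = NA, ref = "C", alt = "A", vclass = "SNP",
                  stringsAsFactors = FALSE)
  m <- design_caps(tmpl, v, elite_allele = "alt")
  elite_tmpl <- tmpl; substr(elite_tmpl, p, p) <- "A"
  expect_equal(genotype_accession(tmpl, m), "other")
  expect_equal(genotype_accession(elite_tmpl, m), "elite")
  # a third, unmodelled allele at the cut site
  third <- tmpl; substr(third, p, p) <- "G"
  expect_true(genotype_accession(third, m) %in% c("unknown", "other"))
  # no amplification when a primer site is destroyed
  broken <- tmpl
  fs <- m$forward$template_start
  substr(broken, fs + 2L, fs + 9L) <- paste(rep(c("A", "C"), 4), collapse = "")
  call <- genotype_accession(broken, m)
  expect_true(call %in% c("no_amplification", "unknown"))
})

test_that("digestion conservation holds for every simulated digest", {
  set.seed(54)
  enz <- default_enzymes()
  for (i in 1:40) {
    amp <- rdna(sample(150:700, 1))
    e <- enz[sample(nrow(enz), 1), ]
    m <- list(enzyme = e, mtype = "CAPS",
              forward = haplomarker:::new_primer(substr(amp, 1, 20), 1, 20, "F"),
              reverse = haplomarker:::new_primer(revcomp(substr(
                amp, nchar(amp) - 19, nchar(amp))), nchar(amp) - 19,
                nchar(amp), "R"))
    bands <- haplomarker:::marker_bands(m, amp)
    expect_equal(sum(bands), nchar(amp))
  }
})

test_that("unresolvable co-migrating bands merge into one", {
  merged <- haplomarker:::merge_bands(c(200, 202, 150), "PAGE")
  expect_equal(length(merged), 2L)
  expect_true(haplomarker:::patterns_match(
    haplomarker:::merge_bands(c(200, 150), "PAGE"),
    haplomarker:::merge_bands(c(201, 151), "PAGE"), "PAGE"))
  expect_false(haplomarker:::patterns_match(
    haplomarker:::merge_bands(c(200, 150), "PAGE"),
    haplomarker:::merge_bands(c(240, 150), "PAGE"), "PAGE"))
})
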