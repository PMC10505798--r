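# Two-tier haplotype classification, elite marking, unique variants and
# subpopulation tallies.

# build a variant table + genotype matrix directly (effects preset)
toy_matrix <- function(effects, geno_rows, accs) {
  n <- length(effects)
  if (n == 0L) {
    variants <- data.frame(variant_id = character(), atg_pos = integer(),
                           region_pos = integer(), genomic_pos = integer(),
                           ref = character(), alt = character(),
                           vclass = character(), region = character(),
                           effect = character(), stringsAsFactors = FALSE)
    geno <- matrix(character(), 0L, length(accs),
                   dimnames = list(NULL, accs))
    return(list(variants = variants, geno = geno))
  }
  variants <- data.frame(
    variant_id = sprintf("v%02d", seq_len(n)),
    atg_pos = seq(100L, by = 10L, length.out = n),
    region_pos = seq(300L, by = 10L, length.out = n),
    genomic_pos = NA_integer_,
    ref = "A", alt = "G", vclass = "SNP",
    region = ifelse(effects == "noncoding", "5'UTR", "exon 1"),
    effect = effects, stringsAsFactors = FALSE)
  geno <- matrix(geno_rows, nrow = n, byrow = TRUE,
                 dimnames = list(variants$variant_id, accs))
  list(variants = variants, geno = geno)
}

toy_panel <- function(accs, subpop = "XI") {
  data.frame(accession_id = accs,
             subpopulation = rep(subpop, length.out = length(accs)),
             stringsAsFactors = FALSE)
}

test_that("a monomorphic panel yields one group HapA with one haplotype HapA-1", {
  accs <- paste0("a", 1:4)
  tm <- toy_matrix(character(0), character(0), accs)
  tm$geno <- matrix(character(0), 0, 4, dimnames = list(NULL, accs))
  asn <- classify_haplotypes(tm$variants, tm$geno, toy_panel(accs), "a1")
  expect_equal(asn$groups$group, "HapA")
  expect_equal(asn$haplotypes$haplotype, "HapA-1")
  expect_true(all(asn$assignment$haplotype == "HapA-1"))
})

test_that("functional variants split groups; silent variants split haplotypes", {
  accs <- paste0("a", 1:6)
  # missense SNP splits 4/2; synonymous splits the reference 4 into 3/1
  tm <- toy_matrix(c("missense", "synonymous"),
                   c("0","0","0","0","1","1",
                     "0","0","0","1","0","0"), accs)
  asn <- classify_haplotypes(tm$variants, tm$geno, toy_panel(accs), "a1",
                             sequenced = accs)
  expect_equal(asn$groups$group, c("HapA", "HapB"))
  expect_equal(asn$groups$n, c(4L, 2L))
  ha <- asn$haplotypes[asn$haplotypes$group == "HapA", ]
  expect_equal(ha$haplotype, c("HapA-1", "HapA-2"))
  expect_equal(ha$n, c(3L, 1L))
})

test_that("novel haplotypes under the five-accession filter are dropped", {
  accs <- paste0("a", 1:10)
  tm <- toy_matrix("missense",
                   c("0","0","0","0","0","0","1","1","1","1"), accs)
  # a1..a6 anchored by a sequenced accession; a7..a10 novel, size 4 < 5
  asn <- classify_haplotypes(tm$variants, tm$geno, toy_panel(accs), "a1",
                             sequenced = "a1", min_novel_size = 5L)
  expect_equal(asn$groups$group, "HapA")
  expect_equal(sum(asn$assignment$status == "rare_novel"), 4L)
  # the same structure is kept when anchored
  asn2 <- classify_haplotypes(tm$variants, tm$geno, toy_panel(accs), "a1",
                              sequenced = c("a1", "a7"))
  expect_equal(asn2$groups$group, c("HapA", "HapB"))
})

test_that("uncalled or heterozygous accessions are excluded, reference must be called", {
  accs <- paste0("a", 1:4)
  tm <- toy_matrix("missense", c("0", "1", NA, "het"), accs)
  asn <- classify_haplotypes(tm$variants, tm$geno, toy_panel(accs), "a1",
                             sequenced = accs)
  expect_equal(asn$assignment$status, c("assigned", "assigned",
                                        "uncalled", "uncalled"))
  tm2 <- toy_matrix("missense", c(NA, "1", "0", "0"), accs)
  expect_error(classify_haplotypes(tm2$variants, tm2$geno, toy_panel(accs),
                                   "a1"), "reference accession")
})

test_that("mark_elite flags zero, one or several groups", {
  accs <- paste0("a", 1:9)
  tm <- toy_matrix(c("missense", "missense"),
                   c("0","0","0","1","1","1","1","1","1",
                     "0","0","0","0","0","0","1","1","1"), accs)
  asn <- classify_haplotypes(tm$variants, tm$geno, toy_panel(accs), "a1",
                             sequenced = accs)
  # one group carries v01 alone, one carries both
  one <- mark_elite(asn, elite_definition("g", 110L, "G"))
  expect_equal(sum(one$groups$elite), 1L)
  both <- mark_elite(asn, elite_definition("g", 100L, "G"))
  expect_equal(sum(both$groups$elite), 2L)
  expect_warning(none <- mark_elite(asn, elite_definition("g", c(100L, 110L),
                                                          c("A", "G"))),
                 "no haplotype")
  expect_equal(sum(none$groups$elite), 0L)
  expect_error(mark_elite(asn, elite_definition("g", 999L, "G")),
               "absent")
})

test_that("unique variants are private alleles of the whole target set", {
  accs <- paste0("a", 1:8)
  tm <- toy_matrix(c("missense", "synonymous", "noncoding"),
                   c("0","0","0","0","1","1","1","1",
                     "0","0","0","0","1","1","1","1",
                     "0","0","1","1","1","1","1","1"), accs)
  asn <- classify_haplotypes(tm$variants, tm$geno, toy_panel(accs), "a1",
                             sequenced = accs)
  target <- asn$assignment$group[asn$assignment$accession_id == "a5"]
  uq <- find_unique_variants(asn, target)
  expect_setequal(uq$variant_id, c("v01", "v02"))
  # waiving the carriers of v03 outside the target recovers it
  uq2 <- find_unique_variants(asn, target, exclude = c("a3", "a4"))
  expect_setequal(uq2$variant_id, c("v01", "v02", "v03"))
  expect_error(find_unique_variants(asn, target, exclude = target),
               "overlap")
  # a target genotypically identical to a non-target has no private alleles
  tm2 <- toy_matrix("missense", c("0","0","1","1","1","1","0","0"), accs)
  asn2 <- classify_haplotypes(tm2$variants, tm2$geno, toy_panel(accs), "a1",
                              sequenced = accs)
  expect_equal(nrow(find_unique_variants(asn2, "HapA")), 0L)
})

test_that("subpopulation tallies have row sums equal to haplotype sizes", {
  accs <- paste0("a", 1:5)
  tm <- toy_matrix("missense", c("0", "0", "1", "1", "1"), accs)
  panel <- toy_panel(accs, c("XI", "XI", "GJ-tem", "GJ-tem", "aus"))
  asn <- classify_haplotypes(tm$variants, tm$geno, panel, "a1",
                             sequenced = accs)
  tab <- subpop_distribution(asn, panel)
  expect_equal(unname(rowSums(tab)),
               asn$haplotypes$n[match(rownames(tab),
                                      asn$haplotypes$haplotype)])
  tabg <- subpop_distribution(asn, panel, level = "group")
  expect_equal(unname(rowSums(tabg)), asn$groups$n)
})

test_that("partition and refinement laws hold on random panels", {
  set.seed(77)
  for (rep in 1:8) {
    cfg <- small_cfg(seed = 300 + rep)
    b <- simulate_panel(cfg)
    asn <- classify_haplotypes(b$variants, b$geno, b$panel,
                               b$truth$reference_accession,
                               sequenced = b$truth$sequenced)
    a <- asn$assignment[asn$assignment$status == "assigned", ]
    # partition: each assigned accession in exactly one haplotype
    expect_false(anyNA(a$haplotype))
    expect_equal(sort(as.integer(table(a$haplotype))),
                 sort(asn$haplotypes$n))
    # group membership = union of its haplotypes
    for (gn in asn$groups$group) {
      hsum <- sum(asn$haplotypes$n[asn$haplotypes$group == gn])
      expect_equal(hsum, asn$groups$n[asn$groups$group == gn])
    }
    # refinement: same haplotype -> identical genotype everywhere;
    # same group -> identical functional genotype
    fun <- asn$functional
    for (hn in sample(asn$haplotypes$haplotype,
                      min(4, nrow(asn$haplotypes)))) {
      m <- a$accession_id[a$haplotype == hn]
      expect_equal(nrow(unique(t(asn$geno[, m, drop = FALSE]))), 1L)
    }
    for (gn in asn$groups$group) {
      m <- a$accession_id[a$group == gn]
      expect_equal(nrow(unique(t(asn$geno[fun, m, drop = FALSE]))), 1L)
    }
  }
})

test_that("unique-variant search agrees with an exhaustive per-variant scan", {
  set.seed(88)
  for (rep in 1:5) {
    b <- simulate_panel(small_cfg(seed = 400 + rep))
    asn <- classify_haplotypes(b$variants, b$geno, b$panel,
                               b$truth$reference_accession,
                               sequenced = b$truth$sequenced)
    target <- sample(asn$groups$group, 1)
    uq <- find_unique_variants(asn, target)
    inT <- asn$assignment$accession_id[!is.na(asn$assignment$group) &
                                         asn$assignment$group == target]
    outT <- setdiff(colnames(asn$geno), inT)
    brute <- asn$variants$variant_id[vapply(seq_len(nrow(asn$variants)),
      function(i) all(asn$geno[i, inT] == "1") &&
                  !any(asn$geno[i, outT] %in% c("1", "het")), logical(1))]
    expect_setequal(uq$variant_id, brute)
  }
})
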