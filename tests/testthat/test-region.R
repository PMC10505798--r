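# Region extraction and variant calling.

test_that("extracted region is upstream pad + gene body + downstream pad", {
  set.seed(7)
  chrom <- c(chr1 = rdna(8000))
  g <- gene_model("g", "chr1", "+", 2501, 5500, cbind(2501, 5500),
                  upstream_len = 2000, downstream_len = 1000)
  reg <- extract_gene_region(chrom, g)
  expect_equal(nchar(reg), 2000 + 3000 + 1000)
  expect_equal(as.character(reg), substr(chrom[["chr1"]], 501, 6500))
  expect_error(extract_gene_region(chrom,
                 gene_model("g", "chrX", "+", 2501, 5500, cbind(2501, 5500))),
               "absent")
})

test_that("regions running off the chromosome are truncated with a warning", {
  set.seed(8)
  chrom <- c(chr1 = rdna(3000))
  g <- gene_model("g", "chr1", "+", 501, 1100, cbind(501, 1100),
                  upstream_len = 2000, downstream_len = 500)
  expect_warning(reg <- extract_gene_region(chrom, g), "truncated")
  expect_equal(nchar(reg), 500 + 600 + 500)
  expect_equal(attr(reg, "trunc_upstream"), 1500L)
})

test_that("minus-strand extraction reverse-complements the genomic slice", {
  set.seed(9)
  chrom <- c(chr1 = rdna(60))
  g <- gene_model("g", "chr1", "-", 45, 16, cbind(16, 45),
                  upstream_len = 10, downstream_len = 5)
  reg <- extract_gene_region(chrom, g)
  expect_equal(as.character(reg), revcomp(substr(chrom, 11, 55)))
})

test_that("variant calling reports SNPs in ATG coordinates", {
  set.seed(10)
  tg <- toy_gene("+", n_exons = 1L, cds_codons = 20L, up = 2000L, down = 20L)
  ref <- tg$region
  smp <- ref
  substr(smp, 2005, 2005) <- setdiff(c("A","C","G","T"),
                                     substr(ref, 2005, 2005))[1]
  cv <- call_variants(ref, c(s1 = smp, same = ref), tg$model)
  expect_equal(nrow(cv$variants), 1L)
  expect_equal(cv$variants$atg_pos, 5L)
  expect_equal(unname(cv$geno[1, ]), c("1", "0"))
  # identical sample alone: empty table
  cv0 <- call_variants(ref, c(s = ref), tg$model)
  expect_equal(nrow(cv0$variants), 0L)
})

test_that("indels are left-normalised to the smallest coordinate", {
  set.seed(11)
  tg <- toy_gene("+", n_exons = 1L, cds_codons = 20L, up = 40L, down = 20L)
  ref <- tg$region
  # force an AAAA run in the upstream pad, delete its third A
  substr(ref, 10, 13) <- "AAAA"
  if (substr(ref, 9, 9) == "A") substr(ref, 9, 9) <- "C"
  if (substr(ref, 14, 14) == "A") substr(ref, 14, 14) <- "G"
  smp <- paste0(substr(ref, 1, 11), substr(ref, 13, nchar(ref)))
  cv <- call_variants(ref, c(s = smp), tg$model)
  del <- cv$variants[cv$variants$vclass == "deletion", ]
  expect_equal(nrow(del), 1L)
  # leftmost equivalent placement: position 10, the first A of the run
  expect_equal(del$region_pos, 10L)
  expect_equal(del$ref, "A")
})

test_that("samples with mostly ambiguous bases are skipped with a warning", {
  set.seed(12)
  tg <- toy_gene("+", n_exons = 1L, cds_codons = 15L, up = 30L, down = 20L)
  junk <- paste(rep("N", nchar(tg$region)), collapse = "")
  expect_warning(cv <- call_variants(tg$region, c(bad = junk), tg$model),
                 "ambiguous")
  expect_equal(ncol(cv$geno), 0L)
})

test_that("calling then re-applying variants reconstructs each sample", {
  set.seed(13)
  for (rep in 1:10) {
    tg <- toy_gene(sample(c("+", "-"), 1), n_exons = sample(1:3, 1),
                   cds_codons = 30L, up = 80L, down = 50L)
    ref <- tg$region
    smp <- ref
    # random edits: SNPs and small indels
    for (k in 1:4) {
      p <- sample(20:(nchar(smp) - 20), 1)
      op <- sample(c("snp", "del", "ins"), 1)
      if (op == "snp") {
        substr(smp, p, p) <- sample(setdiff(c("A","C","G","T"),
                                            substr(smp, p, p)), 1)
      } else if (op == "del") {
        smp <- paste0(substr(smp, 1, p - 1), substr(smp, p + sample(1:4, 1),
                                                    nchar(smp)))
      } else {
        smp <- paste0(substr(smp, 1, p), rdna(sample(1:4, 1)),
                      substr(smp, p + 1, nchar(smp)))
      }
    }
    cv <- call_variants(ref, c(s = smp), tg$model)
    carried <- cv$variants[cv$geno[, "s"] == "1", , drop = FALSE]
    expect_identical(apply_variants(ref, carried), smp)
  }
})
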