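# Shared fixture builders and independent oracles.  Fixtures are built in
# code; nothing is read from disk except the bundled extdata tables.

# deterministic random DNA
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

# a small single-gene toy: plus or minus strand, CDS split into exons.
# Returns list(model, chrom, region): chrom is the chromosome sequence,
# region the extracted coding-strand analysis region.
toy_gene <- function(strand = "+", n_exons = 2L, cds_codons = 40L,
                     intron_len = 30L, up = 60L, down = 40L,
                     chrom_pad = 25L) {
  stopifnot(cds_codons >= 4L)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(sense, cds_codons - 2L, replace = TRUE),
                             collapse = ""), "TAA")
  if (n_exons > 1L) {
    cuts <- sort(sample(seq(6L, nchar(cds) - 6L, by = 3L), n_exons - 1L))
    starts <- c(1L, cuts + 1L); ends <- c(cuts, nchar(cds))
  } else { starts <- 1L; ends <- nchar(cds) }
  exon_seqs <- substring(cds, starts, ends)
  body <- exon_seqs[1L]
  for (k in seq_len(n_exons - 1L))
    body <- paste0(body, paste0("GT", rdna(intron_len - 4L), "AG"),
                   exon_seqs[k + 1L])
  region <- paste0(rdna(up), body, rdna(down))
  chrom <- paste0(rdna(chrom_pad),
                  if (strand == "+") region else revcomp(region),
                  rdna(chrom_pad))
  # genomic coordinates of the coding-strand region inside chrom
  if (strand == "+") {
    atg <- chrom_pad + up + 1L
    stop_end <- atg + nchar(body) - 1L
    pos <- atg; ex <- matrix(0L, n_exons, 2L)
    for (k in seq_len(n_exons)) {
      ex[k, ] <- c(pos, pos + nchar(exon_seqs[k]) - 1L)
      pos <- ex[k, 2L] + 1L + if (k < n_exons) intron_len else 0L
    }
  } else {
    atg <- chrom_pad + down + nchar(body)
    stop_end <- atg - nchar(body) + 1L
    pos <- atg; ex <- matrix(0L, n_exons, 2L)
    for (k in seq_len(n_exons)) {
      ex[k, ] <- c(pos - nchar(exon_seqs[k]) + 1L, pos)
      pos <- ex[k, 1L] - 1L - if (k < n_exons) intron_len else 0L
    }
  }
  model <- gene_model("toy", "chrT", strand, atg, stop_end, ex,
                      upstream_len = up, downstream_len = down)
  list(model = model, chrom = chrom, region = region)
}

# brute-force IUPAC motif scan (independent of the package's regex route):
# per-position set comparison on both strands
brute_scan <- function(seq, motif) {
  sets <- list(A="A",C="C",G="G",T="T",R=c("A","G"),Y=c("C","T"),S=c("C","G"),
               W=c("A","T"),K=c("G","T"),M=c("A","C"),B=c("C","G","T"),
               D=c("A","G","T"),H=c("A","C","T"),V=c("A","C","G"),
               N=c("A","C","G","T"))
  hit1 <- function(s, m) {
    sc <- strsplit(s, "")[[1]]; mc <- strsplit(m, "")[[1]]
    L <- length(mc); n <- length(sc)
    out <- integer()
    if (n < L) return(out)
    for (p in 1:(n - L + 1L)) {
      ok <- TRUE
      for (j in 1:L) if (!(sc[p + j - 1L] %in% sets[[mc[j]]])) { ok <- FALSE; break }
      if (ok) out <- c(out, p)
    }
    out
  }
  rc <- revcomp(motif)
  sort(unique(c(hit1(seq, motif), if (!identical(rc, motif)) hit1(seq, rc))))
}

# independent coding-effect oracle for a SNP: apply the variant, extract
# and translate the full CDS with Biostrings, and classify from the
# protein diff
oracle_snp_effect <- function(region, model, p, alt) {
  ex <- haplomarker:::exons_region(model)
  in_cds <- !is.na(haplomarker:::cds_index(p, ex))
  if (!in_cds) return("noncoding")
  mut <- region
  substr(mut, p, p) <- alt
  cds_of <- function(r) paste(vapply(seq_len(nrow(ex)), function(k)
    substr(r, ex[k, 1L], ex[k, 2L]), character(1)), collapse = "")
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), no.init.codon = TRUE))
  pr <- tr(cds_of(region)); pm <- tr(cds_of(mut))
  if (identical(pr, pm)) return("synonymous")
  d <- which(strsplit(pr, "")[[1]] != strsplit(pm, "")[[1]])[1]
  n <- nchar(pr)
  mut_cds <- cds_of(mut)
  if (d == 1L && substr(mut_cds, 1L, 3L) != "ATG") return("start_loss")
  if (d == n && substr(pr, n, n) == "*") return("stop_loss")
  if (substr(pm, d, d) == "*") return("premature_stop")
  "missense"
}

# write a tiny VCF from explicit lines
write_toy_vcf <- function(path, body_lines,
                          samples = c("S1", "S2", "S3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
            samples), collapse = "\t"),
    body_lines), path)
  path
}

# two labelings induce the same partition iff their cross-table has exactly
# one nonzero cell per row and per column
partition_matches <- function(a, b) {
  if (anyNA(a) || anyNA(b)) return(FALSE)
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}

# run the full pipeline on a simulated panel and compare against truth
recovery_ok <- function(b) {
  asn <- classify_haplotypes(b$variants, b$geno, b$panel,
                             b$truth$reference_accession,
                             sequenced = b$truth$sequenced)
  asn <- mark_elite(asn, b$truth$elite_definition)
  uq <- find_unique_variants(asn, asn$groups$group[asn$groups$elite])
  tl <- b$truth$labels
  main <- tl[!tl$rare_novel, ]
  a <- asn$assignment[match(main$accession_id, asn$assignment$accession_id), ]
  partition_matches(a$group, main$group) &&
    partition_matches(a$haplotype, main$haplotype) &&
    setequal(a$accession_id[a$group %in% asn$groups$group[asn$groups$elite]],
             main$accession_id[main$elite]) &&
    setequal(uq$variant_id, b$truth$unique_elite) &&
    all(asn$assignment$status[match(tl$accession_id[tl$rare_novel],
                                    asn$assignment$accession_id)] ==
          "rare_novel")
}

small_cfg <- function(seed, ...) {
  panel_config(seed = seed, n_accessions = 80L, gene_length = 800L,
               upstream_len = 400L, downstream_len = 250L, ...)
}
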