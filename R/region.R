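# Gene-region extraction, variant calling from (pairwise) alignments, and
# re-application of variants to a reference region.
#
# Variant tables are plain data.frames with one row per biallelic variant:
#   variant_id, atg_pos, region_pos, genomic_pos, ref, alt, vclass
# and, after annotation, region + effect.  Allele conventions:
#   SNP       ref and alt are single bases at region_pos;
#   deletion  ref = deleted bases, alt = "", region_pos = leftmost deleted
#             base after left-normalisation;
#   insertion ref = "", alt = inserted bases, inserted *after* region_pos
#             (left-normalised).

#' Extract the analysed gene region from a genome
#'
#' Returns the coding-strand sequence of the analysis region: `upstream_len`
#' bases upstream of the start codon, the gene body (ATG through the end of
#' the stop codon, introns included), and `downstream_len` bases downstream.
#' Regions running off a chromosome end are truncated with a warning.
#'
#' @param genome named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @param g a [gene_model()].
#' @return character scalar; attributes `gene_id`, `trunc_upstream` and
#'   `trunc_downstream` record the gene and any truncation (bp lost).
#' @export
extract_gene_region <- function(genome, g) {
  if (methods::is(genome, "DNAStringSet")) genome <- toupper(as.character(genome))
  if (!g$chrom %in% names(genome))
    stop("chromosome ", g$chrom, " absent from genome")
  chrom <- genome[[g$chrom]]
  len <- nchar(chrom)
  if (g$strand == "+") {
    lo <- g$atg_genomic_pos - g$upstream_len
    hi <- g$stop_end_genomic_pos + g$downstream_len
  } else {
    lo <- g$stop_end_genomic_pos - g$downstream_len
    hi <- g$atg_genomic_pos + g$upstream_len
  }
  t_lo <- max(1L, lo); t_hi <- min(len, hi)
  if (t_lo > lo || t_hi < hi)
    warning(sprintf("gene region of %s truncated to chromosome bounds (%d bp lost)",
                    g$gene_id, (t_lo - lo) + (hi - t_hi)))
  seq <- substr(chrom, t_lo, t_hi)
  if (g$strand == "-") seq <- revcomp(seq)
  trunc_up <- if (g$strand == "+") t_lo - lo else hi - t_hi
  trunc_down <- if (g$strand == "+") hi - t_hi else t_lo - lo
  structure(toupper(seq), gene_id = g$gene_id,
            trunc_upstream = trunc_up, trunc_downstream = trunc_down)
}

# ---- indel left-normalisation -------------------------------------------

# deletion of L bases starting at p in ref (character vector): smallest
# equivalent start position
normalize_deletion <- function(ref_ch, p, L) {
  while (p > 1L && ref_ch[p - 1L] == ref_ch[p + L - 1L]) p <- p - 1L
  p
}

# insertion of string s after position p (0 allowed): smallest equivalent
# anchor; returns list(pos, seq)
normalize_insertion <- function(ref_ch, p, s) {
  s_ch <- chars(s)
  L <- length(s_ch)
  while (p >= 1L && s_ch[L] == ref_ch[p]) {
    s_ch <- c(ref_ch[p], s_ch[-L])
    p <- p - 1L
  }
  list(pos = p, seq = paste(s_ch, collapse = ""))
}

# ---- variant calling ----------------------------------------------------

new_variant_table <- function() {
  data.frame(variant_id = character(), atg_pos = integer(),
             region_pos = integer(), genomic_pos = integer(),
             ref = character(), alt = character(), vclass = character(),
             stringsAsFactors = FALSE)
}

variant_key <- function(v) paste(v$region_pos, v$ref, v$alt, v$vclass, sep = "|")

#' Call variants from per-accession gene-region sequences
#'
#' Compares each sample region sequence against the reference region and
#' reports SNPs and left-normalised indels in ATG-relative coordinates.
#' Equal-length inputs (optionally containing `-` gap columns when
#' `aligned = TRUE`) are compared column-wise; unequal-length samples are
#' first aligned with a global Needleman-Wunsch alignment (match 2,
#' mismatch -3, gap open -7, gap extend -2).
#'
#' @param ref reference region sequence (coding strand), as from
#'   [extract_gene_region()].
#' @param samples named character vector of sample region sequences.
#' @param g the [gene_model()] (provides the coordinate anchors).
#' @param aligned logical; `TRUE` if inputs are pre-aligned gapped rows of
#'   an external alignment (reference included, same length).
#' @return list with `variants` (variant table) and `geno` (character
#'   matrix variants x samples, entries "0"/"1").
#' @export
call_variants <- function(ref, samples, g, aligned = FALSE) {
  ref <- toupper(as.character(ref))
  stopifnot(!is.null(names(samples)), all(nzchar(names(samples))))
  per_sample <- list()
  for (nm in names(samples)) {
    smp <- toupper(as.character(samples[[nm]]))
    frac_amb <- mean(!chars(gsub("-", "", smp)) %in% c("A", "C", "G", "T"))
    if (frac_amb > 0.5) {
      warning("sample ", nm, " skipped: >50% ambiguous bases")
      next
    }
    if (nchar(smp) == nchar(ref) || aligned) {
      if (nchar(smp) != nchar(ref))
        stop("aligned input rows must have equal length (sample ", nm, ")")
      ra <- ref; sa <- smp
    } else {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(smp), Biostrings::DNAString(ref),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 2, mismatch = -3, baseOnly = TRUE),
        gapOpening = 7, gapExtension = 2)
      ra <- as.character(Biostrings::alignedSubject(al))
      sa <- as.character(Biostrings::alignedPattern(al))
    }
    per_sample[[nm]] <- diff_aligned_pair(ra, sa)
  }
  ref_ungapped <- gsub("-", "", ref)
  union <- new_variant_table()
  keys <- character()
  for (nm in names(per_sample)) {
    v <- per_sample[[nm]]
    if (nrow(v)) {
      k <- variant_key(v)
      new <- !k %in% keys
      union <- rbind(union, v[new, , drop = FALSE])
      keys <- c(keys, k[new])
    }
  }
  if (nrow(union)) {
    union$atg_pos <- region_to_atg(union$region_pos, g)
    union$genomic_pos <- atg_to_genomic(union$atg_pos, g)
    union$variant_id <- sprintf("%s_%+d_%s>%s", g$gene_id, union$atg_pos,
                                ifelse(union$ref == "", "-", union$ref),
                                ifelse(union$alt == "", "-", union$alt))
    ord <- order(union$region_pos, union$vclass, union$alt)
    union <- union[ord, , drop = FALSE]
    rownames(union) <- NULL
  }
  geno <- matrix("0", nrow = nrow(union), ncol = length(per_sample),
                 dimnames = list(union$variant_id, names(per_sample)))
  ukeys <- variant_key(union)
  for (nm in names(per_sample)) {
    v <- per_sample[[nm]]
    if (nrow(v)) geno[match(variant_key(v), ukeys), nm] <- "1"
  }
  list(variants = union, geno = geno)
}

# diff one gapped (ref, sample) pair; returns a variant table fragment with
# region_pos relative to the ungapped reference
diff_aligned_pair <- function(ra, sa) {
  rc <- chars(ra); sc <- chars(sa)
  stopifnot(length(rc) == length(sc))
  ref_ch <- rc[rc != "-"]
  out <- list(); n <- 0L
  rpos <- 0L
  i <- 1L
  N <- length(rc)
  while (i <= N) {
    r <- rc[i]; s <- sc[i]
    if (r != "-" && s != "-") {
      rpos <- rpos + 1L
      if (r != s && s %in% c("A", "C", "G", "T")) {
        n <- n + 1L
        out[[n]] <- data.frame(variant_id = NA_character_, atg_pos = NA_integer_,
                               region_pos = rpos, genomic_pos = NA_integer_,
                               ref = r, alt = s, vclass = "SNP",
                               stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else if (r == "-") {
      j <- i
      while (j <= N && rc[j] == "-") j <- j + 1L
      ins <- paste(sc[i:(j - 1L)], collapse = "")
      if (!grepl("-", ins, fixed = TRUE)) {
        nrm <- normalize_insertion(ref_ch, rpos, ins)
        n <- n + 1L
        out[[n]] <- data.frame(variant_id = NA_character_, atg_pos = NA_integer_,
                               region_pos = nrm$pos, genomic_pos = NA_integer_,
                               ref = "", alt = nrm$seq, vclass = "insertion",
                               stringsAsFactors = FALSE)
      }
      i <- j
    } else {  # sample gap: deletion
      j <- i
      while (j <= N && sc[j] == "-" && rc[j] != "-") j <- j + 1L
      L <- j - i
      p0 <- rpos + 1L
      p <- normalize_deletion(ref_ch, p0, L)
      n <- n + 1L
      out[[n]] <- data.frame(variant_id = NA_character_, atg_pos = NA_integer_,
                             region_pos = p, genomic_pos = NA_integer_,
                             ref = paste(ref_ch[p:(p + L - 1L)], collapse = ""),
                             alt = "", vclass = "deletion",
                             stringsAsFactors = FALSE)
      rpos <- rpos + L
      i <- j
    }
  }
  if (n == 0L) return(new_variant_table())
  do.call(rbind, out)
}

#' Apply variants to a reference region sequence
#'
#' Reconstructs a sample sequence by applying the given variant rows to the
#' reference; the inverse of [call_variants()] for a single haplotype.
#'
#' @param ref reference region sequence.
#' @param variants variant table rows to apply (must not overlap).
#' @return character scalar.
#' @export
apply_variants <- function(ref, variants) {
  if (nrow(variants) == 0L) return(as.character(ref))
  seq <- as.character(ref)
  ord <- order(variants$region_pos, decreasing = TRUE)
  for (i in ord) {
    p <- variants$region_pos[i]
    switch(variants$vclass[i],
      SNP = {
        stopifnot(substr(seq, p, p) == variants$ref[i])
        substr(seq, p, p) <- variants$alt[i]
      },
      deletion = {
        L <- nchar(variants$ref[i])
        stopifnot(substr(seq, p, p + L - 1L) == variants$ref[i])
        seq <- paste0(substr(seq, 1L, p - 1L), substr(seq, p + L, nchar(seq)))
      },
      insertion = {
        seq <- paste0(substr(seq, 1L, p), variants$alt[i],
                      substr(seq, p + 1L, nchar(seq)))
      },
      stop("unknown vclass: ", variants$vclass[i]))
  }
  seq
}
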