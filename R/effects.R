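# Region and coding-effect annotation of variants against a gene model.
#
# Region labels follow the study convention: the whole upstream pad is
# called "5'UTR" and the downstream pad "3'UTR" (deliberately loose; true
# UTR boundaries are not inferred), with "exon k" / "intron k" inside the
# gene body.  Effects: noncoding, synonymous, missense, inframe_indel,
# frameshift, premature_stop, start_loss, stop_loss.

FUNCTIONAL_EFFECTS <- c("missense", "inframe_indel", "frameshift",
                        "premature_stop", "start_loss", "stop_loss")

# region label of a single region-space position
region_label <- function(p, g, ex = exons_region(g)) {
  up <- g$upstream_len
  if (p <= up) return("5'UTR")
  if (p > up + body_length(g)) return("3'UTR")
  for (k in seq_len(nrow(ex))) {
    if (p >= ex[k, "start"] && p <= ex[k, "end"]) return(paste("exon", k))
    if (k < nrow(ex) && p > ex[k, "end"] && p < ex[k + 1L, "start"])
      return(paste("intron", k))
  }
  # gene body but past the last CDS base (can happen if stop_end < last exon
  # end is violated upstream); treat as intron-like noncoding body sequence
  "intron 0"
}

# 1-based CDS index of an exonic region-space position (NA if not exonic)
cds_index <- function(p, ex) {
  cum <- 0L
  for (k in seq_len(nrow(ex))) {
    if (p >= ex[k, "start"] && p <= ex[k, "end"])
      return(cum + (p - ex[k, "start"] + 1L))
    cum <- cum + (ex[k, "end"] - ex[k, "start"] + 1L)
  }
  NA_integer_
}

# concatenated CDS sequence of a region sequence
extract_cds <- function(ref, ex) {
  paste(vapply(seq_len(nrow(ex)),
               function(k) substr(ref, ex[k, "start"], ex[k, "end"]),
               character(1)),
        collapse = "")
}

#' Annotate region and coding effect of variants
#'
#' Fills the `region` and `effect` columns of a variant table.  Exonic SNPs
#' are classified by translating the affected codon under both alleles;
#' exonic indels are frameshift when the number of affected CDS bases is
#' not a multiple of three, in-frame otherwise.  A deletion spanning an
#' exon-intron boundary is labelled by the most severe region touched
#' (exon) and is a frameshift if CDS bases are removed.
#'
#' @param variants variant table (see [call_variants()]).
#' @param g the [gene_model()].
#' @param ref reference region sequence.
#' @return the variant table with `region` and `effect` columns.
#' @export
annotate_effects <- function(variants, g, ref) {
  ex <- exons_region(g)
  cds <- extract_cds(ref, ex)
  n_codons <- nchar(cds) %/% 3L
  rl <- region_length(g)
  region <- character(nrow(variants))
  effect <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    p <- variants$region_pos[i]
    vclass <- variants$vclass[i]
    span_end <- if (vclass == "deletion") p + nchar(variants$ref[i]) - 1L else p
    if (p < 0L || span_end > rl)
      stop("variant ", variants$variant_id[i], " outside the gene region")
    if (vclass == "SNP") {
      region[i] <- region_label(p, g, ex)
      effect[i] <- snp_effect(p, variants$ref[i], variants$alt[i],
                              ex, cds, n_codons)
    } else if (vclass == "deletion") {
      span <- p:span_end
      cdsN <- sum(!is.na(vapply(span, cds_index, integer(1), ex = ex)))
      if (cdsN > 0L) {
        first_ex <- span[which(!is.na(vapply(span, cds_index, integer(1),
                                             ex = ex)))[1L]]
        region[i] <- region_label(first_ex, g, ex)
        effect[i] <- if (cdsN %% 3L != 0L) "frameshift" else "inframe_indel"
      } else {
        region[i] <- region_label(p, g, ex)
        effect[i] <- "noncoding"
      }
    } else {  # insertion after p
      L <- nchar(variants$alt[i])
      in_cds <- !is.na(cds_index(p, ex)) && !is.na(cds_index(p + 1L, ex)) &&
        region_label(p, g, ex) == region_label(p + 1L, g, ex)
      if (in_cds) {
        region[i] <- region_label(p, g, ex)
        effect[i] <- if (L %% 3L != 0L) "frameshift" else "inframe_indel"
      } else {
        region[i] <- region_label(max(p, 1L), g, ex)
        effect[i] <- "noncoding"
      }
    }
  }
  variants$region <- region
  variants$effect <- effect
  variants
}

# effect of an exonic (or not) SNP
snp_effect <- function(p, ref_base, alt_base, ex, cds, n_codons) {
  ci <- cds_index(p, ex)
  if (is.na(ci)) return("noncoding")
  codon_i <- (ci - 1L) %/% 3L + 1L
  off <- (ci - 1L) %% 3L + 1L
  codon <- substr(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  stopifnot(substr(codon, off, off) == ref_base)
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_base
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(alt_codon)
  if (codon_i == 1L) {
    if (alt_codon != "ATG") return("start_loss")
    return("synonymous")
  }
  if (codon_i == n_codons) {
    # natural stop codon
    if (identical(ref_aa, "*") && !identical(alt_aa, "*")) return("stop_loss")
    if (identical(ref_aa, alt_aa)) return("synonymous")
    return("missense")
  }
  if (identical(alt_aa, "*")) return("premature_stop")
  if (identical(ref_aa, alt_aa)) return("synonymous")
  "missense"
}
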