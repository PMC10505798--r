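# Gene models and the ATG-relative coordinate system.
#
# Two coordinate systems coexist in this package:
#   * genomic coordinates: 1-based, chromosome-forward (GFF3/VCF convention);
#   * ATG-relative coordinates: signed integers on the coding strand with the
#     A of the start codon defined as +1, the base immediately upstream as -1,
#     and no zero.  The axis counts *genomic* bases of the gene region
#     (introns included), so deep-intron and downstream positions are
#     addressable.
# A third, internal system is "region space": the 1-based index into the
# extracted gene-region sequence (upstream pad + gene body + downstream pad
# on the coding strand).

#' Construct a gene model
#'
#' A gene model anchors the ATG-relative coordinate system for one gene:
#' the genomic position of the first base of the start codon, the last base
#' of the stop codon, and the coding (CDS) segments in coding order.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param atg_genomic_pos genomic position (1-based) of the A of the start
#'   codon.
#' @param stop_end_genomic_pos genomic position of the last base of the stop
#'   codon.
#' @param exons two-column matrix (`start`, `end`, genomic 1-based closed) of
#'   coding segments, one row per segment, in coding (5'->3') order; for
#'   minus-strand genes this means descending genomic coordinates.
#' @param upstream_len,downstream_len lengths (bp) of the flanking regions
#'   analysed with the gene; defaults 2000 and 1000.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, atg_genomic_pos,
                       stop_end_genomic_pos, exons,
                       upstream_len = 2000L, downstream_len = 1000L) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, "end"] < exons[, "start"]))
    stop("exon end < start")
  cds_len <- sum(exons[, "end"] - exons[, "start"] + 1L)
  if (cds_len %% 3L != 0L)
    stop("CDS length not a multiple of 3 for gene ", gene_id)
  # coding order: ascending genomic on +, descending on -
  ord <- order(exons[, "start"], decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L) {
    s <- exons[order(exons[, "start"]), , drop = FALSE]
    if (any(s[-1L, "start"] <= s[-nrow(s), "end"]))
      stop("overlapping exons in gene ", gene_id)
  }
  first <- exons[1L, ]
  if (atg_genomic_pos < first["start"] || atg_genomic_pos > first["end"])
    stop("ATG not inside first exon of gene ", gene_id)
  g <- list(gene_id = as.character(gene_id), chrom = as.character(chrom),
            strand = strand,
            atg_genomic_pos = as.integer(atg_genomic_pos),
            stop_end_genomic_pos = as.integer(stop_end_genomic_pos),
            exons = exons,
            upstream_len = as.integer(upstream_len),
            downstream_len = as.integer(downstream_len))
  class(g) <- "gene_model"
  g
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%s  ATG@%d  %d CDS segment(s), CDS %d bp\n",
              x$gene_id, x$chrom, x$strand, x$atg_genomic_pos,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

cds_length <- function(g) sum(g$exons[, "end"] - g$exons[, "start"] + 1L)

# length of the gene body (ATG..stop end inclusive, introns included)
body_length <- function(g) abs(g$stop_end_genomic_pos - g$atg_genomic_pos) + 1L

region_length <- function(g) g$upstream_len + body_length(g) + g$downstream_len

#' Convert ATG-relative coordinates to genomic coordinates
#'
#' The A of the start codon is +1; the base immediately upstream is -1;
#' there is no zero.  The axis runs along the coding strand and counts
#' genomic bases, introns included.
#'
#' @param pos integer vector of ATG-relative coordinates (no zeros).
#' @param g a [gene_model()].
#' @return integer vector of genomic coordinates.
#' @export
atg_to_genomic <- function(pos, g) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) stop("no zero coordinate on the ATG-relative axis")
  off <- ifelse(pos > 0L, pos - 1L, pos)
  if (g$strand == "+") g$atg_genomic_pos + off else g$atg_genomic_pos - off
}

#' Convert genomic coordinates to ATG-relative coordinates
#'
#' Inverse of [atg_to_genomic()].
#'
#' @inheritParams atg_to_genomic
#' @param gpos integer vector of genomic coordinates.
#' @return integer vector of signed ATG-relative coordinates.
#' @export
genomic_to_atg <- function(gpos, g) {
  gpos <- as.integer(gpos)
  off <- if (g$strand == "+") gpos - g$atg_genomic_pos else g$atg_genomic_pos - gpos
  ifelse(off >= 0L, off + 1L, off)
}

# ATG coordinate -> 1-based index into the extracted region sequence
atg_to_region <- function(pos, g) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) stop("no zero coordinate on the ATG-relative axis")
  g$upstream_len + ifelse(pos > 0L, pos, pos + 1L)
}

# inverse of atg_to_region
region_to_atg <- function(idx, g) {
  idx <- as.integer(idx)
  off <- idx - g$upstream_len
  ifelse(off >= 1L, off, off - 1L)
}

# exon intervals in region space (1-based closed), coding order
exons_region <- function(g) {
  a <- genomic_to_atg(g$exons[, "start"], g)
  b <- genomic_to_atg(g$exons[, "end"], g)
  lo <- pmin(a, b); hi <- pmax(a, b)
  cbind(start = atg_to_region(lo, g), end = atg_to_region(hi, g))
}

#' Read gene models from a GFF3 file
#'
#' Builds one [gene_model()] per gene from `gene`/`mRNA`/`exon`/`CDS`
#' features.  Coding segments (CDS) define the exon structure used for the
#' ATG-relative coordinate system; minus-strand genes are normalised so the
#' segment order is coding order.
#'
#' @param path GFF3 file.
#' @param gene_ids optional character vector restricting which genes to load.
#' @param upstream_len,downstream_len flanking lengths passed to
#'   [gene_model()].
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, gene_ids = NULL,
                             upstream_len = 2000L, downstream_len = 1000L) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  ids <- as.character(genes$ID %||% genes$Name)
  if (!is.null(gene_ids)) {
    keep <- ids %in% gene_ids
    genes <- genes[keep]; ids <- ids[keep]
    missing <- setdiff(gene_ids, ids)
    if (length(missing))
      stop("gene(s) not found in GFF3: ", paste(missing, collapse = ", "))
  }
  out <- list()
  cds_all <- gr[typ == "CDS"]
  for (i in seq_along(genes)) {
    gid <- ids[i]
    gg <- genes[i]
    # CDS rows whose Parent chains to this gene: match by overlap + same seqname
    inside <- cds_all[as.character(GenomicRanges::seqnames(cds_all)) ==
                        as.character(GenomicRanges::seqnames(gg)) &
                      GenomicRanges::start(cds_all) >= GenomicRanges::start(gg) &
                      GenomicRanges::end(cds_all) <= GenomicRanges::end(gg)]
    if (length(inside) == 0L)
      stop("no CDS features for gene ", gid)
    ex <- unique(cbind(GenomicRanges::start(inside), GenomicRanges::end(inside)))
    strand <- as.character(GenomicRanges::strand(gg))
    if (!strand %in% c("+", "-"))
      stop("gene ", gid, " has no strand")
    if (strand == "+") {
      atg <- min(ex[, 1L]); stop_end <- max(ex[, 2L])
    } else {
      atg <- max(ex[, 2L]); stop_end <- min(ex[, 1L])
    }
    out[[gid]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gg)),
      strand = strand,
      atg_genomic_pos = atg,
      stop_end_genomic_pos = stop_end,
      exons = ex,
      upstream_len = upstream_len, downstream_len = downstream_len)
  }
  out
}
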