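# Readers and writers for the external plain-text formats: accession
# metadata TSV, restriction-enzyme TSV, elite-definition TSV, VCF genotype
# matrices, and per-accession gene-region FASTA.

SUBPOPULATIONS <- c("XI", "XI-IM", "IM", "GJ-IM", "GJ-tem", "GJ-tro",
                    "VI/Aro", "aus", "other")

#' Read an accession metadata table
#'
#' Tab-separated file with columns `accession_id` and `subpopulation`
#' (labels follow the usual rice panel nomenclature: XI, XI-IM, IM, GJ-IM,
#' GJ-tem, GJ-tro, VI/Aro, aus, other).
#'
#' @param path TSV file.
#' @return data.frame with columns `accession_id`, `subpopulation`.
#' @export
read_panel_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession_id", "subpopulation") %in% names(df)))
    stop("panel metadata needs columns accession_id, subpopulation")
  if (anyDuplicated(df$accession_id))
    stop("duplicate accession_id in panel metadata")
  df[c("accession_id", "subpopulation")]
}

#' @rdname read_panel_meta
#' @param panel data.frame as returned by `read_panel_meta`.
#' @export
write_panel_meta <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restriction enzyme definitions
#'
#' `read_enzyme_table()` reads a TSV with columns `name`, `motif` (IUPAC),
#' `cut_offset` (bases after the motif start on the top strand at which the
#' enzyme cuts; 0 = before the first motif base).  `default_enzymes()`
#' returns the built-in library of seven common, inexpensive enzymes used
#' for CAPS/dCAPS design.
#'
#' @param path TSV file.
#' @return data.frame with columns `name`, `motif`, `cut_offset`.
#' @export
read_enzyme_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "motif", "cut_offset") %in% names(df)))
    stop("enzyme table needs columns name, motif, cut_offset")
  validate_enzymes(df)
  df
}

validate_enzymes <- function(df) {
  for (i in seq_len(nrow(df))) {
    motif <- toupper(df$motif[i])
    if (nchar(motif) < 4L)
      stop("enzyme ", df$name[i], ": motif shorter than 4")
    if (!all(chars(motif) %in% names(IUPAC_SETS)))
      stop("enzyme ", df$name[i], ": motif has non-IUPAC characters")
    co <- df$cut_offset[i]
    if (co < 0L || co > nchar(motif))
      stop("enzyme ", df$name[i], ": cut_offset outside motif")
  }
  invisible(df)
}

#' @rdname read_enzyme_table
#' @export
default_enzymes <- function() {
  data.frame(
    name = c("EcoRI", "EcoRII", "HhaI", "PstI", "DraI", "HinfI", "HaeIII"),
    motif = c("GAATTC", "CCWGG", "GCGC", "CTGCAG", "TTTAAA", "GANTC", "GGCC"),
    cut_offset = c(1L, 0L, 3L, 5L, 3L, 1L, 2L),
    stringsAsFactors = FALSE)
}

#' Elite haplotype definitions
#'
#' An elite definition lists the ATG-relative positions and required
#' (non-reference or reference) alleles that the published elite haplotype
#' of a gene carries.  `elite_definition()` builds one in code;
#' `read_elite_definitions()` reads a TSV with columns `gene_id`, `atg_pos`,
#' `allele` (and optional `note`) and returns a named list of definitions.
#'
#' @param gene_id gene identifier.
#' @param positions integer vector of ATG-relative positions (no zeros).
#' @param alleles character vector of required allele strings, parallel to
#'   `positions`.
#' @param note free-text provenance note.
#' @return an object of class `elite_definition`.
#' @export
elite_definition <- function(gene_id, positions, alleles, note = "") {
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(alleles), all(positions != 0L))
  structure(list(gene_id = gene_id, positions = positions,
                 alleles = toupper(as.character(alleles)), note = note),
            class = "elite_definition")
}

#' @rdname elite_definition
#' @param path TSV file.
#' @export
read_elite_definitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "atg_pos", "allele")
  if (!all(need %in% names(df)))
    stop("elite definition table needs columns gene_id, atg_pos, allele")
  lapply(split(df, df$gene_id), function(d) {
    elite_definition(d$gene_id[1L], d$atg_pos, d$allele,
                     note = if ("note" %in% names(d)) d$note[1L] else "")
  })
}

#' Read a per-accession genotype matrix from a VCF file
#'
#' Multi-allelic records are split into biallelic rows.  Genotypes are
#' recoded as `"0"` (homozygous reference), `"1"` (homozygous alternate),
#' `"het"` (heterozygous) or `NA` (missing); only homozygous calls are
#' usable for haplotype classification.
#'
#' @param path VCF 4.x file (uncompressed or bgzipped).
#' @param panel optional accession metadata data.frame; sample ids absent
#'   from the panel trigger a warning.
#' @return list with `variants` (data.frame: variant_id, chrom, genomic_pos,
#'   ref, alt, vclass) and `geno` (character matrix, variants x accessions).
#' @export
read_variant_matrix <- function(path, panel = NULL) {
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    return(list(
      variants = data.frame(variant_id = character(), chrom = character(),
                            genomic_pos = integer(), ref = character(),
                            alt = character(), vclass = character(),
                            stringsAsFactors = FALSE),
      geno = matrix(character(), nrow = 0, ncol = 0)))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  samples <- colnames(gt)
  if (!is.null(panel)) {
    extra <- setdiff(samples, panel$accession_id)
    if (length(extra))
      warning("VCF samples absent from panel: ", paste(extra, collapse = ", "))
  }
  rows <- list(); genos <- list(); rid <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    for (ai in seq_along(alts)) {
      rid <- rid + 1L
      ref <- toupper(fix$REF[i]); alt <- toupper(alts[ai])
      vclass <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP"
                else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
      id <- fix$ID[i]
      if (is.na(id) || id == ".")
        id <- sprintf("%s_%s_%s_%s", fix$CHROM[i], fix$POS[i], ref, alt)
      else if (length(alts) > 1L) id <- paste0(id, "_", ai)
      rows[[rid]] <- data.frame(
        variant_id = id, chrom = fix$CHROM[i],
        genomic_pos = as.integer(fix$POS[i]),
        ref = ref, alt = alt, vclass = vclass, stringsAsFactors = FALSE)
      g <- gt[i, ]
      genos[[rid]] <- vapply(g, function(x) recode_gt(x, ai), character(1))
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  dimnames(geno) <- list(variants$variant_id, samples)
  geno[geno == "NA"] <- NA_character_
  list(variants = variants, geno = geno)
}

# recode one GT string against alternate allele index `ai`
recode_gt <- function(x, ai) {
  if (is.na(x) || x %in% c(".", "./.", ".|.")) return("NA")
  al <- strsplit(x, "[/|]")[[1L]]
  if (any(al == ".")) return("NA")
  al <- as.integer(al)
  if (length(al) == 1L) al <- c(al, al)      # haploid call
  if (length(unique(al)) > 1L) return("het") # heterozygous: unassignable
  if (al[1L] == ai) "1" else "0"             # hom other-alt does not carry
}

# cheap structural validation so malformed body lines are reported by number
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  header <- grep("^#CHROM", lines)
  nfield <- if (length(header)) length(strsplit(lines[header[1L]], "\t")[[1L]]) else NA
  for (i in body) {
    n <- length(strsplit(lines[i], "\t")[[1L]])
    if (n < 8L || (!is.na(nfield) && n != nfield))
      stop("malformed VCF line ", i, ": expected ", nfield, " fields, found ", n)
  }
  invisible(path)
}

#' Read/write per-accession gene-region FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named upper-case
#' character vectors (one record per accession).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_region_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_region_fasta
#' @param seqs named character vector of sequences.
#' @export
write_region_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
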