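# Small sequence utilities shared across the package. Sequences are plain
# upper-case character scalars over A/C/G/T/N unless noted; IUPAC ambiguity
# codes are only ever allowed in restriction-enzyme motifs.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D",
                a = "t", c = "g", g = "c", t = "a", n = "n")

#' Reverse complement of a nucleotide string
#'
#' Case is preserved (lower-case bases mark designed primer mismatches
#' elsewhere in the package); IUPAC ambiguity codes are complemented to
#' their partners.
#'
#' @param x character scalar over IUPAC nucleotide codes.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1L]])
  out <- COMPLEMENT[ch]
  if (anyNA(out)) stop("non-IUPAC character in sequence")
  paste(out, collapse = "")
}

# split a scalar string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# does base b (A/C/G/T) fall in the IUPAC set of motif code m?
# N in the *sequence* never matches any motif code.
iupac_match <- function(b, m) {
  set <- IUPAC_SETS[[m]]
  if (is.null(set)) stop("unknown IUPAC code: ", m)
  b %in% set
}

# deterministic representative base for an IUPAC code (first of the set)
iupac_representative <- function(m) IUPAC_SETS[[m]][1L]

# random DNA string using the current RNG stream
random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

GENETIC_CODE_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  # order: TTT, CTT, ATT, GTT, TCT, ... matches outer() expansion below
  aa <- character(64)
  names(aa) <- codons
  spec <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  spec
})

# translate one codon; NA for codons containing non-ACGT
translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  unname(aa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
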