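# Restriction-site scanning over IUPAC motifs and fragment prediction.
#
# Matching semantics: a motif matches wherever every motif code's IUPAC set
# contains the sequence base; an N in the *sequence* never matches (real
# digests do not read ambiguous template).  Non-palindromic motifs are also
# searched on the bottom strand; matches are always reported in top-strand
# coordinates.

iupac_regex <- function(motif) {
  sets <- vapply(chars(toupper(motif)), function(m) {
    s <- IUPAC_SETS[[m]]
    if (is.null(s)) stop("unknown IUPAC code in motif: ", m)
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  paste(sets, collapse = "")
}

#' Scan a sequence for restriction-enzyme recognition sites
#'
#' Finds all (possibly overlapping) matches of the enzyme's IUPAC motif on
#' both strands.  Positions are 1-based starts of the matched window on the
#' top strand; the `strand` column records which strand the motif reading
#' matched.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param enzyme one row of an enzyme table (list/data.frame with `name`,
#'   `motif`, `cut_offset`).
#' @return data.frame with columns `pos` and `strand`.
#' @export
scan_restriction_sites <- function(seq, enzyme) {
  seq <- toupper(as.character(seq))
  motif <- toupper(enzyme$motif)
  hits <- regex_starts(seq, iupac_regex(motif))
  strand <- rep("+", length(hits))
  rcm <- revcomp(motif)
  if (!identical(rcm, motif)) {
    h2 <- regex_starts(seq, iupac_regex(rcm))
    h2 <- setdiff(h2, hits)
    hits <- c(hits, h2)
    strand <- c(strand, rep("-", length(h2)))
  }
  ord <- order(hits)
  data.frame(pos = hits[ord], strand = strand[ord], stringsAsFactors = FALSE)
}

# all overlapping match starts of a regex
regex_starts <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Top-strand cut positions of an enzyme in a sequence
#'
#' A cut at position `p` severs the backbone between bases `p` and `p + 1`.
#' For bottom-strand matches of non-palindromic motifs the bottom-strand
#' cut offset is mirrored into top-strand coordinates.  Cuts at or beyond
#' the sequence ends are discarded.
#'
#' @inheritParams scan_restriction_sites
#' @return sorted integer vector of cut positions.
#' @export
cut_sites <- function(seq, enzyme) {
  sites <- scan_restriction_sites(seq, enzyme)
  if (nrow(sites) == 0L) return(integer())
  L <- nchar(enzyme$motif)
  co <- as.integer(enzyme$cut_offset)
  cuts <- ifelse(sites$strand == "+",
                 sites$pos + co - 1L,
                 sites$pos + (L - co) - 1L)
  cuts <- cuts[cuts >= 1L & cuts < nchar(seq)]
  sort(unique(as.integer(cuts)))
}

#' Predict restriction fragment sizes
#'
#' @param amplicon_len amplicon length in bp.
#' @param cut_positions cut positions (cut after base `p`), within
#'   `[1, amplicon_len - 1]`.
#' @return integer vector of fragment lengths; sums to `amplicon_len`, one
#'   more fragment than cuts.
#' @export
predict_digestion <- function(amplicon_len, cut_positions) {
  cut_positions <- sort(unique(as.integer(cut_positions)))
  stopifnot(all(cut_positions >= 1L), all(cut_positions < amplicon_len))
  bounds <- c(0L, cut_positions, as.integer(amplicon_len))
  diff(bounds)
}
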