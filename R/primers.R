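# Primer arithmetic and deterministic primer-pair search.
#
# Melting temperature uses the Wallace 2+4 rule (2 C per A/T, 4 C per G/C):
# simple, deterministic, and adequate for the 18-24-mers designed here.
# Designed dCAPS mismatches are written lower-case in the synthesized
# primer sequence; Tm and GC are computed on the synthesized sequence.

#' Wallace-rule melting temperature
#'
#' @param seq primer sequence (case-insensitive).
#' @return Tm in degrees C: `2*(A+T) + 4*(G+C)`.
#' @export
tm_wallace <- function(seq) {
  ch <- chars(toupper(seq))
  2L * sum(ch %in% c("A", "T")) + 4L * sum(ch %in% c("G", "C"))
}

gc_fraction <- function(seq) {
  ch <- chars(toupper(seq))
  mean(ch %in% c("G", "C"))
}

# TRUE if the 3'-terminal base sits in a mononucleotide run of >= 4
terminal_run4 <- function(seq) {
  ch <- chars(toupper(seq))
  n <- length(ch)
  if (n < 4L) return(FALSE)
  length(unique(ch[(n - 3L):n])) == 1L
}

PRIMER_LEN_MIN <- 18L
PRIMER_LEN_MAX <- 24L

# which single constraint (if any) a candidate primer violates
primer_violation <- function(seq, tm_range = c(52, 62), gc_range = c(0.30, 0.70)) {
  gc <- gc_fraction(seq)
  if (gc < gc_range[1L] || gc > gc_range[2L]) return("gc_content")
  tm <- tm_wallace(seq)
  if (tm < tm_range[1L] || tm > tm_range[2L]) return("tm")
  if (terminal_run4(seq)) return("terminal_mononucleotide_run")
  NA_character_
}

new_primer <- function(seq, template_start, template_end, strand,
                       mismatch_positions = integer()) {
  structure(list(seq = seq, template_start = as.integer(template_start),
                 template_end = as.integer(template_end), strand = strand,
                 mismatch_positions = as.integer(mismatch_positions)),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer %s> %s (%d nt, Tm %d)\n", x$strand, x$seq,
              nchar(x$seq), tm_wallace(x$seq)))
  invisible(x)
}

# enumerate admissible primers on one side of a must-span interval.
# side = "left": forward primers ending at positions <= limit;
# side = "right": reverse primers starting at positions >= limit.
# Returns a data.frame of footprints, nearest-to-span first, capped.
enumerate_primers <- function(template, side, limit, reach, fails,
                              cap = 600L, avoid = integer()) {
  n <- nchar(template)
  out <- vector("list", 0L)
  count <- 0L
  empty <- list(cands = data.frame(start = integer(), end = integer(),
                                   seq = character(), tm = numeric()),
                fails = fails)
  # stride the binding-site scan so candidate footprints cover the whole
  # product-size window, not just the positions nearest the target
  stride <- max(1L, reach %/% 120L)
  if (side == "left") {
    lo <- max(PRIMER_LEN_MIN, limit - reach)
    if (limit < lo) return(empty)
    ends <- seq(limit, lo, by = -stride)
  } else {
    hi <- min(n - PRIMER_LEN_MIN + 1L, limit + reach)
    if (limit > hi) return(empty)
    ends <- seq(limit, hi, by = stride)
  }
  for (e in ends) {
    for (l in PRIMER_LEN_MIN:PRIMER_LEN_MAX) {
      if (side == "left") { fs <- e - l + 1L; fe <- e } else { fs <- e; fe <- e + l - 1L }
      if (fs < 1L || fe > n) next
      if (length(avoid) && any(avoid >= fs & avoid <= fe)) {
        fails[["polymorphic_binding_site"]] <- fails[["polymorphic_binding_site"]] + 1L
        next
      }
      raw <- substr(template, fs, fe)
      seq <- if (side == "left") raw else revcomp(raw)
      viol <- primer_violation(seq)
      if (!is.na(viol)) { fails[[viol]] <- fails[[viol]] + 1L; next }
      count <- count + 1L
      out[[count]] <- data.frame(start = fs, end = fe, seq = seq,
                                 tm = tm_wallace(seq), stringsAsFactors = FALSE)
      if (count >= cap) break
    }
    if (count >= cap) break
  }
  list(cands = if (count) do.call(rbind, out) else
         data.frame(start = integer(), end = integer(), seq = character(),
                    tm = numeric()),
       fails = fails)
}

#' Design a primer pair around a target interval
#'
#' Deterministic search for a forward/reverse primer pair whose product
#' contains `must_span` and whose length lies in `product_range`.
#' Constraints: primer length 18-24 nt, GC 30-70%, Wallace Tm 52-62 C,
#' pairwise Tm difference <= 5 C, and the 3'-terminal base must not sit in
#' a mononucleotide run of four or more.  One primer may be fixed (dCAPS
#' design supplies the mismatch-bearing primer).
#'
#' @param template template sequence (coding strand).
#' @param must_span integer length-2: interval the product must contain;
#'   primers bind outside it.
#' @param product_range integer length-2: allowed product lengths.
#' @param fixed_forward,fixed_reverse optional `primer_spec` fixing one
#'   side.
#' @param avoid template positions (known polymorphic sites) that no
#'   primer footprint may cover.
#' @return list with `forward` and `reverse` `primer_spec`s and
#'   `product_len`.
#' @export
design_primer_pair <- function(template, must_span, product_range,
                               fixed_forward = NULL, fixed_reverse = NULL,
                               avoid = integer()) {
  template <- toupper(as.character(template))
  n <- nchar(template)
  must_span <- as.integer(must_span)
  stopifnot(length(must_span) == 2L, must_span[1L] <= must_span[2L],
            must_span[1L] >= 1L, must_span[2L] <= n)
  if (product_range[2L] < 2L * PRIMER_LEN_MIN + (must_span[2L] - must_span[1L] + 1L) &&
      is.null(fixed_forward) && is.null(fixed_reverse))
    stop("product range (", product_range[1L], ",", product_range[2L],
         ") cannot hold two primers around the target")
  fails <- list(gc_content = 0L, tm = 0L, terminal_mononucleotide_run = 0L,
                product_length = 0L, tm_difference = 0L,
                polymorphic_binding_site = 0L)
  reach <- product_range[2L]

  if (is.null(fixed_forward)) {
    ef <- enumerate_primers(template, "left", must_span[1L] - 1L, reach, fails,
                            avoid = avoid)
    Fc <- ef$cands; fails <- ef$fails
  } else {
    Fc <- data.frame(start = fixed_forward$template_start,
                     end = fixed_forward$template_end,
                     seq = fixed_forward$seq,
                     tm = tm_wallace(fixed_forward$seq), stringsAsFactors = FALSE)
  }
  if (is.null(fixed_reverse)) {
    er <- enumerate_primers(template, "right", must_span[2L] + 1L, reach, fails,
                            avoid = avoid)
    Rc <- er$cands; fails <- er$fails
  } else {
    Rc <- data.frame(start = fixed_reverse$template_start,
                     end = fixed_reverse$template_end,
                     seq = fixed_reverse$seq,
                     tm = tm_wallace(fixed_reverse$seq), stringsAsFactors = FALSE)
  }
  if (nrow(Fc) == 0L || nrow(Rc) == 0L)
    return(primer_failure(fails))

  idx <- expand.grid(f = seq_len(nrow(Fc)), r = seq_len(nrow(Rc)))
  plen <- Rc$end[idx$r] - Fc$start[idx$f] + 1L
  ok_len <- plen >= product_range[1L] & plen <= product_range[2L]
  fails$product_length <- fails$product_length + sum(!ok_len)
  dtm <- abs(Fc$tm[idx$f] - Rc$tm[idx$r])
  ok_tm <- dtm <= 5
  fails$tm_difference <- fails$tm_difference + sum(ok_len & !ok_tm)
  ok <- ok_len & ok_tm
  if (!any(ok)) return(primer_failure(fails))
  mid <- mean(product_range)
  sel <- which(ok)
  best <- sel[order(abs(plen[sel] - mid), Fc$start[idx$f[sel]],
                    Rc$end[idx$r[sel]])][1L]
  fi <- idx$f[best]; ri <- idx$r[best]
  fwd <- if (is.null(fixed_forward))
    new_primer(Fc$seq[fi], Fc$start[fi], Fc$end[fi], "F") else fixed_forward
  rev <- if (is.null(fixed_reverse))
    new_primer(Rc$seq[ri], Rc$start[ri], Rc$end[ri], "R") else fixed_reverse
  list(forward = fwd, reverse = rev, product_len = as.integer(plen[best]))
}

primer_failure <- function(fails) {
  worst <- names(fails)[which.max(unlist(fails))]
  stop("no admissible primer pair; most frequent failing constraint: ",
       worst, call. = FALSE)
}
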