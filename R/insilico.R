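# In-silico PCR, digestion and genotype calling: the computational twin of
# running the markers on a gel.
#
# Gel resolution model (stated explicitly because only gel recipes exist in
# common protocols): two bands are resolvable on 6% PAGE when they differ
# by at least max(4 bp, 2% of the smaller band), and on 2% agarose by at
# least max(20 bp, 5% of the smaller band).  Lanes whose largest band is
# under 300 bp are read on PAGE, larger ones on agarose.  Co-migrating
# (unresolvable) fragments within a lane are merged into one band before
# patterns are compared.

#' Gel class for a band size
#'
#' @param max_band largest band in the lane (bp).
#' @return `"PAGE"` if under 300 bp, else `"agarose"`.
#' @export
gel_class <- function(max_band) if (max_band < 300) "PAGE" else "agarose"

#' Are two band sizes resolvable on a gel?
#'
#' @param b1,b2 band sizes (bp, >= 1).
#' @param gel `"PAGE"` or `"agarose"`.
#' @return logical.
#' @export
resolvable <- function(b1, b2, gel = c("PAGE", "agarose")) {
  gel <- match.arg(gel)
  stopifnot(b1 >= 1, b2 >= 1)
  d <- abs(b1 - b2)
  thr <- if (gel == "PAGE") max(4, 0.02 * min(b1, b2))
         else max(20, 0.05 * min(b1, b2))
  d >= thr
}

# merge co-migrating bands within a lane: consecutive sorted bands that are
# not resolvable collapse to one band (rounded mean of the cluster)
merge_bands <- function(bands, gel) {
  bands <- sort(as.numeric(bands))
  if (length(bands) <= 1L) return(bands)
  out <- list(); cur <- bands[1L]
  for (b in bands[-1L]) {
    if (!resolvable(cur[length(cur)], b, gel)) cur <- c(cur, b)
    else { out[[length(out) + 1L]] <- cur; cur <- b }
  }
  out[[length(out) + 1L]] <- cur
  vapply(out, function(cl) round(mean(cl)), numeric(1))
}

# do two merged band patterns look identical on the gel?
patterns_match <- function(m1, m2, gel) {
  if (length(m1) != length(m2)) return(FALSE)
  all(!mapply(resolvable, m1, m2, MoreArgs = list(gel = gel)))
}

#' Simulate PCR of a marker on a template
#'
#' Primers bind where every upper-case base matches the template exactly
#' (up to `max_unintended_mismatches` tolerated mismatches); lower-case
#' designed dCAPS mismatches are tolerated by definition, and the amplicon
#' carries the primer-encoded bases.  The amplicon runs between the primer
#' 5' ends inclusive.
#'
#' @param template accession region sequence (coding strand).
#' @param m a `marker_spec`.
#' @param max_unintended_mismatches tolerated non-designed mismatches per
#'   primer (default 0).
#' @param max_product longest product considered amplifiable (default
#'   5000 bp).
#' @return amplicon sequence, or `NULL` when a primer fails to bind.
#' @export
virtual_pcr <- function(template, m, max_unintended_mismatches = 0L,
                        max_product = 5000L) {
  template <- toupper(as.character(template))
  tch <- chars(template)
  f_sites <- primer_sites(tch, m$forward$seq, max_unintended_mismatches)
  r_foot <- revcomp(m$reverse$seq)        # top-strand footprint, 5'->3'
  r_sites <- primer_sites(tch, r_foot, max_unintended_mismatches)
  lf <- nchar(m$forward$seq); lr <- nchar(m$reverse$seq)
  if (!length(f_sites) || !length(r_sites)) return(NULL)
  prods <- list()
  for (f in f_sites) for (r in r_sites) {
    start <- f; end <- r + lr - 1L
    if (r >= f + lf && end - start + 1L <= max_product)
      prods[[length(prods) + 1L]] <- c(start, end)
  }
  if (!length(prods)) return(NULL)
  if (length(prods) > 1L)
    stop("non-specific marker ", m$name, ": products at ",
         paste(vapply(prods, function(p) paste(p, collapse = "-"),
                      character(1)), collapse = ", "))
  se <- prods[[1L]]
  amp <- substr(template, se[1L], se[2L])
  fseq <- toupper(m$forward$seq)
  substr(amp, 1L, nchar(fseq)) <- fseq
  rfoot_up <- toupper(r_foot)
  substr(amp, nchar(amp) - nchar(rfoot_up) + 1L, nchar(amp)) <- rfoot_up
  amp
}

# start positions where the primer (5'->3' on the top strand; lower-case =
# free designed positions) binds the template with <= max_mm other mismatches
primer_sites <- function(tch, primer, max_mm = 0L) {
  pch <- chars(primer)
  fixed <- which(pch %in% c("A", "C", "G", "T"))
  l <- length(pch)
  n <- length(tch) - l + 1L
  if (n < 1L) return(integer())
  mism <- integer(n)
  starts <- seq_len(n)
  for (i in fixed)
    mism <- mism + (tch[starts + i - 1L] != pch[i])
  starts[mism <= max_mm]
}

#' Call the genotype of one accession at one marker
#'
#' Runs [virtual_pcr()], digests the amplicon when the marker carries an
#' enzyme (using the marker's band model), merges co-migrating fragments,
#' and compares the lane with the marker's expected elite and other band
#' patterns.
#'
#' @param template accession region sequence.
#' @param m a `marker_spec`.
#' @param max_unintended_mismatches passed to [virtual_pcr()].
#' @return one of `"elite"`, `"other"`, `"unknown"`, `"no_amplification"`.
#' @export
genotype_accession <- function(template, m, max_unintended_mismatches = 0L) {
  amp <- virtual_pcr(template, m, max_unintended_mismatches)
  if (is.null(amp)) return("no_amplification")
  bands <- marker_bands(m, amp)
  gel <- gel_class(max(bands, m$elite_bands, m$other_bands))
  lane <- merge_bands(bands, gel)
  if (patterns_match(lane, merge_bands(m$elite_bands, gel), gel)) return("elite")
  if (patterns_match(lane, merge_bands(m$other_bands, gel), gel)) return("other")
  "unknown"
}

#' Genotype a panel of accessions at a set of markers
#'
#' @param templates named character vector of accession region sequences.
#' @param markers list of `marker_spec`s.
#' @param max_unintended_mismatches passed to [virtual_pcr()].
#' @return character matrix of calls, accessions x markers.
#' @export
genotype_panel <- function(templates, markers,
                           max_unintended_mismatches = 0L) {
  mn <- vapply(markers, function(m) m$name, character(1))
  out <- matrix(NA_character_, nrow = length(templates), ncol = length(markers),
                dimnames = list(names(templates), mn))
  for (i in seq_along(templates))
    for (j in seq_along(markers))
      out[i, j] <- genotype_accession(templates[[i]], markers[[j]],
                                      max_unintended_mismatches)
  out
}
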