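# Diagnostic marker design.
#
# Priority rules: an indel of 7-30 bp becomes an Indel marker with a
# 100-300 bp amplicon; an indel > 100 bp an Indel marker with a 400-1000 bp
# amplicon.  SNPs become CAPS markers (300-800 bp amplicon) when one allele
# completes a restriction site naturally, otherwise dCAPS markers
# (100-300 bp amplicon) where up to `k` deliberate primer mismatches create
# a site in exactly one allele's amplicon.
#
# Band model: fragment sizes always sum to the allele's amplicon length.
# For dCAPS markers the engineered site straddles the primer/template
# junction; following the usual genotyping convention the diagnostic small
# fragment is reported as exactly the primer length (cut positions falling
# inside a primer footprint are snapped to the junction), identically at
# design time and during in-silico digestion.

new_marker_spec <- function(name, gene_id, mtype, variant, forward, reverse,
                            enzyme, elite_bands, other_bands,
                            elite_allele, detected = character(),
                            amplicon_len = NULL) {
  stopifnot(mtype %in% c("Indel", "CAPS", "dCAPS"))
  if (mtype == "Indel" && !is.null(enzyme)) stop("Indel markers carry no enzyme")
  if (mtype != "Indel" && is.null(enzyme)) stop(mtype, " markers need an enzyme")
  eb <- sort(as.integer(elite_bands)); ob <- sort(as.integer(other_bands))
  if (identical(eb, ob)) stop("marker does not discriminate: identical band sets")
  structure(list(name = name, gene_id = gene_id, mtype = mtype,
                 variant = variant, forward = forward, reverse = reverse,
                 enzyme = enzyme, elite_bands = eb, other_bands = ob,
                 elite_allele = elite_allele, detected = detected,
                 amplicon_len = amplicon_len),
            class = "marker_spec")
}

#' @export
print.marker_spec <- function(x, ...) {
  bands <- function(b) if (length(b) == 1L) as.character(b)
    else paste0("(", paste(b, collapse = ", "), ")")
  cat(sprintf("<marker %s> %s  %s\n  F %s\n  R %s\n  %s%s/%s\n",
              x$mtype, x$name, x$variant$variant_id %||% "",
              x$forward$seq, x$reverse$seq,
              if (!is.null(x$enzyme)) paste0(x$enzyme$name, "  ") else "",
              bands(x$elite_bands), bands(x$other_bands)))
  invisible(x)
}

# fragment sizes of one amplicon under a marker's enzyme and band model
marker_bands <- function(m, amplicon) {
  L <- nchar(amplicon)
  if (is.null(m$enzyme)) return(L)
  cuts <- cut_sites(amplicon, m$enzyme)
  if (m$mtype == "dCAPS") {
    lf <- nchar(m$forward$seq); lr <- nchar(m$reverse$seq)
    cuts <- ifelse(cuts < lf, lf, cuts)
    cuts <- ifelse(cuts > L - lr, L - lr, cuts)
    cuts <- cuts[cuts >= 1L & cuts < L]
    cuts <- unique(cuts)
  }
  if (length(cuts) == 0L) return(L)
  predict_digestion(L, cuts)
}

# amplicon sequence for one allele of the marker's target variant, given
# the reference region and the primer footprints (region coordinates);
# primer-encoded bases (designed mismatches) overwrite the template.
allele_amplicon <- function(ref_region, m_or_parts, allele) {
  fwd <- m_or_parts$forward; rev <- m_or_parts$reverse
  v <- m_or_parts$variant
  amp <- substr(ref_region, fwd$template_start, rev$template_end)
  off <- fwd$template_start - 1L
  if (allele == "alt") {
    stopifnot(v$vclass == "SNP")   # indel amplicons are built by the caller
    p <- v$region_pos - off
    stopifnot(substr(amp, p, p) == v$ref)
    substr(amp, p, p) <- v$alt
  }
  fseq <- toupper(fwd$seq)
  substr(amp, 1L, nchar(fseq)) <- fseq
  rfoot <- toupper(revcomp(rev$seq))
  substr(amp, nchar(amp) - nchar(rfoot) + 1L, nchar(amp)) <- rfoot
  amp
}

#' Find restriction enzymes that discriminate a SNP's alleles (CAPS)
#'
#' Tests every enzyme for a recognition site that overlaps the SNP and is
#' completed by exactly one allele; enzymes matching both alleles are
#' excluded.
#'
#' @param context nucleotide string centred on the SNP.
#' @param snp_index 1-based position of the SNP within `context`.
#' @param ref_base,alt_base the two alleles.
#' @param enzymes enzyme table (see [default_enzymes()]).
#' @return data.frame with columns `name` and `cut_allele` ("ref"/"alt").
#' @export
find_caps <- function(context, snp_index, ref_base, alt_base,
                      enzymes = default_enzymes()) {
  context <- toupper(as.character(context))
  stopifnot(substr(context, snp_index, snp_index) == toupper(ref_base))
  ctx_alt <- context
  substr(ctx_alt, snp_index, snp_index) <- toupper(alt_base)
  res <- list()
  for (i in seq_len(nrow(enzymes))) {
    e <- enzymes[i, ]
    L <- nchar(e$motif)
    overlap <- function(ctx) {
      s <- scan_restriction_sites(ctx, e)
      any(s$pos <= snp_index & s$pos + L - 1L >= snp_index)
    }
    r <- overlap(context); a <- overlap(ctx_alt)
    if (xor(r, a))
      res[[length(res) + 1L]] <- data.frame(
        name = e$name, cut_allele = if (r) "ref" else "alt",
        stringsAsFactors = FALSE)
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(name = character(), cut_allele = character(),
                  stringsAsFactors = FALSE)
}

#' Design a CAPS marker for a SNP
#'
#' Chooses the first enzyme (in table order) whose site overlaps the SNP in
#' exactly one allele, places primers for a 300-800 bp amplicon around it,
#' digests both alleles in silico and keeps the design only if the allele
#' band multisets differ and are gel-resolvable (constitutive sites of the
#' enzyme inside the amplicon are tolerated as long as they do not destroy
#' discrimination).
#'
#' @param ref_region reference region sequence.
#' @param variant one-row variant table entry (a SNP).
#' @param enzymes enzyme table.
#' @param elite_allele `"ref"` or `"alt"`: which allele elite material
#'   carries.
#' @param product_range allowed amplicon lengths, default `c(300, 800)`.
#' @param name marker name.
#' @param avoid template positions of other known variants; primers will
#'   not bind across them.
#' @return a `marker_spec`, or `NULL` when no enzyme yields a valid design.
#' @export
design_caps <- function(ref_region, variant, enzymes = default_enzymes(),
                        elite_allele = "alt", product_range = c(300L, 800L),
                        name = NULL, avoid = integer()) {
  stopifnot(variant$vclass == "SNP")
  p <- variant$region_pos
  win <- 500L
  lo <- max(1L, p - win); hi <- min(nchar(ref_region), p + win)
  hits <- find_caps(substr(ref_region, lo, hi), p - lo + 1L,
                    variant$ref, variant$alt, enzymes)
  for (i in seq_len(nrow(hits))) {
    e <- enzymes[enzymes$name == hits$name[i], ]
    pr <- tryCatch(
      design_primer_pair(ref_region, must_span = c(p - 20L, p + 20L),
                         product_range = product_range, avoid = avoid),
      error = function(err) NULL)
    if (is.null(pr)) next
    parts <- list(forward = pr$forward, reverse = pr$reverse, variant = variant)
    m0 <- list(enzyme = e, mtype = "CAPS", forward = pr$forward,
               reverse = pr$reverse)
    amp_ref <- allele_amplicon(ref_region, parts, "ref")
    amp_alt <- allele_amplicon(ref_region, parts, "alt")
    b_ref <- marker_bands(m0, amp_ref)
    b_alt <- marker_bands(m0, amp_alt)
    if (!pattern_distinct(b_ref, b_alt)) next
    eb <- if (elite_allele == "ref") b_ref else b_alt
    ob <- if (elite_allele == "ref") b_alt else b_ref
    return(new_marker_spec(
      name %||% paste0(variant$variant_id, "_CAPS"),
      gene_id = attr(ref_region, "gene_id") %||% NA_character_,
      mtype = "CAPS", variant = variant,
      forward = pr$forward, reverse = pr$reverse, enzyme = e,
      elite_bands = eb, other_bands = ob, elite_allele = elite_allele,
      amplicon_len = pr$product_len))
  }
  NULL
}

#' Design a dCAPS marker for a SNP
#'
#' For each enzyme and each placement of its motif over the SNP, searches
#' for at most `k` deliberate template mismatches, confined to the
#' primer-covered side of the motif window and never at the primer
#' 3'-terminal base, such that the modified amplicon of exactly one allele
#' contains the recognition site.  The mismatch-bearing primer abuts the
#' SNP (the SNP sits outside the primer, inside the motif window).
#' Candidates are ranked by fewest mismatches, then most central cut, then
#' smallest amplicon.
#'
#' @inheritParams design_caps
#' @param k maximum number of designed mismatches (default 1).
#' @param product_range allowed amplicon lengths, default `c(100, 300)`.
#' @return a `marker_spec`, or `NULL`; with `diagnostics = TRUE` a list
#'   whose `diagnostics` element reports, per enzyme, why no placement
#'   worked.
#' @param diagnostics return per-enzyme failure notes alongside the result.
#' @export
design_dcaps <- function(ref_region, variant, enzymes = default_enzymes(),
                         elite_allele = "alt", k = 1L,
                         product_range = c(100L, 300L), name = NULL,
                         diagnostics = FALSE, avoid = integer()) {
  stopifnot(variant$vclass == "SNP")
  p <- variant$region_pos
  refseq <- toupper(as.character(ref_region))
  n <- nchar(refseq)
  base_of <- list(ref = toupper(variant$ref), alt = toupper(variant$alt))
  candidates <- list()
  notes <- character(nrow(enzymes)); names(notes) <- enzymes$name
  for (ei in seq_len(nrow(enzymes))) {
    e <- enzymes[ei, ]
    motif <- chars(toupper(e$motif))
    L <- length(motif)
    found_any <- FALSE
    for (o in seq_len(L)) {           # SNP sits at motif position o
      w_start <- p - o + 1L
      w_end <- w_start + L - 1L
      if (w_start < 2L || w_end > n - 1L) next
      ref_in <- iupac_match(base_of$ref, motif[o])
      alt_in <- iupac_match(base_of$alt, motif[o])
      if (ref_in == alt_in) next      # not discriminating at this offset
      cut_allele <- if (ref_in) "ref" else "alt"
      left <- if (w_start <= p - 1L) seq(w_start, p - 1L) else integer()
      right <- if (p + 1L <= w_end) seq(p + 1L, w_end) else integer()
      for (orient in c("F", "R")) {
        side <- if (orient == "F") left else right
        far  <- if (orient == "F") right else left
        # the far side of the window is outside the primer: template must
        # already match the motif there
        far_ok <- all(vapply(seq_along(far), function(j) {
          mo <- motif[far[j] - w_start + 1L]
          iupac_match(substr(refseq, far[j], far[j]), mo)
        }, logical(1)))
        if (!far_ok) next
        mm <- integer()
        for (q in side) {
          mo <- motif[q - w_start + 1L]
          if (!iupac_match(substr(refseq, q, q), mo)) mm <- c(mm, q)
        }
        if (length(mm) < 1L || length(mm) > k) next
        # no designed mismatch at the primer 3'-terminal base
        term <- if (orient == "F") p - 1L else p + 1L
        if (term %in% mm) next
        cand <- dcaps_candidate(refseq, variant, e, motif, w_start, o, orient,
                                mm, cut_allele, elite_allele, product_range,
                                avoid)
        if (!is.null(cand)) {
          candidates[[length(candidates) + 1L]] <- cand
          found_any <- TRUE
        }
      }
    }
    notes[ei] <- if (found_any) "ok" else "no admissible placement"
  }
  if (!length(candidates)) {
    if (diagnostics) return(list(marker = NULL, diagnostics = notes))
    return(NULL)
  }
  rank <- vapply(candidates, function(cc)
    c(cc$n_mismatch, cc$centrality, cc$amplicon_len), numeric(3))
  best <- order(rank[1L, ], rank[2L, ], rank[3L, ])[1L]
  m <- candidates[[best]]$marker
  if (!is.null(name)) m$name <- name
  if (diagnostics) list(marker = m, diagnostics = notes) else m
}

# build and validate one dCAPS candidate; NULL if primers cannot be placed
# or the engineered site is not diagnostic after modification
dcaps_candidate <- function(refseq, variant, e, motif, w_start, o, orient,
                            mm, cut_allele, elite_allele, product_range,
                            avoid = integer()) {
  p <- variant$region_pos
  n <- nchar(refseq)
  # the fixed, mismatch-bearing primer abutting the SNP
  if (orient == "F") {
    fe <- p - 1L
    need_len <- fe - min(mm) + 1L
    l <- max(PRIMER_LEN_MIN, need_len)
    if (l > PRIMER_LEN_MAX) return(NULL)
    fs <- fe - l + 1L
    if (fs < 1L) return(NULL)
    raw <- substr(refseq, fs, fe)
    seq_ch <- chars(raw)
    for (q in mm) seq_ch[q - fs + 1L] <- tolower(dcaps_repl(motif, q - w_start + 1L))
    pseq <- paste(seq_ch, collapse = "")
    if (!is.na(primer_violation(pseq))) {
      # try longer primers for Tm/GC rescue
      ok <- FALSE
      while (l < PRIMER_LEN_MAX) {
        l <- l + 1L; fs <- fe - l + 1L
        if (fs < 1L) break
        raw <- substr(refseq, fs, fe)
        seq_ch <- chars(raw)
        for (q in mm) seq_ch[q - fs + 1L] <- tolower(dcaps_repl(motif, q - w_start + 1L))
        pseq <- paste(seq_ch, collapse = "")
        if (is.na(primer_violation(pseq))) { ok <- TRUE; break }
      }
      if (!ok) return(NULL)
    }
    if (length(avoid) && any(avoid >= fs & avoid <= fe)) return(NULL)
    fixed <- new_primer(pseq, fs, fe, "F",
                        mismatch_positions = sort(mm) - fs + 1L)
    pr <- tryCatch(design_primer_pair(refseq, must_span = c(p, p),
                                      product_range = product_range,
                                      fixed_forward = fixed, avoid = avoid),
                   error = function(err) NULL)
  } else {
    rs <- p + 1L
    need_len <- max(mm) - rs + 1L
    l <- max(PRIMER_LEN_MIN, need_len)
    if (l > PRIMER_LEN_MAX) return(NULL)
    re <- rs + l - 1L
    if (re > n) return(NULL)
    build_r <- function(rs, re) {
      raw <- substr(refseq, rs, re)
      seq_ch <- chars(raw)
      for (q in mm) seq_ch[q - rs + 1L] <- tolower(dcaps_repl(motif, q - w_start + 1L))
      revcomp(paste(seq_ch, collapse = ""))
    }
    pseq <- build_r(rs, re)
    while (!is.na(primer_violation(pseq)) && re < n && (re - rs + 1L) < PRIMER_LEN_MAX) {
      re <- re + 1L
      pseq <- build_r(rs, re)
    }
    if (!is.na(primer_violation(pseq))) return(NULL)
    if (length(avoid) && any(avoid >= rs & avoid <= re)) return(NULL)
    mmo <- sort(mm)
    fixed <- new_primer(pseq, rs, re, "R",
                        mismatch_positions = (re - mmo + 1L))
    pr <- tryCatch(design_primer_pair(refseq, must_span = c(p, p),
                                      product_range = product_range,
                                      fixed_reverse = fixed, avoid = avoid),
                   error = function(err) NULL)
  }
  if (is.null(pr)) return(NULL)
  parts <- list(forward = pr$forward, reverse = pr$reverse, variant = variant)
  m0 <- list(enzyme = e, mtype = "dCAPS", forward = pr$forward,
             reverse = pr$reverse)
  amp_ref <- allele_amplicon(refseq, parts, "ref")
  amp_alt <- allele_amplicon(refseq, parts, "alt")
  # soundness: the engineered site must appear in exactly one allele
  site_over_snp <- function(amp) {
    s <- scan_restriction_sites(amp, e)
    snp_in_amp <- p - pr$forward$template_start + 1L
    any(s$pos <= snp_in_amp & s$pos + nchar(e$motif) - 1L >= snp_in_amp)
  }
  has_ref <- site_over_snp(amp_ref); has_alt <- site_over_snp(amp_alt)
  if (!xor(has_ref, has_alt)) return(NULL)
  if ((cut_allele == "ref") != has_ref) return(NULL)
  b_ref <- marker_bands(m0, amp_ref)
  b_alt <- marker_bands(m0, amp_alt)
  if (!pattern_distinct(b_ref, b_alt)) return(NULL)
  eb <- if (elite_allele == "ref") b_ref else b_alt
  ob <- if (elite_allele == "ref") b_alt else b_ref
  marker <- new_marker_spec(
    paste0(variant$variant_id, "_dCAPS"),
    gene_id = NA_character_, mtype = "dCAPS", variant = variant,
    forward = pr$forward, reverse = pr$reverse, enzyme = e,
    elite_bands = eb, other_bands = ob, elite_allele = elite_allele,
    amplicon_len = pr$product_len)
  cut_amp <- if (cut_allele == "ref") b_ref else b_alt
  centr <- abs(min(cut_amp) - pr$product_len / 2)
  list(marker = marker, n_mismatch = length(mm), centrality = centr,
       amplicon_len = pr$product_len)
}

# replacement base that satisfies motif position j (deterministic)
dcaps_repl <- function(motif, j) iupac_representative(motif[j])

#' Design an Indel marker
#'
#' Primer pair flanking the indel; the amplicon on the longer allele falls
#' in the size class of the indel (7-30 bp indel: 100-300 bp amplicon;
#' > 100 bp indel: 400-1000 bp amplicon); the allele bands differ exactly
#' by the indel length.  Indels of other sizes are rejected unless
#' `force = TRUE`.
#'
#' @inheritParams design_caps
#' @param variant one-row variant table entry (insertion or deletion).
#' @param force override the size-class rule (uses the 100-300 bp window).
#' @return a `marker_spec`.
#' @export
design_indel_marker <- function(ref_region, variant, elite_allele = "alt",
                                force = FALSE, name = NULL,
                                avoid = integer()) {
  stopifnot(variant$vclass %in% c("insertion", "deletion"))
  size <- max(nchar(variant$ref), nchar(variant$alt))
  if (size >= 7L && size <= 30L) {
    rng <- c(100L, 300L)
  } else if (size > 100L) {
    rng <- c(400L, 1000L)
  } else if (force) {
    rng <- c(100L, 300L)
  } else {
    stop("indel of ", size, " bp outside the marker size classes ",
         "(7-30 or >100 bp); use force = TRUE to override")
  }
  refseq <- toupper(as.character(ref_region))
  p <- variant$region_pos
  if (variant$vclass == "deletion") {
    template <- refseq
    span <- c(p, p + size - 1L)
    long_allele <- "ref"
  } else {
    template <- apply_variants(refseq, variant)
    span <- c(p + 1L, p + size)
    long_allele <- "alt"
  }
  pr <- design_primer_pair(template, must_span = span, product_range = rng,
                           avoid = avoid)
  long_band <- pr$product_len
  short_band <- long_band - size
  gel <- gel_class(max(long_band, short_band))
  if (!resolvable(long_band, short_band, gel))
    stop("indel bands ", long_band, "/", short_band,
         " not resolvable on ", gel)
  eb <- if (elite_allele == long_allele) long_band else short_band
  ob <- if (elite_allele == long_allele) short_band else long_band
  m <- new_marker_spec(
    name %||% paste0(variant$variant_id, "_Indel"),
    gene_id = attr(ref_region, "gene_id") %||% NA_character_,
    mtype = "Indel", variant = variant,
    forward = pr$forward, reverse = pr$reverse, enzyme = NULL,
    elite_bands = eb, other_bands = ob, elite_allele = elite_allele,
    amplicon_len = long_band)
  m
}

#' Design a marker for one target variant by the priority rules
#'
#' Indels go to [design_indel_marker()]; SNPs first try [design_caps()]
#' and fall back to [design_dcaps()].
#'
#' @inheritParams design_caps
#' @param mtype `"auto"` or one of `"Indel"`, `"CAPS"`, `"dCAPS"` to force.
#' @return a `marker_spec` or `NULL`.
#' @export
design_marker <- function(ref_region, variant, enzymes = default_enzymes(),
                          elite_allele = "alt", mtype = "auto", name = NULL) {
  if (variant$vclass %in% c("insertion", "deletion")) {
    return(tryCatch(design_indel_marker(ref_region, variant, elite_allele,
                                        name = name),
                    error = function(e) NULL))
  }
  if (mtype %in% c("auto", "CAPS")) {
    m <- design_caps(ref_region, variant, enzymes, elite_allele, name = name)
    if (!is.null(m) || mtype == "CAPS") return(m)
  }
  design_dcaps(ref_region, variant, enzymes, elite_allele, name = name)
}

# distinct as multisets AND resolvable on the relevant gel
pattern_distinct <- function(b1, b2) {
  gel <- gel_class(max(b1, b2))
  m1 <- merge_bands(b1, gel); m2 <- merge_bands(b2, gel)
  !patterns_match(m1, m2, gel)
}
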