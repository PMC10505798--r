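# Two-tier haplotype classification:
#   tier 1 (haplotype groups) keys on protein-altering ("functional")
#   variants: missense, in-frame indels, frameshifts, premature stops,
#   start/stop losses;
#   tier 2 (haplotypes) subdivides each group by the remaining variants
#   (synonymous exonic SNPs and everything in the 5'UTR pad, introns and
#   3'UTR pad).
# The reference accession's group is HapA and its haplotype HapA-1; the
# remaining groups are HapB, HapC, ... by descending member count (ties
# broken by lexicographically smallest member id).  Novel haplotypes (no
# member in the sequenced anchor panel) with fewer than `min_novel_size`
# members are dropped and their accessions left unassigned.

#' Classify accessions into haplotype groups and haplotypes
#'
#' @param variants annotated variant table (needs an `effect` column, see
#'   [annotate_effects()]).
#' @param geno character genotype matrix (variants x accessions) with
#'   entries "0", "1", "het" or `NA`; rownames must match
#'   `variants$variant_id`.
#' @param panel accession metadata data.frame (`accession_id`,
#'   `subpopulation`).
#' @param reference_accession accession id whose type defines HapA/HapA-1.
#' @param sequenced accession ids of the sequenced anchor panel; haplotypes
#'   with no sequenced member are "novel".  Defaults to the reference
#'   accession alone.
#' @param min_novel_size novel haplotypes with fewer members than this are
#'   omitted (default 5).
#' @return an object of class `haplotype_assignment`.
#' @export
classify_haplotypes <- function(variants, geno, panel, reference_accession,
                                sequenced = reference_accession,
                                min_novel_size = 5L) {
  stopifnot(nrow(variants) == nrow(geno))
  if (nrow(variants) > 0L && !is.null(rownames(geno)))
    stopifnot(identical(rownames(geno), variants$variant_id))
  accs <- colnames(geno)
  if (is.null(accs)) {
    accs <- panel$accession_id
    if (nrow(geno) > 0L) stop("genotype matrix must have accession colnames")
    geno <- matrix(character(), 0L, length(accs),
                   dimnames = list(NULL, accs))
  }
  if (!reference_accession %in% accs)
    stop("reference accession ", reference_accession, " not in genotype matrix")
  if ("effect" %in% names(variants)) {
    functional <- variants$effect %in% FUNCTIONAL_EFFECTS
  } else if (nrow(variants) == 0L) {
    functional <- logical(0)
  } else stop("variant table lacks an effect column; run annotate_effects()")

  called <- apply(geno, 2L, function(col) all(col %in% c("0", "1")))
  if (nrow(geno) == 0L) called <- rep(TRUE, length(accs))
  names(called) <- accs
  if (!called[[reference_accession]])
    stop("reference accession has a missing or heterozygous call at a classifying variant")

  # keys get a "k" prefix so the all-reference (empty) key is a valid name
  key_of <- function(rows, acc) {
    if (!any(rows)) return("k")
    paste0("k", paste(geno[rows, acc], collapse = ""))
  }
  assigned <- accs[called]
  gkey <- vapply(assigned, function(a) key_of(functional, a), character(1))
  hkey <- vapply(assigned, function(a) key_of(rep(TRUE, nrow(geno)), a),
                 character(1))

  # ---- novel-haplotype filter ------------------------------------------
  hap_split <- split(assigned, hkey)
  drop <- character()
  for (k in names(hap_split)) {
    members <- hap_split[[k]]
    if (!any(members %in% sequenced) && length(members) < min_novel_size)
      drop <- c(drop, members)
  }
  assigned2 <- setdiff(assigned, drop)
  gkey <- gkey[assigned2]; hkey <- hkey[assigned2]

  # ---- group naming ----------------------------------------------------
  ref_gkey <- vapply(reference_accession, function(a) key_of(functional, a),
                     character(1))
  gsplit <- split(assigned2, gkey[assigned2])
  gnames <- names(gsplit)
  sizes <- vapply(gsplit, length, integer(1))
  minid <- vapply(gsplit, function(m) min(m), character(1))
  is_ref <- gnames == ref_gkey
  ord <- order(!is_ref, -sizes, minid)
  gnames <- gnames[ord]
  group_label <- hap_letters(length(gnames))
  names(group_label) <- gnames

  groups <- data.frame(group = unname(group_label[gnames]),
                       key = unname(gnames),
                       n = unname(sizes[match(gnames, names(sizes))]),
                       novel = unname(vapply(gsplit[gnames], function(m)
                         !any(m %in% sequenced), logical(1))),
                       elite = NA, stringsAsFactors = FALSE,
                       row.names = NULL)
  rownames(groups) <- NULL

  # ---- haplotype naming within groups ----------------------------------
  ref_hkey <- vapply(reference_accession,
                     function(a) key_of(rep(TRUE, nrow(geno)), a), character(1))
  hap_rows <- list()
  for (gi in seq_len(nrow(groups))) {
    gk <- groups$key[gi]
    members <- gsplit[[gk]]
    hs <- split(members, hkey[members])
    hk <- names(hs)
    hsize <- vapply(hs, length, integer(1))
    hmin <- vapply(hs, function(m) min(m), character(1))
    h_is_ref <- hk == ref_hkey & gk == ref_gkey
    hord <- order(!h_is_ref, -hsize, hmin)
    hk <- hk[hord]
    for (j in seq_along(hk)) {
      m <- hs[[hk[j]]]
      hap_rows[[length(hap_rows) + 1L]] <- data.frame(
        haplotype = paste0(groups$group[gi], "-", j),
        group = groups$group[gi], key = hk[j],
        n = length(m), novel = !any(m %in% sequenced), elite = NA,
        stringsAsFactors = FALSE)
    }
  }
  haplotypes <- do.call(rbind, hap_rows) %||%
    data.frame(haplotype = character(), group = character(), key = character(),
               n = integer(), novel = logical(), elite = logical())

  # ---- per-accession assignment ---------------------------------------
  assignment <- data.frame(accession_id = accs,
                           group = NA_character_, haplotype = NA_character_,
                           status = "unassigned", stringsAsFactors = FALSE)
  status <- ifelse(called, "assigned", "uncalled")
  status[accs %in% drop] <- "rare_novel"
  assignment$status <- unname(status)
  idx <- match(assigned2, accs)
  assignment$group[idx] <- unname(group_label[gkey[assigned2]])
  hl <- paste(gkey[assigned2], hkey[assigned2], sep = "\r")
  hmap <- paste(groups$key[match(haplotypes$group, groups$group)],
                haplotypes$key, sep = "\r")
  assignment$haplotype[idx] <- haplotypes$haplotype[match(hl, hmap)]
  assignment$status[idx] <- "assigned"

  structure(list(assignment = assignment, groups = groups,
                 haplotypes = haplotypes, variants = variants, geno = geno,
                 functional = variants$variant_id[functional],
                 reference_accession = reference_accession,
                 sequenced = sequenced, min_novel_size = min_novel_size),
            class = "haplotype_assignment")
}

# HapA, HapB, ..., HapZ, HapAA, ...
hap_letters <- function(n) {
  base <- LETTERS
  if (n > 26L)
    base <- c(LETTERS, as.vector(outer(LETTERS, LETTERS,
                                       function(a, b) paste0(a, b))))
  paste0("Hap", base[seq_len(n)])
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf("<haplotype_assignment> %d accessions: %d assigned, %d uncalled, %d rare-novel dropped\n",
              nrow(x$assignment), sum(x$assignment$status == "assigned"),
              sum(x$assignment$status == "uncalled"),
              sum(x$assignment$status == "rare_novel")))
  cat(sprintf("%d haplotype group(s), %d haplotype(s); %d functional variant(s) of %d total\n",
              nrow(x$groups), nrow(x$haplotypes), length(x$functional),
              nrow(x$variants)))
  invisible(x)
}

#' @export
summary.haplotype_assignment <- function(object, ...) {
  g <- object$groups[c("group", "n", "novel", "elite")]
  h <- object$haplotypes[c("haplotype", "group", "n", "novel", "elite")]
  out <- list(groups = g, haplotypes = h)
  class(out) <- "summary.haplotype_assignment"
  out
}

#' @export
print.summary.haplotype_assignment <- function(x, ...) {
  cat("Haplotype groups:\n"); print(x$groups, row.names = FALSE)
  cat("\nHaplotypes:\n"); print(x$haplotypes, row.names = FALSE)
  invisible(x)
}

# members of a named group or haplotype
members_of <- function(x, name) {
  a <- x$assignment
  if (name %in% x$groups$group) return(a$accession_id[!is.na(a$group) & a$group == name])
  if (name %in% x$haplotypes$haplotype)
    return(a$accession_id[!is.na(a$haplotype) & a$haplotype == name])
  stop("unknown group/haplotype name: ", name)
}

#' Flag elite haplotypes and haplotype groups
#'
#' A haplotype is flagged elite when its genotype carries *all* required
#' alleles of the definition; a group is elite when every haplotype in it
#' is elite.  Zero, one or several groups may end up flagged.
#'
#' @param x a `haplotype_assignment`.
#' @param def an [elite_definition()].
#' @return `x` with `elite` columns filled in `groups` and `haplotypes`.
#' @export
mark_elite <- function(x, def) {
  stopifnot(inherits(x, "haplotype_assignment"), inherits(def, "elite_definition"))
  v <- x$variants
  req_row <- integer(length(def$positions))
  req_val <- character(length(def$positions))
  for (i in seq_along(def$positions)) {
    pos <- def$positions[i]; al <- def$alleles[i]
    # "ALT"/"REF" sentinels require the non-reference/reference allele at
    # the position without naming the base
    hit <- if (al %in% c("ALT", "REF")) which(v$atg_pos == pos)
           else which(v$atg_pos == pos & (v$alt == al | v$ref == al))
    if (!length(hit))
      stop("elite-defining position ", sprintf("%+d", pos), " (allele ", al,
           ") absent from the variant table")
    hit <- hit[1L]
    req_row[i] <- hit
    req_val[i] <- if (al == "REF") "0"
                  else if (al == "ALT" || v$alt[hit] == al) "1" else "0"
  }
  hap_elite <- logical(nrow(x$haplotypes))
  for (j in seq_len(nrow(x$haplotypes))) {
    m <- members_of(x, x$haplotypes$haplotype[j])[1L]
    hap_elite[j] <- all(x$geno[req_row, m] == req_val)
  }
  x$haplotypes$elite <- hap_elite
  x$groups$elite <- vapply(x$groups$group, function(g) {
    hs <- x$haplotypes$elite[x$haplotypes$group == g]
    length(hs) > 0L && all(hs)
  }, logical(1))
  if (!any(hap_elite))
    warning("no haplotype carries all elite-defining alleles for ",
            def$gene_id)
  x$elite_definition <- def
  x
}

#' Find variants unique to target haplotypes or groups
#'
#' Returns variants whose non-reference allele is carried by every member
#' of every target and by no accession outside the targets (accessions in
#' `exclude` are waived, reproducing the omission of rare types; uncalled
#' entries outside the targets are ignored).
#'
#' @param x a `haplotype_assignment`.
#' @param targets character vector of group and/or haplotype names.
#' @param exclude names (groups/haplotypes) or accession ids to waive.
#' @return the matching rows of the variant table, with a `carriers` count
#'   column appended.
#' @export
find_unique_variants <- function(x, targets, exclude = character()) {
  stopifnot(length(targets) > 0L)
  if (length(intersect(targets, exclude)))
    stop("targets and exclude overlap")
  t_acc <- unique(unlist(lapply(targets, members_of, x = x)))
  e_acc <- unique(unlist(lapply(exclude, function(nm) {
    if (nm %in% c(x$groups$group, x$haplotypes$haplotype)) members_of(x, nm)
    else nm
  })))
  others <- setdiff(colnames(x$geno), union(t_acc, e_acc))
  keep <- logical(nrow(x$variants))
  for (i in seq_len(nrow(x$variants))) {
    gt <- x$geno[i, t_acc]
    go <- x$geno[i, others]
    keep[i] <- all(gt == "1") &&
      !any(go %in% c("1", "het"))
  }
  out <- x$variants[keep, , drop = FALSE]
  out$carriers <- vapply(which(keep), function(i)
    sum(x$geno[i, ] == "1", na.rm = TRUE), integer(1))
  rownames(out) <- NULL
  out
}

#' Haplotype-by-subpopulation contingency table
#'
#' @param x a `haplotype_assignment`.
#' @param panel accession metadata data.frame.
#' @param level `"haplotype"` (default) or `"group"`.
#' @return integer matrix, rows = haplotypes (or groups), columns =
#'   subpopulations; row sums equal member counts.
#' @export
subpop_distribution <- function(x, panel, level = c("haplotype", "group")) {
  level <- match.arg(level)
  a <- x$assignment[x$assignment$status == "assigned", ]
  if (nrow(a) == 0L) return(matrix(integer(), 0L, 0L))
  sp <- panel$subpopulation[match(a$accession_id, panel$accession_id)]
  if (anyNA(sp)) stop("panel metadata missing for assigned accessions")
  lab <- if (level == "haplotype") a$haplotype else a$group
  rows <- if (level == "haplotype") x$haplotypes$haplotype else x$groups$group
  tab <- table(factor(lab, levels = rows), sp)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Write a haplotype assignment to TSV files
#'
#' @param x a `haplotype_assignment`.
#' @param prefix path prefix; writes `<prefix>_assignment.tsv` and
#'   `<prefix>_groups.tsv`.
#' @export
write_assignment <- function(x, prefix) {
  utils::write.table(x$assignment, paste0(prefix, "_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$groups[c("group", "n", "novel", "elite")],
                     paste0(prefix, "_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
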