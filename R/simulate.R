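# Synthetic panel generator with planted haplotype structure.
#
# The generator emulates a multi-subpopulation germplasm panel for one
# gene: a reference accession (HapA/HapA-1), haplotype groups separated by
# planted functional variants, haplotypes separated by silent variants, an
# elite group carrying private variants, and rare novel haplotypes below
# the classifier's five-accession filter.  Ground truth (planted variants,
# per-accession labels, expected unique-variant set) is emitted alongside
# the data so every pipeline stage can be checked against it.
#
# Subpopulation structure is label-only: each haplotype gets a "home"
# subpopulation and members are drawn mostly from it, inducing the skewed
# haplotype-by-subpopulation tallies seen in real panels without modelling
# linkage.

# ---- gene scaffold ------------------------------------------------------

# random gene on a plus-strand chromosome that coincides with the analysis
# region (ATG at position upstream_len + 1)
gene_scaffold <- function(n_exons, cds_codons, intron_len, upstream_len,
                          downstream_len, gene_id = "gene1",
                          chrom = "chr1") {
  stop_codons <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste, collapse = "")
  sense <- setdiff(all_codons, stop_codons)
  body_codons <- sample(sense, cds_codons - 2L, replace = TRUE)
  cds <- paste0("ATG", paste(body_codons, collapse = ""), "TAA")
  cds_len <- nchar(cds)
  # split CDS into n_exons chunks of >= 9 bp
  if (n_exons > 1L) {
    cuts <- sort(sample(seq(9L, cds_len - 9L, by = 3L), n_exons - 1L))
    starts <- c(1L, cuts + 1L); ends <- c(cuts, cds_len)
  } else {
    starts <- 1L; ends <- cds_len
  }
  exon_seqs <- substring(cds, starts, ends)
  introns <- replicate(max(0L, n_exons - 1L),
                       paste0("GT", random_dna(intron_len - 4L), "AG"))
  body <- exon_seqs[1L]
  for (k in seq_len(n_exons - 1L))
    body <- paste0(body, introns[k], exon_seqs[k + 1L])
  region <- paste0(random_dna(upstream_len), body, random_dna(downstream_len))
  # genomic coordinates: region index == genomic position
  ex <- matrix(0L, n_exons, 2L, dimnames = list(NULL, c("start", "end")))
  pos <- upstream_len + 1L
  for (k in seq_len(n_exons)) {
    ex[k, ] <- c(pos, pos + nchar(exon_seqs[k]) - 1L)
    pos <- ex[k, 2L] + 1L + if (k < n_exons) intron_len else 0L
  }
  model <- gene_model(gene_id, chrom, "+",
                      atg_genomic_pos = upstream_len + 1L,
                      stop_end_genomic_pos = upstream_len + nchar(body),
                      exons = ex, upstream_len = upstream_len,
                      downstream_len = downstream_len)
  list(model = model, region = region, variants = new_variant_table(),
       used = logical(nchar(region)))
}

# candidate positions of a named region, away from edges and splice sites
region_candidates <- function(s, region) {
  g <- s$model
  up <- g$upstream_len
  rl <- region_length(g)
  ex <- exons_region(g)
  if (region == "upstream") return(seq(31L, up - 30L))
  if (region == "downstream") return(seq(up + body_length(g) + 31L, rl - 30L))
  if (grepl("^exon", region)) {
    k <- as.integer(sub("exon", "", region))
    lo <- max(ex[k, "start"], ex[1L, "start"] + 3L)   # spare the start codon
    hi <- min(ex[k, "end"], ex[nrow(ex), "end"] - 3L) # spare the stop codon
    return(seq(lo, hi))
  }
  if (grepl("^intron", region)) {
    k <- as.integer(sub("intron", "", region))
    return(seq(ex[k, "end"] + 4L, ex[k + 1L, "start"] - 4L))
  }
  stop("unknown region: ", region)
}

mark_used <- function(s, lo, hi, pad = 8L) {
  lo <- max(1L, lo - pad); hi <- min(length(s$used), hi + pad)
  s$used[lo:hi] <- TRUE
  s
}

add_planted <- function(s, id, pos, ref, alt, vclass) {
  s$variants <- rbind(s$variants, data.frame(
    variant_id = id, atg_pos = region_to_atg(pos, s$model),
    region_pos = pos, genomic_pos = atg_to_genomic(region_to_atg(pos, s$model),
                                                   s$model),
    ref = ref, alt = alt, vclass = vclass, stringsAsFactors = FALSE))
  s
}

# plant a SNP with a desired coding effect at a random admissible position
plant_random_snp <- function(s, id, region, effect = NULL) {
  cands <- region_candidates(s, region)
  cands <- cands[!s$used[cands]]
  cands <- sample(cands)
  ex <- exons_region(s$model)
  cds <- extract_cds(s$region, ex)
  n_codons <- nchar(cds) %/% 3L
  for (p in cands) {
    ref_base <- substr(s$region, p, p)
    for (alt in sample(setdiff(c("A", "C", "G", "T"), ref_base))) {
      eff <- snp_effect(p, ref_base, alt, ex, cds, n_codons)
      if (is.null(effect) || eff == effect) {
        s <- add_planted(s, id, p, ref_base, alt, "SNP")
        return(mark_used(s, p, p))
      }
    }
  }
  stop("could not plant SNP ", id, " with effect ", effect %||% "any",
       " in ", region)
}

# plant a SNP inside an engineered restriction context.  `window` is the
# reference context written into the region (SNP ref base included at
# `snp_in_window`); competing motif matches of `enzyme` within +-350 bp are
# scrubbed so designability is structural.  For exonic windows, `frame`
# fixes the CDS phase (0..2) of the window start.
plant_context_snp <- function(s, id, region, window, snp_in_window, alt,
                              enzyme, frame = NULL) {
  L <- nchar(window)
  cands <- region_candidates(s, region)
  ex <- exons_region(s$model)
  ok_start <- function(w0) {
    w1 <- w0 + L - 1L
    if (any(s$used[w0:w1])) return(FALSE)
    if (!all((w0:w1) %in% cands)) return(FALSE)
    if (!is.null(frame)) {
      ci <- cds_index(w0, ex)
      if (is.na(ci) || (ci - 1L) %% 3L != frame) return(FALSE)
    }
    # primer-friendly flanks: moderate GC so an admissible 18-20-mer exists
    left <- substr(s$region, max(1L, w0 - 24L), w0 - 1L)
    right <- substr(s$region, w1 + 1L, min(nchar(s$region), w1 + 24L))
    if (nchar(left) >= 18L && (gc_fraction(left) < 0.3 || gc_fraction(left) > 0.6))
      return(FALSE)
    if (nchar(right) >= 18L && (gc_fraction(right) < 0.3 || gc_fraction(right) > 0.6))
      return(FALSE)
    TRUE
  }
  starts <- sample(cands[cands + L - 1L <= max(cands)])
  w0 <- NULL
  for (cand in starts) if (ok_start(cand)) { w0 <- cand; break }
  if (is.null(w0)) stop("no room to plant context for ", id, " in ", region)
  substr(s$region, w0, w0 + L - 1L) <- toupper(window)
  p <- w0 + snp_in_window - 1L
  ref_base <- substr(s$region, p, p)
  s <- scrub_enzyme_sites(s, enzyme, keep = c(w0, w0 + L - 1L),
                          around = p, alt_at = p, alt_base = alt)
  s <- add_planted(s, id, p, ref_base, toupper(alt), "SNP")
  mark_used(s, w0, w0 + L - 1L)
}

# destroy matches of `enzyme` within +-350 bp of `around` that do not
# overlap the kept window, in both the reference and the alt-substituted
# context, by rewriting one unused base per match
scrub_enzyme_sites <- function(s, enzyme, keep, around, alt_at, alt_base) {
  lo <- max(1L, around - 350L); hi <- min(nchar(s$region), around + 350L)
  L <- nchar(enzyme$motif)
  for (pass in 1:10) {
    ctx <- substr(s$region, lo, hi)
    ctx_alt <- ctx
    substr(ctx_alt, alt_at - lo + 1L, alt_at - lo + 1L) <- alt_base
    hits <- rbind(scan_restriction_sites(ctx, enzyme),
                  scan_restriction_sites(ctx_alt, enzyme))
    hits$pos <- hits$pos + lo - 1L
    hits <- hits[!(hits$pos <= keep[2L] & hits$pos + L - 1L >= keep[1L]), ,
                 drop = FALSE]
    if (nrow(hits) == 0L) return(s)
    for (i in seq_len(nrow(hits))) {
      win <- hits$pos[i]:(hits$pos[i] + L - 1L)
      win <- win[!s$used[win] & win != alt_at]
      if (!length(win)) next
      q <- win[1L]
      motif <- chars(toupper(enzyme$motif))
      off <- q - hits$pos[i] + 1L
      mset <- IUPAC_SETS[[if (hits$strand[i] == "+") motif[off]
                          else COMPLEMENT[[motif[L - off + 1L]]]]]
      repl <- setdiff(c("A", "C", "G", "T"), mset)[1L]
      if (!is.na(repl)) substr(s$region, q, q) <- repl
    }
  }
  s
}

# plant an indel (deletion: removes reference bases; insertion: adds bases
# after the position) of the given size
plant_indel <- function(s, id, region, vclass, size) {
  cands <- region_candidates(s, region)
  cands <- sample(cands[cands > 40L])
  for (p in cands) {
    if (vclass == "deletion") {
      span <- p:(p + size - 1L)
      if (max(span) > max(cands) || any(s$used[span])) next
      ref <- substr(s$region, p, p + size - 1L)
      s <- add_planted(s, id, p, ref, "", "deletion")
      return(mark_used(s, p, p + size - 1L))
    } else {
      if (s$used[p]) next
      ins <- random_dna(size)
      # avoid an ambiguous left-shift: first inserted base must differ
      # from the anchor base
      anchor <- substr(s$region, p, p)
      if (substr(ins, 1L, 1L) == anchor)
        ins <- paste0(setdiff(c("A", "C", "G", "T"), anchor)[1L],
                      substr(ins, 2L, size))
      s <- add_planted(s, id, p, "", ins, "insertion")
      return(mark_used(s, p, p))
    }
  }
  stop("no room to plant ", vclass, " ", id, " in ", region)
}

# ---- panel assembly -----------------------------------------------------

#' Configuration for a simulated panel
#'
#' Defaults describe a desk-scale germplasm panel: 120 inbred accessions
#' over the usual rice subpopulations, a three-exon gene with a 2-kb
#' upstream and 1-kb downstream analysis pad, four elite-defining exonic
#' variants, and one rare novel haplotype below the five-accession filter.
#'
#' @param seed integer seed; the whole panel is a deterministic function of
#'   the configuration.
#' @param n_accessions panel size.
#' @param subpop_weights named proportions over subpopulation labels.
#' @param gene_length gene-body length in bp (ATG through stop).
#' @param n_exons number of coding exons.
#' @param n_functional_variants protein-altering variants besides the
#'   elite-defining ones; each seeds one non-elite haplotype group.
#' @param n_silent_variants synonymous/noncoding variants that subdivide
#'   groups into haplotypes.
#' @param elite_spec list with `n_defining` and `regions` (recycled over
#'   `"upstream"`, `"exon"`, `"intron"`, `"downstream"`).
#' @param rare_haplotype_sizes sizes of rare novel haplotypes to inject.
#' @param indel_sizes sizes of elite-private upstream deletions to plant.
#' @param upstream_len,downstream_len analysis pads (bp).
#' @return list of class `panel_config`.
#' @export
panel_config <- function(seed = 1L, n_accessions = 120L,
                         subpop_weights = c(XI = 0.40, "XI-IM" = 0.07,
                                            IM = 0.05, "GJ-IM" = 0.05,
                                            "GJ-tem" = 0.15, "GJ-tro" = 0.08,
                                            "VI/Aro" = 0.05, aus = 0.10,
                                            other = 0.05),
                         gene_length = 1200L, n_exons = 3L,
                         n_functional_variants = 3L, n_silent_variants = 4L,
                         elite_spec = list(n_defining = 4L, regions = "exon"),
                         rare_haplotype_sizes = 3L, indel_sizes = integer(),
                         upstream_len = 2000L, downstream_len = 1000L) {
  w <- subpop_weights / sum(subpop_weights)
  stopifnot(all(names(w) %in% SUBPOPULATIONS))
  structure(list(seed = as.integer(seed), n_accessions = as.integer(n_accessions),
                 subpop_weights = w, gene_length = as.integer(gene_length),
                 n_exons = as.integer(n_exons),
                 n_functional_variants = as.integer(n_functional_variants),
                 n_silent_variants = as.integer(n_silent_variants),
                 elite_spec = elite_spec,
                 rare_haplotype_sizes = as.integer(rare_haplotype_sizes),
                 indel_sizes = as.integer(indel_sizes),
                 upstream_len = as.integer(upstream_len),
                 downstream_len = as.integer(downstream_len)),
            class = "panel_config")
}

#' Simulate a germplasm panel with planted haplotype structure
#'
#' Generates a reference chromosome, gene model, per-accession region
#' sequences, a VCF genotype matrix, accession metadata, and the ground
#' truth.  The same configuration (including seed) always yields
#' byte-identical outputs.  Structures that would confound recovery
#' (a silent variant incidentally private to the elite group, duplicate
#' haplotype signatures) are detected and resampled.
#'
#' @param cfg a [panel_config()].
#' @param out_dir optional directory; when given, writes `reference.fa`,
#'   `gene.gff3`, `panel.fa`, `panel.vcf`, `panel_meta.tsv`.
#' @return list with `model`, `ref_region`, `chrom_seq`, `variants`
#'   (annotated), `geno`, `panel` (metadata), `sequences` (named vector),
#'   `truth` (see below), and `files` when written.  `truth` carries
#'   `labels` (accession, true group/haplotype ids, elite flag, rare-novel
#'   flag), `unique_elite` (variant ids private to the elite group) and
#'   `elite_definition`.
#' @export
simulate_panel <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "panel_config"))
  set.seed(cfg$seed)
  intron_len <- 150L
  n_intr <- max(0L, cfg$n_exons - 1L)
  cds_len <- cfg$gene_length - n_intr * intron_len
  cds_codons <- max(40L, cds_len %/% 3L)
  for (attempt in 1:25) {
    built <- try(build_random_panel(cfg, cds_codons, intron_len), silent = TRUE)
    if (!inherits(built, "try-error")) break
  }
  if (inherits(built, "try-error"))
    stop("infeasible configuration: ", attr(built, "condition")$message)
  if (!is.null(out_dir)) built$files <- write_panel(built, out_dir)
  built
}

build_random_panel <- function(cfg, cds_codons, intron_len) {
  s <- gene_scaffold(cfg$n_exons, cds_codons, intron_len,
                     cfg$upstream_len, cfg$downstream_len)
  exon_names <- paste0("exon", seq_len(cfg$n_exons))
  pick_exon <- function() sample(exon_names, 1L)
  # elite-defining variants
  regions <- rep(cfg$elite_spec$regions,
                 length.out = cfg$elite_spec$n_defining)
  def_ids <- character(0)
  for (i in seq_len(cfg$elite_spec$n_defining)) {
    id <- sprintf("def%02d", i)
    reg <- regions[i]
    if (reg == "exon") {
      s <- plant_random_snp(s, id, pick_exon(), "missense")
    } else if (reg == "intron" && cfg$n_exons > 1L) {
      s <- plant_random_snp(s, id, sample(paste0("intron",
                                                 seq_len(cfg$n_exons - 1L)), 1L),
                            "noncoding")
    } else {
      s <- plant_random_snp(s, id, if (reg == "downstream") "downstream"
                            else "upstream", "noncoding")
    }
    def_ids <- c(def_ids, id)
  }
  for (i in seq_along(cfg$indel_sizes)) {
    id <- sprintf("defindel%02d", i)
    s <- plant_indel(s, id, "upstream", "deletion", cfg$indel_sizes[i])
    def_ids <- c(def_ids, id)
  }
  # group-seeding functional variants
  fun_ids <- character(0)
  for (i in seq_len(cfg$n_functional_variants)) {
    id <- sprintf("fun%02d", i)
    s <- plant_random_snp(s, id, pick_exon(), "missense")
    fun_ids <- c(fun_ids, id)
  }
  # silent variants
  sil_ids <- character(0)
  for (i in seq_len(cfg$n_silent_variants)) {
    id <- sprintf("sil%02d", i)
    where <- sample(c("synonymous", "upstream", "intron", "downstream"), 1L)
    if (where == "synonymous") {
      s <- plant_random_snp(s, id, pick_exon(), "synonymous")
    } else if (where == "intron" && cfg$n_exons > 1L) {
      s <- plant_random_snp(s, id, sample(paste0("intron",
                                                 seq_len(cfg$n_exons - 1L)), 1L),
                            "noncoding")
    } else if (where == "downstream") {
      s <- plant_random_snp(s, id, "downstream", "noncoding")
    } else {
      s <- plant_random_snp(s, id, "upstream", "noncoding")
    }
    sil_ids <- c(sil_ids, id)
  }
  variants <- annotate_effects(s$variants, s$model, s$region)

  # ---- haplotype structure ---------------------------------------------
  # groups: HapA-analog (all reference), elite (defining variants), one
  # group per remaining functional variant, plus rare novel groups
  n_rare <- length(cfg$rare_haplotype_sizes)
  groups <- list(G_ref = character(0), G_elite = def_ids)
  for (i in seq_along(fun_ids)) groups[[paste0("G_f", i)]] <- fun_ids[i]
  if (n_rare > 0L && length(fun_ids) < 2L)
    stop("rare novel groups need at least two functional variants")
  for (i in seq_len(n_rare)) {
    # pairs of functional variants give the rare group a signature distinct
    # from every main group (which carry zero or one)
    cars <- unique(c(sample(fun_ids, 2L), sample(sil_ids, 1L)))
    groups[[paste0("G_rare", i)]] <- cars
  }
  # haplotypes: 1-2 per main group, silent variants sprinkled on top
  main_groups <- setdiff(names(groups), paste0("G_rare", seq_len(n_rare)))
  haps <- list()
  for (gn in main_groups) {
    nh <- sample(1:2, 1L)
    for (j in seq_len(nh))
      haps[[paste0(gn, "-h", j)]] <- list(group = gn,
                                          carries = groups[[gn]],
                                          novel = FALSE)
  }
  for (i in seq_len(n_rare))
    haps[[paste0("G_rare", i, "-h1")]] <- list(group = paste0("G_rare", i),
                                               carries = groups[[paste0("G_rare", i)]],
                                               novel = TRUE)
  # silent sprinkling with confound rejection
  elite_haps <- names(haps)[vapply(haps, function(h) h$group == "G_elite",
                                   logical(1))]
  for (sid in sil_ids) {
    for (try in 1:50) {
      take <- names(haps)[stats::runif(length(haps)) < 0.4]
      take <- setdiff(take, names(haps)[vapply(haps, `[[`, logical(1), "novel")])
      if (length(take) == 0L || length(take) == length(haps)) next
      if (setequal(take, elite_haps)) next     # would confound uniqueness
      break
    }
    for (hn in take)
      haps[[hn]]$carries <- union(haps[[hn]]$carries, sid)
  }
  # within-group haplotype signatures must differ
  signature <- function(h) paste(sort(h$carries), collapse = ",")
  grp_of <- function() vapply(haps, `[[`, character(1), "group")
  kill <- character(0)
  for (gn in unique(grp_of())) {
    nms <- names(haps)[grp_of() == gn]
    sigs <- vapply(haps[nms], signature, character(1))
    for (nm in nms[duplicated(sigs)]) {
      free <- setdiff(sil_ids, haps[[nm]]$carries)
      if (!length(free)) kill <- c(kill, nm)
      else haps[[nm]]$carries <- union(haps[[nm]]$carries, free[1L])
    }
  }
  haps <- haps[setdiff(names(haps), kill)]
  grp <- vapply(haps, `[[`, character(1), "group")
  for (gn in unique(grp)) {
    sigs <- vapply(haps[names(haps)[grp == gn]], signature, character(1))
    if (anyDuplicated(sigs))
      stop("confounded structure: duplicate haplotype signatures")
  }

  # ---- accession counts -------------------------------------------------
  novel <- vapply(haps, `[[`, logical(1), "novel")
  n_main <- sum(!novel)
  fixed <- sum(cfg$rare_haplotype_sizes)
  remaining <- cfg$n_accessions - fixed
  if (remaining < n_main * 5L)
    stop("more rare-haplotype members than the panel can hold")
  base <- rep(5L, n_main)
  extra <- stats::rmultinom(1L, remaining - sum(base), prob = rep(1, n_main))[, 1L]
  counts <- integer(length(haps)); names(counts) <- names(haps)
  counts[!novel] <- base + extra
  counts[novel] <- cfg$rare_haplotype_sizes
  ref_hap <- names(haps)[vapply(haps, function(h)
    h$group == "G_ref" && length(h$carries) == 0L, logical(1))][1L]
  if (is.na(ref_hap)) ref_hap <- names(haps)[grp == "G_ref"][1L]
  assemble_panel(s, variants, haps, counts, cfg$subpop_weights,
                 elite_groups = "G_elite", ref_hap = ref_hap,
                 expected_unique = def_ids)
}

# expand haplotypes into accessions, genotypes, sequences, metadata and
# ground truth; errors (triggering a resample upstream) if the planted
# elite-unique set is confounded
assemble_panel <- function(s, variants, haps, counts, subpop_weights,
                           elite_groups, ref_hap, expected_unique = NULL,
                           elite_haplotypes = character(0)) {
  hap_names <- names(haps)
  grp <- vapply(haps, `[[`, character(1), "group")
  novel <- vapply(haps, `[[`, logical(1), "novel")
  acc_hap <- rep(hap_names, counts[hap_names])
  acc_ids <- sprintf("ACC%04d", seq_along(acc_hap))
  ref_acc <- acc_ids[match(ref_hap, acc_hap)]
  sequenced <- acc_ids[match(hap_names[!novel], acc_hap)]

  home <- sample(names(subpop_weights), length(hap_names), replace = TRUE,
                 prob = subpop_weights)
  names(home) <- hap_names
  subpop <- vapply(seq_along(acc_hap), function(i) {
    if (stats::runif(1L) < 0.7) home[[acc_hap[i]]]
    else sample(names(subpop_weights), 1L, prob = subpop_weights)
  }, character(1))
  panel <- data.frame(accession_id = acc_ids, subpopulation = subpop,
                      stringsAsFactors = FALSE)

  geno <- matrix("0", nrow = nrow(variants), ncol = length(acc_ids),
                 dimnames = list(variants$variant_id, acc_ids))
  for (i in seq_along(acc_ids)) {
    cars <- haps[[acc_hap[i]]]$carries
    geno[match(cars, variants$variant_id), i] <- "1"
  }
  hap_seq <- vapply(hap_names, function(hn) {
    rows <- variants[variants$variant_id %in% haps[[hn]]$carries, , drop = FALSE]
    apply_variants(s$region, rows)
  }, character(1))
  sequences <- hap_seq[acc_hap]
  names(sequences) <- acc_ids

  elite_flag <- grp[acc_hap] %in% elite_groups |
    acc_hap %in% elite_haplotypes
  elite_acc <- acc_ids[grp[acc_hap] %in% elite_groups]
  non_elite <- setdiff(acc_ids, elite_acc)
  unique_elite <- variants$variant_id[vapply(seq_len(nrow(variants)),
    function(i) all(geno[i, elite_acc] == "1") && all(geno[i, non_elite] == "0"),
    logical(1))]
  if (!is.null(expected_unique) && !setequal(unique_elite, expected_unique))
    stop("confounded structure: incidental elite-private variant")

  def_ids <- expected_unique %||% unique_elite
  def_rows <- variants[match(def_ids, variants$variant_id), , drop = FALSE]
  edef <- if (nrow(def_rows))
    elite_definition(s$model$gene_id, def_rows$atg_pos,
                     ifelse(def_rows$alt == "", def_rows$ref, def_rows$alt),
                     note = "planted elite definition")
  else NULL

  truth <- list(
    labels = data.frame(accession_id = acc_ids, group = unname(grp[acc_hap]),
                        haplotype = acc_hap, elite = unname(elite_flag),
                        rare_novel = unname(novel[acc_hap]),
                        stringsAsFactors = FALSE),
    unique_elite = unique_elite, elite_definition = edef,
    reference_accession = ref_acc, sequenced = sequenced)

  list(model = s$model, ref_region = s$region, chrom_seq = s$region,
       variants = variants, geno = geno, panel = panel,
       sequences = sequences, truth = truth)
}

# ---- file emission ------------------------------------------------------

write_panel <- function(built, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- built$model
  f <- list(
    reference = file.path(out_dir, "reference.fa"),
    gff = file.path(out_dir, "gene.gff3"),
    panel_fa = file.path(out_dir, "panel.fa"),
    vcf = file.path(out_dir, "panel.vcf"),
    meta = file.path(out_dir, "panel_meta.tsv"))
  write_region_fasta(stats::setNames(built$chrom_seq, g$chrom), f$reference)
  write_gff3(g, f$gff)
  write_region_fasta(built$sequences, f$panel_fa)
  write_panel_vcf(built, f$vcf)
  write_panel_meta(built$panel, f$meta)
  f
}

write_gff3 <- function(g, path) {
  ex <- g$exons[order(g$exons[, "start"]), , drop = FALSE]
  lines <- c("##gff-version 3",
    sprintf("%s\thaplomarker\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chrom, min(ex[, "start"]), max(ex[, "end"]), g$strand, g$gene_id),
    sprintf("%s\thaplomarker\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
            g$chrom, min(ex[, "start"]), max(ex[, "end"]), g$strand,
            g$gene_id, g$gene_id),
    sprintf("%s\thaplomarker\texon\t%d\t%d\t.\t%s\t.\tParent=%s.1",
            g$chrom, ex[, "start"], ex[, "end"], g$strand, g$gene_id),
    sprintf("%s\thaplomarker\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.1",
            g$chrom, ex[, "start"], ex[, "end"], g$strand, g$gene_id,
            g$gene_id))
  writeLines(lines, path)
  invisible(path)
}

# minimal VCF with anchor-base indel convention and homozygous GT calls
write_panel_vcf <- function(built, path) {
  v <- built$variants
  geno <- built$geno
  chrom <- built$model$chrom
  ref_seq <- built$ref_region
  accs <- colnames(geno)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(ref_seq)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", accs), collapse = "\t"))
  rows <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    p <- v$region_pos[i]
    if (v$vclass[i] == "SNP") {
      pos <- p; ref <- v$ref[i]; alt <- v$alt[i]
    } else if (v$vclass[i] == "deletion") {
      pos <- p - 1L
      anchor <- substr(ref_seq, pos, pos)
      ref <- paste0(anchor, v$ref[i]); alt <- anchor
    } else {
      pos <- p
      anchor <- substr(ref_seq, pos, pos)
      ref <- anchor; alt <- paste0(anchor, v$alt[i])
    }
    gts <- ifelse(geno[i, ] == "1", "1/1", ifelse(geno[i, ] == "0", "0/0", "./."))
    rows[i] <- paste(c(chrom, pos, v$variant_id[i], ref, alt, ".", "PASS",
                       ".", "GT", gts), collapse = "\t")
  }
  writeLines(c(header, rows[order(v$region_pos)]), path)
  invisible(path)
}

#' Convert a VCF genotype table to a gene-region variant table
#'
#' Trims the VCF anchor base from indel records and converts genomic
#' positions to ATG-relative and region coordinates under the gene model,
#' so the result feeds [annotate_effects()] and [classify_haplotypes()].
#'
#' @param vm list from [read_variant_matrix()].
#' @param g the [gene_model()].
#' @return list with `variants` and `geno`.
#' @export
vcf_to_variant_table <- function(vm, g) {
  v <- vm$variants
  out <- new_variant_table()
  for (i in seq_len(nrow(v))) {
    ref <- v$ref[i]; alt <- v$alt[i]; pos <- v$genomic_pos[i]
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      vclass <- "SNP"
    } else if (substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      if (nchar(ref) > nchar(alt)) {
        vclass <- "deletion"; pos <- pos + 1L
        ref <- substr(v$ref[i], 2L, nchar(ref)); alt <- ""
      } else {
        vclass <- "insertion"
        ref <- ""; alt <- substr(v$alt[i], 2L, nchar(alt))
      }
    } else stop("unnormalised indel record at VCF position ", pos)
    atg <- genomic_to_atg(pos, g)
    out <- rbind(out, data.frame(
      variant_id = v$variant_id[i], atg_pos = atg,
      region_pos = atg_to_region(atg, g), genomic_pos = pos,
      ref = ref, alt = alt, vclass = vclass, stringsAsFactors = FALSE))
  }
  list(variants = out, geno = vm$geno)
}
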