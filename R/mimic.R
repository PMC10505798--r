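# Study-mimic panels: five synthetic gene/panel fixtures reproducing the
# qualitative haplotype and marker structure of the five salt-tolerance
# genes (SKC1/OsHKT8-, GS3-, OsHAK21-, OsPAO3- and RST1/OsARF18-like),
# scaled to desk size.  Only the *structure* is mimicked -- elite groups
# defined by the printed numbers of variants, the marker types of each
# gene (3 + 1 + 3 + 1 + 3 = 11 markers), premature-stop and frameshift
# alleles, promoter indels of the printed sizes -- never the real
# sequences.  Restriction contexts are engineered at the designated marker
# targets so that designability is structural rather than a property of a
# lucky random draw; each build is verified end-to-end (planted effects,
# unique sets, marker designability) and resampled if a random layout
# confounds it.

mimic_attempts <- 40L

mimic_build <- function(builder, label) {
  for (i in seq_len(mimic_attempts)) {
    b <- try(builder(), silent = TRUE)
    if (!inherits(b, "try-error")) return(b)
  }
  stop("could not build ", label, " mimic panel: ",
       attr(b, "condition")$message)
}

# assemble + verify that every designated marker target is designable
finalize_mimic <- function(s, haps, counts, elite_groups, expected_unique,
                           marker_targets, gene, ref_hap = "G_ref-h1",
                           elite_haplotypes = character(0),
                           effect_expect = NULL) {
  variants <- annotate_effects(s$variants, s$model, s$region)
  if (!is.null(effect_expect)) {
    got <- variants$effect[match(names(effect_expect), variants$variant_id)]
    if (!all(got == unname(effect_expect)))
      stop("planted effect mismatch: ",
           paste(names(effect_expect), got, sep = "=", collapse = ", "))
  }
  weights <- c(XI = 0.40, "XI-IM" = 0.07, IM = 0.05, "GJ-IM" = 0.05,
               "GJ-tem" = 0.15, "GJ-tro" = 0.08, "VI/Aro" = 0.05,
               aus = 0.10, other = 0.05)
  built <- assemble_panel(s, variants, haps, counts, weights,
                          elite_groups = elite_groups, ref_hap = ref_hap,
                          expected_unique = expected_unique,
                          elite_haplotypes = elite_haplotypes)
  built$gene <- gene
  built$marker_targets <- marker_targets
  markers <- design_mimic_markers(built)
  if (any(vapply(markers, is.null, logical(1))))
    stop("marker target not designable: ",
         paste(marker_targets$variant_id[vapply(markers, is.null, logical(1))],
               collapse = ", "))
  built$markers <- markers
  # every accession must genotype to its planted allele class; a random
  # layout that breaks a marker (e.g. a constitutive site appearing in one
  # haplotype's amplicon) triggers a resample
  calls <- genotype_panel(built$sequences, markers)
  for (i in seq_len(nrow(marker_targets))) {
    tg <- marker_targets[i, ]
    carrier <- built$geno[tg$variant_id, rownames(calls)]
    want <- ifelse(carrier == (if (tg$elite_allele == "alt") "1" else "0"),
                   "elite", "other")
    if (!all(calls[, tg$name] == want))
      stop("marker ", tg$name, " not concordant with the planted panel")
  }
  built
}

#' Design the designated markers of a mimic panel
#'
#' @param panel one element of [paper_mimic_suite()].
#' @return list of `marker_spec` (or `NULL` where design failed), one per
#'   row of `panel$marker_targets`.
#' @export
design_mimic_markers <- function(panel) {
  tg <- panel$marker_targets
  out <- vector("list", nrow(tg))
  for (i in seq_len(nrow(tg))) {
    v <- panel$variants[panel$variants$variant_id == tg$variant_id[i], ]
    ez <- if (is.na(tg$enzyme[i])) default_enzymes() else enz(tg$enzyme[i])
    avoid <- variant_footprint(panel$variants[
      panel$variants$variant_id != tg$variant_id[i], , drop = FALSE])
    out[i] <- list(switch(tg$mtype[i],
      CAPS = design_caps(panel$ref_region, v, enzymes = ez,
                         elite_allele = tg$elite_allele[i], name = tg$name[i],
                         avoid = avoid),
      dCAPS = design_dcaps(panel$ref_region, v, enzymes = ez,
                           elite_allele = tg$elite_allele[i], name = tg$name[i],
                           avoid = avoid),
      Indel = tryCatch(design_indel_marker(panel$ref_region, v,
                                           elite_allele = tg$elite_allele[i],
                                           name = tg$name[i], avoid = avoid),
                       error = function(e) NULL)))
  }
  out
}

# reference-coordinate positions covered by a set of variants (indel spans
# included): primers must not bind across any of them
variant_footprint <- function(variants) {
  unlist(lapply(seq_len(nrow(variants)), function(i) {
    p <- variants$region_pos[i]
    switch(variants$vclass[i],
           SNP = p,
           deletion = seq(p, p + nchar(variants$ref[i]) - 1L),
           insertion = c(p, p + 1L))
  }))
}

target_row <- function(variant_id, mtype, elite_allele, name,
                       enzyme = NA_character_) {
  data.frame(variant_id = variant_id, mtype = mtype,
             elite_allele = elite_allele, name = name, enzyme = enzyme,
             stringsAsFactors = FALSE)
}

enz <- function(name) {
  e <- default_enzymes()
  e[e$name == name, ]
}

# ---- the five panels ----------------------------------------------------

mimic_skc1 <- function() {
  s <- gene_scaffold(3L, 300L, 200L, 2000L, 1000L, gene_id = "SKC1like")
  s <- plant_context_snp(s, "skc1_e551", "exon1", "GCGC", 3L, "A",
                         enz("HhaI"), frame = 2L)
  s <- plant_context_snp(s, "skc1_u1250", "upstream", "GACTTC", 5L, "C",
                         enz("EcoRI"))
  s <- plant_context_snp(s, "skc1_i1964", "intron1", "ACGGG", 3L, "A",
                         enz("EcoRII"))
  for (id in c("def1", "def3", "def4")) s <- plant_random_snp(s, id, "exon2", "missense")
  s <- plant_random_snp(s, "fun01", "exon3", "missense")
  s <- plant_random_snp(s, "sil01", "upstream", "noncoding")
  s <- plant_random_snp(s, "sil02", "intron2", "noncoding")
  elite_carries <- c("def1", "skc1_e551", "def3", "def4",
                     "skc1_u1250", "skc1_i1964")
  haps <- list(
    "G_ref-h1" = list(group = "G_ref", carries = character(0), novel = FALSE),
    "G_ref-h2" = list(group = "G_ref", carries = "sil01", novel = FALSE),
    "G_elite-h1" = list(group = "G_elite", carries = elite_carries, novel = FALSE),
    "G_elite-h2" = list(group = "G_elite", carries = c(elite_carries, "sil02"),
                        novel = FALSE),
    "G_h-h1" = list(group = "G_h", carries = c("def1", "def3", "def4"),
                    novel = FALSE),
    "G_f1-h1" = list(group = "G_f1", carries = c("fun01", "sil01"),
                     novel = FALSE))
  counts <- c("G_ref-h1" = 12L, "G_ref-h2" = 8L, "G_elite-h1" = 10L,
              "G_elite-h2" = 6L, "G_h-h1" = 12L, "G_f1-h1" = 12L)
  finalize_mimic(
    s, haps, counts, elite_groups = "G_elite",
    expected_unique = c("skc1_e551", "skc1_u1250", "skc1_i1964"),
    marker_targets = rbind(
      target_row("skc1_e551", "CAPS", "alt", "SKC1mim E1C", "HhaI"),
      target_row("skc1_u1250", "dCAPS", "alt", "SKC1mim 5Ud", "EcoRI"),
      target_row("skc1_i1964", "dCAPS", "alt", "SKC1mim I1d", "EcoRII")),
    gene = "SKC1like",
    effect_expect = c(skc1_e551 = "missense", skc1_u1250 = "noncoding",
                      skc1_i1964 = "noncoding"))
}

mimic_gs3 <- function() {
  s <- gene_scaffold(3L, 260L, 180L, 2000L, 1000L, gene_id = "GS3like")
  s <- plant_context_snp(s, "gs3_e1637", "exon2", "CTGCAG", 4L, "A",
                         enz("PstI"), frame = 2L)
  s <- plant_random_snp(s, "fun01", "exon1", "missense")
  s <- plant_random_snp(s, "fun02", "exon3", "missense")
  s <- plant_indel(s, "del13", "exon3", "deletion", 13L)
  s <- plant_random_snp(s, "sil01", "upstream", "noncoding")
  s <- plant_random_snp(s, "sil02", "downstream", "noncoding")
  haps <- list(
    "G_ref-h1" = list(group = "G_ref", carries = character(0), novel = FALSE),
    "G_ref-h2" = list(group = "G_ref", carries = "sil01", novel = FALSE),
    "G_elite-h1" = list(group = "G_elite", carries = "gs3_e1637", novel = FALSE),
    "G_elite-h2" = list(group = "G_elite",
                        carries = c("gs3_e1637", "sil02"), novel = FALSE),
    "G_f1-h1" = list(group = "G_f1", carries = c("fun01", "sil01"), novel = FALSE),
    "G_f2-h1" = list(group = "G_f2", carries = "fun02", novel = FALSE),
    "G_fs-h1" = list(group = "G_fs", carries = c("fun02", "del13"),
                     novel = FALSE))
  counts <- c("G_ref-h1" = 9L, "G_ref-h2" = 6L, "G_elite-h1" = 10L,
              "G_elite-h2" = 6L, "G_f1-h1" = 14L, "G_f2-h1" = 14L,
              "G_fs-h1" = 1L)
  finalize_mimic(
    s, haps, counts, elite_groups = "G_elite",
    expected_unique = "gs3_e1637",
    marker_targets = target_row("gs3_e1637", "CAPS", "alt", "GS3mim E2C", "PstI"),
    gene = "GS3like",
    effect_expect = c(gs3_e1637 = "premature_stop", del13 = "frameshift"))
}

mimic_hak21 <- function() {
  s <- gene_scaffold(3L, 300L, 200L, 2800L, 1000L, gene_id = "HAK21like")
  for (id in paste0("def", 1:4)) s <- plant_random_snp(s, id, "exon1", "missense")
  s <- plant_random_snp(s, "def5", "exon2", "synonymous")
  s <- plant_random_snp(s, "def6", "exon3", "synonymous")
  s <- plant_random_snp(s, "funA", "exon2", "missense")
  s <- plant_random_snp(s, "funB", "exon3", "missense")
  s <- plant_random_snp(s, "fun_f2", "exon1", "missense")
  s <- plant_context_snp(s, "hak21_i1251", "intron2", "TTTAAG", 6L, "A",
                         enz("DraI"))
  s <- plant_indel(s, "hak21_ins391", "upstream", "insertion", 391L)
  s <- plant_indel(s, "hak21_del17", "upstream", "deletion", 17L)
  s <- plant_random_snp(s, "sil01", "intron1", "noncoding")
  defs <- c(paste0("def", 1:6), "hak21_i1251")
  haps <- list(
    "G_ref-h1" = list(group = "G_ref", carries = character(0), novel = FALSE),
    "G_ref-h2" = list(group = "G_ref", carries = "sil01", novel = FALSE),
    "G_eliteA-h1" = list(group = "G_eliteA", carries = c(defs, "funA"),
                         novel = FALSE),
    "G_eliteB-h1" = list(group = "G_eliteB", carries = c(defs, "funB"),
                         novel = FALSE),
    "G_hf2-h1" = list(group = "G_hf2",
                      carries = c("fun_f2", "hak21_ins391", "hak21_del17"),
                      novel = FALSE))
  counts <- c("G_ref-h1" = 12L, "G_ref-h2" = 8L, "G_eliteA-h1" = 14L,
              "G_eliteB-h1" = 12L, "G_hf2-h1" = 14L)
  finalize_mimic(
    s, haps, counts, elite_groups = c("G_eliteA", "G_eliteB"),
    expected_unique = defs,
    marker_targets = rbind(
      target_row("hak21_ins391", "Indel", "alt", "HAK21mim 5U2"),
      target_row("hak21_del17", "Indel", "alt", "HAK21mim 5U1"),
      target_row("hak21_i1251", "CAPS", "alt", "HAK21mim I2C", "DraI")),
    gene = "HAK21like",
    elite_haplotypes = "G_hf2-h1",
    effect_expect = c(hak21_i1251 = "noncoding", def5 = "synonymous",
                      def6 = "synonymous"))
}

mimic_pao3 <- function() {
  s <- gene_scaffold(3L, 320L, 180L, 2000L, 1000L, gene_id = "PAO3like")
  s <- plant_context_snp(s, "pao3_e3474", "exon3", "GAGTTCCA", 6L, "T",
                         enz("EcoRI"), frame = 1L)
  s <- plant_random_snp(s, "pao3_u1141", "upstream", "noncoding")
  s <- plant_random_snp(s, "fun01", "exon1", "missense")
  s <- plant_random_snp(s, "fun02", "exon2", "missense")
  s <- plant_random_snp(s, "sil01", "intron1", "noncoding")
  s <- plant_random_snp(s, "sil02", "exon2", "synonymous")
  haps <- list(
    "G_ref-h1" = list(group = "G_ref", carries = character(0), novel = FALSE),
    "G_ref-h2" = list(group = "G_ref", carries = "sil01", novel = FALSE),
    "G_elite-h1" = list(group = "G_elite",
                        carries = c("pao3_e3474", "pao3_u1141"), novel = FALSE),
    "G_f1-h1" = list(group = "G_f1", carries = c("fun01", "sil02"), novel = FALSE),
    "G_f2-h1" = list(group = "G_f2", carries = c("fun02", "sil01"),
                     novel = FALSE))
  counts <- c("G_ref-h1" = 12L, "G_ref-h2" = 8L, "G_elite-h1" = 14L,
              "G_f1-h1" = 13L, "G_f2-h1" = 13L)
  finalize_mimic(
    s, haps, counts, elite_groups = "G_elite",
    expected_unique = c("pao3_e3474", "pao3_u1141"),
    marker_targets = target_row("pao3_e3474", "dCAPS", "alt", "PAO3mim E9d", "EcoRI"),
    gene = "PAO3like",
    effect_expect = c(pao3_e3474 = "missense"))
}

mimic_rst1 <- function() {
  s <- gene_scaffold(3L, 280L, 180L, 3200L, 1000L, gene_id = "RST1like")
  for (id in paste0("def", 1:4)) s <- plant_random_snp(s, id, "exon1", "missense")
  s <- plant_random_snp(s, "funA", "exon2", "missense")
  s <- plant_random_snp(s, "funB", "exon3", "missense")
  s <- plant_random_snp(s, "fun01", "exon2", "missense")
  s <- plant_context_snp(s, "rst1_u1505", "upstream", "GAGTC", 4L, "C",
                         enz("HinfI"))
  s <- plant_context_snp(s, "rst1_e1612", "exon2", "GGAC", 3L, "C",
                         enz("HaeIII"), frame = 0L)
  s <- plant_indel(s, "rst1_del514", "upstream", "deletion", 514L)
  s <- plant_random_snp(s, "sil01", "downstream", "noncoding")
  defs <- c(paste0("def", 1:4), "rst1_u1505", "rst1_e1612")
  haps <- list(
    "G_ref-h1" = list(group = "G_ref", carries = "rst1_del514", novel = FALSE),
    "G_ref-h2" = list(group = "G_ref", carries = c("rst1_del514", "sil01"),
                      novel = FALSE),
    "G_eliteA-h1" = list(group = "G_eliteA", carries = c(defs, "funA"),
                         novel = FALSE),
    "G_eliteB-h1" = list(group = "G_eliteB", carries = c(defs, "funB"),
                         novel = FALSE),
    "G_f1-h1" = list(group = "G_f1", carries = c("fun01", "rst1_del514"),
                     novel = FALSE))
  counts <- c("G_ref-h1" = 12L, "G_ref-h2" = 8L, "G_eliteA-h1" = 14L,
              "G_eliteB-h1" = 12L, "G_f1-h1" = 14L)
  finalize_mimic(
    s, haps, counts, elite_groups = c("G_eliteA", "G_eliteB"),
    expected_unique = defs,
    marker_targets = rbind(
      target_row("rst1_del514", "Indel", "ref", "RST1mim 5U"),
      target_row("rst1_u1505", "CAPS", "alt", "RST1mim 5UC", "HinfI"),
      target_row("rst1_e1612", "CAPS", "alt", "RST1mim E2C", "HaeIII")),
    gene = "RST1like",
    effect_expect = c(rst1_u1505 = "noncoding", rst1_e1612 = "synonymous"))
}

#' Build the five study-mimic panels
#'
#' Returns synthetic panels mirroring the qualitative structure of the
#' five genes: an elite group defined by four exonic missense variants
#' with one CAPS and two dCAPS targets (SKC1-like); a premature-stop elite
#' allele with a single unique variant and one CAPS target (GS3-like); two
#' elite groups plus an elite haplotype pair carrying 391-bp-insertion and
#' 17-bp-deletion promoter indels, three targets (OsHAK21-like); exactly
#' two elite-private variants with one dCAPS target (OsPAO3-like); and two
#' elite groups plus a 514-bp promoter indel carried by non-elite groups,
#' three targets (RST1-like) -- eleven designable markers in all.
#'
#' @param seed integer seed (the suite is deterministic given the seed).
#' @return named list of five panels, each as returned by
#'   [simulate_panel()] plus `gene`, `marker_targets` and `markers`.
#' @export
paper_mimic_suite <- function(seed = 101L) {
  set.seed(seed)
  list(
    SKC1like = mimic_build(mimic_skc1, "SKC1like"),
    GS3like = mimic_build(mimic_gs3, "GS3like"),
    HAK21like = mimic_build(mimic_hak21, "HAK21like"),
    PAO3like = mimic_build(mimic_pao3, "PAO3like"),
    RST1like = mimic_build(mimic_rst1, "RST1like"))
}
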