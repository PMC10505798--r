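---
title: "From gene-region haplotypes to diagnostic markers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gene-region haplotypes to diagnostic markers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomarker)
```

This vignette is the package's account of the science it implements: the
coordinate and classification models, the marker-design rules, the
numerical conventions, and — because several of these were genuinely open
design decisions — why each was made the way it was, and what the
synthetic-panel tests do and do not demonstrate about real data.

## The analysis region and its coordinates

For each gene the unit of analysis is the *gene region*: a 2,000-bp pad
upstream of the start codon, the gene body from the A of the ATG through
the last base of the stop codon (introns included), and a 1,000-bp pad
downstream. Following common usage in the germplasm literature, the
upstream pad is labelled 5'UTR and the downstream pad 3'UTR even though
neither is a UTR in the transcript sense; the package adopts these labels
verbatim and does not infer true UTR boundaries.

Positions are reported on the **ATG-relative axis**: a signed integer
coordinate on the coding strand where the A of the start codon is +1, the
base immediately upstream is −1, and zero does not exist. The axis counts
*genomic* bases, so intronic and downstream positions are directly
addressable — necessary because published marker targets routinely sit in
introns and promoters. `atg_to_genomic()` and `genomic_to_atg()` are
mutually inverse over the whole region on both strands (a property the
test suite checks on randomly generated gene models). Minus-strand genes
are normalised on ingestion: sequences are reverse-complemented to the
coding strand and exon order is coding order, so all downstream reasoning
is strand-free.

Gene models come from GFF3 via `rtracklayer`; the coding segments (CDS)
define the exon/intron geometry, and the CDS length must be a multiple of
three.

## Variants: calling, normalisation, effects

Per-accession region sequences are compared against the reference region
either column-wise (pre-aligned input) or after a global
Needleman–Wunsch alignment (via `Biostrings::pairwiseAlignment`, match 2,
mismatch −3, gap open −7, gap extend −2 — a deterministic, reproducible
default standing in for the interactive alignment curation such studies
typically use). Indels are left-normalised: a deletion is reported at the
leftmost equivalent placement, an insertion at its leftmost anchor, so
that equivalent placements inside homopolymer runs collapse to one
coordinate. Calling then re-applying variants reconstructs every sample
sequence exactly; this round-trip is a test invariant.

Coding effects are annotated per variant: exonic SNPs by translating the
affected codon under both alleles (`synonymous`, `missense`,
`premature_stop`, plus `start_loss` for ATG disruption and `stop_loss`
for the natural stop), exonic indels by the number of CDS bases affected
(`frameshift` if not a multiple of three, `inframe_indel` otherwise), and
everything else `noncoding`. A deletion spanning an exon–intron boundary
is labelled by the most severe region touched (the exon) and is a
frameshift whenever the count of removed CDS bases is not a multiple of
three; splice-site disruption per se is not modelled. Start-codon SNPs
are grouped with the functional variants, consistent with classifying by
amino-acid-changing variation. The annotation agrees with an independent
oracle that translates the full mutant CDS and diffs the protein
sequences, over a thousand random single-variant toys in the tests.

Heterozygous and missing calls: the accessions in scope are inbred lines,
so a heterozygous call is treated as unassignable, and an accession with
a missing or heterozygous call at any classifying variant is excluded
from haplotype assignment (reported in an "uncalled" bucket) rather than
imputed. Exclusion is the conservative choice; imputed panels are
effectively complete and unaffected by it.

## Two-tier haplotype classification

Tier one partitions fully-called accessions into **haplotype groups** by
their genotype vector over the functional variants (missense, in-frame
indel, frameshift, premature stop, start/stop loss). Tier two partitions
each group into **haplotypes** by the remaining variants. The reference
accession's group is named HapA and its haplotype HapA-1; other groups
are HapB, HapC, … by descending member count. The published naming order
beyond the reference is not fully specified, so ties are broken by the
lexicographically smallest member id — an arbitrary but deterministic
rule chosen for reproducibility.

**Novel-haplotype filter.** Haplotypes observed only in genotype data —
no member in the sequenced anchor panel — are "novel"; novel haplotypes
with fewer than five members are omitted and their accessions left
unassigned. The filter deliberately applies only to novel types: a
haplotype anchored by a sequenced accession is kept at any size, since
its sequence evidence is direct.

**Elite flags.** An elite definition is a list of ATG-relative positions
with required alleles (literal bases, or `ALT`/`REF` sentinels when the
published source names positions but not nucleotides). A haplotype is
elite when it carries *all* required alleles; a group is elite when all
its haplotypes are. Zero, one or several groups can be elite, and elite
status can also live at the haplotype level only (one of the five genes
has an elite haplotype pair inside otherwise non-elite groups); both
levels are therefore flagged and reported separately.

**Unique variants.** A diagnostic marker needs a variant whose
non-reference allele is carried by every member of every target
haplotype/group and by no accession outside the targets; rare types can
be waived via an `exclude` argument (mirroring the published treatment of
one rare haplotype). The search spans all regions — promoter and intron
variants included — because several published markers target promoter
indels. Missing calls outside the target are ignored rather than treated
as carriers; inside the target they disqualify, which keeps the
uniqueness claim strict.

## Marker design rules

Priority follows the published scheme: a 7–30 bp indel first (Indel
marker, 100–300 bp amplicon), an indel over 100 bp next (400–1,000 bp
amplicon); otherwise a SNP becomes a CAPS marker (300–800 bp amplicon)
when one allele naturally completes a restriction site overlapping the
SNP, or a dCAPS marker (100–300 bp amplicon) when a site can be
engineered. Indels of 31–100 bp or under 7 bp are rejected with an
explicit override flag, since they fall between the printed size classes.

The default enzyme library is the seven enzymes used across the published
markers — EcoRI `GAATTC`, EcoRII `CCWGG`, HhaI `GCGC`, PstI `CTGCAG`,
DraI `TTTAAA`, HinfI `GANTC`, HaeIII `GGCC` — as a user-extensible TSV;
"common and inexpensive" is operationalised as this configurable
whitelist because no sharper criterion is published. Restriction scanning
expands IUPAC codes on both strands; an `N` in the *sequence* never
matches (degenerate template is not evidence of a site). The scanner is
checked against an exhaustive brute-force search on 10,000 random
sequence/motif pairs.

**dCAPS search.** For each enzyme and each placement of its motif window
over the SNP, the SNP must be discriminating at its motif offset (one
allele inside the IUPAC set, the other outside); template positions on
the primer side of the window may be rewritten (at most *k* = 1 designed
mismatch by default, matching the single lower-case bases in published
primers), never at the primer's 3'-terminal base; positions on the far
side must already match. Both orientations are tried. Every candidate is
validated by re-scanning both alleles' primer-modified amplicons: the
engineered site must appear in exactly one. Candidates are ranked by
fewest mismatches, then most central cut, then smallest amplicon — a
deterministic order so the same input always yields the same marker.

**Primers.** Length 18–24 nt, GC 30–70%, Wallace-rule Tm (2 °C per A/T,
4 °C per G/C) within 52–62 °C, pairwise Tm difference at most 5 °C, and
the 3'-terminal base must not sit in a mononucleotide run of four or
more. The Wallace rule was chosen over nearest-neighbour thermodynamics
deliberately: the published workflow delegates scoring to commercial
software whose exact model is unavailable, and a simple deterministic
rule keeps designs reproducible; for 18–24-mers it is adequate to rank
candidates. Primer footprints also never cover a *known* polymorphic
position (the `avoid` argument): a primer sitting on another segregating
site would drop out in part of the panel, which is exactly the failure
mode in-silico genotyping exposed during development. Candidate binding
sites are strided across the whole product-size window so that large
amplicon classes (400–1,000 bp) are reachable, and when no pair is
admissible the error names the constraint that failed most often.

**Band model.** Fragment sizes always sum to the allele's amplicon
length, one more fragment than cuts. For dCAPS markers the engineered
site straddles the primer/template junction, and published tables report
the clipped fragment as exactly the primer length (20 bp for a 20-nt
mismatch primer) even though the literal top-strand cut lies a few bases
inside the primer footprint — on a gel the few-bp offset of a sticky-end
cut is not a meaningful distinction. The package adopts this field
convention as its band model: cut positions inside a primer footprint are
snapped to the junction, identically at design time and during in-silico
digestion, so conservation holds and predicted bands match the published
dialect. Constitutive sites of the chosen enzyme elsewhere in the
amplicon are tolerated as long as the allele band multisets remain
distinct and resolvable; otherwise the enzyme is rejected.

## In-silico genotyping and the gel model

`virtual_pcr()` binds primers exactly (designed lower-case mismatches are
tolerated by definition and the amplicon carries the primer-encoded
bases); a tolerance for unintended mismatches exists but defaults to 0
for desk-scale determinism. Multiple possible products raise a
"non-specific marker" error naming the loci. Digestion uses the marker's
band model, and calls are made by comparing the lane to the expected
elite/other patterns.

Gels resolve bands only so finely, and the published protocol names only
gel recipes (6% polyacrylamide below 300 bp, 2% agarose above), so the
resolution thresholds are this package's own explicit model: two bands
are distinguishable on PAGE when they differ by at least max(4 bp, 2% of
the smaller band), on agarose by at least max(20 bp, 5% of the smaller
band). Within a lane, co-migrating (unresolvable) fragments are merged
into one band before comparison, as they would appear on the gel. A lane
matching neither expected pattern is called `unknown`; a failed
amplification `no_amplification`.

## The synthetic panel generator

No germplasm data ships with the package; `simulate_panel()` generates
panels whose defaults describe the study conditions at desk scale: 120
inbred accessions across the standard subpopulation labels (XI-dominant
weights), a three-exon gene with the 2-kb/1-kb pads, an elite group
defined by four exonic missense variants, three further
functional-variant groups, four silent variants splitting haplotypes, and
one rare novel haplotype of three accessions sitting below the
five-accession filter. Planted exonic variants are verified by
translation (a "synonymous" plant is re-drawn until it truly is
synonymous), so planted effect labels are true labels. Subpopulation
structure is label-only — each haplotype gets a home subpopulation and
members are drawn mostly from it — because subpopulations enter the
analysis only as tallies; no linkage or coalescent realism is attempted,
and nothing in the pipeline depends on it.

The generator validates its own output: if a random layout creates a
confound — a silent variant incidentally private to the elite group,
duplicate haplotype signatures within a group — it resamples. Ground
truth (planted variants, per-accession labels, the expected unique set
computed by brute force over the truth genotypes) is emitted alongside
the data, and the recovery criterion — classification, elite marking and
unique-variant search reproducing the planted structure — holds across
200 random panels in the acceptance battery. Panels of 80 accessions
with an 800-bp gene body and 400/250-bp pads are used there; these sizes
keep the battery quick while exercising every code path, and nothing in
the algorithms is size-dependent.

`paper_mimic_suite()` builds five fixed panels mirroring the qualitative
structure of the five salt-tolerance genes: an elite group defined by
four exonic missense variants with one CAPS and two dCAPS targets; a
premature-stop elite allele that is its gene's single unique variant
(CAPS); two elite groups sharing six defining variants plus an elite
haplotype pair carrying 391-bp-insertion and 17-bp-deletion promoter
indels (one CAPS, two Indel targets); a gene with exactly two
elite-private variants (one dCAPS target); and two elite groups plus a
514-bp promoter deletion carried by the non-elite groups (one Indel, two
CAPS targets) — eleven designable markers in all. Local sequence
contexts at the designated targets are engineered (and competing sites of
the intended enzyme scrubbed nearby) so that designability reflects the
published marker chemistry structurally rather than a lucky random draw;
the suite verifies each build end to end (planted effects, unique sets,
marker designability, 100% genotyping concordance) and resamples
otherwise. Only structure is mimicked — counts, regions, effect classes,
indel sizes — never real sequence.

What passing these tests shows: the pipeline's logic is internally
consistent and recovers known structure under clean, complete,
homozygous data. What it does not show: robustness to alignment error,
heterozygosity, imputation artefacts, or paralogous amplification in
real panels — real-world concordance between marker calls and imputed
genotypes is known to be imperfect, and genotyping error is explicitly
not modelled.

## Numerical conventions and degenerate inputs

* Genomic intervals are 1-based closed (GFF3 convention); half-open
  arithmetic is internal only.
* A zero-variant panel classifies as a single HapA/HapA-1.
* VCF ingestion splits multi-allelic records into biallelic rows; a
  genotype heterozygous across any pair of alleles is `het`, homozygosity
  for a different alternate counts as not carrying the row's allele.
* Variant identifiers default to `gene_atgpos_ref>alt` when the input
  provides none.
* All ranking rules (group naming, dCAPS candidates, primer pairs) have
  total, deterministic orderings; no randomness exists outside the
  simulator, which is a pure function of its seed.

## Known limitations

Oligo secondary structure (hairpins, dimers) and multiplex compatibility
are out of scope, as are phasing, haplotype networks, association with
phenotype, BAM/CRAM ingestion and liftover. The Wallace Tm is a ranking
device, not a thermodynamic prediction. The gel model is deliberately
simple; mobility is not modelled beyond the resolvability thresholds.
Splice-site effects are not predicted. One published dCAPS row prints no
lower-case base in either primer; the bundled replica stores the row
verbatim and the validator flags rather than fails it, since whether the
mismatch sits in the unprinted strand or was lost in typesetting cannot
be determined from the table.
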