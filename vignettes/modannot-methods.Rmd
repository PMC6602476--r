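---
title: "Annotating mRNA modification sites with modannot: models and methods"
author: "modannot authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating mRNA modification sites with modannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modannot)
```

## The problem

Chemical modifications of mRNA — N6-methyladenosine (m6A), m1A, m5C,
pseudouridine, ac4C — are not distributed at random: m6A clusters near stop
codons, m1A near the 5'UTR, and the positional pattern of a mark is a strong
hint about its function. Experiments such as MeRIP-seq (wide antibody peaks)
or miCLIP (single-nucleotide sites) deliver modification coordinates as BED
intervals; making sense of them requires projecting those genomic intervals
onto transcript anatomy. `modannot` performs that projection and the full
downstream annotation suite: feature and biotype assignment, metagene and
boundary-coverage profiles, gene-characteristic comparisons, motif and
gene-set enrichment, and group/gene-list contrasts. The same machinery
applies unchanged to CLIP-seq binding sites of RNA-binding proteins.

## Transcript models and coordinates

A GTF and a genome FASTA are parsed into one `TranscriptModel` per
transcript: ordered exons, optional CDS, and the derived 5'UTR/CDS/3'UTR
partition in transcript coordinates. Two conventions are fixed throughout:

* **Coordinates.** GTF records (1-based, closed) are converted on ingest to
  0-based half-open intervals, the BED convention, so sites and features
  share one arithmetic. All output tables state this in their documentation.
* **One representative isoform per gene.** Positional profiles need a single
  transcript-coordinate system per gene. The representative is chosen
  deterministically: protein-coding first, then longest, ties broken by
  smallest transcript id. An `annotation_config(representative = "all")`
  escape hatch keeps every isoform as its own unit.

Derived features per representative transcript: promoter and downstream
intervals (default 1000 nt, clipped at chromosome ends and flagged when
clipped), introns, splice-junction positions (donor = last exonic nucleotide,
acceptor = first nucleotide of the next exon), and translation start/stop
anchors. CDS records in the bundled synthetic GTFs include the stop codon,
and the stop-codon anchor is defined as the last CDS nucleotide; with
annotations whose CDS excludes the stop codon the anchor shifts by three
nucleotides, which is immaterial for profiles at the 100-nt flank scale.

## Feature assignment

Each site is resolved to exactly one category, the highest-priority category
among everything its full interval overlaps:

> CDS > 3'UTR > 5'UTR > intron > non-coding exon > promoter > downstream,

with `intergenic` for sites overlapping nothing. The first four and last two
levels are the conventional priority used by annotation servers in this
field; the non-coding-exon level is this package's addition, placed so that
gene-body evidence always beats flanking regions — without it, a site whose
only overlap is a lincRNA exon could not carry its host gene, and the
biotype table (which tallies host-gene biotypes: protein_coding, lincRNA,
miRNA, ...) would be inconsistent with the category table. Ties within one
category are broken by the feature whose midpoint lies nearest the site
midpoint, then by smallest gene id — arbitrary but deterministic. Sites with
strand `"."` match features on both strands and carry a `both_strand_hit`
flag when candidates exist on both.

Wide peaks and point sites are handled by one rule pair: **assignment uses
the full interval** (a peak straddling a CDS/3'UTR junction is CDS by
priority), while **metagene placement uses the midpoint** (each site
contributes one count to one bin, keeping counts integers and masses
conserved).

## Positional profiles

**Metagene.** Each of 5'UTR, CDS and 3'UTR of every eligible representative
coding transcript is split into `bins` equal bins (default 100). Transcripts
with any requested region shorter than the bin count are excluded and
counted. A site midpoint at region offset `p` falls in bin
`floor(p / len * bins)`; density is total count divided by the number of
eligible transcripts, so `sum(density) * n_transcripts_used` equals the
number of placed midpoints exactly — an invariant the tests assert. The
three regions get equal visual width; a length-proportional display was
considered and rejected as the default because equal per-region binning is
the convention the surrounding outputs assume, and the raw per-bin values
must stay testable.

**Boundary coverage.** For each anchor (TSS, TES, start/stop codon, splice
donor/acceptor) and each anchor instance, a 0/1 vector over offsets
`-flank..+flank` (defaults: 1000 nt for TSS/TES, 100 nt for codons and
splice sites) marks offsets covered by any site interval — coverage
semantics, full interval, strand-compatible sites only. Codon and splice
profiles live in transcript coordinates (site intervals are projected
through the exon structure), TSS/TES profiles in genomic coordinates
oriented by strand. The profile is the mean over instances with a 95%
confidence band, mean ± 1.96 × SEM per offset, the lower bound clipped at
zero. With a single instance the SEM is defined as 0 and the band collapses
onto the mean — the alternative (NA bands) propagates badly into plots. The
denominator is all representative transcripts by default; `covered_only`
restricts it to transcripts with at least one covered offset, for sparse
data. Heatmaps are the underlying instance × offset matrix, rows ordered by
total occupancy (ties keep annotation order); their column means equal the
profile means by construction.

**Summit estimation.** The per-nucleotide argmax of an empirical coverage
profile is a poor summit estimator: for an enrichment of scale sigma the
contrast between adjacent offsets is O(1/sigma) while per-offset sampling
noise is O(1/sqrt(count)), so the raw argmax wanders across a band of width
comparable to sigma. `boundary_coverage(smooth_window = w)` therefore offers
a moving-average column (`mean_smooth`, partial windows at the ends); a
window of roughly twice the expected enrichment scale acts as a matched
filter and localizes a planted summit to within a few nucleotides. The
default stays 0 (raw values) — smoothing is an estimator choice, never
silently applied.

## Gene characteristics

Per region (5'UTR, CDS, 3'UTR, whole transcript): length, GC content, and an
optional secondary-structure score. Computing minimum free energy requires a
thermodynamic folding engine, which is deliberately a plug-in
(`structure_backend` as an R function or a shell command template, e.g.
wrapping an RNA folding tool); the statistical pipeline is fully testable
with a stub backend. Foreground-vs-background comparisons use the two-sided
Mann–Whitney U test — chosen for distribution-free robustness on skewed
length distributions; exact p-values for groups of at most 8, the normal
approximation with tie correction otherwise — with BH adjustment across all
comparisons in a report and effect direction from the median difference.

## Motif and gene-set enrichment

**Flank sequences.** Windows (default 41 nt) centered on site midpoints, on
the host transcript's strand. The background draws an equal number of
length-matched windows from feature intervals with the same category
composition as the foreground (length-weighted feature choice, uniform
position, seeded): a uniform-genome background would mostly rediscover
coding-sequence composition rather than site-specific motifs. Whether the
background should additionally match GC content is an open question; the
category-matched design is documented as this package's choice.

**k-mer test.** For each k (defaults 6, 7, 8), presence/absence counts per
sequence feed a hypergeometric upper-tail test (equivalently one-sided
Fisher on the 2×2 presence table), BH-adjusted within each k, ranked by p
then log2 enrichment (0.5 pseudocounts). A native, exactly defined statistic
was preferred over shelling out to an external motif finder: the p-values
are reproducible and checkable against an enumeration oracle. The top five
per k is the conventional report.

**Exact-site refinement.** Wide peaks are projected onto the spliced
transcript sequence and scanned for an IUPAC consensus; each match yields a
single-nucleotide site at the modified base: offset 2 in RRACH (the
methylated A of the m6A consensus), offset 3 in GAAGAAG (the central A, the
m1A convention), the central position for other motifs, all overridable.
Matches can span exon junctions because the scan runs in spliced
coordinates; the emitted genomic positions are always contained in the peak.

**Gene sets.** Enrichment of the modified-gene list (or any query) against
user-supplied GMT collections: hypergeometric upper tail after intersecting
query and sets with the universe, BH across sets. Ontology/pathway data are
not bundled — collections are inputs, keeping the statistic testable and
release-independent.

## Group and gene-list comparisons

`group_compare` runs the single-case layer per group, reports pairwise
overlap counts (diagonal: group sizes; off-diagonal: overlapping interval
pairs, symmetric), side-by-side category fractions and per-group metagenes,
and a combined set (union or intersection across groups) for shared
annotation. With more than two groups, all pairwise overlaps plus a joint
category table are emitted; no significance test is attached to category
contrasts by default (they are descriptive). `gene_case` splits assignments
into a user gene list (matched by gene id, falling back to gene name,
case-sensitive, unmatched ids reported) versus background and mirrors the
group outputs, adding the characteristics comparison.

## The synthetic fixture generator

`make_transcriptome` / `make_sites` generate the validation data: one
synthetic chromosome (~250 kb at the default 50 genes), multi-exon coding
and non-coding genes on both strands with ATG/TAA planted at CDS termini,
and sites drawn either around a transcript-space anchor
(Gaussian offsets, e.g. stop codon with sd 30 nt — the m6A-like condition)
or per-region rates (e.g. 3'UTR twice the CDS rate, the pseudouridine-like
condition). Default mRNA region lengths (5'UTR 150–300, CDS 300–900, 3'UTR
150–400 nt) are chosen so every coding gene passes the 100-bin metagene
filter while keeping the full pipeline under a minute. Ground truth (host
gene, transcript position, true category, realized anchor offset) is written
as a sidecar table so tests never re-derive it from generator internals.
Motif planting rewrites the genome under each site with a concrete IUPAC
instance centred on the modified base (strand-aware, collision-avoiding), so
motif recovery can be asserted at 100% planting.

What the generator does **not** emulate: overlapping isoforms (one
transcript per gene), realistic exon/intron length distributions, sequencing
noise, antibody specificity, or expression-dependent site detectability.
Passing tests therefore demonstrate correctness of the annotation
arithmetic and statistics, not robustness to the biases of real MeRIP-seq
libraries.

## Numerical and degenerate-input choices

* Bin index uses integer arithmetic (`(offset * bins) %/% len`), clamped to
  the last bin, so region ends land in bins 0 and `bins - 1` exactly.
* Site midpoint is `floor((start + end) / 2)`; duplicate sites are dropped
  (with a warning) so densities are not inflated by resubmitted rows.
* Empty site sets, empty intersections, single-anchor profiles, foreground
  equal to the universe, and transcripts failing the bin filter all return
  defined values or clear errors rather than NaN.
* Random draws are seeded everywhere (generator spec seed, background
  sampling seed); identical seeds give byte-identical fixture files.

## Validation scale

The bundled checks run the full stack at desk scale: 50-gene / 2000-site
fixtures for recovery of planted enrichments over 5 seeds, 200 small
randomized annotations with forced gene overlaps for the priority rule
against a brute-force oracle, and exhaustive genome-transcript round trips
over every exonic position of a 20-gene transcriptome. These sizes keep the
whole suite in the low minutes on one CPU while leaving sampling noise small
relative to the planted effects.
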