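---
title: "Diagnostic InDel marker discovery: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic InDel marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagindel)
```

## The genetic model

Two sister taxa that still interbreed — call them group A and group B — can be
told apart at any locus where the groups are *fixed for different alleles*.
At such a locus every group-A individual is homozygous for one allele, every
group-B individual homozygous for the other, and an F1 hybrid is heterozygous
with certainty. If the two alleles are an insertion/deletion (InDel) of
useful size, a single PCR across the locus turns this into a codominant gel
assay: one band per parental class, two bands in an F1.

`diagindel` operationalizes this as a predicate on a multi-sample VCF. A
locus is **diagnostic** when, over the non-missing genotypes,

* every group-A sample is homozygous for a single allele,
* every group-B sample is homozygous for a single *different* allele, and
* the number of missing genotypes in each group is at most `max_missing`.

We read the usual phrasing "homozygous within the groups, heterozygous
between the groups" as fixation for different alleles — so that the
*inter-group cross* is heterozygous — not as any individual being
heterozygous; only this reading is consistent with validating markers by the
two-band pattern of F1 hybrids. Missingness handling is deliberately exposed
as policy: the default `max_missing = 0` is the strictest reading (every
sample observed and homozygous); raising the tolerance can only grow the
diagnostic set (monotonicity, covered by a property test). Half-calls such as
`0/.` cannot establish homozygosity and count as missing. Multiallelic
records are decomposed per alternate allele into biallelic loci (a genotype
carrying a *different* alternate becomes missing at that decomposed locus),
because gel markers are two-allele systems.

## Synthetic study conditions

The generator emulates the data layout of a two-taxon re-sequencing study:
two groups of diploid samples (default **7 + 7**), genotyped against a
reference assembly that itself belongs to group B, so diagnostic loci appear
as alt-homozygous in group A and ref-homozygous in group B. This polarity is
what produces the characteristic asymmetry in per-sample ref-homo/alt-homo
counts between the two groups, which `summarize_samples()` reports.

Defaults, chosen once as a desk-scale equivalent of the study design:

| parameter | default | rationale |
|---|---|---|
| chromosomes × length | 2 × 200 kb | smallest genome that hosts 250 well-spaced loci with full primer flanks |
| diagnostic / shared / private InDels | 50 / 100 / 100 | recovery is tested against a majority of non-diagnostic loci |
| InDel lengths | uniform on [5, 60] bp | populates every marker tier (>50, >40, >34, >20) and the below-threshold range |
| variant spacing | ≥ 500 bp | each 150–400 bp amplicon covers exactly one planted InDel |
| gene density | 100 genes/Mb, genes 2–8 kb, 2–6 exons | most variants land in genic context so all 12 annotation categories are exercised |
| missing rate / dropout rate | 0 / 0 | clean baseline; both are per-cell/per-band probabilities when enabled |

All randomness derives from a single integer seed; identical configs give
byte-identical FASTA/VCF/GFF3/TSV outputs. F1 individuals (default 8, two
chicks from each of 4 parental pairs) inherit one uniformly drawn allele from
each parent per locus.

What the generator does **not** emulate — and therefore what green tests do
not show about real data: sequencing and alignment error, variant-calling
artifacts (the pipeline deliberately starts from called genotypes),
linkage/haplotype structure, repetitive DNA (flanks are i.i.d. random, so
primer uniqueness is almost automatic), realistic InDel length spectra
(empirical spectra are heavily skewed to short lengths; ours is uniform), and
realistic intergenic tracts. On the last point: with 100 genes/Mb and 5 kb
upstream/downstream windows, nearly all "intergenic" space falls inside a
window, so upstream/intron dominate the toy category summary, whereas real
vertebrate genomes put intron first and intergenic second. The annotation
machinery is validated against a position-painting oracle, not against any
expected category distribution.

## Annotation conventions

The category vocabulary (downstream, exon, intergenic, intron, none, splice
site acceptor/donor/region, transcript, upstream, 5'/3' UTR) follows the de
facto snpEff-style standard, with all windows configurable:

* splice donor / acceptor: first / last 2 bp of an intron in transcription
  direction;
* splice-site region: 3–8 bp into the intron, or the 3 exonic bp flanking an
  internal junction;
* UTRs: exonic sequence outside the CDS, 5'/3' assigned by strand;
* upstream / downstream: 5 kb windows beyond the transcript ends;
* transcript: inside the span of a transcript with no exon structure;
* none: a chromosome absent from the annotation (lenient mode; strict mode
  errors instead).

A locus overlapping several transcripts takes the highest-precedence
category: donor > acceptor > region > UTR5 > UTR3 > exon > intron >
transcript > upstream > downstream > intergenic (most specific wins,
deterministically). An InDel spanning two classes is classified by its VCF
anchor position — a single deterministic coordinate, and a documented
limitation for long InDels straddling a boundary.

## Primer design

For each diagnostic InDel longer than 20 bp the package searches every primer
placement on the reference template with the InDel strictly between the
binding sites (so both primers bind identically on both alleles), primer
length 18–27 bp, GC 40–60%, Tm 48–60 °C, and both allele amplicons inside
150–400 bp. Among feasible pairs it returns the one whose reference amplicon
is closest to the 275 bp midpoint (ties: smaller amplicon, leftmost forward
start, leftmost reverse end, shortest primers — a total order, so the choice
is deterministic and reproducible by the brute-force enumeration oracle used
in the tests). Candidates inherit the input ordering, InDel length
descending, and are tiered into the mutually exclusive intervals >50,
(40, 50], (34, 40], (20, 34] bp so tier counts partition the candidate set.

Melting temperature defaults to duplex nearest-neighbor thermodynamics with
the unified SantaLucia & Hicks (2004) parameter set, duplex initiation and
terminal A·T penalties, the SantaLucia (1998) entropy salt correction
0.368·(N−1)·ln[Na⁺] at 50 mM monovalent salt, and annealing concentration
125 nM (250 nM per primer); the hand-checkable Wallace rule 2(A+T)+4(G+C) is
available as `method = "wallace"` and is used in the design-oracle tests
precisely because it is trivially auditable. The nearest-neighbor
implementation is checked against an independent reference implementation of
the same parameter set to within 0.5 °C.

Genome-wide specificity screening is out of scope (as it is in the underlying
bench protocol); instead each selected primer must match exactly one site,
either strand, within ±10 kb of its locus. Because the synthetic flanks are
random sequence this screen almost never rejects; it exists so that
repetitive flanks fail loudly rather than silently (there is a dedicated
test that defeats it with a duplicated flank). A locus too close to a contig
edge, or with no constraint-satisfying pair, is skipped with a recorded
reason rather than designed badly.

## Gel model and genotype calling

Agarose resolvability is a single threshold: two bands closer than
`min_resolvable_diff` (default 20 bp, a practical floor for 2% agarose in the
150–400 bp range) merge into one reported band at their mean size. This is
deliberately not a migration-physics model; the decision the threshold feeds
— "can a technician call two bands by eye?" — is binary. Increasing the
threshold can only decrease the number of distinct bands (tested property).

Allelic dropout is modeled as independent per-band loss with probability
`dropout_rate` in heterozygotes, the standard abstraction for primer-site
mutations and null alleles. The single-band frequency among heterozygotes is
then 2p(1−p) exactly, which the tests verify by simulation against the exact
binomial interval.

Genotype calling inverts band prediction: bands are matched to the marker's
two allele sizes within ±5 bp; two distinct matches give `het`, one match
gives the corresponding homozygote *unless* the pedigree implies
heterozygosity (a known F1), in which case the call is `dropout_suspect`;
zero matches fail, and a band within tolerance of both alleles fails as
unresolvable. A marker is accepted for the panel only if every tested
individual is called correctly with no dropout suspects and no failures —
one anomalous F1 rejects the marker, which is exactly how a dropout-afflicted
marker with 304/338 bp alleles is rejected in the tests while its clean
companions pass.

## Numerical and degenerate-input choices

* Determinism: every stochastic operation takes (or derives) an explicit
  seed; stage seeds are derived from the run seed so stages are independently
  reproducible.
* Empty inputs flow through: an empty VCF body yields an empty matrix, an
  empty diagnostic set yields zero candidates and an empty panel, and an
  empty individual set yields a report with no acceptance decisions.
* Tie-breaks (scan ordering, primer choice, annotation precedence, donor
  before acceptor in sub-4 bp introns) are all total orders, so outputs are
  stable across platforms.
* Sizing errors are explicit: a chromosome too short for the requested genes
  or variants raises an error naming the limit instead of silently thinning.

## Problem sizes

The bundled tests run the default 2 × 200 kb / 250-locus / 14 + 8-individual
configuration for end-to-end checks, a 100-replicate sweep of 40 kb
single-chromosome genomes for constraint soundness, 4096-configuration
exhaustive oracle comparison for the diagnostic predicate, 1000-position
annotation oracle comparison, and 10,000-draw dropout simulations. These
sizes were chosen so the full suite completes in a few minutes on one core
while still exercising every tier boundary and every category.

## Known limitations

* The anchor-position convention under-counts splice/exon hits for very long
  InDels that straddle boundaries.
* Primer thermodynamics stop at Tm: no dimer/hairpin screening, no multiplex
  compatibility.
* The gel model ignores band intensity and migration nonlinearity.
* Sequence-level marker confirmation (e.g. Sanger traces) is outside the
  package; the panel report is the hand-off point for that step.
* Whether a rejected marker failed through allelic dropout or a true null
  allele is not adjudicated — the `dropout_suspect` flag records the
  ambiguity rather than resolving it.
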