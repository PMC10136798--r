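---
title: "circArch: models, parameters and design choices"
author: "circArch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circArch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circArch)
```

# Scope

circArch studies how circular RNAs (circRNAs) arise from their host
genes: which backsplice junctions are intronic lariat products (ciRNAs)
versus exonic circRNAs, what distinguishes the architecture and sequence
of host genes, how RNA polymerase II (RNAPII) dwells over the
circRNA-forming region, and how a perturbation shifts a gene's circular
versus linear transcriptional output. The package consumes standard flat
formats (GTF, FASTA, BED, bedGraph, TSV) and ships a deterministic
generator that emulates all of them with known ground truth, so every
estimator can be validated end to end.

# The classification model

A backsplice junction is identified by `(chrom, start, end, strand)`,
the genomic span of the backspliced segment. Against one representative
transcript per gene (the longest; ties broken by transcript id) a
junction is:

* **exonic** — its start coincides with an annotated exon start and its
  end with an exon end of the same transcript. Acceptor and donor exon
  indices are reported in transcript orientation; equal indices mean a
  single-exon circRNA, otherwise multi-exon.
* **intronic** — the whole span lies inside a single intron (the lariat
  pathway).
* **unassigned** — anything else, including junctions overlapping no
  gene. Unassigned is a value, not an error: junction callers emit
  calls outside curated models.

The boundary-match tolerance defaults to 0 bp because annotation-aware
callers report annotated boundaries; it is exposed for noisy callers.
When several genes match, the smallest gene span wins — nested genes
resolve to the most specific model, and the rule is deterministic.

# Host-gene architecture

For each exonic circRNA the package records host-gene length, the
lengths of the flanking introns (the intron immediately transcript-5' of
the acceptor exon and immediately 3' of the donor), internal intron
lengths, and backspliced exon lengths. Records with the acceptor at the
first exon (or donor at the last) have the corresponding flank flagged
undefined and are excluded from that flank's mean rather than imputed.
Host genes with several circRNAs contribute one record per circRNA,
matching a per-junction flank analysis.

Length comparisons default to Welch's t on log lengths, because intron
and gene lengths are heavy-tailed and group variances differ; Student's
t on the raw scale is available (`test = "student-raw"`) for parity with
analyses that used it. Both paired and unpaired forms of the
upstream-versus-downstream comparison are provided, since either could
be meant by a per-cohort asymmetry test; the asymmetry summary uses the
paired form on per-circRNA differences.

# Sequence bias

**G-quadruplexes.** The scanner detects `k >= 4` runs of `r >= 3`
guanines separated by loops of 1–7 bases (the "R4" class), maximal,
non-overlapping and left-greedy per strand, with minus-strand motifs
detected as C-run patterns on the reference. One deliberate choice makes
the scan bit-reproducible: loops are defined over the non-G
(respectively non-C) alphabet. If loops could contain G, a long G-run
could be split ambiguously between run and loop and "maximal,
left-greedy" would not be well defined; with the restriction, the
run-chaining implementation is provably identical to a single greedy
regular expression, which the test suite exploits as an independent
oracle. `N` never contributes to a run.

**Repeats.** Enrichment is measured in bp-overlap fractions rather than
element counts, which is robust to fragmented repeat annotations; the
fold is target fraction over background fraction with a seeded bootstrap
CI over target introns (B = 1000 by default). Classes absent from the
background are flagged rather than reported as infinite.

**RBP motifs.** Motif occurrence in the two flanking-intron region sets
is tested per flank against the background per-base rate with a
one-sided binomial test, BH-corrected across motifs; a motif is
"symmetric" when significant in both flanks. This is an intentionally
simple occurrence analogue of positional RBP-map tools — it reports
which motifs flank both backsplice sites, not positional densities.
The default flank region is the full flanking intron, with a fixed
window override, since published analyses rarely state the window.

**Composition.** Base fractions are tallied in 500 bp windows (clipped
at feature boundaries and flagged), with `N` excluded from the
denominator; an all-`N` window is flagged undefined rather than zero.

# RNAPII pausing

Each exonic circRNA defines a region schema over its host gene: E1 (the
gene's first exon when it lies upstream of the circRNA), A (acceptor
exon), I (internal exons), D (donor exon), dsE (first exon downstream of
the donor), and ±300 bp flank windows per labeled exon, trimmed so
labels never overlap. Single-exon circRNAs collapse A and D into one
`AD` label.

The pausing index of a region is its mean per-base nascent-RNA coverage
divided by the gene-body mean. This normalization is a package
definition (NET-seq pausing studies vary in their exact formula): it is
scale-invariant — multiplying a track by any constant changes nothing —
and equals 1 under uniform coverage. Genes with zero body coverage are
excluded, never filled with a pseudo-value.

Changes between conditions are `log2((index_kd + eps) / (index_wt +
eps))` with `eps = 1e-6` guarding empty regions, classified as
increased / decreased / no change at a symmetric threshold `tau =
log2(1.5)`, chosen so that Poisson noise at the generator's default
depth (10 reads/bp over hundreds of exonic bases) rarely crosses the
threshold by chance.

One subtlety drives an option: per-gene body normalization cancels any
concerted shift, because the body-weighted average of region indices is
1 by construction — a gene whose exons *and* introns both gain
occupancy would show no change. Within-gene profiles (metaprofiles over
E1/A/I/D/dsE) therefore use body normalization, while exon-versus-intron
*change* analysis uses raw pooled densities on depth-matched tracks
(`normalize = "none"` in `intronExonPausing()`).

# Circular-to-linear output

Probe counts (one circular-junction and one linear-junction probe per
gene, plus housekeeping probes) are normalized by housekeeping
geometric-mean scaling, the standard practice for hybridization-based
digital counting. Per-probe log2 fold changes use a 0.5 pseudo-count
and a Welch t-test on log2 counts across replicates, BH-corrected. A
probe is "altered" at `|log2FC| > 2` and `p < 0.05` (the volcano-plot
convention; a q-value option exists because some analyses correct
here), and a gene is altered when either probe is.

The C:L ratio change of a gene is `delta_cl = log2FC_circ -
log2FC_linear`; classes use a symmetric threshold `delta = 1` (2-fold)
together with a significant circular change. The threshold is exposed
because published "no significant change" rules are rarely printed; the
tests sweep it. Cross-tabulation of C:L classes with pausing classes
uses Fisher's exact test.

# The generator

The generator's defaults are the study conditions the package is built
around: background genes with 1832 bp mean introns and 292 bp mean
exons (typical Drosophila gene architecture); host genes whose
backspliced exons average 372 bp with flanking introns of 9131 bp
(upstream) and 9355 bp (downstream) in the reference condition and
11251 / 6089 bp under knockdown-like asymmetry; about half of genes on
the minus strand; a quarter of planted junctions intronic. All length
laws are lognormal with log-scale dispersion 0.5 — lognormal matches
heavy-tailed intron length distributions, and 0.5 gives a realistic
coefficient of variation (~0.53) while keeping desk-scale cohort means
stable. Lengths are floored at biological minima (introns 60 bp, exons
50 bp), which biases configured means by well under 1%.

On the stated exon means: reported Drosophila averages are internally
ambiguous between "average exon" and "average circularized exon" around
292 versus 372 bp, so both are plain parameters
(`background_exon_mean`, `circ_exon_mean`) rather than a resolved
constant.

Sequence features are planted only where detection is later tested:
G-quadruplex motifs (loops drawn from the non-run alphabet) are written
into flanking introns at a configured density inside short non-run
buffer pads, so each planted motif is re-detected at exactly its
recorded coordinates (recall 1 by construction); repeats are planted as
annotation intervals at configured bp fractions — their sequence
content is irrelevant to bp-overlap enrichment and is left random.
Coverage is Poisson around `depth x gene_rate x multiplier` with
region multipliers over the schema labels; gene rates are drawn once
and shared across conditions so deltas reflect multiplier ratios only.
Probe counts are negative binomial (dispersion 0.05 by default) with
planted log2 effects; dispersion 0 is the exact-mean limit used in
tests.

What the generator does *not* emulate, and hence what green tests do
not show about real data: mappability and read-level artifacts, GC-
dependent coverage bias, correlated exon/intron structure within genes,
isoform diversity (one representative transcript per gene), and
realistic karyotype (one synthetic chromosome by default,
multi-chromosome via `n_chromosomes`).

The seed determines every emitted byte. Sub-stages derive fixed offsets
from it (+1 planting, +2 coverage, +3 counts) so partial reruns are
reproducible.

# Demonstration cohorts

Four packaged cohort builders (`junctionCohortFixture()`,
`spliceOverlapFixture()`, `probePanelFixture()`,
`pausingCohortFixture()`) construct deterministic desk-scale datasets
with fixed composition — a 284-junction cohort with a known
intronic/exonic partition across three conditions, alternative-splicing
overlap sets, a 26-gene probe panel with planted circular-only effects,
and a 26-gene pausing cohort with planted exon/intron density changes.
They are used in the worked examples and the acceptance script; their
compositions are part of the package's contract and are asserted by the
test suite.

# Numerical choices and degenerate inputs

* Zero-variance groups in a t-test: p = 1 when means are equal, 0
  otherwise, instead of an error.
* Housekeeping probes with zero counts are dropped from normalization
  factors with a warning; all-zero housekeeping is an error.
* Empty motif counts give p = 1; a motif longer than its region counts
  0 without error.
* Genes excluded from pausing (zero body coverage) propagate as absent
  rows, never as zeros.
* Percentages follow the reporting style of the quantities they mirror:
  overlap percentages to one decimal, altered-gene and C:L percentages
  to the nearest integer, pausing-class fractions to one decimal.

# Problem sizes

The test suite and the acceptance script run the generator at desk
scale, chosen to keep each property estimable with comfortable margins:
20 seeds for parameter-recovery checks (flank means within 2 standard
errors), 25–250 host genes per simulation depending on the estimator's
variance, 1000 random sequences for the G4 oracle equivalence, and
40 x 25 null probes for the type-I control. These sizes are the
package's own validation design.

# Known limitations

* One representative transcript per gene; isoform-specific backsplicing
  is out of scope.
* The motif analysis is occurrence-based, not positional.
* The pausing index is coverage-ratio based; it does not model RNAPII
  velocity or promoter-proximal pausing around the TSS.
* Read alignment and junction calling from raw reads are upstream of
  this package; it consumes their tabular output.
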