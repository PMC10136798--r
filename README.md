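# circArch

Circular RNAs (circRNAs) arise when a downstream splice donor joins an
upstream splice acceptor of the same pre-mRNA (backsplicing). Whether a
gene produces circRNAs — and how much circular versus linear output it
makes — is shaped by its architecture (long, often asymmetric introns
flanking the backspliced exons), by sequence features in those introns
(repeat elements, G-quadruplexes, RNA-binding-protein motifs), and by
how RNA polymerase II (RNAPII) moves and pauses across the gene.

circArch is an R/Bioconductor-style package for analysts studying this
interplay — for example in perturbation experiments (such as PARP1
knockdown or PARylation inhibition in Drosophila S2 cells) where
junction calls, nascent-RNA coverage and probe-based counts are
compared across conditions. It provides:

* **Junction classification** — backsplice calls (seekCRIT-style TSV)
  against a GTF: intronic (ciRNA) vs exonic (single-/multi-exon)
  circRNAs, host-gene assignment, condition overlap partitions.
* **Host-gene architecture** — flanking/internal intron and exon length
  statistics with significance tests and an upstream/downstream
  asymmetry summary. Flanking introns are defined in transcript
  orientation: the intron immediately 5' of the acceptor exon and
  immediately 3' of the donor exon.
* **Sequence bias** — a G-quadruplex scanner for the pattern
  G≥3 (N1–7 G≥3)×3 ("R4"), motif densities, repeat-class bp-fraction
  enrichment with bootstrap CIs, symmetric RBP-motif tests, and
  windowed nucleotide composition.
* **RNAPII pausing** — pausing indices from strand-resolved bedGraph
  coverage over a circRNA-anchored region schema
  (E1 / A / I / D / dsE ± 300 bp flanks), where
  `index = mean coverage in region / mean coverage over gene body`,
  plus between-condition deltas classified at |log2 ratio| > log2(1.5).
* **Circular-to-linear output** — housekeeping geometric-mean
  normalization of probe counts (nCounter-style), per-probe log2 fold
  changes with Welch tests and BH correction, altered-gene calls
  (|log2FC| > 2, p < 0.05), C:L ratio classes from
  `Δ_CL = log2FC_circ − log2FC_linear`, and cross-tabulation with
  pausing classes (Fisher's exact test).
* **A synthetic-data generator** — miniature genome, annotation,
  junctions, planted repeats/G-quadruplexes, Poisson coverage with
  region-specific pause multipliers and negative-binomial probe counts,
  all byte-deterministic under a seed, with a ground-truth sidecar for
  parameter-recovery validation.

## Worked example

```r
library(circArch)

params <- simParams(n_host_genes = 12, n_background_genes = 30, seed = 42)
sim <- simulateBundle(params, dir = "demo")   # writes GTF/FASTA/TSV/bedGraph/JSON

circs <- classifyJunctions(sim$junctions, sim$genes)
circs
#> CircRNASet with 12 junction calls
#>   classes: intronic=4 exonic_single=3 exonic_multi=5 unassigned=0
#>   conditions: KD, PARPi, WT

rec <- architectureRecords(circs, sim$genes)
asym <- intronAsymmetry(rec)
sprintf("upstream/downstream ratio: %.2f (paired p = %.3f)", asym$ratio, asym$p)
#> "upstream/downstream ratio: 0.81 (paired p = 0.381)"

prof <- pausingProfile(circs, sim$genes, sim$coverage$WT, collapse_flanks = TRUE)
metaprofile(prof)
#>   region n      mean         sem
#> 1      A 5 2.3720103 0.024667773
#> 2     AD 3 2.3610874 0.045858061
#> 3      D 5 1.4312298 0.014602241
#> 4    dsE 8 0.9413002 0.008674835
#> 5     E1 8 2.8146717 0.027016941
#> 6  flank 8 0.9498281 0.008792097
#> 7      I 4 1.4171210 0.025943407
```

The metaprofile recovers the generator's planted pause multipliers (here
the default reference condition: strong accumulation at E1 and the
acceptor exon, baseline at dsE). Indices sit slightly below the planted
folds because the gene-body mean in the denominator includes the
elevated regions themselves; the vignette discusses this normalization
and when to use raw densities instead.

The architecture summary from the same run shows host flanking introns
an order of magnitude longer than background introns
(`summarizeArchitecture(rec, sim$genes)`): upstream/downstream flank
means in the 7–13 kb range against a 1.7 kb background intron mean
(n = 195), matching the generator's configured study conditions.

A whole-study run from files is one call:

```r
runPipeline(list(
  gtf = "demo/genome.gtf", fasta = "demo/genome.fa",
  junctions = "demo/junctions.tsv", repeats = "demo/repeats.bed",
  coverage = list(WT = "demo/WT", KD = "demo/KD"),
  counts = "demo/probe_counts.tsv",
  reference = "WT", outdir = "demo/out"))
```

which writes per-stage TSVs and a `report.json` whose every number is
traceable to a stage table.

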