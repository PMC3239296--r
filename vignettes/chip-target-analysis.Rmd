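---
title: "Methods: from replicate peak calls to transcriptional status of TF targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from replicate peak calls to transcriptional status of TF targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiptargets)
```

## The analysis problem

A transcription factor ChIP-seq experiment yields, per replicate, a set of
peak calls — genomic intervals with a fold enrichment of IP signal over
background.  Turning those calls into biology takes several downstream
steps that this package implements as a tested, reusable pipeline:

1. **Consensus** — keep only binding sites supported by both replicates.
2. **Annotation** — assign each consensus peak to its nearest gene and a
   location category (promoter-proximal, exonic, intronic, downstream,
   intergenic).
3. **Occupancy** — quantify RNA polymerase II binding over each associated
   gene in RPKM from a parallel Pol II ChIP-seq peak set.
4. **Status** — classify each target gene as transcriptionally inactive,
   very low, low-to-moderate, or high, relative to a housekeeping
   reference gene.
5. **Motifs** — count peaks carrying IUPAC consensus motifs, capping each
   peak's contribution at 0 or 1 per motif.
6. **qPCR** — estimate knockout/control expression fold changes from
   delta-Ct tables, and ChIP-qPCR fold enrichment over an intergenic
   control region.

The motivating use case is a repressor such as Sox6 in fetal muscle: if the
factor silences its targets, the Pol II occupancy of peak-associated genes
should pile up in the "inactive or very low" tiers, and knocking the factor
out should raise the targets' mRNA levels.

## Coordinate conventions

All coordinates are 0-based half-open (`[start, end)`), the native BED
convention; refFlat files already store txStart/txEnd and exon bounds this
way, so both supported gene-model dialects parse without coordinate
shifts.  The TSS of a model is `start` on the plus strand and `end - 1` on
the minus strand.  Using a single internal convention eliminates the
classic off-by-one family of annotation bugs; the round-trip test
(write-then-read refFlat is bit-identical) guards it.

## Consensus matching

Two peaks *correspond* when they overlap or are separated by at most
`max_gap` intervening bases (default 50 bp).  We interpret "within 50 bp"
as a nearest-edge gap — an overlap counts as gap 0 — because the companion
usage of the phrase ("peaks localized within 50 bp of" another factor's
peaks) reads as proximity, not midpoint distance.  One edge case follows
from the worked definition: book-ended intervals (`[a,b)` and `[b,c)`)
have zero intervening bases, so they match even at `max_gap = 0`, which is
therefore "overlap or adjacency" rather than strict intersection.

Matching is one-to-one and greedy by increasing gap, with ties broken by
the leftmost coordinates of the candidate pair.  Greedy-nearest is
deterministic, symmetric in the replicates (the tie-break keys are
symmetric functions of the pair), and simple enough to verify against an
exhaustive all-pairs matcher, which the test suite does.  The consensus
interval is the union of the matched pair — a conservative footprint for
downstream sequence scanning — and the representative fold enrichment is
taken from replicate 1, by convention the deeper data set.

## Location annotation

Each peak is reduced to its midpoint, `floor((start + end)/2)`.  A single
point resolves peaks spanning boundaries and matches the convention that
every peak gets exactly one category.  Classification, in order of
precedence:

* inside a transcript body → **exonic** if the midpoint falls in an exon of
  the assigned model, else **intronic**;
* within 20 kb upstream of a TSS (strand-aware) → **five_prime_upstream**;
* within 20 kb past a transcript end → **three_prime_downstream**;
* otherwise **intergenic**.

The 20 kb window is the published convention for separating
promoter-proximal binding from intergenic binding (more than 20 kb from
any TSS or transcript end).  Reports of this analysis typically name only
three categories (intronic, intergenic, 5'-upstream) covering ~91% of
peaks; the remainder must fall somewhere, so we expose exonic and
downstream explicitly — categories must partition.  Genic placement takes
precedence over another gene's promoter window because the dominant
intronic class in such data implies genic precedence; remaining ties go to
the smaller distance, then lexicographic symbol.  Intergenic peaks still
record their nearest gene (minimal unsigned midpoint-to-body distance),
since nearest-gene assignment of distal peaks is how a peak cohort maps to
a gene cohort.

Two open conventions we resolved and made configurable: the upstream
window is measured from the TSS only (not either transcript boundary), and
"nearest gene" uses body distance (0 inside).  The whole classifier is
checked against an exhaustive position-by-position oracle over a 100 kb
toy chromosome.

## Pol II occupancy in RPKM

Occupancy of gene *g* is

$$\mathrm{RPKM}(g) = \frac{C_g / (L_g/1000)}{N/10^6}$$

with \(C_g\) the summed tag count of Pol II peaks overlapping the gene
body, \(L_g\) the *effective* region length, and \(N\) the library size
(total uniquely mapped reads — a user-supplied scalar, since peak calls
carry no information about unassigned reads).  When several transcript
models share a symbol, the longest body (`txEnd - txStart`, the same span
as the denominator) is used; ties break to the lexicographically smallest
accession for determinism.  When a peak protrudes beyond the gene body,
the protruding footprint is added to \(L_g\); protrusions are merged
before summing so overlapping extensions are not double counted.  A peak
overlapping two genes contributes its full tag count to both — no
splitting rule is published, and double counting is the simplest
documented behaviour.  Genes without overlapping peaks score exactly 0.

## Transcriptional status tiers

The yardstick is the occupancy \(R\) of an abundantly expressed
housekeeping gene (β-actin/Actb; 8.60 RPKM in the motivating data set).
Tiers: **zero** (RPKM = 0), **very_low** (0 < RPKM < R/10),
**low_moderate** (R/10 ≤ RPKM ≤ R/2), **high** (RPKM > R/2).  The outer
tiers carry strict inequalities (matching the printed "<0.86" and
">4.30"), which closes the middle tier at both boundaries; the four-tier
partition is the minimal scheme consistent with all three printed cut
points.  The combined "inactive or very low" percentage is computed from
the summed raw counts and then rounded — not by summing rounded per-tier
percentages, which can differ by a point.  The reference gene itself is
excluded from the cohort it calibrates.  The reference RPKM may be
supplied directly or looked up from the occupancy table; a missing
reference is an error, never a silent default.

## Motif counting

Motifs are IUPAC consensus strings scanned on both strands (the reverse
complement of the motif against the forward sequence), reporting all
overlapping sites via zero-width lookahead matching.  `N` in a sequence is
matched only by an explicit `N` in the motif.  For palindromic motifs a
minus-strand hit spans exactly the bases of the plus-strand hit at the
same offset; such duplicates are collapsed so a single CAGCTG is one site.
The headline count caps each peak at 0-or-1 per motif — it counts
motif-bearing peaks, not sites — while the per-peak table retains every
site.

The default motif set uses canonical consensi for the four families
recurrent in muscle regulatory regions: Sox `WWCAAWG` (consistent with the
functional instance TACAAAG and its binding-dead mutant TCAGAAG), E-box
`CAGSTG`, Runx `TGYGGT`, Tead/MCAT `CATTCCW`.  Exact position-weight
matrices from de-novo discovery are not recoverable from text, so these
defaults are documented assumptions, overridable per run with user IUPAC
strings.  Motif significance (MEME-style E-values) is out of scope: it
depends on a discovery tool's background model, not on counting.

## qPCR fold changes

Per-sample relative expression is \(2^{-\Delta C_t}\) with
\(\Delta C_t = C_t^{target} - C_t^{reference}\).  The knockout/control
fold change is the ratio of group means of the relative levels (matching
the "levels divided by control, mean ± SD, n = 3" presentation), not
\(2^{-\Delta\Delta C_t}\) of mean Cts — both are available, the default
follows the presentation convention.  Significance uses an unpaired
two-tailed Student t-test with equal variances (Welch behind a flag),
either on the relative levels (default) or on the log2 scale
(`on = "dct"`), where Gaussian Ct noise makes the test exact.  Undetected
targets ("u.d."/"n.d.") are missing values, excluded and never imputed as
zero.  Degenerate cases are explicit: identical constant groups give
p = 1; unequal constant groups leave p undefined with a flag.  ChIP-qPCR
fold enrichment is input-normalized IP signal at the target region divided
by the same quantity at an intergenic negative-control region, so the
control region scores exactly 1 against itself.

## The synthetic-data generator

Every pipeline stage is testable without downloads because the generator
plants known structure in the same file formats the pipeline reads:

* **Genome** — non-overlapping gene models (default 101 genes, one of them
  the Actb-like reference) on two 3.5 Mb chromosomes, transcript lengths
  2–20 kb with 2–8 exons, separated by at least 45 kb so a planted
  category near one gene can never collide with a neighbour's 20 kb
  window.
* **Replicate peaks** — 400 true 200 bp sites placed to realize the
  location fractions 13.6 / 0 / 48.4 / 8.8 / 29.2 % (upstream / exonic /
  intronic / downstream / intergenic) *exactly* by largest-remainder
  allocation; gene-proximal sites cycle through a shuffled gene list so
  every gene is peak-associated whenever sites outnumber genes.  Each
  replicate drops sites at rate 0.1, jitters positions by round(N(0, 10 bp)),
  draws log-normal fold enrichments, and adds a Poisson(20) count of
  unrelated background peaks.
* **Pol II profile** — per-gene tiers allocated at 51/33/13/3 % over the
  100 non-reference genes (so the default scenario's summary reproduces
  the 51/33/84 pattern by construction); target RPKMs are drawn from tier
  interiors at least 1.5 tag-equivalents from the boundaries, tag counts
  back-solved as `C = round(rpkm * (L/1000) * (N/1e6))` with N = 2.8
  million, and distributed over 1–3 peaks that may protrude up to 300 bp.
  Zero-tier genes emit no peaks.
* **Peak sequences** — i.i.d. background at 42% GC with one concrete motif
  instance inserted per motif with probabilities 0.68 / 0.60 / 0.52 / 0.19
  (Sox / E-box / Runx / Tead, the motif-bearing fractions such a peak
  cohort exhibits), random strand and non-overlapping offsets.
* **Ct matrices** — per-target control baselines of 3–9 cycles above the
  reference, knockout samples shifted by −log2(planted fold), Gaussian
  noise (SD 0.3 cycles) on the target Ct, n = 3 per group.  Default
  planted folds (779.78, 29.26, 3.64, 1.02, 0.03) span the magnitudes
  printed for strongly derepressed, moderately derepressed, unchanged and
  repressed targets in this kind of knockout comparison.

Each generator derives its own random stream from the master seed by a
fixed label, so outputs are byte-identical across reruns and adding a
generator never perturbs another — the determinism contract is itself
tested.

What the generator does *not* emulate: read-level data (no FASTQ/BAM),
chromatin-driven background structure (background peaks and sequence are
uniform), overlapping genes, amplification-efficiency variation in qPCR,
and any dependence between motif content and binding strength.  Passing
tests therefore demonstrate that the pipeline's arithmetic and matching
semantics are correct under known structure — not that a peak caller's
output on real chromatin satisfies the generators' independence
assumptions.

## Numerical choices and degenerate inputs

* Tag counts and coordinates are integers; RPKM and fold changes are
  doubles; planted-recovery tests assert relative error below 1e-12 where
  the arithmetic is exact.
* Ties are always broken deterministically (lexicographic accession or
  symbol, leftmost interval), so every operation is reproducible.
* Empty inputs: summaries over empty cohorts are errors (a percentage of
  nothing is meaningless); matching against an empty replicate returns an
  empty consensus.
* Percent rounding: location percentages to one decimal; status
  percentages to integers, computed from raw counts.

## Problem sizes

The shipped tests and the reproduction script run on desk-scale cohorts —
hundreds of peaks, ~100 genes, 1066 peak sequences, 2000 Monte-Carlo
repeats for the t-test level — sizes at which the brute-force oracles
(all-pairs matching, position enumeration over 100 kb) remain exact and
fast.  Genome-scale inputs (tens of thousands of peaks, full RefSeq) use
the same code paths; matching and annotation are per-chromosome and scale
linearly in peaks times genes per chromosome.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
dir <- tempfile()
sim <- simulate_inputs(cfg, dir)
run <- run_pipeline(list(
  rep1 = sim$files[["rep1"]], rep2 = sim$files[["rep2"]],
  gene_models = sim$files[["gene_models"]], polii = sim$files[["polii"]],
  library_size = cfg$library_size,
  fasta = sim$files[["fasta"]], ct = sim$files[["ct"]]),
  outdir = file.path(dir, "out"))
print(run)
```

## Known limitations

* Exactly two replicates; no irreproducible-discovery-rate analysis.
* No read-level processing: peak calling, alignment and pileups are
  upstream of this package.
* Consensus motif matching only (IUPAC strings); PWM scoring is not
  implemented, and motif significance is out of scope.
* No multiple-testing correction in the qPCR stage (none is conventional
  for small targeted panels); users testing many targets should adjust
  p-values themselves.
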