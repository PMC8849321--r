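---
title: "Methods: binding-site classification, motif affinity, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site classification, motif affinity, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pioneerbind analyzes what happens when a candidate pioneer transcription
factor (FOXA1) and a partner factor (HNF4A) are ectopically expressed,
alone and together, in a cell type where neither is active. This vignette
documents the models and procedures, the parameters that matter, the
synthetic-data generator that provides ground truth, and the numerical and
design choices made where the problem left them open.

## Coordinate conventions and peak handling

All intervals are 0-based half-open, the BED convention; two intervals
overlap iff they share at least 1 bp (`a.start < b.end && b.start < a.end`),
so abutting peaks do not overlap. Interval algebra is backed by IRanges.

**Replicate merging.** Reproducible peaks are derived by pooling the two
replicates, clustering by transitive ≥1-bp overlap, and keeping the union
span of every cluster supported by at least one peak from each replicate.
This is a deliberately transparent substitute for model-based replicate
analysis: it makes the merge a pure interval operation that an independent
connected-component oracle can verify. The same cluster-and-span rule, with
the two factors' double-expression tracks in place of replicates, defines
co-bound sites, so co-bound coordinates are union spans too. Nothing in the
merge fixes output coordinates more finely than this; the union span is a
package choice.

**Accessibility, opening, taxonomy.** A bound site is *accessible* iff it
overlaps the merged uninduced ATAC set, and *opened* iff it was inaccessible
and overlaps the merged induced set — opening is defined only for previously
inaccessible sites. A co-bound site is FP if it overlaps the FOXA1-alone
track but not the HNF4A-alone track, HP symmetrically, BOTH if both, CB if
neither; the four labels partition the co-bound set.

**ChromHMM composition.** Each site is assigned to the chromatin-state
segment with maximal bp overlap; ties go to the segment with the leftmost
start (a deterministic tie-break; the underlying data rarely produce ties
because real segmentations tile the genome). Sites with no overlapping
segment are reported as `unassigned` so per-class fractions always sum to 1.

**Gene attribution.** A peak belongs to a gene iff it overlaps
`[tss - h, tss + h)` with `h` = 25 kb for single-factor sites and 50 kb for
co-bound sites (co-binding is rarer, so the window doubles). The window is
strand-independent — a symmetric window cannot depend on strand — and a peak
may be attributed to several genes.

**Analysis windows.** Motif analyses use 500 bp centered on the site
midpoint, `mid = start + floor((end - start)/2)` (floor for odd lengths).
The midpoint is used rather than a summit because the merge step emits no
summits. Windows are clipped at chromosome boundaries with a warning rather
than rejected.

## Motif model

PWMs are parsed from JASPAR PFM text; each count column gets a pseudocount
(default 0.1 per cell, the FIMO convention) and is normalized to
probabilities. The background is uniform by default; both are configurable.
A window scores `sum_i log2(p_i(x_i)/b(x_i))` bits; windows containing
non-ACGT bases are skipped, not scored against the background.

**Exact p-values.** Per-position scores are integerized at a granularity of
1000 bins/bit (default; anything ≥100 is accepted) and the null pmf of the
integerized window score under the background is computed by exact
convolution across positions. Zero-probability bases score −Inf; their mass
is tracked separately and such windows carry p-value 1. The scanner uses the
same integer grid, so scan p-values are exactly the null's tail values —
the test suite checks the pmf against exhaustive enumeration of all `4^w`
windows for widths ≤ 8. Scanning covers both strands; overlapping hits and
same-position two-strand hits are all retained (again the FIMO default).

**Aggregate affinity score.** The "summed motif content" of a window is
`sum max(0, S)` over all PWMs, strands, and offsets. Summing *thresholded*
scores at a p-value threshold of literally 0 would admit nothing, so the
package operationalizes "allow weak contributions" by clipping at background
odds: every offset scoring above background contributes, however weakly, and
the score is finite and monotone in motif content. The alternative reading —
counting hits at a relaxed p-value threshold — is available via
`mode = "relaxed_count"`; both are exposed because the choice is genuinely
open, and the combined two-factor variant simply passes both PWMs.

**ROC.** The classifier is a bare threshold on the aggregate score, swept
over the union of observed scores (ties form one step); AUC is the
trapezoidal area, which equals the normalized Mann–Whitney U — an identity
the tests assert to 1e-12. Negative sets are drawn 1:1 with the positives
(the balance is unstated in the underlying design, so 1:1 is the package's
documented choice), uniformly over positions whose window avoids the
accessible set and is <10% non-ACGT. FP-vs-CB and HP-vs-CB comparisons use
the single relevant factor's PWM.

## Expression model

The differential stage is deliberately transparent rather than a
reimplementation of a shrinkage-based NB model: genes with <10 total reads
are dropped, columns are scaled by median-of-ratios size factors, and the
fold change is `log2((induced + 1)/(uninduced + 1))` on condition means (the
pseudocount keeps zero baselines finite). A per-gene table produced by an
external differential tool can be substituted as long as it carries the same
fields; when it includes `padj`, activation calls additionally require
`padj <= 0.05`, otherwise calls are threshold-only — the activation rules
themselves are explicit thresholds (`log2FC >= 1`, uninduced mean `< 50`),
and the synthetic effects are planted far from both so calls are robust to
the estimator.

Tissue enrichment follows the fourfold rule (own tissue ≥ 4× the maximum
elsewhere, boundary inclusive; a gene expressed only in the tissue of
interest counts, an all-zero gene does not). The enrichment universe is the
set of genes surviving the 10-read filter — the genes that *could* have been
called — not the full annotation; the report exposes all four hypergeometric
arguments (`k, K, n, N`) rather than fixing any of them. The upper-tail
p-value comes from `phyper` in log space, so genome-scale arguments cannot
underflow.

## The synthetic benchmark

The generator's defaults define the reference conditions; they are chosen
once and every test and the acceptance script runs against them.

* Genome: two 2-Mb chromosomes, i.i.d. bases at GC 0.41. A toy genome by
  design — no repeats, isochores, or assembly gaps.
* Sites: 1,640 disjoint 500-bp windows on a shuffled 2-kb grid: 202 FP,
  340 HP, 379 BOTH, 219 CB (proportional to the observed genome-wide
  2023/3398/3789/2192 split), 100 of each single-factor
  accessible/inaccessible class, 100 background.
* Motif multiplicities: FOXA1 2–4 and HNF4A 3–6 at the factor's own
  pioneered/inaccessible sites, 1–2 / 1–3 at accessible sites, 0–1 each at
  CB sites, 0 at background. Instances are sampled per column from the PWM
  (so score distributions are realistic), written at non-overlapping random
  offsets on random strands; a consensus-forcing mode exists so exact
  string-match oracles can verify the ledger. Accessible sites get fewer
  motifs than inaccessible ones on the affinity rationale the pipeline is
  designed to probe: binding already-open chromatin needs less affinity.
* Peaks: a site's window becomes a peak in every track its class implies;
  co-bound classes are planted inaccessible-then-opened (they appear in
  induced but not uninduced ATAC). Per replicate, boundaries are jittered
  (Gaussian, sd 10 bp) and peaks dropped with probability 0.01. The dropout
  default was set by arithmetic, before any end-to-end run, from the
  multi-track structure of the labels: a co-bound site's full label depends
  on up to three merged tracks, each retained with probability
  `(1 - dropout)^2`, so 1% dropout yields ~98% per-track retention and
  ~96% expected per-site full-label fidelity, keeping the benchmark's
  planted signal dominant while still exercising the reproducibility filter.
  Real CUT&Tag replicates are far noisier; this generator models
  post-QC peak calls, not raw replicate discordance.
* Counts: 3+3 samples, NB with size 10; non-target genes draw log-normal
  baselines around mean 200 shared across conditions; the 60 planted
  activated genes sit at uninduced mean 5 (well under the 50-read ceiling)
  with a planted log2 fold change of 3. With `activated_lfc = 0` the truth
  set is empty and the simulation is null.
* Tissue table: per-gene log-normal base levels times per-tissue multipliers
  in [0.8, 1.25], so no unplanted gene can reach fourfold enrichment
  (multiplier ratio < 1.6); truth genes' own-tissue value is set to exactly
  `tissue_fold ×` their maximum elsewhere. Values are rounded to a 6-decimal
  grid so the planted boundary relation survives text round-trips exactly
  (scaling a decimal by the default fold of 4 is binary-exact).
* Reproducibility: one master seed; each stage derives a fixed offset seed
  (genome +101, sites +202, peaks +303, counts +404, tissue +505, genes
  +606, activated-gene choice +707) with a documented draw order inside each
  stage, so stages are bit-reproducible both standalone and in the pipeline.

**What passing the benchmark does and does not show.** The generator plants
exactly the structure the pipeline assumes: disjoint fixed-width sites,
independent background sequence, noise limited to boundary jitter and peak
dropout. Recovery on this benchmark validates the *logic* — the overlap
rules, the taxonomy, the calibration of the scanner, the threshold
classifier — not the pipeline's behavior on real data, where peaks vary in
width, motifs cluster in repeats, accessibility is graded rather than
binary, and expression noise is structured.

**Recovery metric.** Ledger recovery is scored per planted bound site: the
site must be found (by window overlap) in the tracks its class requires, and
all of its labels must match. Sites lost to dropout cannot be classified at
all and are excluded from the accuracy denominator; the recovered fraction
is reported alongside so neither number hides the other. Noise-free runs
recover 100% of sites with 100% label accuracy.

## Problem sizes and runtime

The default conditions (4 Mb genome, 1,640 sites, 5,000 genes) were sized so
a full simulate-plus-analyze cycle completes in about a minute: large enough
that the co-bound class mix, the 60-gene activation set, and 500+ windows
per ROC side give stable statistics, small enough for routine reruns. The
test suite uses a reduced configuration (0.4 Mb, 145 sites, 300 genes) for
pipeline mechanics and reserves the full configuration for the end-to-end
validation tests.

## Known limitations

* The accessibility and opening calls are binary overlap decisions; no
  signal-level (read-count) model of differential accessibility is included.
* The differential-expression stage estimates fold changes without
  dispersion shrinkage or significance testing unless an external table
  supplies `padj`.
* The scanner's null assumes an i.i.d. background; no higher-order
  background models or q-values.
* Random negative windows are drawn with replacement (independent draws), so
  at extreme densities two negatives can overlap.
* The shipped PFMs are synthetic stand-ins (a forkhead-like and a DR1-like
  motif) with the dominant-base structure of the real matrices; analyses of
  real data should supply the actual JASPAR matrices as files.
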