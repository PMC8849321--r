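# pioneerbind

Peak-level analysis of ectopic pioneer transcription-factor activity.

When a putative pioneer factor such as FOXA1 and a partner factor such as
HNF4A are expressed in a naive cell type, three questions decide between the
classical pioneer-factor model and an affinity-based alternative:

1. **Where does each factor bind relative to pre-existing chromatin
   accessibility?** A binding site is *accessible* if it overlaps an
   uninduced ATAC peak, *inaccessible* otherwise, and *opened* if it was
   inaccessible but overlaps an induced ATAC peak.
2. **Who pioneers co-bound sites?** A co-bound site (overlapping FOXA1 and
   HNF4A peaks in the double-expression condition) is classified *FP*
   (FOXA1-pioneered: FOXA1 also binds it when expressed alone), *HP*
   (HNF4A-pioneered), *BOTH*, or *CB* (cooperatively bound: neither factor
   binds alone).
3. **Does motif content predict binding?** If "pioneering" is just
   high-affinity binding, inaccessible bound sites should carry more motifs
   than accessible ones and than random inaccessible sequence, and a bare
   threshold on summed motif content should discriminate bound from random
   windows.

pioneerbind implements the full pipeline behind these questions —
replicate peak merging, the accessibility/opening and FP/HP/BOTH/CB
classifications, ChromHMM state composition, activation calls on RNA-seq
counts with cumulative hypergeometric tissue enrichment, FIMO-style PWM
scanning with exact null p-values, and threshold-sweep ROC analysis — plus a
synthetic-data generator that plants all of this structure with known ground
truth, so every stage can be validated end to end.

## The core quantities

**Motif scan.** A PWM of width *w* scores a window `x_1..x_w` by
`S = sum_i log2(p_i(x_i) / b(x_i))` (bits). Per-position scores are
integerized at 1000 bins/bit and the exact null distribution of `S` under
the background is obtained by convolving the per-position distributions, so
every hit's p-value `P(S >= s)` is exact rather than sampled. Scanning runs
over both strands and reports hits at `p <= 1e-3`.

**Aggregate affinity score.** The "summed motif content" of a 500-bp window:
`A = sum over PWMs, strands, offsets of max(0, S_offset)`, so weak motifs
contribute and motif-free sequence contributes ~0. A threshold on `A` swept
over observed scores yields the ROC curve; the AUC equals the normalized
Mann–Whitney U statistic.

**Activation.** Counts are normalized by median-of-ratios size factors;
genes with < 10 total reads are dropped; a gene is *activated* when
`log2FC >= 1` and its uninduced normalized mean is `< 50`.

**Tissue enrichment.** A gene is tissue-enriched if its expression is at
least fourfold its maximum in any other tissue. For `k` tissue-set genes
among `n` activated draws from a universe of `N` containing `K` set genes,
the enrichment p-value is the cumulative hypergeometric upper tail
`P(X >= k)`, computed in log space.

**Gene attribution.** Binding sites are attributed to a gene if they overlap
±25 kb of its TSS (±50 kb for co-bound sites).

## Worked example

Simulate a small dataset with planted ground truth and analyze it:

```r
library(pioneerbind)
cfg <- sim_config(seed = 42,
  chrom_sizes = c(chr1 = 400000L, chr2 = 400000L),
  n_genes = 1000,
  site_plan_counts = c(FP = 40, HP = 60, BOTH = 70, CB = 40,
    FOXA1_accessible = 20, FOXA1_inaccessible = 20,
    HNF4A_accessible = 20, HNF4A_inaccessible = 20, background = 20),
  n_activated = 25)
sim <- run_simulate(cfg, "demo_data")
res <- run_analyze("demo_data", "demo_results", run_config(seed = 42))

table(res$cobound$cobind_class)
#> BOTH   CB   FP   HP
#>   65   44   38   58
```

The recovered taxonomy tracks the planted 40/60/70/40 mix; the differences
are replicate-dropout noise — a peak lost from a single-expression track
demotes an FP/HP/BOTH site toward CB, and a peak lost from a
double-expression track removes the site from the co-bound set entirely.

```r
res$enrichment[res$enrichment$tissue == "liver", ]
#>   tissue set_size n_activated universe observed expected       pvalue log10_pvalue
#> 1  liver       25          25     1000       25    0.625 2.098994e-50    -49.67799
```

All 25 planted liver genes are recalled as activated against an expectation
of 0.625 by chance.

```r
res$motif_summary[res$motif_summary$group %in%
                    c("foxa1_fp", "hnf4a_hp", "foxa1_cb", "random_foxa1"), ]
#>          group   n   q1 median q3 whisker_lo whisker_hi
#> 1     foxa1_fp  38 2.00      3  4          1          6
#> 2     hnf4a_hp  58 5.25      6  8          3         11
#> 3     foxa1_cb  44 0.00      1  2          0          4
#> 9 random_foxa1 146 0.00      1  1          0          2
```

FOXA1-pioneered sites carry a median of 3 FOXA1 motifs versus 6 HNF4A motifs
at HNF4A-pioneered sites, and cooperative (CB) sites look like random
sequence — the planted multiplicity structure read back through the scanner.

```r
res$rocs$foxa1_inaccessible_vs_random
#> ROC: AUC = 0.9419 (126 positives vs 126 negatives, 193 thresholds)
res$rocs$foxa1_accessible_vs_random
#> ROC: AUC = 0.7550 (20 positives vs 20 negatives, 40 thresholds)
```

Motif content predicts inaccessible binding well and accessible binding less
well. Finally, `res$recovery` scores the classification against the planted
ledger (here 97.9% of sites recovered, 95.8% with all labels correct under
default noise; a noise-free run returns 100/100).

A thin command-line wrapper with `simulate` / `analyze` / `report`
subcommands is installed at `inst/scripts/pioneerbind-pipeline.R`.

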