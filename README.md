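# tadakit

Analysis of **Targeted DamID (TaDa)** binding profiles and **CaTaDa**
chromatin accessibility, from aligned read positions to normalized
GATC-fragment profiles, replicate-consistent broad peaks,
binding-pattern clusters, peak–gene annotation, and enrichment
statistics linking binding to differential expression.

## The problem

In DamID, a protein of interest fused to *E. coli* Dam methylase marks
its binding sites with adenine methylation at GATC motifs; methylated
GATC-to-GATC fragments are amplified and sequenced. Targeted DamID
drives the fusion at trace levels from a cell-type-specific promoter,
giving *in vivo*, cell-type-resolved binding maps from small cell
numbers — e.g. NOTCH and RBPJ binding in radial glial cells (RGCs)
versus intermediate progenitors (IPCs) of the embryonic cortex.
Untethered Dam ("Dam-only") preferentially methylates accessible
chromatin, so the control channel doubles as an accessibility assay.

`tadakit` implements the complete downstream analysis for such
experiments:

1. **GATC coordinate backbone** — fragments delimited by GATC motifs
   (`gatc_fragments()`), fixed-width bins (`fixed_bins()`).
2. **Profiles** — per 300 bp bin, `r = log2((fusion_RPM + c) /
   (Dam_RPM + c))`, projected onto GATC fragments by length-weighted
   mean; replicate profiles quantile-normalized, averaged on log2 scale
   and backtransformed to a linear track with midline 1
   (`compute_ratio()`, `quantile_normalize_profiles()`,
   `average_backtransform()`); Dam-only RPM as accessibility
   (`accessibility_profile()`).
3. **Peaks** — Poisson broad caller per fusion × Dam-only pair with
   Benjamini–Hochberg control at FDR < 1e-5, gap merging, and
   base-level intersection across all replicate pairs
   (`call_broad_peaks()`, `replicate_consistent_peaks()`).
4. **Binding patterns** — consensus peaks across constructs, z-scored
   length-normalized intensity matrix, silhouette-optimized k-means
   (`merge_consensus()`, `intensity_matrix()`, `select_k()`).
5. **Annotation & enrichment** — nearest protein-coding TSS
   (`nearest_tss()`), collapsed genomic features with randomized
   overlap enrichment (`feature_overlap_enrichment()`), exact binomial
   enrichment of peak–gene associations across DE significance
   thresholds with Bonferroni correction (`enrichment_curve()`), and
   hypergeometric gene-set overlaps with a sampled random-gene null
   (`hypergeometric_overlap()`, `sampled_overlap_null()`).
6. **Metaplots** — peak-centered signal matrices with exclusion masks,
   average ± s.e.m. profiles, Kruskal–Wallis + pairwise Wilcoxon
   accessibility comparisons (`signal_matrix()`, `average_profile()`,
   `compare_accessibility()`).
7. **Synthetic data** — a generator planting 8 binding archetypes,
   accessibility states, replicate noise and DE ground truth
   (`sim_config()`, `simulate_experiment()`), so the whole pipeline is
   validated end to end without downloads.

See `vignettes/tadakit-methods.Rmd` for the models, parameters and
design decisions.

## Worked example

Simulate the default study (2 × 1 Mb genome, 400 planted sites over 8
archetypes, NOTCH/RBPJ × RGC/IPC plus Dam-only, 3 replicates at 5×10^5
reads) and run the full analysis:

```r
library(tadakit)

cfg <- sim_config(seed = 7)
sim <- simulate_experiment(cfg)
analysis <- run_tada_analysis(sim)

recovery <- evaluate_peak_recovery(analysis, sim$truth)
cat(sprintf("peak recovery: sensitivity %.3f, precision %.3f\n",
            recovery$sensitivity, recovery$precision))
#> peak recovery: sensitivity 0.940, precision 1.000

analysis$k_selection$k
#> [1] 8
```

The silhouette criterion peaks at the eight planted binding archetypes
(`mean_silhouette` 0.797 at k = 8 vs 0.758 at k = 7 and 0.792 at
k = 9), and the k-means partition matches the planted archetype labels
with an adjusted Rand index of 0.895. Linking the recovered
constitutive-binding cluster (the analogue of NOTCH+RBPJ sites bound in
both cell types) to the simulated differential-expression table:

```r
cmap <- cluster_archetype_map(analysis, sim$truth)
tss <- truth_tss_table(sim$truth)
assoc <- nearest_tss(
  analysis$consensus[analysis$clusters$cluster == which(cmap == 6)[1]], tss)
curve <- enrichment_curve(list(cluster6 = assoc), sim$de)
curve[curve$threshold == 1e-5, ]
#>   peak_set threshold   N  S  n  k        p_raw        p_adj
#> 5 cluster6     1e-05 300 63 42 35 1.034949e-17 1.034949e-16
```

Of `n = 42` peak–gene associations, `k = 35` hit genes differentially
expressed at q < 1e-5 (against `S = 63` of `N = 300` genes genome-wide
— a background rate of 0.21), giving a Bonferroni-adjusted binomial
enrichment p of ~1e-16: the planted association between constitutive
binding and RGC-specific expression is recovered.

A thin command-line wrapper over the same functions ships in
`inst/scripts/tada.R` (subcommands `index`, `simulate`, `normalize`,
`catada`, `callpeaks`, `cluster`, `annotate`, `exprlink`, `metaplot`);
every stage is byte-reproducible given the same seed.

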