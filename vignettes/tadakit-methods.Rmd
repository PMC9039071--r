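---
title: "tadakit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tadakit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tadakit` analyses Targeted DamID (TaDa) experiments: a DNA-binding
protein fused to *E. coli* Dam methylase deposits adenine methylation at
GATC motifs near its binding sites; methylated GATC-to-GATC amplicons
are sequenced, and binding is read out as the ratio of Dam-fusion to
Dam-only (untethered Dam) signal. Untethered Dam preferentially
methylates accessible chromatin, so the Dam-only channel doubles as a
chromatin accessibility readout (CaTaDa). This vignette documents the
models, the tunable parameters and the design decisions; the README
shows a worked example.

## Coordinate backbone: GATC fragments

The native resolution of DamID is the *GATC fragment*, the interval
between two successive GATC motifs. `gatc_fragments()` tiles each
chromosome with boundaries at `{start} U {motif starts} U {end}`. A
motif is assigned to the fragment it *begins*: DamID reads start at the
cut GATC, so 5' read positions fall at fragment starts. The upstream
processing pipelines this package interoperates with do not state their
motif-to-fragment assignment; ours is declared, not inferred. Motif
instances containing `N` are not motifs; `N` runs are ordinary
sequence. Internally all intervals are 1-based closed `GRanges`; every
on-disk format (BED, bedGraph) is 0-based half-open.

## Binding profiles

Per sample, read 5' positions are counted into 300 bp bins and
RPM-normalized (reads per million mapped; `rpm_normalize()`). For each
Dam-fusion x Dam-only replicate pair,

```
r(bin) = log2( (fusion_RPM + c) / (control_RPM + c) )
```

with pseudocount `c = 0.5` RPM added to both numerator and denominator.
The pseudocount value is not dictated by the upstream convention, so it
is a declared default: 0.5 RPM bounds the log ratio on zero-count bins
while preserving sign symmetry (swapping fusion and control negates
`r`). Each GATC fragment then receives the length-weighted mean of `r`
over the 300 bp bins it overlaps — a deterministic, resolution-preserving
projection chosen because the per-bin ratio and the per-fragment
reporting conventions must be bridged somehow and the weighted mean is
the conservative option.

All pair profiles of one construct are quantile-normalized to each
other (classic rank-mean normalization; ties receive the mean of the
reference values at the tied ranks — `limma::normalizeQuantiles` with
`ties = TRUE`, cross-checked in the test suite against an independent
rank-averaging oracle). Profiles are then averaged fragment-wise on the
log2 scale and backtransformed (`2^mean`, i.e. a geometric mean on the
linear scale), giving a linear track with midline 1.

Replicate pairing is the full cross product: every fusion replicate
against every Dam-only replicate of the matching cell type, both for
ratio profiles and for peak calling.

## Accessibility profiles

`accessibility_profile()` reports Dam-only RPM per GATC fragment.
"Non-normalized" accessibility means *not ratio-normalized against a
fusion sample*; depth (RPM) scaling is still applied. Whether replicate
accessibility tracks should additionally be quantile-normalized to each
other is an open choice; both behaviours are supported
(`quantile_norm = TRUE` by default, mirroring the treatment of ratio
profiles), with averaging on the linear scale.

## Broad peak calling

`call_broad_peaks()` is a self-contained Poisson broad caller with the
interface of the usual external tools (an adapter, `read_broadpeak()`,
accepts externally produced peak files). Per 300 bp bin the local rate
is the Dam-only count scaled to the fusion depth, floored at the
genome-wide mean fusion rate; the p-value is the upper-tail Poisson
probability of the fusion count; q-values are Benjamini-Hochberg across
all bins. Significant bins (`q < 1e-5` by default — a deliberately
stringent threshold) merge across gaps up to `max_gap = 900` bp; peaks
shorter than 300 bp are dropped. Because the Dam-only control is a
matched local background, no multi-scale lambda windows are used.

Replicate consistency: a peak is kept only if present in **all**
pairwise fusion x control comparisons of one condition.
"Present in all" is read strictly as base-level intersection (a genomic
base survives iff covered in every comparison); a laxer
union-of-overlapping-peaks mode is available via `mode = "overlap"`.

## Binding-pattern clustering

Peaks from all constructs merge into consensus peaks (overlapping or
book-ended intervals; merge distance 0, configurable). The intensity of
construct `c` at consensus peak `j` is the length-normalized signal
`sum(overlap_bp x linear score) / peak_length` — per-bp mean signal,
the natural reading of "normalized for length". Columns (constructs)
are z-scored. k-means (Euclidean on z-scores, Lloyd iterations capped
at 300, best of `n_init = 25` restarts under a deterministic derived
seed stream, clusters relabeled by descending size) is run for
`k = 2..12` and the k with the highest mean silhouette width is chosen,
ties toward smaller k. Silhouette is the single declared selection
criterion; the search range 2..12 comfortably brackets the eight
planted binding archetypes of the simulator. Note `cluster::silhouette`
needs the full distance matrix — fine at thousands of consensus peaks,
quadratic beyond that.

## Peak-gene annotation and feature overlap

`nearest_tss()` assigns each peak the protein-coding TSS minimizing the
linear-genome distance: 0 if the TSS lies inside the peak, otherwise
the distance to the nearer peak edge (0-based start for upstream TSSs,
exclusive end for downstream; sign positive downstream). Equidistant
TSSs resolve to the lexicographically smallest gene id — an explicit,
reproducible tie-break. Edge distance (not midpoint distance) is used.

`build_features()` collapses transcript models into feature categories
(5 kb strand-aware upstream windows, UTRs, exons, introns, intergenic);
categories are collapsed internally but may overlap each other.
`feature_overlap_enrichment()` compares the observed percent of peak
bases in each category with a randomization null that re-places every
peak uniformly within its own chromosome (length-preserving, overlaps
allowed, whole chromosomes as workspace). This is a simplification of
segment-aware annotation samplers, adequate for whole-chromosome
workspaces; the empirical p uses the add-one rule and is never 0. The
default `n_samples = 10000` is a desk-scale default (raise it for
publication-grade resolution).

## Linking binding to differential expression

Since several peaks can hit the same gene, peak-gene associations
falling on significantly differentially expressed genes are modelled as
binomial: with `S` of `N` genes significant at threshold `t` (in the
requested direction) and `k` of `n` associations on significant genes,
the enrichment p-value is the exact upper tail `P(X >= k | n, S/N)`.
The equivalent phrasing as a lower-tail test on the non-significant
association count (`P(X <= n-k | n, 1-S/N)`) is *identical* by tail
complementarity — both are implemented and tested equal, so the choice
of phrasing is cosmetic. Direction matters: tests are run separately
per direction of the cell-type contrast, each against its own `S`.
Genes absent from the DE table are dropped from both `n` and `k`.

`enrichment_curve()` repeats the test over a threshold grid (decade
steps `1e-1..1e-10` by default) and peak sets, Bonferroni-adjusting
over all tests of the call. Gene-set overlaps are additionally modelled
as hypergeometric (`hypergeometric_overlap()`, upper tail), with
`sampled_overlap_null()` providing the matching empirical null (random
gene draws without replacement, 1000 iterations by default).

Calibration note: the exact binomial tail is discrete and conservative,
so its null p-values are stochastically *larger* than uniform. A
two-sided uniformity test would reject on discreteness alone; the
meaningful calibration check — implemented in the test suite — is
one-sided: no excess of small p-values (empirical CDF never
significantly above the diagonal), plus an explicit bound on the
rejection rate at 0.05.

## Metaplots and group comparisons

`signal_matrix()` samples a profile in fixed windows (default 150 bp
bins over ±2.5 kb) around region midpoints; scaled-body mode is not
implemented. Windows running past a chromosome end are missing values,
excluded from averages with per-column n. Regions overlapping an
exclusion list are dropped entirely (stricter than masking columns) —
the use case is removing loci whose signal is artefactual, e.g.
mitochondrial DNA or promoter fragments present on the transfected
plasmids, and a partially masked region would still leak such signal.
`average_profile()` reports mean ± s.e.m. per position;
`compare_accessibility()` runs Kruskal-Wallis across cell-type groups
with post-hoc pairwise two-sided Wilcoxon tests, Holm-adjusted (Holm is
the conventional default for that post-hoc procedure).

## The synthetic study

`sim_config()` defines the simulated study the test-suite validates
against; its defaults are the study conditions, not tuning knobs:

* 2 chromosomes x 1 Mb; GATC motifs planted at exponential gaps of
  mean 256 bp (chance 4-mers add further motifs, as in real genomes);
* 400 planted binding sites over 8 archetypes (equal proportions),
  with 300 genes;
* binding effect `beta = 6`: expected methylation at a fully occupied
  open site is 6x the unbound level;
* accessibility states open = 1.0 / reduced = 0.3;
* 3 replicates per sample at 5e5 reads, log-normal depth jitter
  (sd 0.1) so quantile normalization is exercised non-trivially;
* DE tables: the gene nearest each archetype-6 site is RGC-specific
  with probability 0.8 against a 0.1 background; RGC-specific genes
  draw effect ~ N(2, 0.5) and q = 10^-U(5,20), null genes effect ~
  N(0, 0.3), q ~ U(0.1, 1).

Expected reads per fragment are `length x accessibility(cell type) x
(1 + (beta-1) x occupancy)` for fusions (occupancy term absent for
Dam-only); counts are Poisson; read 5' ends sit at GATC fragment
boundaries, alternating ends with matching strand — DamID amplicons
span GATC to GATC, and the paper trail for a finer read model does not
exist, so the simplest boundary model is declared.

Two structural choices deserve emphasis:

1. **Planted sites are GATC-delimited and grid-aligned.** Sites carry
   planted GATC motifs at both edges and are aligned to the 300 bp
   analysis grid (widths 900/1200/1500 bp, >= 2 kb apart). Ground truth
   is then unambiguous at the caller's native resolution, making
   base-level sensitivity/precision well-defined quantities rather than
   artefacts of partial bins. Real peaks are not grid-aligned;
   recovery numbers on real data would be correspondingly fuzzier.
2. **Archetypes sharing a binding pattern differ by intensity tier.**
   The fusion/Dam-only ratio cancels accessibility by construction
   (both channels scale with it), so "RBPJ-only in RGCs, open" and
   "RBPJ-only in RGCs, reduced accessibility" are indistinguishable in
   ratio space at equal occupancy. The generator therefore separates
   them by occupancy tier (archetype 5 at 0.6, archetype 8 at 1.0),
   and models archetype 8 as constitutive RBPJ sites that retain full
   binding in RGCs but lose accessibility upon differentiation to IPCs
   — which is also where the accessibility contrast is planted and
   measured. Tiers 0.7/1.0/0.4 distinguish archetypes 2/6/7. The
   low tier (0.4, i.e. linear ratio 3) is the detection floor at these
   depths: below it, sites fail the stringent FDR in some replicate
   pairs and the consistency intersection removes them.

What the simulator does **not** emulate: mappability and GC bias,
plasmid methylation background, fragment-length biases of the DamID
PCR, overdispersion beyond Poisson, correlated replicate artefacts, and
real gene structure (genes are TSS points; transcript models for
feature-overlap analyses are exercised with hand-built fixtures
instead). Passing recovery tests therefore demonstrates correctness of
the analysis logic under the declared generative model, not performance
on real libraries.

## Problem sizes and determinism

The shipped validation runs the full default study (18 samples x 5e5
reads on a 2 Mb genome, ~16,000 GATC fragments) in a couple of minutes
on one CPU; unit fixtures are smaller. All randomness flows from
explicit seeds: per-sample seeds derive deterministically from the
config seed, k-means restarts use a prefix-stable derived seed stream
(so more restarts can only improve the best WCSS), and every CLI stage
rerun with the same seed produces byte-identical files (numeric output
is serialized with `%.17g`, which round-trips doubles exactly).

## Known limitations

* The Poisson caller has no overdispersion term; on real data the
  Dam-only control absorbs most biological variance, but a
  negative-binomial extension would be the first upgrade.
* `select_k` trusts the silhouette criterion alone; on data without
  clear archetype structure it will still return *some* k. Inspect the
  full silhouette table it returns.
* Base-level intersection across many replicate pairs is strict; with
  noisy replicates consider `mode = "overlap"`.
* The feature-overlap null ignores chromosome composition beyond
  length; do not use it with workspaces narrower than whole
  chromosomes.
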