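---
title: "Methods: valley-guided discovery of temporal transcription-factor regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valley-guided discovery of temporal transcription-factor regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valleytf)
```

## The problem

Stimulated immune cells — the motivating system is LPS-stimulated mouse
bone-marrow-derived macrophages — mount a transcriptional program in which
hundreds of genes follow distinct temporal expression trajectories, each
presumably driven by a distinct combination of transcription factors (TFs).
Identifying those TFs from sequence alone is hard: promoter scanning ignores
the epigenetic state that decides which binding sites are actually
accessible, and correlating TF transcript levels with target expression
misses TFs that are regulated post-translationally.

`valleytf` implements an epigenome-guided alternative. Histone acetylation
(HAc) marks open, active chromatin, and functional TF binding sites
concentrate in local *valleys* — dips of roughly 100 bp — within otherwise
strongly acetylated regions, where bound factors displace or exclude
nucleosomes. Scoring TF binding-site (TFBS) motif enrichment inside
valley-defined regions near each gene's transcription start site (TSS), at
each time point of a stimulation time course, yields a per-motif *temporal
binding propensity* signal. Correlating that signal, with a physiologic
time lag, against the median expression of each temporal gene cluster
nominates TFs as activators or repressors of the cluster.

## Valley detection

The HAc ChIP-seq signal is point-sampled on a 10 bp grid (reads are first
deduplicated and 3'-extended by 122 bp when coverage is built from
intervals). The track is then smoothed by discrete convolution with a
Gaussian kernel of standard deviation $\sigma = 40$ bp. For every sample
point $i$, let $L_i$ and $R_i$ be the maxima of the smoothed signal in the
windows 50–500 bp to the left and right. Point $i$ is a **valley point**
when

$$ v_i < 0.7 \cdot \min(L_i, R_i), $$

with a strict inequality, and its **valley score** is $\min(L_i, R_i)$;
elsewhere the valley-score signal is zero. Runs of consecutive valley
points are merged into one reported interval (one dip spans many 10 bp
points), scored by the maximum point score in the run.

Numerical choices:

* the kernel is truncated at $\pm 4\sigma$ (tail mass below $10^{-4}$) and
  renormalized;
* convolution edges use local kernel-mass renormalization, so a constant
  track is reproduced exactly at chromosome ends and total mass is
  conserved away from boundaries;
* down-sampling to the grid precedes smoothing; the two orders are nearly
  equivalent for $\sigma \gg$ step, and sampling first makes the smoothing
  cost independent of read depth;
* a point whose left or right window contains no sample point (chromosome
  edge) is not callable — the rule requires both flanking maxima;
* a point exactly at the threshold is *not* a valley ("less than" is
  strict);
* flanking maxima are computed with a monotonic-queue sliding-window
  algorithm (O(n), in C++); the test suite requires exact agreement with an
  exhaustive window scan.

Because the 70% rule is a ratio, valley *calls* are invariant under
rescaling of the track, and scores scale linearly — both are asserted as
properties in the tests.

The IP-versus-control mapping of acetylated regions is out of scope here:
valleys are called directly on the IP-derived track, and any user-supplied
mask of enriched regions can be applied to the calls afterwards.

## Active promoter regions

A valley becomes an **active promoter region (APR)** of a gene when it
overlaps the $\pm 5000$ bp window around the gene's TSS. Overlap by any
shared base pair qualifies (a `containment` flag switches to full
containment); a valley near two TSSs serves both genes, since no principled
tie-break exists at this window size. APR sequences are extracted
per-region and scored independently — regions are never concatenated, so no
motif placement can span two regions.

## Motif enrichment scoring

TFBS motifs are position-weight matrices (PWMs) read from TRANSFAC flat
files or MEME minimal files; count matrices receive a pseudocount of 0.375
per cell (TRANSFAC matrices contain zeros) before normalization.

For a PWM $M$ of width $w$ and a sequence $s$ of length $L$, the **average
likelihood ratio** is

$$ \mathrm{ALR}(M, s) = \frac{1}{2(L-w+1)} \sum_{\text{placements, both strands}}
   \prod_{j=1}^{w} \frac{P_M(b_j)}{P_{bg}(b_j)}, $$

and the **raw score** of a sequence set is $\ln$ of the mean ALR over its
sequences. A PWM whose columns equal the background composition scores
exactly 0 on any input. Conventions: ambiguous bases (N) contribute a
neutral likelihood ratio of 1; reverse-strand placements use the
complemented background frequencies, which makes the score exactly
symmetric under reverse complementation even for asymmetric backgrounds;
the log base is natural (the base is a constant offset and cannot affect
any ranking); sequences shorter than $w$ are skipped with a warning.

This is the single-placement log-average-likelihood statistic of the
Clover family of tools; the original tool's multi-instance recursion is
deliberately not reproduced, and no byte-level equivalence with that
binary is claimed. The enrichment p-value is obtained by background
resampling instead: the observed raw score of a target set of $n$
sequences is compared with raw scores of $R$ random $n$-subsets of the
background set (promoters, $-1500/+500$ around the TSS, of all expressed
genes), giving $p = (1 + \#\{\text{draws} \ge \text{obs}\})/(R+1)$.
Draws are matched to the target's total length within $\pm 10\%$ whenever a
size-$n$ background subset can reach that total at all; when the length
distributions are structurally disjoint (short valley fragments versus
full-length promoters) plain subsets are drawn, since rejection could
never succeed. Background base frequencies are estimated from the
background sequences themselves.

A (motif, cluster) series is **retained** when its enrichment p is at most
0.01 at one or more time points. Retained motifs are ranked within each
cluster, by default by the score range $\max_t(\text{score}) -
\min_t(\text{score})$; highest score at any time, score at the cluster's
peak-expression time, and absolute optimal-lag correlation are available as
alternative sort keys. Ties break lexicographically by motif id.

## Expression processing

Input is a gene-by-sample matrix of log2 intensities with a sample sheet
giving each sample's time point. Genes whose maximum intensity reaches
$2^6 = 64$ (log2 of 6) form the *expressed* universe — the background for
both motif enrichment and the ChIP validation test.

Differential expression across the time course uses a one-way ANOVA F per
gene with a permutation null: each of $B$ *balanced permutations*
reassigns whole samples to time points, preserving group sizes, and is
applied to all genes at once (the exact historical permutation scheme
behind this design is not recoverable; label permutation preserving group
sizes is the standard reading and is documented as such). Per-gene p-values
are $(1 + \#\{F^{(b)} \ge F\})/(B+1)$; q-values are the plug-in empirical
FDR against the pooled permutation null, monotonized to be nonincreasing in
F and capped at 1. With a single replicate per time point F is undefined
and selection falls back, with a warning, to the fold-change criterion.

A gene is differentially expressed when $q \le 0.01$ **and** its maximum
absolute log2 fold change versus the 0 h baseline reaches $\log_2 5$; the
contrast against 0 h (rather than adjacent time points) is a documented,
configurable choice. Direction is the sign of the maximum-magnitude fold
change. Up- and down-regulated genes are clustered separately by k-means
under the correlation distance $d(x, y) = 1 - r(x, y)$: profiles are
z-scored across time, each is assigned to its most-correlated centroid, and
centroids are re-standardized member means; random restarts keep the
solution with the smallest within-cluster $\sum (1-r)$. Defaults are 5 up-
and 3 down-clusters, chosen to mirror the eight-cluster structure of the
motivating study (which does not state how k was selected); the proprietary
clustering tool used there is not reproducible, so this open, documented
algorithm stands in its place and is cross-checked against Euclidean
k-means on z-scored profiles in the tests. Cluster labels `UC*`/`DC*` are
assigned in decreasing size order.

Cluster median profiles (median and interquartile range of member fold
changes per time point) are the expression side of the correlation
analysis. The expression time grid is configurable; the default is
0/2/4/12 h (the motivating study's methods use this grid for
interpolation even though its expression results mention 1/4/12 h — the
methods grid is the one that makes the lag analysis well-defined, and the
discrepancy is noted here deliberately).

## Time-lagged correlation

Motif scores live on the ChIP time grid (0/1/2/4 h) and are **never**
interpolated; the cluster-median expression is linearly interpolated at
$t + \tau$ (no extrapolation — the 0–2 h lag range with the default grids
keeps all queries inside 0–12 h). For a lag $\tau$, $R_\tau$ is the Pearson
correlation between the four motif scores and the interpolated expression
at the four shifted times.

Three lag policies are reported per (motif, cluster): no lag
($R_{\tau=0}$); a **fixed per-cluster lag**, the $\tau$ maximizing
$\sum_{\text{retained motifs}} R_\tau^2$; and a **per-motif optimal lag**,
the $\tau$ maximizing $|R_\tau|$ (signed R reported). Maximizing $|R|$
rather than $R$ is deliberate: strong repressor candidates have large
negative correlations at positive lags. Optimization is a dense grid
search with step 0.001 h over [0, 2] h — deterministic, trivially
oracle-testable, and exact to the grid step; exact objective ties resolve
to the smallest lag. With only four paired points no correlation p-values
are attached; sorting and sign interpretation (activator for $R > 0$,
repressor for $R < 0$) are the intended uses.

## ChIP-seq validation

For a TF with ChIP-seq reads at matching time points, each cluster's
summed read count in promoter windows ($-2000/+500$ around the TSS, or the
gene's valley regions via the region-provider option) is compared with
1000 random same-size sets of expressed genes. The statistic is
$\log_2(1 + \sum \text{counts})$ — the pseudocount guards empty sums, which
the plain "log2-transformed counts" convention leaves undefined. With
$\mu$ and $s$ the mean and SD over random sets, $z = (\text{obs} - \mu)/s$
and $p = 2(1 - \Phi(|z|))$; Benjamini–Hochberg adjustment runs over all
non-degenerate (TF, time, cluster) tests in the run (the FDR family is a
documented choice). A degenerate null ($s = 0$) yields an undefined z,
excluded from the FDR. The `predicted` flag marks cells whose TF motif was
retained as enriched at that time point, and the concordance report gives
the Pearson correlation between raw motif scores and observed log-counts
split by prediction status.

## The synthetic data generator

All tests run without any external data. The generator plants known
structure at every level:

* **Genome and genes** — random sequence (configurable base composition),
  default 2 chromosomes of 2 Mbp with 200 genes whose $\pm 5$ kbp TSS
  windows are disjoint; alternating strands.
* **Clusters** — four planted temporal clusters (two up, two down, 15
  member genes each) with distinguishable shapes (early peak versus late
  rise), planted lags 0.5–2 h covering the allowed range, and both
  activator and repressor regulator roles.
* **Valleys and motifs** — each member promoter carries three upstream
  motif-bearing regulatory sites (outside the $-1500/+500$ background
  window) plus one always-open empty site near the TSS; each gene's
  promoter is a signal plateau (height 100) with Gaussian dips
  ($\sigma = 60$ bp, depth 85) at the sites that are *open* at a given
  time. A cluster's occupancy level at time $t$ is its lag-shifted median
  expression profile, min–max normalized, scaled to 0–3 open sites (and
  inverted for repressors), so the motif content of the open valleys
  tracks the planted activity. Additive Gaussian noise (default SD 10, 10%
  of the plateau) is clipped at zero.
* **Expression** — member genes follow their cluster's median fold-change
  profile with per-gene scale jitter (0.9–1.1) and log2 noise (SD 0.3, 3
  replicates, baseline intensity 8); expressed filler genes are flat;
  a configurable set stays below the intensity-64 filter.
* **TF reads** — per planted regulator and ChIP time point, ~20000 reads
  uniform over the genome plus Poisson extras over target promoters scaled
  by occupancy and a 3-fold enrichment factor.

The construction `simulate_lag_series()` used for lag calibration defines
motif scores *as* the lag-shifted interpolated expression plus noise, so
noiseless recovery is exact by construction and noisy recovery measures
the estimator, not the generator.

What the generator does **not** emulate: fragment-level sequencing noise
(errors, GC bias, mappability), replicate correlation structure,
isoform-resolved TSSs, overlapping gene neighborhoods, chromatin domains,
or motif instances of varying affinity. Passing tests therefore
demonstrate the correctness and calibration of the algorithms under the
stated generative model, not performance on real ChIP-seq libraries.

## Problem sizes and reproducibility

The test suite and the acceptance script run the reference synthetic study
at the default scale above. Replicated analyses (20 seeded end-to-end
replicates; calibration over 500 resampling trials) use resampling depths
of 200–500 permutations/draws/sets rather than the interactive default of
1000 — the calibration properties under test are insensitive to the
resampling depth beyond the implied p-value floor, and these sizes keep a
full replicated study to a few minutes on one CPU. Every stochastic stage
accepts a seed, and a fixed master seed reproduces every output
byte-for-byte.

## Known limitations

* Valley calling assumes an approximately locally stationary plateau;
  strongly sloped acetylation domains shift the effective dip threshold.
* The empirical-FDR q-value is a plug-in estimate; it is validated for
  control, not for optimality, and is conservative for small F.
* The normal-tail ChIP p-value inherits mild anti-conservativeness from
  estimating $\mu$ and $s$ on finitely many random sets; BH adjustment at
  the reported set count keeps the realized false-positive rate at its
  nominal level in the null simulations.
* With four time points, lag estimates and correlations are descriptive
  screening statistics, not inference; ranking, not testing, is the
  intended use.
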