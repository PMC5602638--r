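# valleytf

Epigenome-guided discovery of temporal transcription-factor regulators.

`valleytf` finds the transcription factors (TFs) that drive distinct
temporal gene-expression programs — the motivating system is LPS-stimulated
macrophages — by combining a histone-acetylation (HAc) ChIP-seq time course
with a matched expression time course:

1. **Valley detection.** Functional TF binding sites concentrate in ~100 bp
   dips ("valleys") of the HAc signal inside otherwise acetylated regions.
   The signal, sampled on a 10 bp grid and smoothed with a Gaussian kernel
   (σ = 40 bp), yields a valley at sample point *i* when
   `v_i < 0.7 · min(L_i, R_i)`, where `L_i`, `R_i` are the signal maxima in
   the windows 50–500 bp to either side; the valley score is
   `min(L_i, R_i)`.
2. **Active promoter regions (APRs).** Valleys within ±5 kbp of a gene's
   TSS are that gene's candidate regulatory elements at each time point.
3. **Motif enrichment.** For each TFBS position-weight matrix *M* and
   sequence set *S*, the raw score is the log-average-likelihood
   `ln mean_s ALR(M, s)` with
   `ALR = (1 / 2(L−w+1)) Σ_placements Π_j P_M(b_j)/P_bg(b_j)` over both
   strands; enrichment p-values come from resampling same-size subsets of
   the expressed-gene promoter background. Motifs with p ≤ 0.01 at any
   time point are retained.
4. **Time-lagged correlation.** Each retained motif's raw-score series
   (0/1/2/4 h) is correlated with the cluster-median expression of each
   temporal cluster (k-means under a 1 − r distance on fold-change
   profiles, q ≤ 0.01 and fold change ≥ 5), linearly interpolated at a lag
   τ ∈ [0, 2] h. Large |R| at the optimal lag, with rank-1 score range
   max(score) − min(score), nominates the motif as the cluster's regulator
   — activator for R > 0, repressor for R < 0.
5. **ChIP validation.** Predicted TF–cluster links are checked against TF
   ChIP-seq: cluster promoter read counts (−2000/+500) versus 1000 random
   expressed-gene sets, z-score → two-tailed normal p → Benjamini–Hochberg
   q.

A fully synthetic data module generates genomes, HAc tracks, expression and
TF reads with known planted regulators, lags and roles, so the entire
pipeline is testable end-to-end with no downloads.

## Worked example

Simulate the reference synthetic study (2 × 2 Mbp genome, 200 genes, four
planted clusters with known regulator motifs, lags and roles) and run the
whole pipeline:

```r
library(valleytf)

sim <- simulate_dataset(sim_config(), seed = 42)
run <- run_valley_tf(sim, run_params(k_up = 2, k_down = 2, n_perm = 300,
                                     n_draws = 200, n_sets = 300), seed = 42)
glance(run)
#> # A tibble: 1 × 5
#>   n_valleys  n_de n_clusters n_retained_series chip_tested
#>       <int> <int>      <int>             <int> <lgl>
#> 1     24576    60          4                26 TRUE

evaluate_run(run, sim$truth)
#> # A tibble: 4 × 8
#>   true_cluster found_cluster jaccard motif_id      rank rank1  r_opt sign_ok
#>   <chr>        <chr>           <dbl> <chr>        <int> <lgl>  <dbl> <lgl>
#> 1 DC1          DC2                 1 V$TARGET_DC1     1 TRUE   0.755 TRUE
#> 2 DC2          DC1                 1 V$TARGET_DC2     1 TRUE  -0.909 TRUE
#> 3 UC1          UC2                 1 V$TARGET_UC1     1 TRUE   0.955 TRUE
#> 4 UC2          UC1                 1 V$TARGET_UC2     1 TRUE  -0.893 TRUE
```

Reading the output: ~6100 valleys are called per time point; all 60
planted differentially expressed genes are recovered and partition into
four clusters that match the planted memberships exactly (Jaccard 1;
recovered labels are size-ordered, hence permuted relative to the planted
names). In every cluster the planted regulator motif ranks first by score
range among retained motifs, and the sign of its optimal-lag correlation
matches the planted role — positive for activators, negative for the
planted repressors (`V$TARGET_DC2`, R = −0.909; `V$TARGET_UC2`,
R = −0.893). `run$chip` holds the ChIP validation table (z, p, q per TF ×
time × cluster), `run$associations` the full motif–cluster report, and
`tidy(run$lagfit)` the correlations under all three lag policies.

A thin command-line wrapper covers the same flow:

```sh
exec/valleytf simulate --out data/ --seed 1
exec/valleytf call-valleys --in data/hac_t0.bedgraph --out valleys0.bed
exec/valleytf run --dir data/ --out results/ --seed 1
```

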