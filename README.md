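# proteopanel

Tools for classifying tumor proteomes measured against a heavy spike-in
(super-SILAC) standard, aimed at the two-subtype, small-cohort,
thousands-of-proteins setting typical of archival (FFPE) tissue studies —
for example separating the activated-B-cell-like (ABC) and germinal-center
(GCB) subtypes of diffuse large B-cell lymphoma from protein expression
alone, and distilling the difference into a minimal protein panel.

The package implements the full chain as composable, pipe-friendly
functions, plus a cohort simulator with known ground truth so every stage
is testable without patient data:

1. **Hybrid SILAC/label-free quantification.** For each protein group and
   sample pair (a, b), every peptide feature contributes
   `log2((L_a/H_a)/(L_b/H_b))` when its SILAC ratio exists in both samples,
   falling back to `log2(L_a/L_b)` when both light intensities are present
   — so proteins absent from the spike-in standard (typically secreted and
   extracellular-matrix proteins) are still quantified. Median peptide
   ratios per pair feed an unweighted least squares
   `min Σ (x_a − x_b − r(a,b))²` that reconstructs a relative log2 profile
   per protein over all samples.
2. **Conditioning**: keep proteins with ≥ 75% valid values
   (`ceil(0.75 × 20) = 15` of 20 samples), impute missing values per sample
   from `Normal(m − 1·s, (0.3·s)²)` (missing-not-at-random, biased toward
   the detection limit), then normalize every sample to median 0 / IQR 1.
3. **Unsupervised**: SVD-based PCA with automatic selection of the
   subtype-separating component pair, loading drivers, signature-subset
   PCA, correlation/average-linkage hierarchical clustering and a
   two-cluster subtype-recovery check.
4. **Enrichment**: exact Fisher tests (with Benjamini–Hochberg correction)
   for annotation categories among component drivers, and rank-based 1D/2D
   annotation enrichment scores `s = 2U/(m(n−m)) − 1 ∈ [−1, 1]`.
5. **Supervised**: features ranked by the S0-moderated statistic
   `d = (mean_A − mean_B)/(se + s0)`, linear SVMs trained inside a
   1,000-repetition stratified 90/10 random-sampling cross-validation
   (ranking sees training samples only), per-k error curves, a minimal
   panel at the error-optimal size, and the clustering-loss cutoff — the
   largest ranked feature set whose unsupervised clustering still splits
   the subtypes.

## Worked example

```r
library(proteopanel)

cohort <- generate_cohort(sim_config(n_proteins = 2000, seed = 42))
cohort$truth
#> <cohort_truth> 2000 proteins x 20 samples (13 vs 7), 50 differential, 1800 in standard

profile <- quantify_matrix(cohort$peptides)
quant_report(profile)
#> # A tibble: 1 × 5
#>   mode   n_proteins n_quantified n_fallback mean_per_sample
#>   <chr>       <int>        <int>      <int>           <dbl>
#> 1 hybrid       2000         1991       1846           1802.

processed <- preprocess_profile(profile, seed = 1)   # filter -> impute -> normalize
pca <- profile_pca(processed)
pca
#> <profile_pca> 20 samples x 1741 proteins; top variance fractions: 11.3%, 7.2%, 6.7%, 6.4%, 6.1%

labels <- cohort$truth$samples
select_component_pair(pca, labels)    # components that separate the subtypes
#> [1]  1 18

cv <- cv_feature_selection(processed, labels, repetitions = 100, seed = 7)
cv
#> <svm_cv> 100 repetitions; optimal panel size 3 with 0.0% held-out error
#> panel: P00304, P01893, P00498

final_panel(processed, labels, k = cv$optimal_k, cv = cv)
#> # A tibble: 3 × 8
#>   protein_id mean_A mean_B log2fc statistic p_value  rank frequency
#>   <chr>       <dbl>  <dbl>  <dbl>     <dbl>   <dbl> <int>     <dbl>
#> 1 P00304      0.536 0.0694  0.467      3.79 0.00134     1      1
#> 2 P01893      0.998 0.574   0.424      3.59 0.00210     2      0.97
#> 3 P00498     -0.312 0.154  -0.466     -3.53 0.00240     3      0.39

ranked <- rank_features(processed, labels)
clustering_loss_cutoff(processed, labels, ranked$protein_id)
#> [1] 670
```

Reading the output: 1,991 of 2,000 simulated proteins were quantified, most
of the 200 standard-absent ones only thanks to the light-intensity fallback
(`n_fallback` counts proteins with any fallback contribution). After
conditioning, 1,741 proteins survive the 15-of-20 valid-value rule. The
cross-validation finds that three proteins suffice for error-free held-out
classification of the two subtypes; `frequency` is how often each panel
member entered the per-repetition top-k, and the clustering-loss scan says
the top ~670 ranked proteins still cluster the cohort into the correct
subtypes. `autoplot(pca, labels = labels)`, `autoplot(cv)` and
`autoplot()` on 2D enrichment results give the standard figures;
`tidy()`/`glance()` return tabular views. `run_pipeline(pipeline_config(...))`
executes the whole chain from one config with serialized stage artifacts,
and `generate_annotations()` + `enrichment_2d()` cover the category-level
view.

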