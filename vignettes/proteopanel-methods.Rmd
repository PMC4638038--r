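---
title: "Methods: hybrid quantification, matrix conditioning and panel selection"
author: "proteopanel"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: hybrid quantification, matrix conditioning and panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopanel)
```

# Scope and model

`proteopanel` implements an analysis chain for classifying tumor proteomes
measured by mass spectrometry against a pooled heavy-labeled spike-in
(super-SILAC) standard: two molecular subtypes, a handful of archival
samples per subtype, thousands of protein groups. The chain is

1. **hybrid quantification** of peptide-level light/heavy intensities into a
   relative protein profile matrix,
2. **matrix conditioning** (valid-value filtering, missing-value imputation,
   width normalization),
3. **unsupervised analysis** (SVD-based PCA, loading drivers, hierarchical
   clustering),
4. **category enrichment** (Fisher tests on component drivers, rank-based
   1D/2D annotation scores),
5. **supervised panel selection** (S0-moderated feature ranking inside a
   random-sampling SVM cross-validation).

Because raw patient-level MS data cannot ship with a package, a peptide-level
cohort simulator with full ground truth stands in for the measurement, and
every stage is validated against it and against independent oracles.

# Hybrid SILAC/label-free quantification

Each peptide feature in each sample carries a *light* intensity (the sample)
and, when the peptide exists in the spike-in standard, a *heavy* intensity
(the common reference, spiked 1:1). For a protein group and an ordered sample
pair $(a, b)$, each peptide contributes one log~2~ ratio:

* if the SILAC ratio $L/H$ is computable in **both** samples, the
  *ratio of ratios* $\log_2\frac{L_a/H_a}{L_b/H_b}$ — this cancels the
  peptide's response factor *and* run-to-run nuisance through the common
  reference;
* otherwise, if both light intensities are present, the plain light ratio
  $\log_2(L_a/L_b)$;
* otherwise nothing.

The per-pair summary is the **median** over contributing peptides (kept only
when at least `min_ratio_count` peptides contribute; default 1). Mixed pairs
are allowed: for the same sample pair some peptides may contribute
ratio-of-ratios and others light ratios, because the rule is defined per
peptide feature. The per-protein profile $x \in \mathbb{R}^{\text{samples}}$
then minimizes

$$\sum_{(a,b)\ \text{defined}} \bigl(x_a - x_b - r(a,b)\bigr)^2 ,$$

solved per connected component of the sample graph. Only differences are
identified; the free additive constant per component is fixed by an anchor
rule. The default (`sum_of_light`) rescales so the profile's total linear
intensity equals the protein's total observed light intensity — presentation
only; `geometric_mean_one` (component mean 0 in log space) is the algebraic
minimum-norm solution and is what the test oracles compare against.

Deliberate simplifications, documented rather than hidden: the median
per-pair summary and the unweighted least squares are simpler than the full
label-free extraction machinery they descend from (support counts are
retained for a future weighted mode); delayed normalization is omitted
because between-sample normalization happens downstream in the conditioning
stage. No claim of bit-equivalence with any external software is made — the
contract is the least-squares formulation above, verified against a
pseudoinverse oracle to 1e-8 on hundreds of random instances.

# Matrix conditioning

The order is fixed: **filter → impute → normalize**.

* **Valid-value filter.** Keep proteins quantified in at least
  $\lceil f \cdot n \rceil$ samples, default $f = 0.75$: with 20 samples the
  threshold is 15 valid values. `ceil` is pinned by that worked value.
* **Downshifted imputation.** Missing values in proteomics are
  missing-not-at-random — preferentially low-abundance. Per sample $j$ with
  observed mean $m_j$ and SD $s_j$, each missing cell is drawn independently
  from $\mathcal{N}(m_j - \delta s_j,\ (w s_j)^2)$ with downshift
  $\delta = 1$ and width $w = 0.3$. Imputation is per sample because the
  detection limit is a property of the individual run; whether the original
  analysis pooled the whole matrix instead is not documented anywhere we
  could pin down, so the per-sample choice is stated here explicitly.
* **Width normalization.** Per sample, subtract the median and divide by the
  interquartile range (linear-interpolation quantiles, type 7). Every sample
  ends with median 0 and IQR exactly 1; the common IQR value is free in
  principle and fixed at the canonical 1.

# Unsupervised analysis

PCA treats samples as observations and proteins as centered variables and is
computed by singular value decomposition. Two determinism conventions are
pinned so tests can be exact: each loading column is flipped so its
largest-magnitude entry is positive, and components whose singular value is
below $10^{-10}$ of the largest are dropped (a centered matrix has one
exactly-null direction whose floating-point noise would otherwise pollute
score-based statistics). `select_component_pair()` replaces the eye-ball
choice of a separating component pair with the two components maximizing the
absolute two-sample t statistic of scores between subtype labels — on real
cohorts the separating pair need not be (1, 2); on the 20-sample reference
design it was a low-variance component that captured the subtype axis.

Hierarchical clustering uses Pearson-correlation distance ($1 - r$) with
average linkage — the standard heatmap choice; neither is dictated by the
underlying analysis description, so both are arguments. The subtype-recovery
check cuts the sample tree into exactly two clusters and demands the exact
label bipartition.

# Category enrichment

* **Component-driver enrichment.** "Associated with a component" is
  interpreted as $|$loading$|$ above the 90th percentile on that component
  (configurable); each catalog category is then tested with a two-sided
  Fisher exact test (full hypergeometric enumeration; ties in table
  probability included under a $1+10^{-7}$ relative guard) and
  Benjamini–Hochberg correction at cutoff 0.05. The *enrichment factor* is
  the in-category fraction among associated proteins over the in-category
  fraction overall — an interpretation, since no formal definition exists
  upstream.
* **Rank-based scores.** For a category of size $m$ among $n$ proteins with
  Mann–Whitney rank-sum statistic $U$ (mid-ranks for ties), the score is
  $s = 2U / (m(n-m)) - 1 \in [-1, 1]$: $+1$ when members occupy all top
  ranks, $-1$ at the bottom, expectation 0 under exchangeability. The 2D
  version scores the same category on two per-protein dimensions (here: the
  median profile of each subtype), so categories off the diagonal are
  subtype-specific. Joint significance is deliberately conservative — twice
  the smaller of the two per-dimension Mann–Whitney p values, BH-adjusted
  across categories — because no combination rule is specified upstream.
  Mann–Whitney p values are exact for groups of at most 25 without ties and
  use the tie-corrected normal approximation otherwise.

# Supervised panel selection

Features are ranked by the S0-moderated two-sample statistic

$$d_i = \frac{\bar{x}_{A,i} - \bar{x}_{B,i}}{\mathrm{se}_i + s_0},$$

with $\mathrm{se}_i$ the pooled two-sample standard error. $s_0 = 0$ is the
classical pooled t statistic; $s_0 > 0$ (default 0.1 on normalized log~2~
data — the upstream value is nowhere stated, so this is a package default,
overridable) penalizes features whose significance rests on a tiny variance
rather than a real fold change, so equally-significant features with larger
fold changes rank better. P values come from the Student reference with
$n_A + n_B - 2$ df by default; a permutation mode (per-protein null over
label permutations) is provided since this statistic family is classically
calibrated by permutation.

Cross-validation: in each of `repetitions` (default 1,000; the acceptance
runs use the documented scaled-down 100) draws, a **stratified** random 90%
of each class trains; ranking and SVM training see only those samples.
Stratification is a deliberate deviation from plain random sampling: with a
13-vs-7 cohort, unstratified 90/10 splits regularly produce one-class test
sets. For each panel size $k$ in the grid (1–20 then sparser to 500) a
linear soft-margin SVM (cost 1) on the top-$k$ training-ranked features is
scored on the held-out samples. `optimal_k` is the smallest $k$ attaining
the minimum mean error (parsimony). The final panel is the top-`optimal_k`
of the full-data ranking, reported alongside each feature's selection
frequency across repetitions — the two notions of "final panel" (full-data
rank vs selection stability) are both reported because either is defensible.
The held-out error is aggregated as total misclassified held-out predictions
over total held-out predictions; with stratified single-sample-per-class
test sets this equals the mean per-repetition error rate.

**No-leakage property.** Ranking inside the CV loop must not see held-out
samples. The suite asserts this behaviorally: on label-permuted data the
held-out error must stay at chance. Two statistical subtleties are worth
recording. First, with one held-out sample per class, any classifier blind
to the test labels errs at exactly 0.5 in expectation — that is the
majority-class rate on such test sets. Second, *conditional on a single
finite null dataset or permutation*, the CV error fluctuates around 0.5
with a dataset-level spread far exceeding the per-repetition Monte-Carlo
error (and a small systematic optimism, since a permutation partially
aligned with the true subtype structure is genuinely learnable). The checks
therefore average over several permutations and use a band (±0.15) wide
enough for these effects yet far above the near-zero error an actual leak
produces.

**Clustering-loss cutoff.** To extend the minimal panel to a broader
discriminating set, panel sizes are scanned upward along the ranked list and
the cutoff is the largest scanned size at which a two-cluster cut of the
sample dendrogram still reproduces the subtypes at every scanned size so
far. The default grid is 3–50 then steps of 10: sizes 1–2 are excluded
because the Pearson correlation between samples is undefined over one
feature and identically ±1 over two. A related limitation: correlation
distance subtracts each sample's mean across the selected features, so a
feature set whose effects all point the same way carries its signal in
exactly the component correlation discards; discriminating sets with
effects in both directions (as planted cohorts and real subtype signatures
have) are the intended use, and a Euclidean distance option exists for the
degenerate case.

# The cohort simulator

`generate_cohort()` draws, in a fixed documented order (proteins → peptides
→ samples):

* protein base abundance $\log_{10} \sim \mathcal{N}(7, 1)$ — several orders
  of magnitude of dynamic range around typical Orbitrap feature intensities;
* a planted differential subset (default fraction 0.025, matching 50 of
  2,000 at the scale the acceptance cohort uses) with $|\log_2$FC$|$ drawn
  uniformly from a configurable range and random sign, added to subtype B;
* standard coverage: a configurable fraction of proteins (default 0.9) has a
  heavy channel; the uncovered remainder is drawn disjointly from the
  differential set where possible so standard coverage cannot confound the
  subtype signal, and is collected into a `standard_absent_like` catalog
  category by default — emulating the extracellular/secreted character of
  proteins absent from cell-line-derived standards;
* peptide counts $1 + \mathrm{Poisson}(\mu - 1)$ (default mean 3) with
  log-normal peptide response factors (SD 0.5 log~10~) shared across
  samples;
* multiplicative log-normal measurement noise (default CV 0.2) per
  observation, independently for light and heavy;
* logistic abundance-dependent detection,
  $\Pr(\text{detected}) = \mathrm{logit}^{-1}\bigl((\log_2 I - 20)\cdot
  0.5\bigr)$, applied per channel — the missing-not-at-random structure the
  imputation stage assumes. A slope of 0 means "always detected", the
  noiseless/complete limit used by exactness tests.

The per-protein peptide distributions, response-factor spread, noise CV and
detection parameters are plausibility choices (the real cohort's values are
not recoverable from any published table) — they are defaults, not claims.
What the simulator deliberately omits: retention time, charge states,
fractionation, identification errors, shared peptides between protein
groups, correlated biological within-subtype variation. Passing tests
therefore demonstrate algorithmic correctness and statistical calibration
under the stated generative model, not performance on real FFPE cohorts;
with within-group variance coming from measurement noise only, planted
effects of 1–2 log~2~ units are easy, which is exactly what makes the
near-zero cross-validation error of the acceptance cohort an algorithm
check rather than a clinical claim.

One RNG stream per generator call, consumed in the order above: adding
samples changes earlier draws. This is documented rather than engineered
away.

# Problem sizes and numerical choices

The test and acceptance cohorts use 200–2,000 proteins and 12–20 samples —
sizes chosen so the full suite runs in minutes while every statistical
property under test already holds at comfortable margins; the pipeline
itself has no scale-dependent logic and runs unchanged at
real-proteome scale (10–20k proteins). Other pinned conventions: base-2
logs throughout; IQR with type-7 quantiles; ranking ties broken by larger
absolute fold change then protein ID; optimal-k ties toward smaller k;
PCA sign fixing as above; per-stage seeds derived from one global pipeline
seed by fixed offsets.

# Known limitations

* The quantification least squares is unweighted; pairs supported by many
  peptides count the same as single-peptide pairs.
* Protein-group inference, peptide-level identification and FDR control are
  out of scope; protein groups are taken as given.
* The enrichment machinery treats categories as flat sets (no ontology
  propagation).
* Survival or prognosis modeling is out of scope; the panel is a molecular
  subtype discriminator, not a clinical classifier.
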