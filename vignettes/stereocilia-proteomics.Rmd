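---
title: "Quantitative workflows for stereocilia membrane proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative workflows for stereocilia membrane proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoquant)
```

## The scientific problem

Hair-cell stereocilia carry their mechanotransduction machinery in and
on a membrane that makes up a vanishingly small part of the inner ear.
Identifying the protein complexes of that membrane — for example the
partners of the deafness-associated motor MYO7A — requires (i) a bulk
enrichment of stereocilia membranes across a series of purification
fractions, (ii) an immunoaffinity purification (IP) of the bait from the
solubilized membranes with nonspecific-IgG controls, and (iii) targeted
(PRM) mass spectrometry to confirm low-abundance co-precipitation. This
package implements the quantitative analysis for all three stages, plus
a ground-truthed synthetic-data generator so every stage is testable
without raw instrument files.

## Label-free quantitation model

Protein abundance enters as iBAQ (summed peptide intensity divided by
the number of theoretically observable peptides). We convert to
**riBAQ**, a molar-fraction estimate: per sample,

$$\mathrm{riBAQ}_i = \frac{\mathrm{iBAQ}_i}{\sum_{j \notin \text{contaminants}} \mathrm{iBAQ}_j},$$

so riBAQ sums to one over the non-contaminant proteins of each sample
(`compute_ribaq()`). Missing values mean *not detected* throughout; zero
intensities are coerced to missing on input so detection-count filters
behave identically across export conventions.

When a protein group mixes isoforms (e.g. closely related Ca^2+^-pump
paralogs of which only one resides in stereocilia), the group riBAQ is
apportioned by isoform-unique peptides: isoform *k*'s share in a sample
is its unique-peptide intensity divided by the summed intensity of all
isoform-unique peptides of the group (`apportion_isoforms()`). Shared
peptides support group quantitation only. Shares are computed per
sample (the `per-sample` choice is deliberate: relative isoform levels
change across fractions, which is exactly what the adjustment is meant
to capture); a single global share can be emulated by averaging.

## Enrichment-slope profiling

For each protein detected in at least `min_detected` fractions
(default 3 of 5) we fit an ordinary least-squares line of
log~10~ riBAQ against the purification-fraction index (unit spacing)
over the detected fractions only; the slope — decades of enrichment per
purification step — is the **enrichment slope** (`enrichment_slope()`).
Missing fractions are omitted, never imputed, matching the
detection-based treatment elsewhere. The log base is configurable;
ranking is base-invariant (log~2~ slopes are exactly
$\log_2\!10$ times log~10~ slopes).

Two diagnostics accompany the slopes:

* `tm_rolling_average()` — proteins sorted by slope, block means (window
  50) of a 0/1 transmembrane-helix flag; membrane enrichment shows up
  as a rising trend.
* `cluster_profiles()` — profiles standardized per row
  (`row_standardize()`, sample SD by default; the population-SD variant
  is exposed because both conventions circulate in clustering
  ecosystems) and clustered with in-package Gaussian-mixture models.

The mixture engine (`fit_gmm()`) fits shared-diagonal and shared-full
covariance structures by EM for each candidate k, initialized by seeded
k-means++ with 10 restarts, keeping the best likelihood; the model and
k are selected by BIC. Clusters are then reindexed by decreasing mean
enrichment slope of their members, so cluster 1 always holds the
steepest, most membrane-co-enriching profiles. Only complete profiles
are clustered (proteins detected in every profiled sample), mirroring
standard practice for model-based profile clustering. Determinism is
pinned by the seed; permutation equivariance holds whenever EM reaches
the same optimum, which the restarts make routine for separated data.

## IP statistics

Two complementary readouts identify specific interactors:

* **Binary control subtraction** (`filter_specific()`): keep proteins
  detected in ≥ 4 of 6 bait-antibody runs and absent from all control
  runs. Both thresholds are parameters.
* **Enrichment continuum** (`enrichment_ratio()`): mean eluate riBAQ
  over mean starting-material (total) riBAQ, averaging detected runs
  only (zero-imputation is available for sensitivity analysis).
  Proteins seen only in the eluate are segregated (`eluate_only`) with
  a censored lower-bound ratio against the smallest detected total
  riBAQ rather than an invented pseudo-count; `total_only` proteins get
  no ratio.

Significance uses an empirical-Bayes **moderated t-test**
(`moderated_t_test()`) on log~2~, median-normalized riBAQ
(`log2_median_normalize()`): per-protein pooled variances are shrunk
toward a prior variance $s_0^2$ with prior degrees of freedom $d_0$,
both estimated from the variance ensemble by a method-of-moments fit of
the scaled-F marginal using moments of $\log s_g^2$
(`fit_f_dist()`); the moderated statistic is referred to a t
distribution on $d_0 + d_g$ degrees of freedom (capped at the pooled
residual df, so the $d_0 \to \infty$ limit keeps a finite reference).
Setting $d_0 = 0$ recovers the ordinary pooled t-test exactly; the
implementation is verified against the reference empirical-Bayes
implementation to numerical precision in the test suite. P-values are
adjusted by Benjamini–Hochberg step-up (`bh_fdr()`); the FDR variant is
fixed to BH.

Bait-relative **stoichiometry** (`stoichiometry()`) reports, per
protein, eluate riBAQ over the bait's eluate riBAQ (unadjusted), and
that value rescaled by the bait-to-protein riBAQ ratio in the starting
extract (adjusted); the bait is exactly 1 under both definitions, and
proteins absent from totals get a missing adjusted value.

## Targeted-PRM quantitation

Fragment-ion chromatograms for a peptide are summed pointwise
(`sum_traces()`, linear interpolation onto the densest grid when grids
differ) and the summed trace is integrated by the trapezoid rule with a
zero baseline (`integrate_peak()`). A candidate peak is located by a
fixed-width moving-mean smoother; the apex is the maximum near the
reference retention time when one is given, and boundaries extend to
where the smoothed trace falls below
`max(noise_floor, floor_frac * apex)`. Peak localization is a
deterministic surrogate for the manual curation a chromatogram GUI
would provide.

Acceptance (`qualify_peak()`) requires (1) ≥ 3 co-eluting fragment
ions — each fragment's apex within one peak-width of the summed apex
and above the noise floor; (2) ≥ 2 data points across the peak; and
(3) a matched MS2 identification inside the peak. When criterion 3
fails, a fallback accepts the peak iff its apex is within 2 min
(strict boundary) of an identified peak of the same peptide from
another run *and* the above-noise fragment set matches that reference
(set equality by default, subset matching optional). A peak failing
qualification has area exactly zero — the zero-fill rule — with its
rejection reasons recorded. Heavy-standard traces supply reference
retention times only and are never added to areas.

Numerical choices worth stating: the boundary threshold `floor_frac`
defaults to 1% of the apex. A Gaussian peak truncated at 1% of apex
retains 99.7% of its analytic area, keeping noise-free integration
error near 0.3%; a 5% threshold would already lose 1.4%, more than the
1% recovery the package promises on clean peaks. The integration
baseline is zero (no local baseline subtraction), flagged as
configurable by construction of the boundaries.

Experiment-level scaling uses the bait's own peptides
(`experiment_normalization()`): each bait peptide's area in an
experiment is divided by that peptide's mean across experiments, and
the factors are averaged over bait peptides; for a complete bait matrix
the factors average to exactly 1. `ip_over_total()` then averages
normalized areas per condition, reports mean specific-eluate area over
mean starting-material area (and the control analogue), and compares
specific vs control with a two-tailed two-sample t-test (Welch by
default; pooled-variance optional) with a 95% CI. All replicates are
pooled equally; pooling technical within biological replicates first is
a design-file decision, not hard-coded.

The fraction-report arithmetic (`fraction_of_reference()`,
`per_ug_fold_enrichment()`) combines a protein assay (µg per fraction)
with per-µg PRM intensities: fraction totals are per-µg intensity × µg,
percentages are relative to the post-nuclear supernatant and rounded to
integers for reporting, and per-µg folds are reported to one
significant figure — the conventions of the printed purification
report.

## What the synthetic data emulate — and what they do not

`simulate_purification()` draws log~10~ baseline abundances from a
normal with SD 1.2 decades around 10^6^ (the broad dynamic range of
deep proteome surveys), assigns a designated membrane subset (15% by
default) true slopes around 0.4 decades/step (a ~40-fold S1→S7 gain
over five fractions, of the order of the ~50-fold per-µg target-protein
enrichment the procedure achieves), background slopes centered at 0
with the same SD 0.1, multiplicative log-normal measurement noise
(0.2 decades), and logistic detection dropout on log abundance
(midpoint 10^4^, steepness 1.5 — ~90% of cells detected at the
defaults, like deep fraction profiling). Isoform groups appear as
summed group rows with shared plus isoform-unique peptides. The
default problem size is 500 proteins — large enough for stable rank
statistics, small enough that the whole suite runs in seconds; the
generator scales to thousands unchanged.

`simulate_ip()` amplifies the bait (capture efficiency 1) and its
planted partners (efficiencies in (0,1]) by a 10^4^ capture gain over
their starting abundance, samples nonspecific binders
abundance-proportionally with the *same* distribution in specific and
control runs — the premise that justifies computational control
subtraction — and applies log-normal run noise (σ 0.3) and Bernoulli
detection (0.95) to captured proteins. Captured proteins' own
nonspecific binding is not modelled; it is negligible next to capture
and its absence is what makes "absent from controls" a meaningful
filter.

`simulate_prm()` generates co-eluting Gaussian fragments with shared
center and width (σ 0.1 min), 3-s sampling, non-negative uniform noise
and apex-concentrated matched MS2 events, with analytic areas recorded.

None of the generators emulate peptide-level stochastic sampling,
retention-time drift between runs, interference from co-isolated
precursors, or intensity-dependent variance structure beyond the
log-normal. Passing tests therefore demonstrate that the *computations*
are correct and that the pipeline recovers truth under the stated
statistical structure — not that the structure captures every pathology
of real instrument data.

## Degenerate inputs and tie-breaks

Slope ranking breaks ties lexicographically by protein id. Constant
rows cannot be z-scaled and are dropped with a warning (ids recorded);
samples with fewer than two detections cannot be median-normalized and
raise an error naming the sample; a sample whose non-contaminant signal
is zero raises an error rather than silently producing NaN. EM restarts
that empty a component are discarded; the shared covariance carries a
1e-8 ridge.

## Known limitations

* The moderated test assumes a two-group design; paired or covariate
  designs would need the full linear-model machinery of the reference
  implementation.
* The mixture engine fits shared-covariance structures only (the two
  the profile-clustering task needs); per-cluster covariances are out
  of scope.
* Censored (`eluate_only`) enrichment ratios are lower bounds and are
  deliberately excluded from the moderated test.
* PRM peak localization assumes one dominant peak per window; severely
  multimodal chromatograms should be curated upstream.
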