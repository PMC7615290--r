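---
title: "CNV intermediate phenotypes: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV intermediate phenotypes: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvsig)
```

`cnvsig` studies a two-cohort design. A *clinical cohort* holds carriers of
eight recurrent copy-number variants (deletions and duplications at
1q21.1, 15q11.2, 16p11.2, 22q11.2) plus controls, with regional grey-matter
volumes on a parcel atlas. A much larger *population cohort* holds
volumes on the same atlas together with a broad phenome table. The package
(i) estimates one brain-wide signature per CNV in the clinical cohort,
(ii) scores the signature's expression in every population subject, and
(iii) correlates those expressions with every phenotype. The scientific
question the final report answers is whether CNVs that differ strongly in
their brain maps nonetheless share phenome association profiles.

This vignette documents the statistical models, the synthetic-data
generator, the tunable parameters, and the choices made where the design
was genuinely open. It states no empirical result that the package's test
suite and `scripts/acceptance.R` do not themselves compute.

## Confound adjustment

Regional volumes are residualized region-by-region with ordinary least
squares before any analysis. The clinical recipe uses intracranial volume,
age, age², sex, and acquisition site; the population recipe uses head size,
body-mass index, head motion, age, sex, and site. Site enters as indicator
columns — a *fixed* effect. Mixed-model (random-site) estimation would be
an alternative; the fixed-effect projection was chosen because it is
deterministic, closed-form, and equivalent in expectation for balanced
designs. Coefficients are estimated on a designated fit population and can
be applied to any other subjects (`adjust_confounds(fit_subjects = ...)`),
so each cohort is residualized with its own nuisance model. A single-site
cohort drops the site columns with a warning; rank-deficient designs raise
an error naming the offending columns.

Z-scoring (`zscore_columns`) uses sample standard deviations (n − 1
divisor) computed over a reference subset — for the effect-size analysis,
the union of one CNV's carriers and the controls, matching the per-CNV
normalization of the study design. The discriminant models consume
*adjusted but not z-scored* volumes: whether the original analysis z-scored
before classification is not documented, and adjustment alone preserves the
covariance structure the shrinkage estimator is meant to stabilize;
z-scoring is confined to the Cohen's d stage where it is explicitly part of
the definition.

## Effect maps and spatial nulls

Per-region effect sizes use Cohen's d with sample SDs,
`d = (x̄₁ − x̄₂)/√((s₁² + s₂²)/2)`. Map-to-map similarity is the Pearson
correlation over regions. Because smooth spatial maps have far fewer
effective degrees of freedom than regions, significance comes from a *spin
permutation*: parcel centroids live on a unit sphere, a Haar-uniform random
rotation (QR of a Gaussian matrix with sign correction) is applied, and
each region takes the value of the region whose original centroid is
nearest its rotated position. Two open details were fixed as follows:
the test is two-sided on |r| (both strong positive and strong negative
similarities are reported as significant), and duplicate nearest-neighbour
assignments are allowed (the simplest well-defined parcel-spin variant).
P-values use the `(1 + #{|r_null| ≥ |r_obs|})/(n_perm + 1)` estimator, so
the smallest attainable p is `1/(n_perm + 1)`. Across the 28 CNV pairs,
multiplicity is controlled with Benjamini–Hochberg FDR (the procedure
behind the generic "FDR" label).

Lin's concordance correlation,
`ρ_C = 2s₁₂/(s₁² + s₂² + (x̄₁ − x̄₂)²)`, uses population-form (n divisor)
moments — the dominant convention for this statistic — while Cohen's d uses
n − 1 SDs; both choices are stated to remove cross-implementation
ambiguity.

## The bagged shrinkage-LDA estimator

The core estimator (`bagged_lda`) addresses a p ≫ n problem: up to ~400
regions against as few as 15 carriers. The covariance is shrunk toward a
scaled identity, `Σ(α) = (1 − α)S + α (tr S/p) I`, with `S` the
maximum-likelihood (n divisor) pooled within-class covariance; any α > 0
is invertible. Per bootstrap replicate:

* **Stratified resampling.** Carriers and controls are resampled with
  replacement separately, preserving the dataset's class counts in-bag.
* **Shrinkage selection.** α is chosen from the grid 0, 0.1, …, 1 by exact
  leave-one-out: every in-bag subject is predicted by a model fitted
  without it, the pooled LOO confusion matrix is scored with the MCC, and
  ties go to the smallest α. The selection metric is not documented in the
  original description; MCC was chosen for consistency with the evaluation
  metric. The LOO models are computed exactly via a rank-one downdate of
  the pooled covariance in its eigenbasis (Sherman–Morrison), so the whole
  grid costs one eigendecomposition per replicate rather than
  `n × 11` refits.
* **Evaluation.** The fitted discriminant classifies the out-of-bag
  subjects; MCC is recorded. If the out-of-bag set lacks a class the draw
  is repeated up to 10 times, then the iteration is marked invalid and
  excluded from the MCC mean (the count is reported) — this preserves B for
  very small carrier groups.
* **Aggregation.** Discriminants are sign-aligned by the sign of their
  correlation with the group's Cohen's d map (ties align to +1,
  deterministically), unit-L2-normalized — otherwise high-variance
  bootstrap fits dominate the mean — and averaged into the signature `W`.
  Expressions are dot products with `W`, i.e. the average one-dimensional
  discriminant projection.

Region-wise 2.5/97.5% percentiles of the aligned ensemble give the
significance mask (interval excluding zero). The bootstrap count matters
here: percentile intervals need on the order of 100 replicates for nominal
coverage, and the package defaults to B = 100; desk-scale analyses that
only need the signature direction can run B = 25.

Chance performance comes from a label-permutation null that reruns the
*entire* bagged procedure (including per-replicate shrinkage selection) on
shuffled labels; the observed mean MCC is compared with the null's 97.5th
percentile. Whether the original nulls reselected shrinkage per permutation
is unstated; refitting it is the honest (full-pipeline) null, and the
per-permutation bootstrap count `B_null` is configurable to control cost.

Two low-dimensional views complement the 8 binary models: a PCA embedding
fitted on carriers with controls projected post hoc, and a multiclass
shrinkage-LDA embedding (generalized eigenvectors of between- versus
shrunk within-class scatter; at most classes − 1 dimensions, shrinkage
selected by leave-one-out pooled accuracy).

## Transfer, outlier filtering, and the PheWAS

Expressions in the population cohort are `adjusted volumes · W`, computed
with population-fit confound coefficients (the alternative — reusing
clinical-cohort coefficients — mixes nuisance models across scanners and
was rejected). Subjects outside the Tukey fences
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` on *any* of the 8 expression columns are
discarded from all scans (union rule, matching the single discarded
participant set of the study design); quartiles use standard linear
interpolation.

The scan correlates each expression column with each phenotype on
pairwise-complete cases (binary and ordinal phenotypes enter as numeric
scores), with two-sided t-distribution p-values (df = n − 2), a Bonferroni
threshold of α divided by the number of *testable* phenotypes, and BH-FDR
within each scan. Phenotypes with fewer than 10 complete pairs (a floor
guarding against spurious extreme correlations under missingness) are
marked untestable and excluded from multiplicity counts. Carrier/control
expression shifts are tested with a two-sample bootstrap mean test whose
null is enforced by re-centering both groups on the pooled mean; the
replicate default is 10,000 with smaller counts available via
configuration.

Profile similarity across CNVs is the Pearson correlation between two
scans' per-phenotype correlation vectors; its significance uses
phenotype-label permutation rather than a t approximation because the P
correlation entries are mutually dependent. `condition_out` residualizes
each expression column on the other seven (OLS with intercept, rank
tolerant) to expose CNV-unique associations. Note that this per-column
operation is *not* idempotent: each residual is orthogonal to the original
other columns, not to their residuals; re-applying it changes values, which
is inherent to the operation rather than an implementation artifact.

The final convergence report pairs the 28 off-diagonal absolute
similarities of the Cohen's-d-map matrix with those of the profile matrix,
computes Lin's ρ_C between the two 28-vectors, and counts pairs whose
phenome similarity exceeds their map similarity.

## The synthetic cohorts

The generator plants a complete ground truth so that every stage above has
a recoverable target.

**Atlas.** Parcel centroids form a Fibonacci lattice on a single unit
sphere; networks are nearest-seed-direction patches (7 by default, with
the conventional large-scale network names). Hemispheres and a medial wall
are deliberately absent: bilateral surface handling is irrelevant to the
statistics under test, and a single sphere keeps the spin null exact.

**Signatures.** Each CNV map is a sum of spherical Gaussian-like bumps
(`exp(κ(cosθ − 1))`, κ = 12, 6 bumps) — genuinely spatially smooth, so the
spin test is exercised meaningfully — weighted per network, centered, and
unit-normalized. Within a locus the duplication map is
`−ρ·β_del + √(1 − ρ²)·e` with `e` an orthogonalized independent smooth
map, making the deletion/duplication correlation exactly `−ρ`
(the mirror effect; defaults 0.3/0.4/0.4/0.5 across loci, echoing the
reported range of mirror strengths).

**Effect scale.** Carriers of CNV k receive `θ_k √p · β_k` added to their
volumes, with unit regional noise. The √p factor makes `θ` the
root-mean-square *per-region* effect in noise-SD units, so θ = 1 produces
regional Cohen's d of order 1 — the regime of the strongest reported CNV
effects and the scale at which the clinical design (groups of 15–146
against 312 controls) supports signature recovery.

**Cohorts.** The clinical simulator uses the published group sizes
(24, 15, 112, 146, 80, 69, 69, 19 carriers; 312 controls), four sites, and
ICV/age/age²/sex loadings; the population simulator uses the published
carrier counts (12, 14, 117, 155, 4, 7, 5, 47 among 38,731 non-carriers)
with its own nuisance set and disjoint site identifiers. The published
demographic table's counts imply a total of 39,092, which the package
keeps; desk-scale runs default to N = 4,000 with proportionally scaled
carrier counts.

**Phenome.** Each subject's latent dose vector is
`t = (carrier effect + regional noise) · βᵀ` — the volume component that
survives confound removal, which defines an unambiguous recovery target.
Phenotypes are `γ·t + noise`; coupling rows are
`c·shared + (1 − c)·independent` with `c` the convergence dial, giving
pairwise row correlations `c²/(c² + (1 − c)²)` (0 at c = 0, 1 at c = 1,
monotone between). Rows are rescaled to RMS 0.1, which yields per-phenotype
correlations around 0.1 at N = 4,000 — the magnitude regime of reported
population-scale brain-phenome associations; no quantitative phenome noise
model exists for the real data, so this is a realism choice, not an
estimate. A quarter of phenotypes are binarized at the latent median,
15% binned into 4 ordinal levels, and 5% of values are removed completely
at random (matching the pairwise-complete correlation contract downstream,
which assumes no informative missingness).

**What the generator does not emulate.** No voxel/surface data, no genotype
calling, no scanner physics, no site-by-effect interactions, no informative
missingness, no non-Gaussian phenome tails beyond
binarization/binning. Passing tests therefore demonstrate statistical
correctness and calibration of the machinery under the stated generative
model — not robustness to the messier failure modes of real imaging data.

One structural property of the generator deserves emphasis: because
expressions are brain-mediated (`t = volumes·βᵀ`), a phenotype coupled to
CNV l's latent is also detected by any signature k whose map overlaps
β_l. Phenome-profile similarity therefore inherits brain-map similarity
with a gain of roughly two even when coupling rows are fully independent —
smooth spherical maps cannot be made arbitrarily orthogonal (≈ 25
effective degrees of freedom at κ = 12), so at zero convergence profile
similarity still sits slightly above map similarity. The convergence dial
separates the regimes cleanly at the high end (c = 0.8 produces profile
similarity several times map similarity), which is the contrast the
headline analysis rests on.

## Numerical choices and degenerate inputs

* Stage seeds derive deterministically from one master seed
  (`pipeline_config`), and two runs with the same seed produce
  digest-identical artifacts.
* Singular covariances: α = 0 with p ≥ n raises an explicit error in a
  direct fit and scores `−Inf` in the selection grid; Sherman–Morrison
  denominators ≤ 1e−10 are treated the same way.
* Constant maps/vectors raise errors naming the offending region rather
  than returning NaN (Cohen's d, z-scoring, spin test, Lin's ρ_C with both
  vectors constant).
* Percentile thresholds and Tukey quartiles use R's default linear
  interpolation (type 7, the numpy-compatible convention).
* PCA and multiclass-LDA embeddings truncate to the available
  non-degenerate directions instead of erroring when a second component
  does not exist; only zero-variance input errors.

## Problem sizes

Default desk-scale runs use 100 regions, the full clinical group-size
design (846 subjects), a 4,000 × 200 population phenome, B = 25 bootstrap
iterations, and 199 spin/permutation draws; the full-scale settings
(400 regions, 39,092 subjects, 977 phenotypes, B = 100, 1,000 spins) are
reached by configuration. These sizes were chosen so that a complete
pipeline run, including every calibration, remains a minutes-scale
computation while preserving the class imbalance, multiplicity burden and
spatial-autocorrelation structure that the statistics are sensitive to.

## Known limitations

* Site is a fixed effect; no REML/mixed-model residualization.
* No cross-site harmonization beyond residualization, no nonlinear
  classifiers, no feature selection.
* The PheWAS is correlational by design; nothing here supports causal
  claims.
* The spin null is parcel-level (centroid rotation), not a vertex-level
  surface spin or a generative variogram null.
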