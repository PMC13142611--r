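---
title: "Methods: estimating recurrent-CNV dosage effects on height and BMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating recurrent-CNV dosage effects on height and BMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdose)
```

# The problem

Recurrent copy-number variants (CNVs) — deletions (DEL) and duplications
(DUP) generated repeatedly at the same hotspot by non-allelic homologous
recombination between flanking segmental duplications — are among the
largest-effect variants influencing anthropometric traits. Because carriers
are rare (typically 1 in 1,000 to 1 in 10,000), their effects can only be
estimated by pooling very large cohorts, and because individual-level data
cannot leave the participating biobanks, the analysis must be *federated*:
each cohort runs an identical workflow locally and only summary statistics
cross cohort boundaries.

cnvdose implements that workflow end to end: locus-level CNV genotyping from
raw call intervals, harmonized trait scaling, per-cohort association and
interaction models, inverse-variance fixed-effects meta-analysis,
dose-response decomposition, sex- and age-context analyses, subregion
additivity tests, and a synthetic multi-cohort generator with known truth
used to calibrate every test in the package.

# CNV genotyping from raw calls

A hotspot is modelled as an ordered set of non-overlapping breakpoint
*segments* (0-based, half-open coordinates); an *allele span* is a
contiguous run of segments, optionally guarded by *flanking* segments. For
each sample and state (DEL/DUP), same-state calls are merged (union of
intervals) so that fragmented caller output is not penalized, and the span
is state-positive iff

* every segment of the span has merged coverage fraction ≥ `min_fraction`
  (default 0.5), and
* no flanking segment reaches `min_fraction`.

Exactly one positive state gives that genotype; neither gives `REF`; both
give `NO_CALL` (conservative, and reported rather than dropped). The
coverage fraction is taken **of the target segment**. The bedtools-style
alternative — fraction of the call interval — conflicts with the intent of
"at least half the target region" for large calls, but is preserved as
`overlap_mode = "call"` for comparability. The flanking exclusion uses the
same threshold as span inclusion (a single tunable), and is evaluated per
state; whether the original convention tested flanking involvement per
state or jointly across states is not recoverable, and per-state is the
less aggressive choice.

The genotyper is verified against a brute-force oracle that counts covered
bases of every segment directly — 10,000 randomized call/locus
configurations, including 22q11.2-style multi-breakpoint loci with
flanking exclusion, must match exactly.

The packaged catalog (`default_catalog()`) contains 41 single-breakpoint
hotspots plus one eight-breakpoint segmented locus with six spans
(A-B … A-D), i.e. 47 testable spans and 94 DEL/DUP alleles. Its names and
positions are realistic but synthetic — it is a stand-in constructed for
this package, not a published clinical locus list — and the loader accepts
any catalog in the same JSON dialect (`one_based = TRUE` converts 1-based
inclusive input).

# Trait scaling

Adult traits are scaled per cohort in three steps: (1) residualize on sex,
age and age²; (2) split by sex, standardize to unit variance, shift to
positive support (−min + 1) and Box-Cox transform at the per-sex
maximum-likelihood λ (profile likelihood on [−5, 5], near-ties resolved to
λ = 1); (3) standardize to mean 0 / SD 1 within sex and recombine. Effect
sizes downstream are therefore in trait SD units relative to same-sex,
same-age peers — the same estimand in every cohort, which is what justifies
fixed-effects pooling. The pre-shift standardization makes the whole chain
invariant to the raw trait's units (cm vs m); the per-sex split equalizes
response variance across sexes, which keeps interaction models correctly
specified. The transform is monotone within sex, so within-sex rank order
is never disturbed.

Pediatric traits use LMS z-scores, `z = ((value/M)^L − 1)/(L·S)` with L, M,
S interpolated linearly in age within sex (log-limit as L → 0). The package
ships a compact synthetic growth reference (ages 2–18, both sexes, height
in cm and BMI in kg/m²) so no external download is needed; it is not the
WHO/CDC table, and analyses of real pediatric data should supply the real
reference through the same `ref` argument. Samples aged ≥ 18 take the adult
chain; younger samples the LMS chain.

# Association models

Per cohort, the CNV main effect is the genotype-factor coefficient
(reference = REF, `NO_CALL` dropped per span, not per sample) in a linear
model with the top 10 ancestry PCs. Interaction models add
genotype × moderator terms (moderator = a standardized PGS, or sex coded
0/1) and report the allele × moderator coefficient with z = β/SE; moderator
× PC terms are not included, matching the model as specified. Variance
explained compares R² of all-loci-as-factors + PCs against PCs alone, with
listwise removal of `NO_CALL` rows and lm-style aliasing for collinear
genotype columns.

Medication context: per-sample prescription codes collapse into
antidepressant / antipsychotic / mood-stabilizer flags plus their union;
enrichment among carriers is an uncorrected 2×2 chi-square. Stratified
group means (genotype × PGS quartile × medication) use quartile boundaries
from the full cohort — carriers are rare enough (< 5%) that excluding them
from the quantile computation changes boundaries negligibly, and the full-
cohort version is simpler to reproduce.

# Meta-analysis

Fixed effects throughout: weights 1/SE², pooled SE = 1/√Σw. Heterogeneity
(Q, I²) is computed and reported but never switches the estimator to random
effects — the per-cohort scaling makes the estimand common by construction.
R² values pool on the Fisher-z scale of √R² with weights n − 3 (the inverse
sampling variance of Fisher's z for a correlation; the natural choice where
the convention is otherwise unstated), then back-transform. Carrier
filters: ≥ 10 combined carriers for main effects, ≥ 200 for interaction
designs. Bonferroni correction uses m = 47 for locus main effects and
m = 32 for interaction tests; both `m` are arguments.

# Dose-response decomposition

DEL and DUP meta-effects pair into per-locus dose-response points (both
alleles ≥ 10 carriers). The decomposition fits a Gaussian mixture of linear
regressions of β_DUP on β_DEL, with each point's SE² added to the component
noise. This is the minimal model class that can express the two observed
archetypes: a *mirror* component (negative slope) and an *asymmetric*
component (slope ≈ 0: one allele null regardless of the other). Fitting is
generalized EM (exact weighted-least-squares update for slope/intercept,
1-D likelihood maximization for each component variance — both coordinate
ascent, so the likelihood is monotone) with ≥ 20 seeded restarts; one k = 2
start is the degenerate split of the k = 1 solution, which guarantees the
2-component log-likelihood never falls below the 1-component one. Model
choice is by BIC; AIC or a bootstrap LRT would be defensible alternatives,
and BIC was chosen as the most conservative standard criterion for a
mixture with few points. Measurement error on the x-axis (SE_DEL) is
ignored in the default fit and is a known attenuation source; a regression-
calibration correction is deliberately out of the default path.

Sex differences: female effects regress on male effects across loci and an
F-test of the joint hypothesis {intercept = 0, slope = 1} measures
deviation from the identity line. Grouped contrasts (positive / neutral /
negative by Bonferroni-significant main effect sign) pool per-locus
female-minus-male differences with SE = √(SE_F² + SE_M²) — exact for
sex-stratified fits on disjoint samples.

# Age trajectories and mediation

Trajectory tests use fixed-df natural cubic splines rather than penalized
smooths: the null (constant carrier offset) and full (carrier offset +
carrier-specific spline in age, default df = 5) models are then genuinely
nested and the LRT has an exact asymptotic chi-square reference, which
makes the null calibration testable. df is exposed; sensitivity to it is
the user's to explore. Group comparisons (obesity, sex, PGS quartile) use
shared-smooth vs group-specific-smooth nesting, and are invariant to label
swaps. The obesity split defaults to the 90th BMI percentile with a 30th-
percentile preset for alleles where obesity is sparse.

Age-binned cross-sectional mediation works on raw phenotypes with sex and
age as covariates (ancestry PCs are deliberately absent, matching the
specification of the mediator and outcome models): mediator model
`BMI ~ sex + age + CNV`, outcome model `HEIGHT ~ BMI + sex + age + CNV`,
ACME = a·b (product of coefficients), ADE = the outcome-model CNV
coefficient, percentile bootstrap (default 1,000 resamples, seeded, bit-
reproducible) for CIs. Bins are upper-exclusive; bins with < 10 carriers
are flagged underpowered. In the all-linear specification ACME + ADE equals
the total-effect coefficient to machine precision, which the tests assert.
The reverse-direction run swaps mediator and outcome: a genuinely
BMI-mediated effect shows a forward ACME but a null reverse ACME when the
direct and mediated height effects cancel (the deletion archetype).

# Subregion additivity

For a composite span (e.g. A-D), the additive expectation is the sum of
disjoint component effects with SE = √ΣSE² (independence; component and
composite carriers are disjoint groups sharing only the reference pool, so
the neglected covariance is small and the test conservative). The deviation
z = (obs − exp)/√(SE_obs² + SE_exp²) is two-sided normal; significant
attenuation of magnitude tags `sub-additive` (buffering), amplification
`super-additive`. The verdict α defaults to 0.05 uncorrected — one
pre-specified composite test per locus. The expectation operator is
associative, which the tests verify on nested decompositions.

# The synthetic-data generator

`simulate_cohorts()` emulates the federated setting: five adult cohorts
with the relative sizes and sex ratios of large biobanks (one strongly
male-dominated), uniform ages within cohort-specific ranges, 10
standard-normal PCs, standard-normal PGS per trait, per-allele Bernoulli
carriers (mutually exclusive within a locus, as NAHR alleles effectively
are at these frequencies), raw CNV intervals with N(0, 20 kb²) breakpoint
jitter, 5% fragmentation and a 1e-4 false-call rate, and medication
assignment by a logistic model with a carrier odds ratio feeding a BMI
side-effect. Adult raw units are monotone per-sex maps of the latent SD
scale (height affine, BMI log-scale so the raw distribution is
right-skewed); pediatric phenotypes are generated on the LMS z scale — so
non-carrier z-scores are standard normal at every age by construction —
and converted to raw units through the packaged reference.

The default effect map plants the headline archetypes: a 16p11.2-like
mirror pair (DEL +BMI/−height with an obesity-gated childhood growth bump;
DUP −BMI with a child-short/adult-tall height trajectory), a 22q11.2-like
segmented locus with opposing A-B/C-D duplication effects and a
sub-additive full-span deletion, a 15q11.2-like female-biased BMI allele,
and mixed mirror/asymmetric effects elsewhere with magnitudes centred near
the ~0.34 SD scale characteristic of recurrent CNVs. Trajectory presets are
smooth: the divergent pattern is a pubertal-transition sigmoid from −0.5 z
to +0.5 z centred at age 13, and the transient pattern a smoothed plateau
over ages 8–13 — shapes a growth curve can plausibly take and that a
spline basis can represent.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, probe-level intensity noise, platform-specific call
quality, genuine ancestry stratification (PCs are exchangeable normals
unless confounding is explicitly planted), longitudinal within-person
correlation, and informative missingness. Passing calibration on synthetic
data therefore demonstrates the statistical machinery is correct under the
stated generative assumptions, not that real-data confounding is handled
beyond what PC adjustment can do.

# Numerical choices and problem sizes

* Regression fits use QR decompositions; rank deficiency is an error in
  the association paths and lm-aliasing (with warning) in the variance-
  explained path. Degenerate strata are reported with n = 0, never imputed.
* EM convergence: |Δ log-likelihood| < 1e-10, max 500 iterations,
  best-so-far returned and flagged if unconverged. Components are ordered
  by slope for stable labelling.
* All randomness flows from explicit seeds through private RNG streams
  (per-cohort streams derive from the master seed, so adding a cohort
  leaves existing cohorts' draws unchanged); reruns are byte-identical.
* Calibration problem sizes were chosen to give stable rates at desk
  scale: 10,000 genotyper oracle instances; 200 replicates of the
  5-cohort, 500,000-sample recovery of a −0.341 SD allele at carrier
  frequency 5e-4; 1,000 replicates for interaction size and additivity
  calibration; 2,000 replicates for meta CI coverage; 40–60 seeds for
  mixture model selection. The recovery runs skip raw-call emission and
  use truth genotypes directly — breakpoint-noise robustness is measured
  separately by the genotyper oracle and round-trip tests.

# Limitations

Mixed-effects/kinship adjustment, multi-caller consensus and CNV-level QC,
PGS weight estimation, longitudinal growth modelling, and non-linear
(U-shaped) dose-response fits are out of scope. The additivity SE ignores
the shared-control covariance (conservative). The LMS reference and the
locus catalog shipped here are synthetic stand-ins; substantive analyses
must supply real ones.
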