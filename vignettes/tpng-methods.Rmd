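---
title: "Total plasma N-glycome traits and diabetes complications: methods"
author: "tpng package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total plasma N-glycome traits and diabetes complications: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

The total plasma N-glycome (TPNG) is the ensemble of N-linked glycans
released enzymatically from all plasma proteins and quantified by mass
spectrometry as relative abundances of glycan *compositions* — count
vectors of hexose (H), N-acetylhexosamine (N), fucose (F) and
linkage-differentiated sialic acid (L = alpha2,3-linked, E =
alpha2,6-linked, distinguishable after linkage-specific derivatization).
`tpng` turns a panel of such compositions into 45 *derived traits* that
each summarize one structural feature (antennarity, bisection,
fucosylation, galactosylation, sialylation per linkage), screens every
trait for association with prevalent (logistic regression) and incident
(Cox regression) diabetes complications — cardiovascular disease (CVD),
nephropathy, retinopathy — in two cohorts, pools the two estimates per
trait by DerSimonian–Laird random-effects meta-analysis with I²
heterogeneity, and controls the false discovery rate by
Benjamini–Hochberg within each endpoint × design × model family of 45
traits. Because the patient-level data of the motivating studies are not
publicly available, the package ships a synthetic two-cohort generator
that reproduces the published *structure* of those cohorts (sizes,
covariate distributions, complication rates, plate layout, replicate
precision) with known planted effects, so that every stage is testable
end to end.

## Glycan model

### Composition grammar and classification

Compositions are written `H5N4F1E1`-style; H and N are mandatory, F/L/E
default to zero, and N ≥ 2 because plasma N-glycans retain the chitobiose
core. Classification uses a deterministic rule table:

* **high-mannose**: N = 2 and 4 ≤ H ≤ 9 (Man4–Man9); never fucosylated or
  sialylated;
* **hybrid**: N = 3 and H ≥ 5;
* **complex**: everything else with N ≥ 3 and H ≥ 3. Antennarity is
  min(N − 2, 4). A composition with N = a + 3 (1 ≤ a ≤ 4) and H ≤ a + 3
  is instead read as *bisected* with antennarity a: the extra HexNAc is a
  bisecting GlcNAc on the core mannose rather than an additional antenna
  (N5 with H ≤ 5 is bisected diantennary; N5 with H6 is triantennary).

Composition-level data cannot separate core from antenna fucose, so
F ≥ 1 simply marks a composition as fucosylated. Galactoses on complex
glycans are min(H − 3, antennarity) — three hexoses belong to the
trimannosyl core — floored at L + E because every sialic acid caps a
galactose; for hybrid species (antennarity recorded as 0) the floor is
what carries the single decorated arm. A composition whose L + E exceeds
its available galactoses is rejected at panel load: silent clipping would
hide transcription errors in a panel file.

The bisection-versus-triantennary disambiguation is the one genuinely
underdetermined point of any composition-level rule table. The packaged
panel therefore supports per-composition `override_class` /
`override_antennarity` / `override_bisected` columns, and uses them to pin
the classic agalactosylated diantennary species (N4 with H ≤ 4, e.g. the
IgG G0/G0F compositions H3N4 and H3N4F1) to non-bisected A2, which the
generic rule would otherwise read as bisected monoantennary.

### The packaged panel and trait set are synthetic stand-ins

The curated 68-composition panel and the 45 trait formulas of the
motivating studies are not public. The packaged files
(`glycan_panel_synthetic.tsv`, `derived_traits_synthetic.tsv`) are
constructed stand-ins: 68 compositions spanning Man4–Man9, six hybrids,
and complex mono- to tetra-antennary species with fucosylation, bisection
and mixed L/E sialylation; and 45 traits covering the canonical families
(complexity including the high-mannose/hybrid ratio MHy and the
antennarity fractions CA1–CA4; fucosylation; bisection, e.g. A2FS0B =
bisection within fucosylated non-sialylated diantennary species;
galactosylation per antenna; and per-antenna or per-galactose sialylation
split by linkage, e.g. A3E, A4F0GL). Any analysis of real data should
replace both files with the laboratory's own curated versions; the
loaders validate them (unique names, known keywords, non-empty scopes,
sialylation cap).

Two deliberate consequences of the rule table: non-bisected triantennary
species require H ≥ 6 and are then fully galactosylated, so a
"galactosylation per antenna in A3/A4" trait would be structurally
constant over this panel; the galactosylation family therefore lives on
the diantennary scopes, where under-galactosylated species exist.

### Trait algebra

With abundances $x_j$ (row-normalized to 1) and panel annotation, each
trait is a ratio of weighted sums over its *scope* $S$ (a conjunction of
structural predicates):

* **fraction**: $\sum_{j \in S \cap F} x_j / \sum_{j \in S} x_j$ for a
  feature predicate $F$;
* **per-antenna**: $\sum_{j \in S} c_j x_j / \sum_{j \in S} a_j x_j$ with
  $c_j$ a count (E, L, S = L + E, or galactoses) and $a_j$ the
  antennarity — the abundance-weighted count ratio, not a mean of
  per-glycan ratios, which keeps the denominator away from zero;
* **per-galactose**: as above with galactoses in the denominator;
* **ratio**: two disjoint groups, e.g. MHy = high-mannose / hybrid mass
  (the plain ratio; the alternative reading with a combined denominator
  is not used).

A sample with zero denominator mass gets a missing value; missing trait
values are dropped pairwise downstream and never imputed (only clinical
covariates are). Traits are Z-scaled per cohort (mean 0, SD 1, n − 1
denominator) so that all effects are per-SD and poolable across cohorts.

## Preprocessing

Order is fixed: quality control on *raw* spectra (total intensity below a
threshold, default 10% of the median row sum since absolute scales are
instrument-dependent), then total-area normalization, then traits,
replicate precision, batch correction, Z-scaling.

Technical precision is the percent relative SD (n − 1) of each trait
across pooled-plasma replicate wells; the package reports it both for
derived traits and for the normalized compositions themselves. Ratio
traits average independent per-composition noise, so derived-trait RSDs
sit *below* the composition-level CV — with the default 5% technical CV
the composition RSDs recover ≈5% while derived-trait RSDs land near 2%.

Batch (plate) correction is a parametric empirical-Bayes location–scale
harmonization implemented in the package: per-feature standardization
against the size-weighted grand mean and pooled variance, per-batch
location/scale estimates shrunk toward common normal / inverse-gamma
priors fitted across features by moments, fixed-point iteration to
convergence (relative tolerance 1e-8), back-transformation. No covariate
term is included. The test suite verifies the implementation against the
reference empirical-Bayes batch correction in `sva` to ~1e-3 and notes a
property worth knowing: shrinkage deliberately leaves a per-feature
remainder of each batch mean's deviation from the common prior, so a
planted constant plate shift is removed >90% *in the mean across
features* (and exactly by the unshrunk variant, `eb = FALSE`). Correction
is applied to derived traits by default — traits are the analysis unit —
with a switch for composition-level correction
(`preprocess_cohort(batch_on = "compositions")`).

## Covariate imputation

Missing clinical covariates (BMI, HDL-c, non-HDL-c, systolic blood
pressure, HbA1c, smoking, diabetes duration, creatinine) are completed by
chained equations: predictive mean matching for continuous variables
(Bayesian parameter draw, donor pool of 5 nearest predicted neighbours)
and a multinomial draw for smoking, m = 5 completed tables, 10 iterations
per chain, variables visited in order of increasing missingness,
deterministic under the seed. Non-HDL cholesterol is derived as total
cholesterol − HDL-c wherever both are observed before imputation.
Observed cells are never modified. Downstream association can run on each
completed table with Rubin's-rules pooling (between/within variance, t
reference) or on a single completed table; with identical tables the
pooled result collapses to the single fit exactly.

## Endpoints

Nephropathy at baseline follows the urinary albumin-to-creatinine-ratio
rule: microalbuminuria (ACR ≥ 2.5 mg/mmol men, ≥ 3.5 women) at two of
three *consecutive* measurements, or high micro-/macroalbuminuria
(≥ 12.5 men, ≥ 17.5 women) at a single measurement; all thresholds
inclusive. "Two of three consecutive" is a width-3 sliding window (the two
qualifying values need not be adjacent); trajectories shorter than three
visits use the available consecutive pair only if both qualify, and a
single moderate value is never a case. CVD and retinopathy arrive
pre-adjudicated as boolean-plus-date columns.

Prevalent analysis uses everyone with known baseline status; the incident
risk set is the baseline-negative subjects with time = event time −
baseline, censored at the last visit. An "incident" event dated at or
before baseline is a data inconsistency and is moved to the prevalent set
with a log message.

## Association models and meta-analysis

One model per trait (45 models per endpoint × design × cohort, mirroring
the one-row-per-trait reporting convention). Model 1 adjusts for age, sex
and age×sex; the full model adds BMI, HDL-c, non-HDL-c, systolic blood
pressure, diabetes duration, HbA1c and smoking (two indicators, never =
reference), plus creatinine for the CVD and retinopathy endpoints.
Logistic fits use iteratively reweighted least squares (deviance change
< 1e-8, ≤ 50 iterations); separation flags the trait and suppresses its p
value. Cox fits maximize the Efron-tie partial likelihood
(`survival::coxph`); the tie-free equivalence of Efron and Breslow is a
regression test guarding the default. Negating a trait negates its
coefficient exactly, and identical inputs give bit-identical fits.

Per trait, the two cohort estimates are pooled by DerSimonian–Laird:
fixed-effect weights $w_i = 1/se_i^2$, Cochran's
$Q = \sum w_i (b_i - b_{FE})^2$, method-of-moments
$\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}$,
re-weighting by $1/(se_i^2 + \tau^2)$, and a normal-reference two-sided p
value — with two studies a Knapp–Hartung t adjustment is unstable, so z
is used. $I^2 = \max\{0, (Q - (k-1))/Q\} \times 100$. FDR is
Benjamini–Hochberg per endpoint × design × model over the full 45-trait
family, significant and non-significant alike.

## The synthetic generator

The generator's defaults are the published structure of the two emulated
cohorts and are not tuning knobs:

| parameter | DiaGene-like | Hoorn-DCS-like |
|---|---|---|
| n passing QC | 1815 | 1518 |
| age (y), mean (SD) | 65.2 (10.6) | 64.5 (10.6) |
| female | 46.3% | 43.7% |
| BMI (kg/m²) | 29.5 (5.5) | 30.4 (5.4) |
| HbA1c (%) | 7.0 (1.1) | 6.8 (1.0) |
| follow-up (y), median | 7.0 | 8.5 |
| prevalent CVD / nephropathy / retinopathy | 34.6 / 20.2 / 16.0% | 19.0 / 15.5 / 14.2% |
| incident CVD / nephropathy / retinopathy | 10.1 / 20.1 / 16.1% | 8.0 / 12.4 / 9.9% |

Glycome profiles are logistic-normal: a heuristic mean log-abundance
profile (galactosylated alpha2,6-sialylated diantennary species dominate,
Man5 leads the high-mannose series) plus three correlated biological
factors — bisection loading positively on fucosylation and negatively on
full galactosylation, an E-versus-L sialylation trade-off, and a
branching factor — plus independent log-normal noise, mapped through a
softmax so every sample is compositional by construction. A Dirichlet
profile could not encode this trait–trait correlation structure, which is
exactly what makes multiple-testing behaviour realistic. Plates carry 80
clinical samples plus two wells of a single pooled-plasma profile;
measured intensities apply a per-plate per-composition multiplicative
shift (log-SD 0.05), 5% multiplicative technical noise, and a log-normal
total intensity. Covariates come from the published means/SDs with a
shared one-factor metabolic structure (positive loadings on BMI, blood
pressure, HbA1c, total cholesterol and creatinine, negative on HDL-c)
that preserves the marginal SDs while making the covariates mutually
predictive — without that, a masking experiment for imputation would be
meaningless. Missingness is MCAR at 3% per covariate (< 7%).

Outcomes are generated from the traits computed on the *noise-free*
latent profiles: prevalent flags from a logistic model whose intercept is
solved numerically to hit the cohort's target prevalence given the
planted per-SD trait effects and mild age/sex effects; incident events
from an exponential hazard (Weibull-free baseline kept deliberately
simple) calibrated the same way against per-subject administrative
censoring drawn around the published median follow-up. ACR trajectories
are constructed so the nephropathy rule reproduces the planted label
(configurable agreement). The default planted effects cover positive,
negative and null traits: A2FS0B +0.32 and A3L −0.18 (prevalent CVD), A3E
+0.25 and A2FS0G −0.20 (prevalent nephropathy), MHy −0.24 (prevalent
retinopathy), and smaller incident analogues; all other traits are null.

What the generator does **not** emulate: raw mass spectra and peak
picking, isomer structure beyond the composition heuristics, informative
missingness, competing risks, medication effects, and real biological
effect patterns across many correlated traits. Passing tests therefore
demonstrate that the *machinery* is correct and calibrated, not that the
synthetic effect sizes transfer to real cohorts.

## The recovery experiment and why the null check is a separate arm

`recovery_experiment()` plants a log OR of 0.32 per SD (OR 1.38) on a
single trait (default A2FS0B), simulates both cohorts at full size (1815
+ 1518, pooled prevalence 0.275), runs the trait computation, Z-scaling,
basic-model logistic screen and DerSimonian–Laird meta-analysis, and
averages the pooled estimate over 200 replicates; plate effects and
technical noise are off so the experiment isolates the estimation
machinery. Because the glycome is correlated, traits correlated with the
causal trait are *genuinely* marginally associated — flagging them is
correct behaviour of a marginal screen, not a false discovery. The
false-discovery property is therefore measured in a matched all-null arm
(every planted effect zero), where the FDR-significant fraction across
the 45 traits must stay at or below 5%. Both arms run inside the
acceptance suite and `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Zero-variance traits abort Z-scaling by name; all-zero spectra are
  dropped with an exclusion record; an empty QC result is a hard error.
* Batch correction requires ≥ 2 batches of ≥ 2 samples and suggests
  merging singletons; its fixed-point iteration caps at 200 steps.
* PMM uses a 1e-5 ridge; the multinomial imputer falls back to the
  two-level case automatically.
* Separation (|β| > 15 or non-convergence) and monotone Cox likelihoods
  flag the trait; flagged cohort results blank the pooled row rather than
  poison it.
* Meta-analysis refuses k < 2 or non-positive SEs; BH refuses p outside
  (0, 1].
* All simulation seeds are small integers; every exported generator sets
  its own seed so stages are independently reproducible.

## Problem sizes used by the packaged experiments

The test suite and acceptance script run the recovery experiment at the
full cohort sizes with 200 replicates, the replicate-precision and
batch-correction experiments at a few hundred samples, the oracle
equivalences at 100 random samples (traits) and 1000 random vectors
(FDR), and one complete pipeline run (both cohorts, both models, all
endpoints) at full size with a single completed imputation table — sizes
chosen so the whole suite stays comfortably inside a coffee break on one
CPU while keeping Monte-Carlo error well below the asserted tolerances.

## Known limitations

* The packaged panel/trait spec is a constructed stand-in; structure
  assignments for ambiguous compositions follow the rule table plus
  overrides, not curated structural evidence.
* Only two cohorts: τ² estimation from k = 2 is noisy by nature and I²
  is reported descriptively.
* The exponential incident hazard has no time-varying effects; the Cox
  screen is correctly specified for it by construction.
* Medication use, competing risks and informative censoring are out of
  scope.
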