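# tpng — total plasma N-glycome traits and diabetes complications

`tpng` is an R package plus analysis workflow for studying how the **total
plasma N-glycome (TPNG)** — the ensemble of N-linked glycans released from
all plasma proteins and quantified by mass spectrometry — relates to
complications of type 2 diabetes (cardiovascular disease, nephropathy,
retinopathy) in two cohorts. It is written for glycomics and
epidemiology groups who have composition-level glycan abundances and
clinical endpoint data and want a tested, reproducible screen from raw
intensities to meta-analyzed, FDR-controlled per-trait effects.

## What it computes

Glycan compositions are count vectors `H` (hexose), `N`
(N-acetylhexosamine), `F` (fucose), `L` (alpha2,3-linked sialic acid) and
`E` (alpha2,6-linked sialic acid), written `H5N4F1E1`-style. From a
68-composition panel the package derives **45 structural traits** — e.g.
A2FS0B (bisection within fucosylated non-sialylated diantennary glycans),
A3E (alpha2,6-sialylation per antenna on triantennary glycans), MHy
(high-mannose/hybrid ratio) — as ratios of abundance-weighted sums:

* fraction traits: Σ ab(scope ∧ feature) / Σ ab(scope)
* per-antenna: Σ count·ab / Σ antennarity·ab over the scope
* per-galactose: Σ sialic-count·ab / Σ galactoses·ab

Each Z-scaled trait is screened per cohort with logistic regression
(prevalent outcomes) and Cox regression with Efron ties (incident
outcomes), under a basic model (age, sex, age×sex) and a full covariate
model (plus BMI, HDL-c, non-HDL-c = TC − HDL-c, systolic BP, diabetes
duration, HbA1c, smoking; creatinine for CVD/retinopathy). The two cohort
estimates are pooled by **DerSimonian–Laird random-effects
meta-analysis** (Q, τ², I²) and the 45 traits of each endpoint × design ×
model family are **Benjamini–Hochberg** FDR-controlled at 5%.

Around the core sit the supporting stages a real study needs, all
implemented and tested: total-area normalization, intensity-based QC,
pooled-replicate precision (RSD%), empirical-Bayes plate/batch correction,
chained-equations covariate imputation with Rubin pooling, and the
sex-specific albumin-to-creatinine-ratio nephropathy case rule. Because
the motivating patient data are not public, a synthetic two-cohort
generator (n = 1815 and 1518, published covariate and complication
structure, planted per-trait effects) makes every stage testable; the
packaged panel and trait spec are labelled `_synthetic` accordingly.

## Worked example

Classify compositions and inspect the structural annotation:

```r
library(tpng)
panel <- read_glycan_panel(tpng_panel_file())
defs  <- read_trait_panel(panel = panel)
classify_composition(parse_composition(c("H5N2", "H5N4F1E1", "H5N5F1")))
#>      label glycan_class antennarity bisected galactoses fucosylated sialylated
#> 1     H5N2 high-mannose           0    FALSE          0       FALSE      FALSE
#> 2 H5N4F1E1      complex           2    FALSE          2        TRUE       TRUE
#> 3   H5N5F1      complex           2     TRUE          2        TRUE      FALSE
```

H5N2 is Man5; H5N4F1E1 is a fucosylated, digalactosylated diantennary
glycan with one alpha2,6-linked sialic acid; the extra HexNAc of H5N5F1
is read as a bisecting GlcNAc.

Run the full two-cohort pipeline on small synthetic cohorts and look at
the meta-analyzed prevalent-CVD screen (basic model):

```r
cfg <- default_sim_config()
cfg$cohorts$diagene$n <- 400L; cfg$cohorts$dcs$n <- 350L
res <- run_pipeline(cfg, seed = 7)
m1 <- subset(res$meta, model == "model1" & design == "prevalent-logistic" &
                       endpoint == "cvd")
head(m1[order(m1$p), c("trait", "effect", "se", "q", "i2", "p", "p_fdr")], 5)
#>    trait effect     se      q i2       p  p_fdr
#>   A2FS0B  1.298 0.0817 0.5017  0 0.00140 0.0269
#>  A2F0S0G  0.767 0.0834 0.1843  0 0.00149 0.0269
#>    A2F0G  0.777 0.0810 0.1968  0 0.00179 0.0269
#>      A3L  0.773 0.0865 0.0267  0 0.00294 0.0331
#>    A2FGE  1.249 0.0823 0.0127  0 0.00684 0.0616
```

`effect` is the odds ratio per 1 SD of the trait. The generator plants a
positive effect on A2FS0B (log OR 0.32) and a negative one on A3L (−0.18)
for prevalent CVD; both surface at the top of the screen even at these
reduced sizes, together with traits correlated with them, and `p_fdr`
shows which survive FDR control within the 45-trait family. `q`, `i2`
quantify between-cohort heterogeneity.

## Analysis workflow

The numbered scripts under `analysis/` run the whole study at full cohort
sizes, writing intermediates to `scratch/analysis/` and small summary
tables to `results/analysis/`:

```sh
Rscript analysis/01_simulate.R     # two cohorts, plates, outcomes, truth
Rscript analysis/02_preprocess.R   # QC, normalization, traits, RSD, ComBat
Rscript analysis/03_endpoints.R    # ACR nephropathy rule, analysis sets
Rscript analysis/04_associate.R    # per-trait logistic + Cox, m = 5, Rubin
Rscript analysis/05_meta.R         # DL meta-analysis, I², BH-FDR
Rscript analysis/06_report.R       # trait report + OR-vs-HR pairing
```

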