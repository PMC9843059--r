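# tmebenefit

Quantifies the tumor microenvironment (TME) of EGFR-mutant lung
adenocarcinoma from nuclei centroid maps and predicts which patients
benefit from EGFR tyrosine-kinase-inhibitor (TKI) therapy.

Pathology slides processed by a nucleus segmentation/classification model
yield, per slide, the centroid and type of every nucleus (tumor, stroma,
lymphocyte, red blood cell, macrophage, karyorrhexis). From these maps the
package computes 12 image features — six cell-type densities and six
tumor–X cellular-interaction fractions

&nbsp;&nbsp;&nbsp;&nbsp;*I*(tumor, k) = (# Delaunay edges joining a tumor cell to a type-k cell) / (# Delaunay edges incident to a tumor cell)

over up to one hundred 1024×1024 px patches sampled from the tumor region
(tiles of 500×500 px with ≥ 10 tumor nuclei), plus the tumor/stroma ratio
(TSR). An elastic-net penalized Cox model on TKI-treated patients turns the
features into a risk score Σ βⱼfⱼ (higher = predicted not to benefit); a
median split defines predicted benefit groups, validated by log-rank tests
and an adjusted treatment-by-group interaction Cox model. A genomics stage
correlates the predictive features with gene expression (Spearman), runs
preranked GSEA with Benjamini–Hochberg adjustment, and checks specificity
with a patient-ID-shuffle negative control.

The clinical cohorts such a model is built on are not public, so the
package includes generators for cell maps (tumor nests with controllable
stroma mixing), survival cohorts (proportional hazards with planted
per-10% hazard ratios 0.73 and 1.53 and group-restricted treatment
benefit), and expression matrices (Gaussian-copula planted correlations).
Every stage of the analysis is exercised end to end on synthetic data.

## Worked example

```r
library(tmebenefit)

# one synthetic slide -> 12 image features
m   <- simulate_cell_map(seed = 7)
sf  <- slide_features(m, seed = 3)
round(sf$interaction_tumor_stroma, 3)   # 0.518
round(sf$tsr, 2)                        # 1.19
sf$n_patches_used                       # 26

# cohort-level: fit, score, split, validate
f   <- simulate_feature_matrix(400, seed = 11)
co  <- simulate_cohort(f, seed = 12)
mod <- fit_penalized_cox(f, co, seed = 13)
print(mod)
#> risk_model: elastic-net Cox (alpha=0.50, lambda=0.05619, n=282, 148 events)
#> selected features include:
#>   interaction_tumor_tumor          -2.1372
#>   interaction_tumor_stroma          4.2931
asg <- median_split(score_patients(mod, f))
table(asg$group)
```

The fitted signs mirror the biology the model encodes: a higher
tumor–tumor interaction (cohesive, proliferative tumor) is protective under
TKI therapy (negative coefficient, per-10% HR < 1), while a higher
tumor–stroma interaction (stromal infiltration, fibroblast crosstalk) is
harmful (per-10% HR > 1).

The same computation, presented as a narrative, lives in the numbered
scripts under `analysis/` (simulate → extract features → fit → validate →
image genomics); each writes its tables under `results/`.

## Package layout

- `R/` — feature extraction, survival modeling, image genomics, synthetic
  generators, pipeline orchestration (`run_pipeline()` over a YAML config;
  a small bundled study config sits in `inst/extdata/study_config.yaml`)
- `analysis/` — numbered narrative drivers over the package functions
- `vignettes/tme-tki-benefit.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles (empty-circumcircle Delaunay, running-sum
  GSEA, hypergeometric log-rank)
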