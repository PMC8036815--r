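# immunocontext

Immune-contexture quantification and ensemble prognosis for
muscle-invasive bladder cancer (MIBC).

## The problem

MIBC is staged clinically with the TNM system, but patients within the
same anatomical stage vary widely in outcome.  The tumour-immune
microenvironment — tumour-infiltrating lymphocytes (CD3+ general and
CD8+ cytotoxic T cells), tumour-associated macrophages (CD68+ total,
CD163+ M2), PD-L1 expression, and tumour buds (detached epithelium
objects of 1–4 nuclei at the invasive front) — carries prognostic
signal that TNM ignores.  This package implements, as tested R code, a
full pipeline that turns cell-level whole-slide immunofluorescence data
into a 5-year prognosis:

1. **Phenotyping** — cells are marker-positive iff the mean normalised
   intensity over an 11 px circular neighbourhood of the nucleus is
   ≥ 0.125; seven phenotype populations derive from the flags plus
   tumour-bud membership (8-connected epithelium objects with 1–4
   nuclei).
2. **Region partition** — tumour core vs the invasive front: 500 µm
   inside (front-in) and 500 µm outside (front-out) the tumour border,
   by Euclidean-disc morphology on the mask.
3. **Spatial statistics** — cross-type Ripley K and its
   variance-stabilised L transform,

   K̂ₓᵧ(r) = A/(nₓ·nᵧ) · ΣᵢΣⱼ 1(dᵢⱼ ≤ r),  Lₓᵧ(r) = √(K̂ₓᵧ(r)/π),

   evaluated at r ∈ {20, 50, 100, 150, 200, 250} µm for ten population
   pairs (immune cells and PD-L1 around tumour buds; PD-L1 around
   immune cells).  Under complete spatial randomness L(r) = r.
4. **Features** — a named 201-feature vector per patient: 126 image
   (counts and densities of 21 populations × 3 regions), 60 spatial
   (10 pairs × 6 radii), 15 clinical (age, sex, TNM one-hots), with
   seven standard feature subsets.
5. **Labels** — survival binarized at 60 months: MIBC death within 5
   years = bad prognosis, survival past the cut-off = good; patients
   censored before the cut-off are excluded.
6. **Learning** — nested cross-validation (5-fold random search inside
   a 2-fold comparison) over five classifier families, then a voting
   ensemble of four submodels — linear SVM on image features, decision
   tree on image + clinical, logistic model on image + spatial, random
   forest on all features — with high risk ⇔ ≥ 2 bad-prognosis votes.
7. **Evaluation** — AUROC/accuracy/sensitivity/specificity/F1,
   Kaplan–Meier curves, log-rank tests and univariate Cox hazard
   ratios against the TNM baseline (stage IV = high risk), plus
   post-hoc feature importance (2× mean or 2× median retention rules).

Because no cohort of this kind is publicly deposited, the package
includes a synthetic-cohort generator with known ground truth — point
patterns (Poisson and Thomas-clustered), detached tumour-bud objects,
rendered immunofluorescence patches, TNM-like clinical covariates, and
competing-risk exponential survival driven by planted feature effects —
so the whole pipeline is testable end to end.

## Worked example

```r
library(immunocontext)

cfg    <- cohort_config(n_patients = 78, seed = 1)
cohort <- generate_cohort(cfg)
feats  <- cohort_features(cohort)          # 78 x (1 + 201)
lab    <- binarize_survival(cohort$clinical)

keep  <- lab$labels != "excluded"
y     <- lab$labels[keep]; fm <- feats[keep, ]
split <- stratified_split(y, 0.25, seed = 1)

ens  <- build_ensemble(fm[split$train, ], y[split$train],
                       n_configs = 40, seed = 1)
pred <- ensemble_predict(ens, fm[split$test, ])
roc_auc(pred$votes, y[split$test], positive = "bad")
```

Run on the seed-1 synthetic cohort (via `analysis/01` … `04`), this
prints:

```
labels: 48 bad, 22 good, 8 excluded (10% exclusion)
70 labelled patients -> 52 train / 18 test
  svm             on 'image'                       train AUROC 96.2%, CV 80.1%
  decision_tree   on 'image and clinical'          train AUROC 93.0%, CV 74.6%
  logistic_model  on 'image and spatial'           train AUROC 90.8%, CV 89.9%
  random_forest   on 'image, spatial, and clinical' train AUROC 98.6%, CV 92.1%
  logistic_model retains 2 features (2x mean rule); top: TB_any_core_density,
    cytotoxic_T_neg_frontin_density, ...
test  ensemble AUROC  92.4  acc  83.3  sens  66.7  spec  91.7  F1  72.7  HR 5.8 (1.3, 27.0)  logrank p 0.012
test  tnm      AUROC  45.8  acc  33.3  sens  83.3  spec   8.3  F1  45.5  HR 0.5 (0.1, 4.0)  logrank p 0.52
```

What these numbers mean: the synthetic cohort plants a harmful
tumour-bud density in the core (+1 log-hazard per SD) and a protective
cytotoxic-T density at the front-in (−1 per SD).  The ensemble
stratifies the held-out patients sharply (AUROC 92.4%, hazard ratio
5.8 between risk groups, log-rank p = 0.012) and both planted drivers
top the post-hoc importance rankings.  Sensitivity is reported on
good-prognosis patients, so "specificity" is the correctly-classified
fraction of patients who succumb.  The TNM baseline sits at chance by
construction — the generator's default hazard has no clinical-stage
effect — so the comparison exercises the machinery rather than making
a biological claim.  Numbers vary with the seed; the seed-averaged
held-out AUROC over five 400-patient cohorts is 82% (recomputed by
`scripts/acceptance.R`).

The numbered scripts under `analysis/` run the same study as a
narrative workflow — `01_simulate_cohort.R` (cohort + Table-1-style
summary), `02_quantify_features.R` (feature matrix + labels),
`03_train_ensemble.R` (ensemble + importance tables),
`04_evaluate.R` (metrics, KM curves, TNM comparison) — writing their
tables under `results/`.

## Layout

```
R/                 package code (generator, phenotyping, regions,
                   spatial stats, features, labels, learning, reporting)
src/               Rcpp kernels: pair counting, 8-connected labelling
tests/testthat/    unit + property tests, acceptance suite
analysis/          numbered workflow scripts (write to results/)
scripts/           acceptance.R
vignettes/         methods vignette (models, assumptions, design choices)
```
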