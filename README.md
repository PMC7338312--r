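# petromics

PET radiomics texture analysis and survival-based prognostic modeling for
head-and-neck tumors, motivated by minor salivary gland carcinoma (MSGC) —
a rare malignancy whose course is poorly predicted by AJCC stage and WHO
histology risk alone. The package is written for imaging scientists and
biostatisticians who want to quantify [¹⁸F]FDG uptake heterogeneity on PET
and fold it, together with clinical factors, into a validated prognostic
index — and to test every step of that pipeline on synthetic data when
patient images cannot be shared.

## What it computes

**Lesion quantification.** Tumors and nodes are segmented at a fixed 40%
of SUVmax (T40), iterated to a fixed point over the seed's 26-connected
component. From the segmented volume of interest (VOI) the package
computes SUVmax, metabolically active tumor volume (MATV, mL), mesh-based
asphericity

&nbsp;&nbsp;&nbsp;&nbsp;ASP = (S³ / 36πV²)^{1/3} − 1,

and, after fixed-bin-number (FBN) discretization onto B = 16 gray levels,
the discretized intensity entropy H = −Σᵢ pᵢ ln pᵢ (nats) together with six
texture features from the standard matrices:

| matrix | features |
|---|---|
| GLCM (13 directions, Chebyshev distance 1, symmetric) | angular second moment ASM = Σ p(i,j)²; sum entropy −Σₖ p_{x+y}(k) ln p_{x+y}(k) |
| GLRLM (13 directions) | run-length nonuniformity RLNU; high gray-level run emphasis HGLRE |
| GLSZM (26-connected zones) | zone-size nonuniformity ZSNU; high gray-level zone emphasis HGLZE |

Node-level features aggregate across lesions (MATV summed, SUVmax and
asphericity maximal; no nodal texture).

**Survival modeling.** Features are screened against overall survival by
ROC analysis with Youden-optimal cutoffs and a Bonferroni gate (family-wise
α = 0.10 over the ten parameters). A two-stage rule produces the
three-level PET risk pattern — subgroup 1: SUVmax ≤ 6.67; subgroup 2:
SUVmax > 6.67 but entropy ≤ 2.50; subgroup 3 (high risk): both exceeded —
and multivariable Cox models with 1,000-sample bootstrap intervals and
Schoenfeld diagnostics test its independence. A survival CART
(log-rank-split recursive partitioning with fivefold cross-validation)
composes the high-risk PET pattern with the clinical flag (ECOG 2 or
N2c–N3) into a poor/good prognostic index, compared against other scores by
paired concordance-index tests. Fisher/McNemar/odds-ratio/Spearman/
Mann-Whitney/chi-square/propensity-balance utilities round out the toolbox.

**Synthetic data.** `generatePhantom()` builds seeded SUV phantoms (flat
avid core, 40%-isocontour radius, heterogeneity knob adding correlated
noise and sub-foci) with segmentation ground truth; `generateCohort()`
draws 75-patient-style cohorts whose feature distributions match the
published summaries (ACC tumors larger but more homogeneous) and whose
OS/RFS times follow a proportional-hazards law with configurable log-hazard
coefficients. All generators are bit-reproducible under a seed.

## Worked example

```r
library(petromics)

## phantom -> segmentation -> feature vector
ph  <- generatePhantom(phantomSpec(heterogeneity = 0.4, seed = 8))
les <- segmentT40(ph$image, seed_point = c(24, 24, 24))
round(extractFeatures(ph$image, les)[, 1:6], 3)
#>  suv_max   matv asphericity intensity_entropy glcm_asm glcm_sum_entropy
#>   13.509 13.288       0.007             2.569    0.013            3.088

## synthetic cohort -> 1.5:1 split -> prognostic index -> validation
cc    <- generateCohort(cohortConfig(seed = 8))
sp    <- splitCohort(cc$cohort, ratio = 1.5, seed = 8)
train <- sp$training
train$pet_high_risk <- assignPETSubgroup(train) == 3L
train$clinical_flag <- train$ecog2 | train$n2c3
model <- buildRPATree(train, c("pet_high_risk", "clinical_flag"), seed = 8)
model
#> PrognosticModel (log-rank recursive partitioning)
#>   predictors: pet_high_risk, clinical_flag
#>   split on clinical_flag
#>    clinical_flag = FALSE:
#>       split on pet_high_risk
#>        pet_high_risk = FALSE:
#>           leaf: good (n = 27, events = 5)
#>        pet_high_risk = TRUE:
#>           leaf: poor (n = 12, events = 9)
#>    clinical_flag = TRUE:
#>       leaf: poor (n = 6, events = 5)
#>   CV split stability: pet_high_risk 80%, clinical_flag 100%

val <- sp$validation
val$pet_high_risk <- assignPETSubgroup(val) == 3L
val$clinical_flag <- val$ecog2 | val$n2c3
poor <- classifyPatients(model, val) == "poor"
km   <- kmLogrank(val$os_time, val$os_event, poor)
sprintf("validation log-rank p = %.3g; C-index (OS) = %.2f",
        km$p, cIndex(val$os_event, as.numeric(poor)))
#> "validation log-rank p = 0.00103; C-index (OS) = 0.75"
```

The phantom lesion (segmented from a noisy, heterogeneity-0.4 image) has
SUVmax 13.5, a 13.3 mL metabolic volume and entropy 2.57 nats — above the
2.50 cutoff, so together with its high SUVmax it carries the high-risk PET
pattern. On the synthetic cohort the fitted index labels a patient poor
exactly when they show the high-risk PET pattern or the clinical flag, and
that label separates validation survival (log-rank p ≈ 0.001).

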