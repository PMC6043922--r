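# spatialgf

Functional spatial analysis of cell–cell interactions in multiplexed
immunofluorescence (mIF) images, with random-forest classification of
tissue state.

## The problem

Pancreatic intraductal papillary mucinous neoplasms (IPMNs) are cystic
precursors of pancreatic ductal adenocarcinoma. Deciding whether a cyst
carries low- or high-grade dysplasia — and whether a low-grade cyst is
likely to progress — currently rests on broad morphology. mIF imaging
yields, for every cell in an image, its coordinates and the positivity of
a six-marker panel (AE1/AE3, PD-L1, CD3, CD8, PD-1, CD68), from which
seven phenotypes are gated: epithelial cells (± PD-L1), T lymphocytes,
cytotoxic (CD3+CD8+) and antigen-experienced (CD3+PD-1+) T cells, and
macrophages (± PD-L1). `spatialgf` quantifies how immune phenotypes
infiltrate the neighbourhood of epithelial and macrophage populations and
turns those spatial signatures into classifiers, for anyone analysing
cell-level exports from platforms such as inForm.

## The method

For a reference phenotype *i* and target phenotype *j*, the cross-type
nearest-neighbour distribution function

G<sub>ij</sub>(r) = P(a type-*i* cell has at least one type-*j* cell
within distance *r*)

is estimated per image with boundary-censoring corrections (raw,
reduced-sample border, Kaplan–Meier; under complete spatial randomness
G(r) = 1 − exp(−λπr²)). Twelve interactions are interrogated: each of
{epithelial, epithelial PD-L1+, macrophage, macrophage PD-L1+} against
each of {T cell, cytotoxic T, antigen-experienced T}. Each curve is
summarised three ways over [0, r<sub>max</sub>]:

1. **simple AUC** — the area under G(r);
2. **K-bins AUC** — areas over K equal-width distance bins, preserving
   curve shape;
3. **K-bins MFPCA** — the P×K bin areas of all interactions compressed by
   a two-step multivariate functional PCA (per-interaction FPCA, then a
   joint eigendecomposition of the stacked scores) into the smallest k
   components explaining ≥ 95 % of the variance.

Feature blocks (plus per-phenotype counts and Morisita–Horn
colocalization indices) feed 500-tree random forests evaluated by
leave-one-out cross-validation (by image or, recommended, by patient);
member probabilities are averaged into an ensemble, scored by ROC AUC
with DeLong or bootstrap confidence intervals, and the twelve
interactions are ranked by grouped permutation importance: the mean
decrease in out-of-fold classification accuracy (%) when an
interaction's bin columns are row-permuted under each fold's fixed
transform and model.

A built-in simulator generates cohorts of marked point patterns
(clustered epithelium, immune populations drawn from an attraction
mixture with infiltration fraction θ and scale τ) so the whole pipeline
is testable without patient data.

## Worked example

```r
library(spatialgf)

# synthetic 29-patient cohort: class signal planted in the
# epithelium / T-cell interaction
bm    <- make_benchmark("planted", seed = 1)
feats <- spatial_features(bm$cells, r_max = 32, K = 7)
ev    <- classify_images(feats, task = "grade",
                         members = c("mfpca", "counts"),
                         grouping = "patient", seed = 1,
                         importance = TRUE)
ev
#> <spatial_eval> task = grade, 230 images, LOOCV by patient
#>   ensemble [mfpca + counts]: AUC 0.993 (95% CI 0.986-0.999), accuracy 0.922, p = 0
#>   top interaction: Epithelial vs Tcell (23.6% accuracy decrease)

head(ev$importance, 3)
#>   ref            target     label                  mean_decrease_accuracy rank
#> 1 Epithelial     Tcell      Epithelial_Tcell                       23.6      1
#> 2 EpithelialPDL1 Tcell      EpithelialPDL1_Tcell                   11.2      2
#> 3 EpithelialPDL1 CytotoxicT EpithelialPDL1_Cytotox…                 1.54     3
```

The ensemble separates the two grades almost perfectly (AUC 0.993 over
230 out-of-fold probabilities), and the permutation importance recovers
the planted interaction: destroying the epithelium→T-cell bin features
costs 23.6 percentage points of accuracy, twice the runner-up — which is
the PD-L1+ epithelial subset of the same reference population, as
expected for nested phenotypes.

Single curves work the same way:

```r
cells <- image_split(bm$cells)[["P01_high_1"]]
g <- gcross(cells, "Epithelial", "Tcell", r_max = 32)   # KM-corrected
simple_auc(g)        # 19.625 (µm)
kbins_auc(g, K = 7)  # 0.534 1.378 2.367 3.313 3.748 4.036 4.250
autoplot(g)
```

`glance()`, `tidy()` and `autoplot()` methods cover fitted MFPCA models
and evaluation results; `write_eval()`, `write_feature_table()` and
`write_mfpca()` serialize results for reuse. A command-line front end
(`inst/cli/spatialgf.R`) chains `simulate → features → classify → report`
over CSV/JSON files.

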