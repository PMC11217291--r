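# morphospec

Label-free morpho-molecular phenotyping of single cells from paired Raman
hyperspectral maps and refractive-index (RI) tomograms.

## What it does, and for whom

Confocal Raman microscopy measures a cell's chemistry: one
fingerprint-region spectrum (600–1800 cm⁻¹) per pixel. Tomographic phase
microscopy measures its morphology: a 3D refractive-index volume. This
package is for cell biologists and imaging scientists who want to turn
those two raw data types into quantitative, interpretable phenotype
calls — here for colorectal cancer lines (HT29, RKO, T84) — and for
methodologists who want a fully testable reference implementation of the
analysis chain:

- **Raman preprocessing** — cosmic-spike removal (running-median/MAD),
  per-pixel adaptive smoothness penalised least squares (asPLS,
  λ = 5×10⁶) baseline subtraction, Savitzky–Golay smoothing (7, 2),
  Frobenius normalisation, in that fixed order;
- **Cell segmentation** from PC1 of each processed cube (Otsu threshold
  with hysteresis rim recovery) and cell-averaged spectra plus marker
  band integrals;
- **Tomographic morphometry** — RI > 1.345 segmentation and the eight
  indexes: mean RI, dry mass DM [pg], dry-mass density D [pg µm⁻³],
  sphericity Φ = π^{1/3}(6V)^{2/3}/S, volume V, triangulated surface
  area S, footprint A, thickness T = 3/2·V/A, using the refraction
  increment relation n_cell = n₀ + αC with n₀ = 1.3342, α = 0.19 ml/g;
- **PCA–MLR screening** — standardised PCA across cell-averaged spectra,
  ordinary least squares of the phenotype code on the first 10 PC scores,
  two-tailed t-tests (df = n − k − 1), partial-leverage plots
  (Frisch–Waugh), selection of significant PCs, loading annotation;
- **Group statistics** — exact Mann–Whitney tests (full enumeration for
  5 vs 5), Pearson correlation matrices with t-based p at df = n − 2, and
  the origin-fixed protein-band-integral vs dry-mass fit;
- **Phenotype inference** — multinomial logistic models on chemical,
  morphological and combined features, compared by likelihood-ratio test
  against the intercept-only null, AIC = 2k − 2lnL with k = (G−1)(p+1),
  training accuracy and leave-one-out cross-validation;
- **A synthetic paired-data generator** reproducing the reference
  cohort's group statistics (three phenotypes, n = 5 cells each), so the
  entire pipeline runs and is tested without any instrument data.

## Worked example

```r
library(morphospec)

cohort  <- generate_cohort(5, seed = 1)      # 15 synthetic cells, paired data
records <- extract_cell_records(cohort)      # preprocess, segment, average
morph   <- cohort_morphology(cohort)         # eight indexes per cell

pca  <- fit_pca_standardized(cell_spectra_matrix(records), 10)
fit  <- mlr_on_scores(pca$scores, records$label)
sig  <- select_significant_pcs(fit)
sig
#> [1] 1 2

top_pc <- sig[which.min(fit$coefficients$p.value[sig + 1])]
models <- compare_models(
  list(chemical      = pca$scores[, sig, drop = FALSE],
       morphological = as.matrix(morph[, c("D", "phi", "T")]),
       combined      = cbind(PC = pca$scores[, top_pc], D = morph$D)),
  records$label)
```

On this seed the screen flags PCs 1 and 2 as phenotype-discriminating
(synthetic contrasts are simpler than real ones, so they surface in the
leading components), segmentation overlaps the generator's ground-truth
masks with Dice ≥ 0.96 on all 15 cells, and the recovered dry-mass
densities match the generated truth to 0.4% — e.g. an HT29 cell generated
at D = 0.159 pg µm⁻³ comes back at mean RI 1.3644, exactly n₀ + αD. The
`models` table reports lnL, k, AIC, LRT p, training and LOOCV accuracy
per feature set and marks the minimum-AIC model. `autoplot()` methods
draw band-integral images, loadings, and the model comparison;
`tidy()`/`glance()` return the fits as tibbles.

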