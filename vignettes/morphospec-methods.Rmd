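---
title: "Label-free morpho-molecular phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free morpho-molecular phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two label-free imaging modalities look at the same living cell and report
complementary things. Confocal Raman microscopy delivers a hyperspectral
cube — one fingerprint-region spectrum (600–1800 cm⁻¹, 870 samples) per
pixel of a 50 × 50 grid covering 40 × 40 µm² — that encodes chemistry:
nucleic acids, proteins, lipids, and the quartz/PBS background each
contribute characteristic bands. Tomographic phase microscopy delivers a
3D refractive-index (RI) volume of the same cell, which encodes
morphology and, through the linear relation between RI and dry-matter
concentration, biophysics.

`morphospec` implements the full analysis that turns these two raw data
types into a phenotype call for colorectal cancer cell lines (HT29, RKO,
T84), plus a synthetic paired-data generator so that every stage is
testable without instrument data.

# Pipeline overview

```{r}
library(morphospec)

cohort <- generate_cohort(5, seed = 1)          # paired synthetic cells
records <- extract_cell_records(cohort)         # preprocess + segment + average
morph <- cohort_morphology(cohort)              # the eight indexes per cell

pca <- fit_pca_standardized(cell_spectra_matrix(records), 10)
screen <- mlr_on_scores(pca$scores, records$label)
sig <- select_significant_pcs(screen)

models <- compare_models(
  list(chemical = pca$scores[, sig, drop = FALSE],
       morphological = as.matrix(morph[, c("D", "phi", "T")]),
       combined = cbind(pca$scores[, sig, drop = FALSE],
                        D = morph$D)),
  records$label)
```

# Raman preprocessing

Raw spectra are processed per cube in a fixed order; each stage stamps the
cube's provenance so the order is auditable.

1. **Cosmic-spike removal.** Single-sample detector hits are found per
   spectrum as residuals from a 5-point running median exceeding 8 robust
   standard deviations (median absolute deviation × 1.4826) and replaced by
   that median. Ends are padded by replication. The detector and its z = 8
   default are this package's choice; they flag nothing on clean spectra and
   leave unflagged samples bit-identical.
2. **Baseline subtraction (asPLS).** The fluorescence baseline of each
   pixel spectrum is fit by adaptive smoothness penalised least squares:
   iterate solving (W + λ·A·D₂ᵀD₂)z = W·y with second-difference penalty
   λ = 5 × 10⁶, logistic weights wᵢ = 1/(1 + exp(2(yᵢ − zᵢ)/σ)) where σ is
   the standard deviation of the negative residuals, and the adaptive vector
   A = |y − z|/max|y − z| stiffening the penalty under peaks. Iteration
   stops when the weight vector changes by less than 10⁻³ relative, or at 50
   iterations — then a warning flag is set rather than an error. The
   pentadiagonal solve is compiled code (diagonally dominant, no pivoting
   needed), which is what makes per-pixel fitting of 2,500 spectra cheap.
   Peak-area fidelity degrades gracefully with the baseline-to-peak ratio;
   for peaks a few times taller than the baseline curvature scale the
   post-subtraction areas are within ~5%.
3. **Savitzky–Golay smoothing** with a 7-point window and order-2
   polynomial (`signal::sgolayfilt`; its transient handling is exactly the
   truncated-window polynomial fit). An order-2 filter reproduces
   quadratics, so band shapes are preserved to second order.
4. **Frobenius normalisation** of the whole cube to unit √ΣI², which
   removes per-acquisition intensity scale while keeping pixel-to-pixel
   ratios.

Normalisation comes last and segmentation operates on the fully processed
cube; the alternative order (segment before normalising) changes nothing
downstream of the cell average because the average is renormalised
implicitly by the standardised PCA.

# Cell segmentation in the Raman maps

Cell pixels are selected on the first principal component of the processed
cube (pixels × wavenumbers, centred). PC1's sign is arbitrary, so it is
fixed against the organic-matter band integral (1400–1680 cm⁻¹): high
score must mean more organic matter.

The threshold is Otsu's criterion, with two engineering details that both
matter at this image size and are worth stating honestly:

- Cell scores are not bimodal in the textbook sense: the signal scales
  with the locally sampled thickness, so cell pixels form a long graded
  tail rather than a second mode. Otsu's criterion on the raw histogram
  then cuts deep into the cell. We therefore apply the criterion to
  log-compressed scores, log(s − median + 3·MAD), which maps the tail into
  a mode of width comparable to the background's. If the resulting
  selection exceeds a quarter of the field of view — impossible for a
  single cell in a 40 × 40 µm² FOV — the raw-score Otsu cut is used
  instead (that regime, a tiny cell occupying a few percent of the image,
  is the one where the raw criterion works and the compressed one fails).
- When the Otsu selection is spatially incoherent — the largest
  8-connected component holds less than half of the selected pixels, the
  signature of a cut that landed inside residual background structure
  rather than between background and cell — the threshold is raised to a
  robust background-outlier floor (median + 1.5 MAD of the scores).
  Coherent selections keep the Otsu cut, which also covers cells filling
  much of the field of view, where median/MAD statistics themselves break
  down.
- The faint cell rim (sub-µm sampled thickness) sits barely above the
  background noise. After the core is extracted (largest 8-connected
  component), rim pixels above the same permissive floor that are
  8-connected to the core are added — hysteresis thresholding in the
  Canny sense. Scattered background pixels above the floor stay excluded
  because they do not touch the core.

On synthetic cohorts at the default noise this keeps the Dice overlap
with the generator's ground truth above ~0.92 across the sampled
geometry range; cells with footprints below ~100 pixels remain the
hardest regime (their rim carries most of the boundary information), and
the tests bound them separately.

# Tomographic morphometry

Cell voxels are RI > 1.345 (largest 26-connected component, no hole
filling — both choices ours, made for reproducibility). From the binary
mask:

- **V** = voxel count × voxel volume; **A** (footprint) = XY columns
  containing ≥ 1 masked voxel × pixel area; **T** = 1.5·V/A, which is the
  exact ellipsoid relation (V/A = 4c/3, so T = 2c);
- **S** is a triangulated isosurface area: marching tetrahedra (six
  tetrahedra per voxel cell, level 0.5) on a Gaussian-smoothed copy of the
  mask, σ = (1, 1, 0.6) voxels. Raw staircase surfaces overestimate a
  sphere's area by ~30% (and plain face counting by ~50%), which would
  push sphericity far from 1; the smoothed triangulation is within ~2.5%
  across spheres and flat ellipsoids at the default anisotropic voxels.
  Face counting is retained in the tests as an exact oracle for
  voxel-aligned shapes only.
- **Φ** = π^(1/3)·(6V)^(2/3)/S, Wadell sphericity, the standard 3D
  definition consistent with a 0–1 range.
- **Concentration** C = (RI − n₀)/α per masked voxel with n₀ = 1.3342
  (PBS) and α = 0.19 ml/g (protein refraction increment); negative values
  (noise below background) are clipped to zero and counted. **DM** =
  ΣC·ΔxΔyΔz, **D** = DM/V, so DM = D·V identically. D is deliberately read
  as a volume-averaged concentration (pg·µm⁻³): integrating C over the
  volume is dimensionally a mass, and the product relation DM = D·V pins
  the density reading; this interpretation also reproduces the
  RI-vs-density consistency of the reference cohort (n₀ + α·0.159 =
  1.36441 → 1.364).

# Chemometric screen (PCA–MLR)

Cell-averaged spectra (cells × 870) are column-standardised (sample sd,
n − 1; constant channels zeroed and flagged) and decomposed by SVD.
Loading signs follow a largest-element-positive convention so annotations
are reproducible. The phenotype is coded numerically — HT29 = 1, RKO = 2,
T84 = 3, the disease-progression order; the coding is configurable and
recorded in the fit — and regressed on the first 10 PC scores by ordinary
least squares. Each coefficient gets a two-tailed t-test at df = n − k − 1
(4 for the reference design of 15 cells and 10 predictors); PCs with
p < 0.05 are the selected chemical features. Partial-leverage plots
isolate each predictor's contribution; their slope equals the
multiple-regression coefficient exactly (Frisch–Waugh), which the tests
assert to 10⁻⁹.

# Group statistics

Mann–Whitney comparisons use full enumeration of all C(n+m, n) label
assignments (midranks for ties) whenever n + m ≤ 12 — the reference
design is 5 vs 5, where complete separation gives exactly p = 2/252 —
and the tie-corrected normal approximation beyond. Pearson correlations
get two-sided p from t = r√((n−2)/(1−r²)) at df = n − 2. No
multiple-testing correction is applied anywhere, matching the reporting
convention of the reference analysis; reports flag this. The
protein-vs-dry-mass relation is fit through the origin (slope = Σxy/Σx²,
t at df = n − 1); because the ordinary correlation coefficient and the
origin-fixed fit quality answer different questions under a forced zero
intercept, both are reported.

# Phenotype inference (multinomial logistic models)

Multinomial logistic fits use maximum likelihood (`nnet::multinom` behind
the package's interface) with the first label alphabetically as reference
class; predictors are standardised internally and coefficients
back-transformed. Exactly aliased predictors — mean RI and D satisfy
RI = n₀ + αD — are detected by QR and dropped with a message. Model
statistics follow the k = (G−1)(p+1) parameter convention (intercepts
included): AIC = 2k − 2lnL, LRT statistic 2(lnL − lnL₀) against the
intercept-only null lnL₀ = Σ n_g ln(n_g/n) at df = k − (G−1). This
convention is not arbitrary: recovering lnL = (2k − AIC)/2 from each of
the six reported AIC values of the reference study and recomputing the
chi-square tail reproduces every reported LRT p-value to its printed
precision, which simultaneously validates the parameter count, the null
likelihood and the tail implementation (the acceptance tests do exactly
this).

Fifteen cells and near-separated classes mean quasi-complete separation
is the norm, not a pathology: fits whose standardised coefficients exceed
50 are flagged, reported at the iteration cap, and LOOCV refits use a
small ridge (10⁻⁴ on standardised predictors) so every fold is fittable;
unfittable folds would count as errors. Leave-one-out accuracy refits on
n − 1 cells and predicts the held-out cell by maximum probability.

# The synthetic generator

The generator emulates the reference cohort's statistical structure, not
its optics:

- **Geometry.** Cells are oblate spheroids resting on the substrate. Per
  cell, dry-mass density D, sphericity Φ and thickness T are drawn from
  per-phenotype Gaussians whose means and spreads are the reference
  group statistics (D = 0.159/0.133/0.148 pg·µm⁻³, Φ =
  0.685/0.572/0.566, T = 2.835/2.465/2.289 µm for HT29/RKO/T84; the
  reported values are standard errors at n = 5, so simulation spreads use
  sd = SE·√5). Draws are truncated at ±2 sd — symmetric, so means are
  preserved — because independent Gaussian draws of Φ and T otherwise
  produce tail combinations (high Φ with low T) whose implied footprint
  radius is far below anything an adherent epithelial cell shows. The
  equatorial radius is then solved from (Φ, T) through the exact oblate
  surface area, making Φ and T exactly controllable while V, S, A follow;
  the reference data report no V/S/A group means to anchor directly.
- **Spectra.** Each molecular class (nucleic acids, protein, lipid,
  cytoplasm, quartz, PBS, water) is a sum of Lorentzian lines at standard
  assignment positions, normalised to unit area. Lorentzian is the
  natural Raman line shape; nothing in the reference analysis depends on
  it. Background pixels carry the quartz + PBS mixture; cell pixels add
  the weighted cellular mixture scaled by the locally *sampled* thickness
  min(t, 1.5 µm) — a high-NA confocal probe saturates once the cell is
  thicker than its focal depth, and without this cap the thickness-graded
  signal has no plateau and no threshold rule segments it cleanly. The
  nucleic-acid component is enriched 3× (concentration ratio) inside a
  concentric nucleus sub-ellipsoid, mass-conserving. A random positive
  cubic polynomial per pixel models fluorescence; Gaussian noise
  (sd 0.002 in normalised units, an SNR of order 10 at the strongest cell
  bands) and Poisson-count single-pixel cosmic spikes (≥20× local
  amplitude, 2 expected per cube) complete the model.
- **Chemical contrasts.** The default phenotype weights encode the
  reference cohort's qualitative chemistry — HT29 elevated in nucleic
  acids, T84 reduced in protein/lipid — at magnitudes comparable to the
  between-cell variability, so the PCA–MLR screen separates types without
  being trivial. These magnitudes are configuration, not measured values.
- **Tomograms.** Voxels inside the ellipsoid get RI = n₀ + α·C with the
  nucleus offset +0.015 pg·µm⁻³ (mass-conserving split) and additive RI
  noise of sd 5 × 10⁻⁴, small against the ~0.011 cell–background
  contrast. The default grid is 128 × 128 × 64 voxels over 40³ µm³, a
  scaled stand-in for the instrument's 425 × 425 × 210; at Δz = 0.625 µm
  a 2.3 µm-thick cell spans only ~4 voxel layers, so thickness and
  footprint of thin cells carry up to ~10% digitisation error while V, D
  and DM stay within a few percent. A cell whose noiseless RI falls below
  the 1.345 threshold is rendered anyway and flagged.
- **Fast path.** `simulate_cell_spectra()` produces the per-cell records
  (cell-averaged spectrum + morphology) directly from the same
  distributions, skipping image rendering; the cell average is the
  background mixture plus the mean sampled thickness times the cellular
  mixture, with noise shrunk by the effective pixel count. Statistical
  properties that need hundreds of cohorts (type-I calibrations, model
  selection frequencies) run on this path; the image path is exercised
  end to end at full size once per test run.
- **Planted separation.** `planted_separation_params()` configures the
  structure used for the model-selection property: HT29 differs from the
  others only chemically, RKO only morphologically, T84 matches HT29
  morphologically and RKO chemically. No single-channel model can resolve
  all three classes, the combined one can — under the pinned reference
  group statistics the single-channel gaps are ~1.3 sd and any of the
  three models can legitimately win AIC in a given draw, which is a
  faithful property of those conditions, not of the implementation.

What the generator does **not** model: optical hardware, interferogram or
tomographic reconstruction, co-registration error between the two
microscopes (inputs are assumed co-registered per cell), photodamage,
focus drift, water-immersion artifacts, and subcellular organelles beyond
a single nucleus compartment. Passing tests therefore show the analysis
chain is correct and calibrated under this data model — not that it is
robust to instrument effects the model omits.

# Problem sizes and runtime

The test suite runs most statistics on a 300-sample axis and reduced
grids, and one full-size cohort (15 cells, 50 × 50 × 870 cubes,
128 × 128 × 64 tomograms) end to end, which completes in roughly three
minutes on one CPU; model-selection frequencies use 100 feature-level
cohorts. These sizes are the package's reference configuration for
desk-scale reproduction.

# Known limitations

- Thickness of thin cells inherits ~10% z-digitisation error at the
  default tomogram grid; rerun with finer `tomo_dims` if T matters.
- asPLS underestimates peak areas when the fluorescence baseline is an
  order of magnitude taller than the peaks; λ is per-dataset tunable.
- The exact Mann–Whitney enumeration is O(C(n+m, n)) and is capped at
  pooled size 12 before switching to the normal approximation.
- Reported β magnitudes of the reference screen depend on its undisclosed
  ordinal phenotype coding; the package reproduces selection patterns and
  significance structure, not those coefficients.
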