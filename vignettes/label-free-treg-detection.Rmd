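---
title: "Label-free Treg detection from single-cell Raman spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free Treg detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regulatory T cells (Tregs) suppress immune responses and are defined by
the intracellular transcription factor Foxp3, which cannot be stained in
live, unmodified cells. Live Treg isolation therefore relies on surrogate
surface markers (CD25, CD45RA, CD127), whose gates are imperfect: sorted
"Treg" tubes typically validate at 73–92% purity and "Tconv" tubes at
87–97%. ramanTreg implements a label-free alternative: classify single
cells as Tconv or Treg from their Raman spectra with a sparse
(L1-regularized) logistic model, treat the sorting impurity as
class-conditional label noise, prune likely-mislabeled training cells by
confident learning, and validate on mixtures and on donors held out of
training entirely.

Because no suitable single-cell Raman dataset is publicly deposited, the
package ships a first-class synthetic-cohort generator that emulates the
relevant structure of such data, so that every stage is testable against
planted ground truth.

## The synthetic world

A spectrum is a sum of Lorentzian bands (Gaussian selectable) on a
wavenumber axis, plus a fluorescence-like polynomial baseline, additive
Gaussian channel noise and occasional single-channel cosmic-ray spikes.
The default axis spans 600–3050 cm⁻¹ in 1016 channels (~2.41 cm⁻¹
spacing), chosen so that excising the biologically silent 1800–2700 cm⁻¹
region leaves exactly 643 channels.

Phenotype is encoded as small multiplicative amplitude differences on a
subset of bands. The default discriminative set mirrors the murine band
assignments packaged with the band table: amide III β-sheet/α-helix and
tryptophan bands stronger in Tconv; phenylalanine-ring, CH-deformation
and related bands stronger in Treg. Key scales, with defaults:

* `class_effect`: 3–5% amplitude difference per discriminative band —
  far below the per-cell variability, which is the regime that makes the
  problem non-trivial.
* `cell_cv`: lognormal per-band amplitude variability per cell, 8–12%
  on discriminative bands and 15% on shared bands. The per-band values
  were calibrated once so that a linear classifier reaches roughly
  0.85–0.95 test AUC at a few thousand cells: with twelve independent
  discriminative bands the achievable separation is
  $d^2=\sum_b(\text{effect}_b/\text{cv}_b)^2 \approx 2.6$, i.e. a Bayes
  AUC of about 0.87. A flat 15% on all bands would cap the AUC near
  0.79, so the discriminative bands use the lower end of realistic
  variability. This is a stated calibration, fixed once, not a tuning
  surface.
* `cell_intensity_cv` (25%): a global per-cell intensity factor
  emulating correlated cell-size/density variability. It carries no
  class information and a linear model can project it out.
* Donor/batch structure: 3 donors × 3 batches by default; each batch
  carries a lognormal global intensity factor (sd 5%) and a rigid
  wavenumber shift (sd 0.5 cm⁻¹) — the two artifact families that daily
  calibration against an ethanol reference is designed to absorb.
* Class imbalance: Tconv:Treg = 3 (the field reports 2–5).
* Label corruption: sorted-tube composition purities, default 0.92
  (Tconv) and 0.82 (Treg). These are *compositions of the sorted
  classes*, not per-cell flip rates; `corrupt_labels()` converts them to
  flip probabilities in closed form from the class ratio and applies
  independent per-cell flips (see its help page for the algebra).
* Fraction III: an optional per-donor pool of unlabeled Tconv/Treg
  mixtures (planted fraction configurable per donor) that is never used
  in training — the independent validation pool.

What the generator does **not** emulate: absolute Raman cross-sections,
detector etaloning or flat-field structure, fluorescence photobleaching
dynamics, multi-channel cosmic-ray events (width is configurable but
defaults to 1), and any dye or staining influence. A green test
establishes that the algorithms behave correctly in this stated world —
it is not evidence about any particular instrument's data.

## Preprocessing conventions

The chain runs despiking → baseline correction → wavenumber calibration
→ silent-region excision → PCA outlier filtering, with every stage
switchable and parameterized.

* **Despiking** flags channels whose positive deviation from a 5-channel
  running median exceeds 8× a robust local scale (running MAD floored by
  a first-difference noise estimate — median-filter residuals are
  exactly zero on smooth runs, so an unfloored MAD collapses). A flagged
  channel must also exceed one third of its local peak prominence;
  a single-channel cosmic ray carries essentially all of its prominence
  in the median residual while a real band top (a few channels wide at
  this spacing) carries only ~10–30%, so band tops are never despiked
  even in noiseless spectra. Only flagged channels are modified.
* **Baseline correction** fits a cubic B-spline (knots every 100 cm⁻¹)
  by iteratively reweighted least squares anchored from below: channels
  more than two noise standard deviations above the current curve drop
  to near-zero weight, so the spline interpolates beneath peaks from
  flanking anchors instead of being dragged up by clipped plateaus. The
  noise scale comes from first differences, once per spectrum. Output is
  not clipped; small negatives are expected and harmless.
* **Calibration** detects known reference bands (packaged ethanol
  centers) by windowed maxima with log-domain parabolic refinement, fits
  nominal→true wavenumber (affine for <4 detected peaks, monotone cubic
  with linear extrapolation otherwise), verifies monotonicity, and
  re-interpolates all spectra onto the canonical axis.
* **Silent-region excision** removes 1800–2700 cm⁻¹ as a closed
  interval.
* **Outlier filtering** automates what is usually done by eye on PCA
  score plots: flag cells beyond 5 MADs from the component median on any
  of the first 6 components. A deterministic rule was chosen over manual
  inspection for reproducibility; at Gaussian scores it flags well under
  1%.

No intensity normalization is applied by default; none of the standard
choices (area, protein band) is obviously implied by the workflow this
package reproduces, and the linear model's per-channel standardization
absorbs global scale. The global per-cell intensity factor is instead
treated as a nuisance the classifier handles.

## Classifier

`fit_lasso_logistic()` minimizes mean negative log-likelihood plus
λ‖β‖₁ with an unpenalized intercept on internally standardized channels
(population standard deviation, which keeps the fit invariant under
duplicating the data). λ > 0 is solved by glmnet via a warm-started
path ending exactly at the requested λ; λ = 0 falls back to IRLS. Both
routes are checked in the test suite against an independent brute-force
NLL minimizer. The coefficient vector on the standardized scale is the
*separation vector*; `annotate_bands()` matches its extremes against a
packaged band-assignment table with expected signs.

λ is selected by stratified k-fold cross-validation maximizing mean
out-of-fold AUC, with exact ties resolved to the larger (sparser) λ.
Two caveats are worth recording. First, AUC-based selection cannot
reliably return the all-zero model on pure-noise labels: a constant
model scores exactly 0.5 and the maximum over a grid of noisy 0.5s
almost always beats it. We keep the AUC rule because it matches the
quantity the studies report; the package's null-safety claim is instead
the (true) downstream property that the *test* AUC of the selected model
stays at chance on null data. Second, no class re-weighting is applied
by default despite the 3:1 imbalance — plain accuracy at threshold 0.5
is the reported quantity — but `weights = "balanced"` is available and
the mixture-scoring workflow requires it (below).

## Confident learning

Out-of-fold probabilities (5 folds; λ chosen once on the full pool by
the same CV rule) feed the standard confident-learning chain: per-class
thresholds are mean self-confidences; the confident joint counts each
cell at (given label, inferred label) when its probability clears the
inferred class's threshold; pruning removes, for each off-diagonal entry
with count k, the k cells with the largest probability margin
(`by_noise_rate`; `by_class` is available for sensitivity analysis).
Removed cells are flagged, never relabeled. Fraction III cells are never
pruned.

We deliberately use the *raw* confident joint for prune counts. The
reference formulation also offers a row calibration (scaling rows to
class counts); we measured both on planted corruption (purities
0.92/0.82): the raw joint over-removes mildly (~+3–5 percentage points
per class at Bayes AUC ≈ 0.87) while the calibrated joint over-removes
severely in this regime (~+10–16 points), because cells the model simply
cannot classify confidently get redistributed proportionally into the
off-diagonal. The residual over-removal of the raw rule is the expected
behavior of confident learning when class overlap is substantial: a
fraction of genuinely-correct boundary cells clears the opposite class's
threshold. It shrinks as the classes separate (it is near zero on a
sharply separable template, where removal precision is ~100%), and its
flip side is useful: over-pruning costs a little clean data but still
removes the planted noise. Even at zero planted impurity it removes
roughly 7% of cells at the default class overlap — the boundary cells
the model is confidently "wrong" about. The acceptance suite measures
both effects and reports them as they come out.

## Mixture scoring and the balanced-weights requirement

For Fraction III pools the package reports, per donor, the fraction of
cells with p < 0.10 and p > 0.90, plus the point estimate
f̂ = hi/(hi + lo). That estimator is unbiased only when the two
confident tails have class-symmetric coverage. A model trained without
re-weighting on 3:1 imbalanced data carries an intercept offset of
log(1/3) ≈ −1.1, which makes p < 0.10 far easier to reach than
p > 0.90 and biases f̂ downward by well over five points — an analysis
that follows directly from the logistic form, and which we confirmed in
simulation. The mixture-scoring workflow therefore trains its scoring
model with balanced class weights; all other workflows keep the
unweighted default. A second, structural limit is worth knowing: with
label noise, a *calibrated* model's probabilities asymptote at
purity-determined values (e.g. at 18% Treg-sorted impurity a true Treg
can at best reach p ≈ 0.91), so the 0.10/0.90 tails are only usable
after pruning has raised the effective training purity. Scoring uses the
pruned-data model for exactly this reason.

## Donor holdout

`run_donor_holdout()` prunes and trains on all donors but one and scores
every sorted cell of the held-out donor, unpruned — a deployed model
cannot prune data it has never seen. With batch effects off, holdout and
random-split test AUC agree closely; increasing batch wavenumber shift
degrades holdout performance monotonically (the acceptance suite sweeps
0/1/3 cm⁻¹ with common random numbers across the sweep to pair the
comparison).

## Numerical choices and degenerate inputs

* glmnet convergence threshold 1e-6 during cross-validation path fits,
  1e-8 for final fits (1e-12 in oracle-equivalence tests); λ grid spans
  two decades below the analytic λ_max in 25 log-spaced points.
* AUC is computed as an integer-count trapezoid with a single final
  division, making it bit-exact equal to pairwise concordance with ties
  counted one half.
* Score ties at the call threshold go to Treg (documented convention;
  affects only degenerate score sets).
* Splits and folds are stratified; every randomized stage takes a seed,
  and workflows fork per-stage seeds deterministically from one master
  seed, so any report is reproducible from its config echo.
* Constant channels are standardized with scale 1 and forced to zero
  coefficients; an entirely constant matrix at λ = 0 is an error, as is
  a class with fewer than two cells, a non-monotone calibration map, or
  fewer than two detectable reference peaks.

## Known limitations

* Confident learning's removed fractions track planted corruption rates
  with a positive bias of a few percentage points at the default
  (deliberately hard) class overlap; see above.
* The mixture tail estimator carries a residual bias of roughly ±3–5
  points at default purities even with balanced weights and pruning,
  dominated by residual label noise in the pruned training pool.
* Baseline correction inevitably absorbs a small part of broad
  Lorentzian tails into the baseline; isolated-peak recovery is within
  2%, but densely overlapping regions (e.g. the CH stretch cluster) are
  reconstructed less faithfully.
* The generator's acquisition artifacts are deliberately simple; none of
  the claims here transfer to real instruments without re-validation.
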