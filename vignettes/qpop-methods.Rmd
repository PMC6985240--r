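---
title: "Methods: quadratic-surface ranking of drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadratic-surface ranking of drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

An ex-vivo combinatorial drug screen asks: out of all dose-level
combinations of an n-drug panel, which k-drug combination kills this
particular tumor sample best? Testing the full grid is impossible with
patient material — an 11-drug, 3-level panel spans 3^11 = 177,147
conditions. qpopr instead assumes the phenotypic response (normalized
viability y) is smooth enough in the coded dose levels to be captured by a
second-order polynomial,

y = b0 + sum_i b_i x_i + sum_i b_ii x_i^2 + sum_{i<j} b_ij x_i x_j,

fits that surface to a small designed experiment, and reads the ranking of
every combination off the fitted surface. The quadratic assumption is the
platform's core bet: it captures per-drug potency (b_i), dose curvature
(b_ii) and pairwise synergy/antagonism (b_ij), but nothing of higher order
(three-way interactions fold into the pairwise terms).

### The coded dose scale

Coded levels are used directly as the regression scale: x_i = 0 (vehicle),
1, ..., L. Two properties drove this choice over a centered −1/+1 scale:

* the all-vehicle run sits at the coded origin, so the intercept b0 *is*
  the predicted vehicle viability, exactly — a useful anchor for
  normalization diagnostics;
* the ranking only ever queries grid points, so the fit and the ranking
  live on the same scale and no per-drug affine bookkeeping can drift.

Concentrations (which are drug-specific and span orders of magnitude)
appear only at I/O boundaries via the panel's level-to-concentration
mapping. A per-drug log-concentration scale was considered and rejected for
the default: the design is defined on coded levels, and coefficient
comparability across drugs is better served by a common unit grid.

## The screening design

`build_oacd()` concatenates three portions:

1. **Two-level orthogonal array** over levels {1, 2} (internally -1/+1).
   With the default `oa_strength = 4` this is a full two-level factorial
   for n <= 5 and a regular resolution-V fraction for n = 6..11 (64 or 128
   runs), whose defining words all have length >= 5 — the property that
   keeps every main effect and every two-factor interaction unaliased.
   The generator sets were found by exhaustive search over word lengths and
   are fixed constants; the test suite recomputes the word-length property.
   `oa_strength = 2` substitutes a Hadamard / 12-run Plackett-Burman
   screening array: far smaller, exactly orthogonal in main effects, but
   structurally unable to estimate the 78-coefficient quadratic at n = 11 —
   `fit_surface()` then refuses without an explicit ridge penalty. The
   interaction-clear strength is the default because the package's whole
   downstream (ranking by b_ij-laden predictions) is only as good as the
   interaction estimates.
2. **Axial runs**: each drug alone at every non-zero level. Within a
   two-level portion x and x^2 are affinely confounded; the axial runs (plus
   the centers) are what separates b_ii from b_i.
3. **Center runs**: 3 all-vehicle replicates by default. How many center
   replicates the original platform used is unknown; 3 is the conventional
   composite-design choice and gives a pure-error anchor for the intercept.

The largest supported panel is n = 11 (the largest generator set shipped);
beyond that `build_oacd()` errors naming the limit. User-supplied designs
of any shape can be read verbatim from CSV and validated with
`validate_design()`, which reports per-drug level counts, exact OA-portion
correlations, and a QR rank check of the full quadratic model matrix,
naming any non-estimable terms.

## Fitting

`fit_surface()` is ordinary least squares via QR, nothing more, because no
loss or regularization beyond least squares is implied by the modeling
assumption. A ridge penalty (excluding the intercept) exists strictly as a
guarded fallback for rank-deficient user designs; it is never applied
silently — OLS on a deficient design raises an estimability error listing
the confounded terms. Leave-one-out RMSE (computed from the hat matrix) is
reported as a diagnostic but never used for model selection: silent model
changes would make ranks irreproducible. Viability readouts are expected
normalized to vehicle control and are deliberately **not clipped** to
[0, 1]; clipping noise at the boundaries biases least squares.

## Ranking

The counting unit is a (drug subset, one non-zero level per member)
assignment: n = 11, L = 2 gives C(11,5) * 2^5 = 14,784 five-drug and
C(11,3) * 2^3 = 1,320 three-drug combinations. Enumeration order is
lexicographic by member index tuple then level tuple; it is deterministic
and doubles as the tie-break, so ranks are bit-reproducible across
platforms. Scores are predicted viabilities; ranking is ascending (rank 1 =
most kill). Named regimens are located by best-rank-over-levels by default
(a regimen prescribes drugs, not grid levels); exact-level lookup is
available. Exhaustive enumeration is the right tool at panel scale —
stochastic search would only add irreproducibility below n ~ 15.

## Pharmacodynamics

* **4PL**: `response = bottom + (top - bottom)/(1 + (dose/ic50)^hill)`,
  fitted by bounded L-BFGS-B from five deterministic starts (hill in
  {0.5, 1, 2, 4} at the half-range crossing dose, plus hill = 1 at the dose
  geometric mean; the sign of the dose-response correlation orients the
  slope), then polished by Gauss-Newton. 4PL fits are
  initialization-sensitive; multi-start with a fixed recipe keeps them
  deterministic. Data whose per-dose mean range falls below `noise_floor`
  (default 0.05) are flagged "no dose effect" with IC50 not determined,
  rather than returning an arbitrary huge IC50.
* **Median effect**: linear regression of log(fa/(1-fa)) on log D; Dm and m
  follow from slope and intercept. Only points with fa strictly inside
  (0, 1) carry information; others are excluded with a warning, and fa
  derived from viability is clamped to (1e-6, 1 - 1e-6) before logs —
  numerical safety with no material bias at realistic noise.
* **Combination index**: CI(fa) = sum_i d_i / D_i(fa), the mutually
  exclusive (Loewe-consistent) Chou-Talalay form, under which the sham
  "drug combined with itself" identity CI = 1 holds exactly — the property
  the test suite asserts to 1e-9. The non-exclusive variant (extra
  cross-term) is available behind a flag for comparability with older
  literature. A fixed-ratio dilution series is the assumed sampling design;
  arbitrary-ratio points are computed pointwise.
* **Response surface maps** evaluate the fitted quadratic over a drug
  pair's coded rectangle (others at vehicle) or bilinearly interpolate a
  measured grid; with resolution 2 the four corners are returned exactly.

## The synthetic world

The generators state the conditions the package is tested under; they are
fixed, not tuned:

* **Screens** (`surface_truth` + `simulate_screen`): viability = quadratic
  truth + additive Gaussian noise, default SD 0.05 on normalized viability
  — the scale of technical-replicate scatter in luminescent viability
  assays. The planted-optimum truth (`surface_truth_planted`) gives three
  drugs linear coefficients -0.2 and pairwise interactions -0.05 among
  themselves, +0.02 linear for the rest: the planted triple at top levels
  then leads the runner-up by ~0.46 viability units, i.e. a well-separated
  optimum relative to the noise.
* **Combination series** (`hill_combo_truth` + `simulate_combo_series`):
  single agents are Hill curves with top 1 / bottom 0 (so viability maps
  directly to fraction affected and the median-effect parameters are
  exactly Dm = IC50, m = hill); the combination's fraction affected at
  component doses d solves sum_i d_i / D_i(fa) = alpha. `loewe_alpha` is
  thereby the combination index the series embeds — alpha = 0.5 means the
  analysis pipeline should read back CI = 0.5, which is what the tests
  assert. Default series: 8-9 points, 2-fold dilution, centered on the
  total dose giving half effect. Single-agent IC50 magnitudes typical of such panels
  (3e-4 to ~60 dose units) shape the test fixtures.

What the generators do **not** emulate — and hence what a green test does
not establish: plate/edge effects, assay drift, heteroscedastic noise
(variance growing near full kill), biological (as opposed to technical)
replication, deviations of true dose-response from the quadratic/Hill
shapes, and 3+-drug Loewe interactions. A ranking validated on this world
is validated as *computation*, not as biology.

## Numerical choices and degenerate inputs

* Least squares via QR; estimability = exact column rank of the QR.
* Stable ordering everywhere (ties by enumeration index).
* All seeded generation goes through an RNG-state-preserving wrapper, so
  generators are pure functions of (truth, design, seed).
* Degenerate inputs fail loudly with classed conditions (schema /
  validation / estimability / fit), which the CLI maps to distinct exit
  codes (2 / 5 / 3 / 4).

## Known limitations

* Quadratic surfaces cannot represent non-monotone synergy confined to a
  dose sub-window, nor three-way interaction structure.
* The OACD estimates interactions on the {1, 2} sub-grid; quadratic terms
  lean heavily on the 2n axial runs, so single-run outliers there have
  high leverage (visible in the LOOCV diagnostic).
* CI is computed for two components; the median-effect linearization
  weights all interior points equally regardless of their precision.
* Panel size is capped at 11 factors by the shipped orthogonal arrays.
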