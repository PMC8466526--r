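---
title: "Models and methods behind ftirmcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ftirmcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirmcell)
```

This vignette explains the models implemented in ftirmcell, the choices we
made where the methodology was genuinely open, and what the synthetic
validation does and does not establish about real data.

## The measurement and its data model

A single-cell FTIR microspectroscopy campaign produces, per cell, an
absorbance spectrum $A(\nu)$ on a wavenumber grid $\nu$ (cm⁻¹) spanning
roughly 4000–800 cm⁻¹, recorded through a masking aperture of about the
cell's size; mapping mode rasters one cell at a µm-scale step. ftirmcell
stores populations as long tibbles (one row per cell × wavenumber, with
`cell_line` and `treatment` labels) and rasters as `hypermap` objects.
Instruments commonly store spectra descending in wavenumber; everything is
flipped to ascending at ingestion so that integrals and derivatives have
one sign convention. The synthetic default grid is 800–4000 cm⁻¹ at
2 cm⁻¹ spacing: a 4 cm⁻¹ instrument resolution stored with the typical
two-fold oversampling. The stored point spacing is an assumption (the
acquisition resolution constrains only the optical bandwidth), which is
why it is a constructor argument rather than a constant.

## Preprocessing operators

**EMSC.** Each raw spectrum is regressed on a reference $m(\nu)$ (the set
mean by default) plus a polynomial in the wavenumber rescaled to
$[-1, 1]$:
$A(\nu) = a + b\,m(\nu) + \sum_{k=1}^{p} d_k \tilde\nu^k$, solved per cell
by ordinary least squares; the corrected spectrum is
$(A - a - \sum_k d_k \tilde\nu^k)/b$. We default to $p = 2$ — the common
choice when the method is cited without a model order — and include no
interferent spectra in the design. Gains $b \le 10^{-6}$ are rejected
rather than silently inverted. Note that idempotence (re-correcting
changes nothing) holds with respect to the *same* reference: the residual
of an OLS fit is orthogonal to the design columns, so refitting corrected
spectra against the original reference returns $a=0, b=1, d=0$ exactly,
while refitting against the corrected set's own mean does not.

**SNV and unit-vector normalization.** SNV centres each spectrum to mean 0
and scales to sample standard deviation 1 (denominator $n-1$, the
chemometrics convention — stated explicitly so tests can be exact).
Unit-vector normalization scales to unit Euclidean norm. Constant and
all-zero spectra are errors, not NaNs.

**Rubber-band baseline.** The baseline is the lower convex hull of the
$(\nu, A)$ point set (Andrew's monotone chain), interpolated linearly
between hull vertices and subtracted; the result is non-negative and
vanishes at the hull vertices. We deliberately implement the single-pass
hull — the canonical definition — with no iterative refinement, since the
method is conventionally named without parameters.

**Savitzky–Golay derivatives.** Defaults are window 9, polynomial order 3,
second derivative, scaled by the actual grid spacing (the grid must be
uniform to 10⁻⁶ relative; resample first otherwise). The
$(\text{window}-1)/2$ edge points are *dropped*, not padded: padding
fabricates curvature exactly where the downstream minima search is most
fragile. One accuracy fact worth knowing: for a band of width
$\sigma = 10$ cm⁻¹ sampled at 1 cm⁻¹, the 9-point cubic filter's second
derivative deviates from the analytic derivative by about 4% of its
extreme value (a truncation error that shrinks quadratically with the
spacing — about 1% at 0.5 cm⁻¹). This does not move minima positions
materially, but it is why derivative *amplitudes* should not be
interpreted quantitatively at coarse sampling.

**Resampling.** `resample_spectra()` uses a natural cubic spline by
default. Linear interpolation systematically clips band maxima (for
$\sigma = 8$ cm⁻¹ sampled at 4 cm⁻¹ the peak error is ~0.03 of the band
height, versus ~5×10⁻⁴ for the spline), which would bias every
height-based metric computed after pooling grids; `method = "linear"` is
available when strictly local behaviour matters more.

## Amide-I secondary-structure deconvolution

The procedure, in order: average the selected cells over 1700–1600 cm⁻¹;
subtract the straight line anchored at the window ends; normalize to unit
norm; assign the five component centres (sidechain 1610, β-sheet 1630,
α-helix 1652, β-turn 1682, antiparallel β-sheet 1690 cm⁻¹) to local minima
of the Savitzky–Golay second derivative within ±8 cm⁻¹ of the nominal
positions; fit five Gaussians by bound-constrained least squares; report
analytic areas $h\sigma\sqrt{2\pi}$, percent areas, ∫α/∫β and the summed
squared error.

Several choices here deserve justification:

* **Centres bounded, not fixed.** Real second-derivative minima drift with
  composition; assigning them and then bounding the fitted centres within
  ±4 cm⁻¹ prevents two components from swapping labels mid-fit. When two
  overlapped components merge into a single minimum (the 1682/1690 pair
  does this readily), the minimum is kept for the nearest nominal centre
  and the other component falls back to its nominal position, flagged
  `center_fallback`.
* **A residual-background term in the fit.** The end-anchored linear
  baseline cannot distinguish true background from the tails of the outer
  components, so it removes a small chord of band area. If the subsequent
  least squares contains only the five Gaussians, that chord is
  redistributed across the components and can bias the α/β area ratio
  severely (tens of percent on noiseless model-consistent input, in either
  direction, depending on composition). The fit therefore carries a free
  constant + linear background by default (`fit_background = TRUE`), which
  absorbs the chord exactly; reported areas and the squared error always
  refer to the Gaussian components alone, and `fit_background = FALSE`
  restores the strict Gaussians-only formulation.
* **Optimization.** Heights enter the model linearly, so each start first
  runs a variable-projection pass — only widths and centres iterated, the
  heights solved at every step by non-negative least squares with the
  background projected out — whose solution seeds the fully nonlinear
  bounded fit. Starts span initial widths {4, 6, 8, 10, 12, 14} cm⁻¹ from
  both the assigned and the nominal centres; the lowest squared error
  wins, and the search stops early once the error reaches rounding level
  (10⁻¹⁸ on unit-normalized data). There is no randomness anywhere in the
  fit. Naive single-basin fitting of overlapped Gaussian quintets stalls
  in local minima routinely; the variable-projection multi-start is what
  makes noiseless recovery exact in practice.
* **β denominator.** ∫α/∫β uses the 1630 cm⁻¹ β-sheet component only,
  matching how the ratio is conventionally quoted alongside "α-helix and
  β-sheet" percentages; `beta_denominator = "all_beta"` pools β-sheet,
  β-turn and antiparallel areas instead. A profile with (numerically) zero
  β area yields a flagged undefined ratio, never an infinity.
* **Statistical limits.** With noise at 1% of the profile maximum, the
  five-component fit is ill-conditioned enough that even an estimator
  restarted from the true parameters shows a few-percent median and
  >10% occasional error in the recovered ratio. That is a property of the
  estimation problem, not of the optimizer; ratios from noisy single
  averages should be treated as having that uncertainty, and group
  averaging (the default input here) is what keeps the effective noise
  low.

## Band metrics and detection

`band_integral()` is a trapezoidal integral over the grid points in a
closed window, optionally minus a local linear baseline. Two baseline
flavours exist for a reason: the textbook chord through the two
window *endpoint samples* (`"local_linear"`), and a line fitted by least
squares to the outer 8 points at each end (`"edge_linear"`). For noisy
data the chord is a poor estimator — endpoint noise enters the integral
multiplied by half the window width, inflating its variance several-fold —
so the B–H uptake index and map integration default to the edge-fitted
line, whose anchor segments are band-free at any realistic band width in
the 160 cm⁻¹ B–H window.

The B–H index applies a detection floor: the detrended integral is a fixed
linear functional $c^\top y$ of the window samples, so its noise standard
deviation is $\|c\|$ times the per-point noise sd, estimated from first
differences (`sd(diff(d))/sqrt(2)`, barely inflated by smooth bands).
Integrals below 3 times that sd are reported as 0 and flagged
`below_detection` — the operational version of calling a small treated
signal "detectable" while controls read as zero. A 3σ floor still passes
~0.1% of pure-noise cells, so population summaries should quote the
below-detection fraction rather than insist on an exactly zero mean.

The unsaturation index divides the 3010 cm⁻¹ olefinic integral by the
2850 cm⁻¹ CH₂ integral, each in a ±10 cm⁻¹ window with a local baseline.
The windows are a package default (the positions are standard; the widths
are not stated anywhere authoritative): narrow enough to isolate the
bands, wide enough for typical widths. Note the finite windows clip band
tails; when numerator and denominator bands share a width the clipping
cancels in the ratio, but for unequal widths the index is a *comparative*
quantity across groups rather than an absolute area ratio. The
CH₃/CH₂ ratio uses peak heights (maxima within ±4 cm⁻¹ of 2960 and
2921 cm⁻¹); literature cites both 2960/2921 and 2966/2922, and the
defaults take the former with the search window covering the latter.

Map summaries break hotspot ties by row-major first occurrence (flagged),
clamp baseline-corrected intensity images at zero, and define
`mask_fraction` as the fraction of total image intensity inside a supplied
mask.

## Region-wise PCA

PCA is mean-centred SVD with no autoscaling — spectra are already
normalized by the region's preprocessing chain (EMSC→SNV for fingerprint
and lipids; EMSC→second derivative→unit vector for DNA, where derivative
spectra resolve the overlapped phosphate bands). Per-wavenumber scaling
would inflate noise channels to unit weight, which is why it is omitted.
$k = 3$ components are kept by default, matching the PC-1..PC-3 plots this
kind of analysis reports; signs follow a deterministic convention (largest
loading element positive) so scores are reproducible. Degenerate inputs
(identical spectra, $k \ge n$) are errors.

## The synthetic generator: what it does and does not emulate

`synthetic_model()` encodes the study conditions: Gaussian component bands
for protein (amide I substructure + amide II), DNA phosphate, lipid
CH₂/CH₃/olefinic stretches, and the drug's B–H doublet (2557/2537 cm⁻¹)
plus cluster C–H (3031 cm⁻¹); per-cell lognormal amplitude jitter
(sd 0.1); a random degree-≤2 polynomial baseline; a multiplicative scatter
transform with gain in [0.7, 1.3]; and additive Gaussian noise
(sd 0.005 AU). Group effects are multiplicative amplitude factors per
assignment: controls carry exactly zero drug bands; treated groups carry
positive factors that grow with dose; protein factors shift the α/β
balance down under treatment and make the mesenchymal line strongly
α-dominated; lipid factors lower unsaturation under treatment and move the
CH₃/CH₂ balance in opposite directions in the two lines. The published
work reports only the *directions* and significance of these changes, so
the shipped magnitudes are explicitly synthetic conventions; only
directions should be compared. A single global random stream with a
documented draw order (per cell: band jitters in library order, baseline
coefficients, scatter offset and gain, noise vector) gives bit-identical
populations per seed.

The generator deliberately omits Mie and resonant-Mie scattering,
water-vapour lines, detector nonlinearity, and realistic covariance
between distant bands. Consequently, passing end-to-end tests establish
that the pipeline's *estimators recover what the model family can
express* — they do not establish robustness to scatter artefacts or
atmospheric contamination, which real measurements must handle upstream.
A visible instance of model-vs-reality gap inside the package itself: on
full synthetic populations the recovered α/β ratio sits above the
generator's programmed band-library value because the amide II tail leaks
into the 1600–1700 cm⁻¹ window — a reminder that the deconvolution
measures the *window content*, not the protein alone.

## Statistics

Group comparisons use the two-sided Welch *t* test by default (a pooled
variant by flag): with per-cell band metrics there is no reason to assume
equal variances between treatment groups. Stars follow 0.05/0.01/0.001
with *p* exactly 0.05 not significant; two constant equal groups return
*t* = 0, *p* = 1 by convention. No multiple-testing correction is applied
by default, matching how per-band tests are conventionally reported in
this literature; a Bonferroni pass is trivial to add downstream via
`p.adjust` on the comparison table. The viability helper implements the
standard A570 normalization formula exactly.

## Problem sizes used in validation

The shipped validation suite uses group sizes of 50 cells per group across
5 seeds for end-to-end drug detection, 20 replicates for map hotspot
localization, 20×50 matrices for the PCA-vs-eigendecomposition oracle, and
50-point spectra for the brute-force convex-hull oracle — sizes at which
every oracle can be enumerated or simulated exactly while the behaviour of
interest (separation, localization, equivalence) is already asymptotic.
The acceptance script's recovery targets run on 101-point amide-I windows,
one deterministic fit per published group ratio.

## Known limitations

* Only the `(X++(Y..Y))` affine-scaled JCAMP-DX form is read; OPUS/SPC/ENVI
  binaries and interferogram processing are out of scope.
* No atmospheric (water vapour / CO₂) compensation; spectra are assumed
  already compensated by the acquisition software.
* The deconvolution assumes Gaussian component shapes throughout
  (generator and fit alike); Voigt/Lorentzian profiles are not offered, so
  shape misfit on real data folds into the residual background term and
  ΣError².
* Absolute boron quantitation is out of scope — the B–H index is
  proportional to, but not calibrated against, intracellular boron mass.
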