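# ftirmcell

Chemometrics for single-cell mid-infrared (FTIR) microspectroscopy of
drug-treated cells, built around one concrete use case: detecting uptake of
the anionic boron cluster cobaltabis(dicarbollide), Na[*o*-COSAN], in glioma
initiating cells (GICs) and quantifying the biochemical changes it induces.
The package is aimed at spectroscopists and cell biologists who record
100–200 single-cell absorbance spectra per condition (plus hyperspectral
rasters of individual cells) and need a reproducible, scripted version of
the usual workflow: preprocessing, region-wise PCA, amide-I
secondary-structure deconvolution, band metrics, chemical imaging and group
statistics.

## What it computes

**Preprocessing** (`emsc_correct()`, `snv_normalize()`,
`unit_vector_normalize()`, `rubber_band_correct()`,
`linear_baseline_correct()`, `savgol_derivative()`). Extended
multiplicative signal correction models each raw spectrum against a
reference *m*(ν) as

    A(ν) = a + b·m(ν) + Σₖ dₖ Tₖ(ν̃),   corrected = (A − a − Σ dₖTₖ)/b

removing additive baselines and multiplicative scatter per cell. SNV and
unit-vector normalization implement the standard per-spectrum scalings; the
rubber-band baseline is the lower convex hull of the spectrum; and
Savitzky–Golay filtering (default: window 9, 3rd-order polynomial, 2nd
derivative) resolves overlapped bands, whose centres appear as
second-derivative minima.

**Amide-I deconvolution** (`deconvolve_amide_i()`). The amide I band
(1700–1600 cm⁻¹) is modelled as five Gaussians — sidechain 1610, β-sheet
1630, α-helix 1652, β-turn 1682, antiparallel β-sheet 1690 cm⁻¹ — assigned
from second-derivative minima and fitted by bound-constrained least squares
(heights ≥ 0, σ ∈ [3, 25] cm⁻¹, centres within ±4 cm⁻¹ of assignment).
Component areas are analytic (h·σ·√2π) and the headline readout is the
α-helix/β-sheet integrated area ratio **∫α/∫β** together with the summed
squared fit error.

**Band metrics** (`bh_index()`, `unsaturation_index()`, `peak_ratio()`).
The drug-specific marker is the B–H stretch doublet (2557 cm⁻¹ with a
2537 cm⁻¹ sub-peak) in the organic-silent 2620–2460 cm⁻¹ window; its
baseline-corrected integral, with a 3σ detection floor, is the per-cell
uptake index. Lipid state is summarized by the unsaturation index
(∫3010 / ∫2850) and the CH₃(2960)/CH₂(2921) peak-height ratio.

**Chemical imaging** (`generate_map()`, `integrate_map_band()`). Per-pixel
band integration of hyperspectral rasters (e.g. 1.5 µm point spacing) gives
drug-localization images with hotspot, intensity centroid and
nucleus-mask fraction.

**PCA and statistics** (`run_pca()`, `compare_groups_ttest()`).
Mean-centred SVD PCA per spectral region (DNA 1350–900 on second
derivatives; fingerprint and lipids on EMSC+SNV spectra), and two-sided
Welch *t* tests with conventional significance stars.

**Synthetic single-cell generator** (`synthetic_model()`,
`generate_population()`). Because single-cell FTIR datasets are rarely
deposited, the package ships a generator that emulates the study design —
Gaussian component bands for protein/DNA/lipid/drug, per-cell amplitude
jitter, polynomial baselines, multiplicative scatter, Gaussian noise, and
group effects (treated cells gain the B–H band, shift α/β, lose lipid
unsaturation) — so the full pipeline is testable end to end with known
ground truth.

## Worked example

```r
library(ftirmcell)
library(dplyr)

model <- synthetic_model(seed = 101)
cells <- generate_population(model, n_per_group = 40,
  groups = list(c("GIC7", "control"), c("GIC7", "200uM")))

fit <- deconvolve_amide_i(cells, cell_line = "GIC7", treatment = "control")
glance(fit)
#> # A tibble: 1 × 6
#>   group        ratio_alpha_beta sum_sq_error percent_alpha percent_beta flags
#> 1 GIC7 control             3.74   0.00000816          66.1         17.7 center_…

met <- spectral_metrics(cells)
compare_groups_ttest(met$bh_index[met$treatment == "200uM"],
                     met$bh_index[met$treatment == "control"],
                     metric = "bh_index")
#>     metric   mean_a mean_b t_statistic      p_value stars
#>   bh_index 1.132102      0    22.10855 1.140907e-23   ***

run_pca(cells, "lipids", recipe = "snv")
#> <ftir_pca> region lipids [2800-3000], recipe 'snv', 80 cells, 3 components
#> explained: 31.6%, 13.5%, 2.7%
```

Reading the output: the control group's amide-I envelope decomposes to an
α/β area ratio of 3.74 with 66% α-helix area (the generator's programmed
protein mix seen through realistic baselines and amide-II overlap); every
control cell's B–H index sits below the detection floor (mean exactly 0)
while treated cells average ≈1.1 AU·cm⁻¹, separating at p ≈ 10⁻²³; and the
lipid-region PCA concentrates a third of the variance in PC-1.
`autoplot()` methods on PCA, deconvolution and map objects give the
standard figures; `run_pipeline(pipeline_config(...))` executes the whole
chain and writes delimited report tables plus a provenance manifest.

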