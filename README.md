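# wetrad

Water-equivalent thickness (WET) accuracy analysis for energy-painted
helium-ion radiography, as a fully synthetic, tested R pipeline.

## The problem

Particle-therapy treatment planning rests on a map of relative stopping
power (RSP). The quantity that actually decides where ions stop is the
water-equivalent thickness of each beam path,

```
WET = ∫ RSP ds   (mm of water),
```

predicted clinically from single-energy CT via a Hounsfield lookup table
(SECT-HLUT) or from dual-energy CT (DECT-DirectSPR). A helium-ion
radiograph measures WET directly at two orders of magnitude less dose, by
tracking single ions and reading their energy deposition dE in a thin
detector on the steep rising edge of the Bragg curve; an *energy painting*
scheme assigns each image region the beam energy whose monotone dE–WET
calibration window contains the region's expected WET.

`wetrad` is for medical-physics researchers who want the complete
comparison machinery of such a study — phantom, modality emulation,
radiograph simulation, and scoring — reproducible from a single seed:

* a procedural voxel head phantom (six tissue surrogates, cortical shell,
  cavities) calibrated so its 48 × 36 mm imaged region has mean WET
  135 mm with all pixels inside 90–180 mm;
* SECT/DECT-like RSP volumes as per-material bias models (blur + noise +
  clinical-grid resampling), with DECT biases smaller by construction;
* an energy-painted single-ion radiograph simulator: power-law range–energy
  closure `R = αE^q`, Bragg-edge calibration curves with range straggling,
  12-ROI planning, per-ion dE noise and Coulomb-scattering blur, median
  per-pixel reconstruction;
* the comparison metrics: relative WET difference maps
  `ΔWET(p) = 100·(WET(p) − WET_R(p))/WET_R(p)`, MAPE and RMSPE with
  42-subregion standard errors, local gamma analysis (0.7 %, 1 mm),
  distribution summaries, folded-normal consistency
  `E|N(μ,σ)| = σ√(2/π)e^(−μ²/2σ²) + μ·erf(μ/σ√2)`, and Pearson correlation
  of WET errors with per-channel material abundance.

## Worked example

```r
library(wetrad)

res <- run_pipeline(default_config(seed = 7))
report_table(res$reports)
```

```
Metric       arad              dect              sect
MAPE (%)     0.52 +/- 0.03     0.65 +/- 0.04     0.71 +/- 0.05
RMSPE (%)    0.73 +/- 0.04     0.95 +/- 0.06     0.99 +/- 0.06
std (%)      0.73              0.95              0.96
gamma (%)    94.0 +/- 0.9      91.3 +/- 1.2      91.8 +/- 1.2
```

Reading this: the simulated helium radiograph (`arad`) deviates from the
reference WET map by 0.52 % on average (absolute), the DECT-like volume by
0.65 % and the SECT-like volume by 0.71 % — DECT beats SECT because its
bias magnitudes are smaller, mirroring the clinical situation. RMSPE ≥ MAPE
always (Jensen); `gamma` is the fraction of pixels passing the local
0.7 %/1 mm criterion. Per-modality reports also carry the error–abundance
correlations:

```r
print(res$reports$sect)
#> sect: MAPE (0.71 +/- 0.05)%, RMSPE (0.99 +/- 0.06)%, std 0.96%
#>   gamma (0.7%, 1 mm): pass rate (91.8 +/- 1.2)%
#>   abundance correlation (%): air 35, soft_tissue -33, sinus_cavity 29,
#>     trabecular_bone -21, cortical_bone -20, spinal_cord NA
```

WET overestimation clusters where air and sinus surrogate dominate the
pixel channel, underestimation where cortical bone does — the signature the
bias models are built to reproduce. A homogeneous-slab accuracy benchmark
is one call:

```r
slab_benchmark(n_ions = 1e4, seed = 42)$mape   # ~0.01-0.05 (%), well below 0.3
```

`run_pipeline(cfg, out_dir = "runs/demo")` writes all WET maps (CSV),
reports (JSON + text table), the ROI plan, a config echo and a
checksummed manifest; `inst/cli/wetrad.R` wraps this for the shell.

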