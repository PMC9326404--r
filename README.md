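# leafspec

Estimation of leaf potassium content (LKC, % of dry mass) from
visible/near-infrared hyperspectral leaf images, by fusing continuous
wavelet transform (CWT) spectra with grayscale-image texture and color
features under partial least squares regression (PLSR).

Potassium is highly mobile in plants, so leaf K status shifts quickly
between growth stages; a non-destructive imaging estimate is the practical
alternative to digestion + flame photometry (K% = ρ·V·t_s·10⁻⁴ / m). K
status changes both the leaf spectrum — chlorophyll absorption near 450 and
680 nm, the green peak near 550 nm, the red edge over 690–760 nm, and a NIR
plateau (760–950 nm) that *brightens* under K deficiency — and the spatial
appearance of the leaf surface. The package implements the full chemometric
chain and, because no public dataset of this kind exists, a seeded synthetic
leaf-scene generator with known ground truth against which every stage is
validated.

The pipeline:

1. **simulate** — 128-band (376–1044 nm) scenes of lobed leaves on a dark
   plate with a gray reference panel; per-stage K drawn from truncated
   normals matching published stage statistics (60 leaves × 3 stages);
2. **calibrate** — DN → reflectance against the panel;
3. **segment** — threshold 0.25 at the band nearest 800 nm, largest
   4-connected component;
4. **spectra** — whole-leaf mean reflectance, trimmed to the 106 bands in
   400–950 nm;
5. **CWT** — sym2 wavelet at dyadic scales 2¹…2¹⁰ ("CWT-1"…"CWT-10"),
   W(a,b) = Σ_λ f(λ)ψ_a,b(λ), plus |r|-vs-K correlation maps;
6. **select** — characteristic wavelengths (≤ 10) by CARS (50 Monte Carlo
   runs, 5-fold CV, exponential forced reduction, adaptive reweighted
   sampling) or random frog (10,000 iterations, selection-probability
   thresholds 0.40/0.21/0.23 per stage);
7. **image features** — masked gray-level co-occurrence matrices (256
   levels, step 1, 0°/45°/90°/135°) giving 24 texture features per
   characteristic-wavelength image, plus 3 color moments; screened by
   correlation (p < 0.05) then CARS;
8. **model** — SIMPLS regression with RMSECV-chosen latent count on a 2:1
   concentration-gradient split (60 → 40/20), comparing the R-spectrum
   baseline, every CWT scale, and the fusions spectra / +color / +texture /
   +color+texture by validation R² and RMSE.

## Worked example

One growth stage end to end, desk-scale (96×96 scenes, 60 leaves, three
scales, CARS selection):

```r
library(leafspec)

cfg <- run_config(scene = scene_config(image_shape = c(96, 96)),
                  stages = "boll", scales = c(1, 3, 9),
                  selectors = "cars", seed = 11)
res <- run_stage(cfg, "boll")
res$report$scale_rows[, c("feature_set", "n_features", "r2_val", "rmse_val")]
res$report$fusion_rows[, c("feature_set", "n_features", "r2_val", "rmse_val")]
round(res$correlation_map$per_scale_max, 2)
```

```
  feature_set n_features    r2_val  rmse_val
1           R         10 0.5068233 0.3981234
2       CWT-1         10 0.1911439 0.5098613
3       CWT-3         10 0.2829407 0.4800583
4       CWT-9          4 0.4150177 0.4335985
              feature_set n_features    r2_val  rmse_val
1                   CWT-9          4 0.4150177 0.4335985
2           CWT-9 + color          6 0.5732915 0.3703242
3         CWT-9 + texture          7 0.8681264 0.2058711
4 CWT-9 + color + texture          9 0.8574077 0.2140742
CWT-1 CWT-3 CWT-9 
 0.74  0.75  0.79 
```

Reading the tables: spectra alone estimate this stage's potassium only
moderately well (validation R² 0.41–0.51 — the generator's leaves carry
K-independent biological variation, as real ones do), while fusing the GLCM
texture features extracted at the selected characteristic wavelengths
lifts validation R² to 0.87 and cuts RMSE to 0.21 % K. Texture helps
because the generator couples K to leaf-surface speckle; stacking color on
top of texture brings no further gain. The correlation-map maxima
(|r| ≈ 0.74–0.79) show where wavelet coefficients track potassium most
strongly. Exact numbers vary with the scene seed; the qualitative ordering
— texture fusion beats spectra-only — is the stable finding.

`run_pipeline(cfg, outdir)` runs all configured stages and writes the
comparison tables, correlation-map CSV/PNGs, selected wavelengths and a
YAML manifest that `read_run_config()` can reload exactly.

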