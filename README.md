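# msidiscrim

Discrimination of cancerous from normal oral mucosa in MALDI mass
spectrometry imaging (MSI) data, as a tested, reusable R pipeline. MSI
registers one mass spectrum per pixel of a tissue raster; `msidiscrim`
turns those raw spectra into quantified "molecular components" (modelled
peaks) and asks, in either the tryptic-peptide domain (m/z 800–4000) or
the lipid domain (m/z 300–1200), which components separate cancer from
normal epithelium and how well a compact spectral signature classifies
individual pixels.

The pipeline has six stages, each usable on its own:

1. **Preprocessing** — spectrum resampling onto a common m/z grid,
   adaptive baseline correction (morphological opening with an
   m/z-widening window), outlier-spectrum removal by generalized-boxplot
   fences on the TIC distribution, FFT alignment to the average spectrum,
   and TIC normalization.
2. **GMM features** — the cohort average spectrum is modelled as a
   Gaussian mixture, `f(x) = Σ_k w_k φ(x; μ_k, σ_k)`, fitted by EM per
   contiguous signal region with a BIC sweep over the component count.
   High-variance / low-amplitude components are flagged; right-side
   isotope satellites (≈1.003 Da spacing) are merged into their left
   major. The abundance of surviving component *c* in pixel *p* is the
   inner product `Σ_bins s_p(x) φ_c(x) Δx`.
3. **Segmentation** — divisive 2-means (k-means++ seeding) over
   log-abundances with data-driven stopping: a node stops when it is
   below 1% of the tissue or its centroid-distance distribution passes
   Hartigan's dip test for unimodality.
4. **Comparative statistics** — per-component CV, Lilliefors and F
   screens, two-sided Mann–Whitney U with Benjamini–Hochberg control,
   and a robust Cohen's d = (trimmed mean difference) / (pooled
   Winsorized SD), categorized at |d| > 0.5 / 0.8 / 1.2
   (medium / large / very large).
5. **Classification** — 50× multiple random validation (stratified 50/50
   splits, class-balancing downsampling, forward stepwise logistic
   regression under BIC), feature scoring by test accuracy × positional
   weight, knee-rule signature sizing with a plateau advance, per-pixel
   cancer probability maps.
6. **Annotation** — mass matching against candidate lists: peptides at
   ±0.05% relative tolerance (observed MH+ masses), lipids at 0.5 Da
   with [M+H]+/[M+Na]+/[M+K]+ adducts and lowest-|Δm| best hits.

A synthetic phantom generator (`make_phantom`, `make_component_library`,
`synthesize_dataset`) plants known region maps, peak positions, isotope
envelopes, effect sizes (calibrated in the same robust-d metric the
pipeline estimates), baseline drift, m/z jitter, TIC spread and outlier
pixels, so every stage is testable without real tissue.

## Worked example

```r
library(msidiscrim)

map <- make_phantom(c(20, 20), cancer_fraction = 0.4, seed = 3)
lib <- make_component_library(30, c(800, 1100), frac_discriminatory = 0.3,
                              effect_size_range = c(1.2, 2), seed = 5)
syn <- synthesize_dataset(map, lib, seed = 7)
pp  <- preprocess(syn$dataset, roi = syn$roi)
pp$report
#> <preprocess_report> 400 pixels in, 9 outliers removed
#>   mean |shift|: 0.731 bins; mean baseline fraction: 0.339

gm <- fit_gmm(average_spectrum(pp$dataset))
gm <- merge_skewed(filter_components(gm, sd_max = 1, weight_min = 0.01))
ft <- quantify_abundances(gm, pp$dataset)
ft
#> <feature_table> [peptide] 69 components x 391 pixels

eff <- compare_components(ft, pp$roi)
table(eff$category[eff$significant])
#> negligible     medium      large very_large
#>          0          3          0         11

seg <- divik_segment(ft, seed = 2)
runs <- run_random_validation(ft, pp$roi, n_iter = 50, seed = 11)
sc   <- score_and_rank_features(runs, ft$component_ids)
sel  <- select_signature(sc, ft, pp$roi, seed = 11)
sel$size
#> [1] 6
model <- train_classifier(ft, pp$roi, sel$signature, seed = 11)
evaluate_classifier(model, ft, pp$roi)$weighted_accuracy
#> [1] 94.44369
```

The preprocessing report above is real output: 9 of 400 phantom pixels
are dropped by the TIC fences (the phantom plants ~1% extreme-TIC
outliers plus natural spread), the mean alignment shift reflects the
planted 0.1 Da calibration jitter, and a third of the raw ion current is
removed as baseline. The 69 fitted components cover the 30 planted peaks
plus their isotope satellites and a few shoulder components; 14 of them
test significantly different between regions, 11 with very large robust
effects (the phantom plants 9 discriminatory peaks whose satellites
inherit the effect). The 6-component signature classifies held-out
pixels at 94.4% weighted accuracy.

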