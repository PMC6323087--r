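---
title: "Methods: models, parameters and design choices in msidiscrim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in msidiscrim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`msidiscrim` implements a complete analysis chain for MALDI mass
spectrometry imaging of tissue: preprocessing, Gaussian-mixture peak
modelling and quantification, unsupervised segmentation, robust
differential statistics, a validated logistic classifier, and mass-based
annotation. This vignette records the models, the tunable parameters
with their defaults and units, the numerical choices, and the design
decisions made where the field leaves the design genuinely open. It
states no empirical result that the package's tests do not themselves
compute.

## The data model

A `spectra_dataset` is a pixel-by-bin intensity matrix on a strictly
increasing m/z grid, with 0-based integer raster coordinates kept in
row-major order; the physical pitch (100 µm by default) is metadata
only, since every algorithm operates on grid topology. Intensities are
arbitrary detector units, assumed nonnegative and — important for one
model choice below — roughly proportional to ion counts, as is usual
for TOF detectors summing hundreds of laser shots per pixel.

## Preprocessing

The stage order is fixed: resample → baseline → outlier removal → align
→ TIC normalize. Each stage's contract is behavioural, and the
implementations are deliberately simple:

* **Resampling** (`grid_step`, default 0.1 Da peptide / 0.05 Da lipid):
  linear interpolation onto an even grid. The step is chosen finer than
  the ~0.3 Da peak SD of the phantoms so that peak areas survive within
  1%.
* **Baseline** (`window`, default 5 Da at the low-mass end): a
  morphological opening — rolling minimum then rolling maximum, which
  follows any smooth baseline exactly on monotone stretches while
  erasing peaks narrower than the window — followed by a rolling mean,
  with the window widening proportionally to m/z because TOF peaks
  broaden with mass. Any estimator leaving under 5% residual ion current
  on a peak-free spectrum would be conforming; this one leaves well
  under 1% on smooth decays.
* **Outlier spectra**: the total ion current (TIC) distribution of MSI
  pixels is extremely skewed, so plain boxplot fences misfire. We reduce
  TICs to `log(TIC/median)` (making the rule invariant to global
  rescaling), fit a Tukey g-and-h tail model by quantile matching (g
  captures asymmetry from the 10/90 quantiles, h tail heaviness from the
  growth of the 80% vs 50% spans, h clamped to [0, 1]), and flag pixels
  beyond the modelled 0.35%/99.65% quantiles — a 0.7% two-sided tail
  level, the "extreme" fence level of generalized boxplots. Degenerate
  all-equal TICs flag nothing.
* **Alignment** (`max_shift`, default 1 Da, capped at 10% of the range):
  one global integer-bin lag per spectrum, the argmax of the FFT
  cross-correlation with the cohort average; ties prefer the smallest
  lag. No segment-wise warping is attempted — the phantom plants a
  single per-pixel calibration shift, which is also what a global lag
  can correct. With few pixels (< ~8) the average itself is contaminated
  by the shifted spectrum and the recovered lag can be off by one bin;
  the tests use ≥ 8 pixels.
* **TIC normalization**: every spectrum is scaled to the cohort mean
  input TIC. Any common constant is equivalent up to global scale; the
  mean keeps intensities in the input's numeric range.

## Gaussian mixture modelling of the average spectrum

The average spectrum is treated as a sample-weighted density over m/z.
Fitting one EM across ~32,000 bins is numerically fragile, so the
spectrum is split at runs below a threshold (the larger of 5·10⁻⁴ of the
tallest bin and median + 5 MAD, the latter estimating the residual noise
pedestal) into contiguous signal regions, merged across gaps under 1 Da
so isotope envelopes stay together.

Per region, EM runs on bin centres weighted by intensity. Initialization
places one component at every above-threshold local maximum with an SD
from the half-height width of the tallest peak. Since an above-threshold
local maximum of an averaged, baseline-corrected spectrum is direct
evidence of a peak, the component count is floored at the maxima count;
a greedy sweep then repeatedly adds a component at the residual maximum
and keeps the count with the best BIC. Two conventions deserve note:

* **BIC sample size.** The BIC penalty uses the region's total
  intensity as the effective count. With bin counts instead, a
  satellite carrying a few percent of an envelope's mass can never
  justify three extra parameters and the exact-satellite-recovery
  property fails; treating intensities as pseudo-counts matches the
  ion-counting character of TOF detection. The consequence — component
  counts grow slowly with overall intensity scale — is documented
  behaviour.
* **Amplitude** for filtering means density apex height (weight/SD),
  not mixture weight: a broad, heavy component is still a *low* peak.

Filtering (`sd_max`, `weight_min`) only annotates; merging
(`envelope_window` = 3.1 Da, covering +1/+2/+3 satellites of singly
charged species; `dominance_ratio` = 0.9) maps right satellites
transitively onto their nearest left major of sufficiently larger
amplitude. Equal-amplitude neighbours never merge. Quantification is the
inner product of each spectrum with the unit-area merged component
density (satellite densities folded in, mixture-weighted) times the grid
step — the only reading of "convolution" that yields one scalar per
component and spectrum; it is exactly linear in the spectrum.

## Segmentation

Divisive 2-means: at each node, components whose within-node linear-scale
CV falls below the node median are dropped (per-level feature selection),
then 2-means (k-means++ seeding, 10 restarts, Lloyd iterations) splits
the node in log1p-abundance space. A node becomes a leaf when it holds
fewer than `min_cluster_frac` (default 1%) of all pixels or when the
distances of its pixels to the node centroid pass the dip test at
α = 0.05. The stop test sees the node's *full* feature space — filtering
first costs exactly the distance contrast the test needs.

The dip statistic is computed by an independent implementation verified
against a brute-force feasibility search of the definitional quantity
(the minimum sup-distance between the empirical cdf and any unimodal
cdf); implementations following the classical order-statistic
interpolation convention can differ by O(1/n). P-values come from a
Monte-Carlo uniform null (B = 200, cached per sample size) built from
the same statistic, so the test is exactly calibrated by construction.
Nodes above 512 pixels are randomly subsampled (deterministically) —
*random* subsampling, because order-statistic thinning produces
super-uniform samples and silently destroys the test's power.

A known limitation: distances-to-centroid collapse a multivariate
cluster structure to one dimension, and two clusters placed symmetric
about the centroid (equal sizes) are invisible to any such rule. In
tissue images region sizes are unequal, which is what the phantoms
emulate.

## Comparative statistics

* Mann–Whitney U is exact (via the Wilcoxon null) when both groups have
  ≤ 8 observations without ties, else the tie-corrected normal
  approximation with continuity correction. BH runs across all
  components of one molecular domain (one family per comparison).
* The robust effect size divides the difference of 20% trimmed means by
  the pooled Winsorized SD, pooling variances with weights (group
  size − 1); `trim = 0` recovers classical Cohen's d exactly. The 20%
  default is the robust-statistics standard. Categories use strict
  "above": |d| = 0.8 is still medium.
* The Lilliefors screen uses a Monte-Carlo null (parameters estimated
  per sample), cached per sample size; the F screen is the classical
  two-sided variance-ratio test. Both are descriptive; neither gates the
  rank test.
* The similarity index ranks components by mean abundance across both
  groups and reports the cosine similarity of √-transformed abundances
  over the top n — a standard variance-stabilized spectral similarity;
  any fixed monotone transform meeting the identity/orthogonality
  contracts would conform.

## Synthetic phantoms: what they emulate, and what not

`make_phantom` lays a connected cancer blob (exactly the requested pixel
fraction, as the nearest-k pixels to a random interior centre) in an
epithelium field. `make_component_library` spaces peak centres at least
4 SDs apart (evenly with jitter), draws base abundances log-normally
(median 100, log-SD 0.5 — a realistic MALDI dynamic range), gives a
chosen fraction of components region effects, and attaches 1–3 right
satellites (1.003 Da spacing, weights 0.5^k) to a chosen fraction.
Region CVs default to 0.4 (cancer) vs 0.3 (epithelium) — dispersion
higher within tumours, as observed in imaging cohorts.

Two calibration choices matter:

* **Planted effects are expressed in the pipeline's own metric.** The
  log-normal median multiplier for a target robust d is solved
  numerically from population trimmed means and Winsorized variances
  (deterministic quantile quadrature), assuming equal group weights. The
  planted d is therefore recovered by `cohens_d_robust` within
  Monte-Carlo error by construction, not by luck.
* **Abundance dispersion lives in the library, not the corruption
  knobs.** With all corruption parameters (noise, baseline, jitter, TIC
  spread, outliers) at zero, pixels of one region still differ through
  their abundance CVs; setting the CVs to zero as well makes every
  region's spectra bit-identical — the degenerate world used by the
  identity tests.

The generator does *not* model physical isotope distributions, detector
saturation, chemical noise, or spatial autocorrelation of abundances
within a region. A green phantom test therefore establishes algorithmic
correctness against the stated generative model, not instrument-level
realism. For the satellite-merge acceptance check the envelope phantom
uses `min_separation = 4.5` Da so whole envelopes stay disjoint —
when a satellite coincides with a neighbouring major, no method can
attribute it, and the check would measure geometry, not the rule.

## Classification

Logistic regression is fitted by IRLS with a 10⁻⁸ ridge so that the
perfect separation expected on strong phantoms cannot crash selection,
on log1p-abundances. Each of the 50 random-validation iterations makes a
stratified 50/50 split, downsamples the training half to equal class
counts (test halves keep natural prevalence), and grows the signature
forward while BIC (penalty log n on the training count) improves.

The scoring recipe — test accuracy, membership, and position in the
signature — is realized as score(f) = Σ over runs containing f of
(weighted accuracy as a fraction) × (L − pos + 1)/L. The signature size
is the knee of the score curve (maximum signed elevation above the
first-to-last chord after normalizing both axes to [0, 1]; flat or
convex-everywhere curves fall back to 1), advanced to the first k whose
retrained weighted accuracy is within 0.5 percentage points of the curve
maximum when that plateau point is larger. The retraining curve averages
five repeated stratified 50/50 holdouts (train balanced, evaluate on the
untouched half) — the "classifier stability" smoothing without which a
single noisy holdout lets irrelevant features set a spuriously late
maximum. Tie-breaks everywhere are by ascending m/z.

The standard harmonic-mean F-measure is implemented. Reported MSI
classifier tables sometimes print F values inconsistent with the
harmonic mean of their own precision and sensitivity; the package
asserts only the internally consistent identities (weighted accuracy =
mean of sensitivity and specificity).

## Annotation

Peptide candidates are observed singly protonated masses, matched at
±0.05% of the *component* m/z (closed window; at this tolerance the
choice of reference is negligible but pinned). Lipid candidates are
neutral masses expanded to [M+H]+, [M+Na]+, [M+K]+ (cation mass minus
one electron: +1.007276, +22.989218, +38.963158 Da) and matched at an
absolute 0.5 Da. Best hits minimize |Δm|; exact ties prefer the lighter
adduct, then the candidate id. "Most probable hit" in the source
methodology also mentions expected tissue abundance; without abundance
priors, lowest |Δm| alone is implemented.

## Known limitations

* The dip-based stop rule is conservative; moderate multivariate
  structure (per-feature effects ≲ 2 with few features) often stays a
  single cluster. This mirrors the behaviour of distance-profile
  stopping rules generally.
* GMM component counts depend on the intensity scale through the
  pseudo-count BIC (see above).
* The imzML reader/writer covers exactly the continuous-mode subset the
  package writes (float64 arrays, one shared m/z axis); vendor files
  with other encodings are out of scope.
* Alignment corrects integer-bin global shifts only; sub-bin or
  mass-dependent miscalibration is left in place (and shows up as a
  ≤ 0.5-bin residual in the phantom audits).
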