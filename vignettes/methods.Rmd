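---
title: "Methods: single-synapse transfer functions of IHC active zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-synapse transfer functions of IHC active zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, numerical choices and known
limitations of the `ihcsynapse` pipeline, and what the synthetic-data
generator does and does not emulate.

## The measurement model

An inner hair cell (IHC) is voltage-clamped while two reporters are imaged
sequentially at its ribbon synapses:

* **Synaptic Ca²⁺ influx.** During a voltage ramp (−87 → +63 mV, 1 mV/ms),
  the low-affinity Ca²⁺ indicator Rhod-FF forms a fluorescent "hot spot" at
  each active zone. The fluorescence–voltage relation is the product of a
  Boltzmann channel-activation term and the linear driving force:

  $$F(V) = F_0 + g_{max}\,(V - V_r)\,\frac{1}{1 + e^{(V_{1/2}-V)/k}}$$

  with the reversal potential fixed at $V_r = +47.6$ mV (after liquid
  junction correction) and never fitted. By the sign convention used
  throughout, $g_{max} < 0$, so the fluorescence change is positive below
  $V_r$. `fit_ca_fv()` estimates $(F_0, g_{max}, V_{1/2}, k)$; the
  *fractional activation* curve is the fitted curve minus baseline divided
  by the extrapolated line $g_{max}(V-V_r)$, which equals the sigmoidal
  factor exactly. (The alternative reading — dividing the full curve
  including the baseline by the line — produces a quantity that is not
  bounded by 1 and is not used.) The fitted midpoint of the sigmoidal factor
  is reported as $V_{1/2}$.

* **Glutamate release.** During 50-ms steps (−57…−17 mV, pseudo-randomized
  order), iGluSnFR on the postsynaptic bouton reports release. The response
  of each step is reduced to an area under the curve (AUC) over 40 frames
  from stimulus onset, and the AUC–voltage relation, normalized to its
  maximum, is fitted by a plain Boltzmann. Threshold and dynamic range
  follow in closed form: $V_{10} = V_{1/2} - k\ln 9$, $DR_{10-90} =
  k\ln 81$.

* **Apparent Ca²⁺ cooperativity.** The two fitted curves are evaluated on a
  −57…−17 mV grid in 1 mV steps, normalized, and the power law
  $AUC = A\,(\Delta F_{Ca})^m$ is fitted in linear space over the grid
  points where release is at or below 25% of its maximum (to avoid
  pool-depletion saturation). The log–log regression slope provides the
  initial value and serves as an independent oracle in the tests. Fits with
  $R^2 \le 0.7$ are flagged excluded, as are Boltzmann fits below the same
  gate.

## Trace processing

Raw ROI-mean traces are processed in a fixed forward order
(raw → background-subtracted → ΔF/F₀ → bleach-corrected):

1. background subtraction using the mean over a square region on the pillar
   side of the frame, where no sensor fluorescence is expected (60 × 60 px
   on full camera frames; 12 × 12 px on the compact synthetic frames);
2. ΔF/F₀ with F₀ the mean of the background-subtracted baseline (15
   pre-stimulus frames);
3. on the 100 Hz Ca²⁺ channel, a zero-phase (forward–backward) Butterworth
   band-stop around 33.3 Hz removes the spinning-disk illumination artifact
   (2,000 rpm). The stop band is narrow (±2 Hz): the artifact is a single
   spectral line, and a wide notch measurably distorts the ramp transient
   and inflates the fitted slope factor. The filter meets ≥20 dB attenuation
   at 33.3 Hz with <1 dB below 10 Hz; the mean is restored exactly. The
   50 Hz glutamate channel cannot resolve 33.3 Hz and is never filtered
   (the function refuses);
4. photobleaching correction: a single exponential *with offset*,
   $b_0 e^{-t/\tau_b} + c$, is fitted to the ΔF/F₀ samples outside a
   40-frame response window after each stimulus onset and subtracted. The
   offset is required because dividing a bleaching fluorophore by a fixed
   F₀ leaves an additive constant; without it the model cannot represent
   the data even noiselessly. Non-convergent fits fall back to a linear
   trend with a warning;
5. Hanning smoothing (window 7, reflection edges) is applied *only* for
   peak detection and the 2×-baseline-SD detectability rule; AUCs and all
   fits use unsmoothed corrected traces;
6. AUC by the trapezoidal rule over 40 frames (a fixed frame count, as the
   window tracks the indicator decay in frames; a time-based option exists
   for cross-rate comparisons).

### Exposure-aware ramp fitting

At 100 Hz and 1 mV/ms, each Ca²⁺-channel frame integrates 10 mV of the ramp.
Assigning the mid-exposure voltage to the frame and fitting the pointwise
model broadens the apparent slope factor by ≈ $\sqrt{k^2 + w^2/12}$
(w = 10 mV): roughly +25% at k = 4 mV. `fit_ca_fv(exposure_mV = 10)`
therefore averages the model over the swept span (5-point midpoint rule),
which removes the bias; the pipeline enables this automatically from the
protocol's ramp rate and frame rate.

## ROI detection

ΔF images (mean of 5 response frames minus mean of 15 baseline frames) are
filtered (median, footprint 4–6 px, or Gaussian, σ 1–3 for the dual-color
data), thresholded by Kapur's maximum-entropy criterion on a 256-bin
histogram, and labeled by watershed. The watershed runs on the **masked
filtered-intensity surface**, not on the distance transform of the binary
mask: overlapping spots a few pixels apart produce a convex mask whose
distance transform has a single maximum, so no distance-transform watershed
can separate them, whereas the intensity surface is bimodal whenever the
peaks are resolvable. Seeds closer than 2 px merge, and bumps shallower than
10% of the suprathreshold range do not found their own region; regions under
20 px are dropped. One mask per cell (from the strongest stimulation) is
reused across recordings. For the Ca²⁺ channel the per-ROI plane with the
largest ΔF is selected; exact ties break toward the central plane.
Glutamate ROIs are paired with the nearest Ca²⁺ hot spot within 10 px,
standing in for the ribbon-marker proximity check used with immunolabels.

## Position, clustering, statistics

The cell outline is an ellipse fitted to the Rhod-FF baseline (Otsu
threshold, largest component, second moments; semi-axes are
$2\sqrt{\lambda_i}$ of the pixel covariance). The major axis is the
pillar–modiolar axis; which vertex is the pillar side is a per-recording
configuration (the rig fixes it, the image does not). A synapse's position
is the normalized coordinate of the orthogonal projection of its hot spot
onto that axis, clipped to [0, 1].

Eleven per-synapse properties (four Ca²⁺-curve descriptors, the peak Ca²⁺
signal, four release-curve descriptors, the maximal AUC, and m — positional
and whole-cell quantities deliberately excluded) are z-scored before K-means
(K = 3, 25 restarts) and PCA; mixing millivolts and arbitrary units unscaled
would be meaningless. Cluster labels are re-ordered by ascending centroid m,
so "cluster 1" is always the lowest-cooperativity (nanodomain-like) subtype
and labels are reproducible across seeds on separable data. Group
comparisons gate the test choice on a D'Agostino–Pearson omnibus normality
check (implemented from the published formulas and verified against an
independent reference implementation): t-test when both groups pass,
Mann–Whitney U otherwise; Levene's test for dispersion; one-way ANOVA with
Tukey HSD across clusters. Pillar vs modiolar groups split at position 0.5.

## The synthetic-data generator

`sample_ground_truth()` draws per-synapse parameters; `render_movie()` and
`synth_ephys()` render the experiment. The defaults are the study
conditions:

| parameter | default | note |
|---|---|---|
| $V_{1/2}$ of Ca²⁺ influx | −45.15 + 8·position ± 5.2 mV | population mean −41.15, SD 5.7 mV; positive pillar→modiolar gradient |
| slope factor $k$ | 5 ± 1 mV (truncated 2.5–9) | |
| cooperativity m | 1 + lognormal(log 1.3, 0.55) | ≥ 1; median ≈ 2.3, tail to ~8 |
| RRP size | lognormal, median 2.3 a.u. | ≈ 10 vesicles at 0.23 a.u./SV |
| depletion τ | lognormal, median 11.4 ms | release rate at −17 mV is 1/τ |
| sustained rate | lognormal, median 42.7 a.u./s | Ca²⁺-dependent, see below |
| indicator τon, τoff | 10 ms, 80 ms | double-exponential kernel |
| bleach τ | 3 s | glutamate channel only |
| artifact | 1% amplitude at 33.3 Hz | multiplicative |
| noise | read SD 1.5 a.u.; shot var = 0.02·I | |
| axial attenuation | Gaussian, FWHM 1.55 µm | ≈ 25% loss at ±0.5 µm |
| spot shape | symmetric Gaussian, σ 4 px | |
| geometry | 96 px frames, 103 nm px, 5 planes à 0.5 µm | hot spots ≥ 18 px apart (~2 µm AZ spacing) |

Release follows a power law on the *instantaneous* rate,
$\lambda(V) = \tau^{-1} (\Delta Ca(V)/\Delta Ca(-17\,\mathrm{mV}))^m$, with
cumulative release $Q(V,T) = RRP(1-e^{-\lambda T}) + s(V)\,T$. Two modeling
choices deserve emphasis:

* **The sustained rate is Ca²⁺-dependent** with the same exponent,
  $s(V) = s_0 (\Delta Ca/\Delta Ca_{ref})^m$. Sustained release is
  Ca²⁺-driven replenishment; a voltage-independent sustained term would put
  a constant floor under release at hyperpolarized potentials and destroy
  the power relation the analysis measures.
* **The depletion rate is anchored to the measured depletion constant**:
  the rate scale at the −17 mV reference is $1/\tau_{depletion}$ (median
  11.4 ms), so pool-fit recovery has a well-defined truth and the strongest
  step depletes most of the pool within 50 ms, as observed.

The generator does **not** emulate: optical PSF physics or diffraction,
glutamate diffusion and spill-over between boutons, indicator saturation,
response run-down across sweeps (each sweep bleaches independently;
pseudo-randomized presentation order exists to balance run-down in real
data), mitochondrial Ca²⁺ contamination, or motion. Passing recovery tests
therefore demonstrates correctness of the analysis chain under the stated
forward model, not robustness to those real-data effects.

## What recovery shows — and the apparent-m compression

On rendered movies at default noise, the pipeline recovers the Ca²⁺-curve
midpoint with a median error of ~0.1 mV and the slope factor within a few
percent; the planted pillar–modiolar gradient and its sign are recovered by
regression on the profile table, and the first three PCA components explain
~80% of the population variance (all recomputed by the test suite and
`scripts/acceptance.R`).

The apparent cooperativity is different. With the pool depleting at
$\tau \approx 11$ ms at strong steps, even the sub-25% fit range sits at
$\lambda T \approx 0.4$, where $1 - e^{-\lambda T}$ is visibly sublinear:
the measured exponent is compressed toward lower values by roughly 20–25%
(median across the population), independent of noise. This is a property of
the estimator — which is precisely why it is called *apparent*
cooperativity — not an implementation defect: the same procedure applied to
the closed-form curves shows the same compression, and shortening the
depletion constant in the generator makes it grow. The rank ordering of m
across synapses, on which the subtype clustering rests, is preserved
(Spearman ρ ≈ 0.7 at default noise). Recovery bounds that require the
absolute exponent back within 15–20% are not attainable under these
depletion kinetics.

## Numerical choices

* All nonlinear fits use trust-region Levenberg–Marquardt (`minpack.lm`)
  with analytic initializations and multi-start fallbacks: the modified
  Boltzmann initializes $V_{1/2}$ at the half-rise of the rising limb plus a
  small grid of alternatives (a single bad start can make the Jacobian
  numerically singular when $g_{max}$ is small); the pool fit uses variable
  projection (the model is linear in RRP and slope given τ) over a τ grid,
  which also handles the degenerate pure-linear limit.
* The power fit runs in linear space (matching the fitted quantity); the
  log–log slope is used only for initialization and as a test oracle.
* The Kapur threshold maps the image linearly onto 256 bins and returns the
  upper edge of the best background bin; the tests verify exact argmax
  agreement with a brute-force entropy scan.
* Problem sizes in the test and acceptance runs — 34 cells / 55 synapses
  for the population run, 60 cells / 120 synapses for recovery — mirror the
  scale of the experimental dataset while completing in minutes on one CPU.
* Degenerate inputs have defined behavior: constant images raise a
  degenerate-histogram error; circular cells set the axis angle to 0 with a
  flag; zero baseline SD in detectability uses a machine-epsilon floor with
  a warning; empty scenes yield empty ROI sets, not errors.

## Known limitations

* The 11-property set is a reconstruction: the property count and the
  exclusion of positional/whole-cell information are fixed, but the exact
  identity of the properties is configurable and recorded in output
  metadata.
* The ellipse-projection position assumes the pillar–modiolar axis is the
  major axis of the mid-section outline; strongly tilted cells would bias
  positions.
* The apparent-m compression above; absolute m values should be compared
  only between synapses analyzed with the same protocol and cutoff.
* HDF5 bundle export is not provided; movies round-trip as 16-bit TIFF,
  tables and traces as CSV, protocols/ground truth as JSON.
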