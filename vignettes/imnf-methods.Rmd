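---
title: "Methods: spatially invariant MNF denoising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially invariant MNF denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imnf)
```

## The transform

A hyperspectral absorbance cube is arranged as a matrix $X$ of $m$ pixel
spectra across $v$ wavenumbers. MNF denoising estimates a noise
covariance $\Sigma_\delta$, whitens the data against it,

$$\Sigma_\delta = V \Lambda_\delta V^\top, \qquad
  W = X\, V \Lambda_\delta^{-1/2},$$

finds the variance-maximising orthogonal components of the whitened data,

$$W^\top W = G \Lambda_\omega G^\top,$$

and — because the whitened noise has unit variance in every direction —
ordering those components by variance orders them by signal-to-noise
ratio. The forward map $\Phi_K = V\Lambda_\delta^{-1/2} G_K$ projects
spectra onto the top $K$ components; the reconstruction
$R_K = G_K^\top \Lambda_\delta^{1/2} V^\top$ returns them to absorbance
space. Denoising is $D = (X\,\Phi_K)\,R_K$. With $K = v$ the composition
is the identity; with white noise ($\Sigma_\delta \propto I$) the whole
transform collapses to uncentred truncated-SVD (PCA) reconstruction.
Both facts are enforced as tests rather than assumed.

Neither decomposition mean-centres the data: raw cross-products
($N^\top N$, $W^\top W$) are used throughout, which matches the fast-MNF
implementation lineage this package follows and keeps `pca_denoise()`
(uncentred truncated SVD) the exact white-noise reference.

The second decomposition is computed through the SVD of $W$ rather than
an eigendecomposition of $W^\top W$: it is the numerically stable route
and gives the same eigensystem. When a *dense* noise covariance is rank
deficient — fewer difference spectra than bands, or collinear noise —
the whitening is restricted to the rank-$r$ noise subspace (with a
warning), the standard dimensionality-reduction treatment in fast-MNF
implementations; $K$ may not exceed $r$.

## The two noise models

**Adjacent differencing (standard MNF).** $N_i = X_i - X_{i+1}$ over the
row-major unrolled pixel order, $\Sigma_\delta = N^\top N$. The estimate
is deliberately order-*dependent*; it is retained as the comparison
method and for data where spatial order is trustworthy. Row-boundary
pairs (the last pixel of an image row against the first of the next) are
included by default — for a $512\times512$ image they are 511 of 262 143
pairs, under 0.2 % (`edge_transitions()`) — with an option to drop them.

**Silent-region model (iMNF).** Four composable steps, each exported:

1. `sg_base_variance()` — a Savitzky–Golay first derivative (window 5,
   order 2 by default) is applied across the silent-window columns and
   the mean per-band variance of the *interior* filter outputs is taken.
   The derivative acts as a high-pass filter: slowly varying chemistry
   survives in the baseline but is removed by differentiation, so the
   remaining variance is attributable to noise. Edge outputs of the
   filter are excluded so one-sided fits never contaminate the estimate.
   Variances use the population (denominator-$n$) form; at the pixel
   counts involved the distinction is immaterial, but it is fixed and
   documented here because it is a classic source of drift.
2. `to_transmittance()` — $\bar T = 10^{-\bar A}$, the base-10
   Beer–Lambert convention, clamped below at $10^{-6}$ so saturated
   bands cannot degenerate.
3. `reference_transmittance()` — the arithmetic mean of $\bar T$ over
   the silent window.
4. `noise_profile()` — noise variance in absorbance units is inversely
   proportional to the square of transmittance (the logarithmic
   conversion of near-constant transmittance noise), so the base
   variance measured where $\bar T = \bar T_{\mathrm{ref}}$ is scaled as
   $S_v = (\bar T_{\mathrm{ref}}/\bar T_v)^2$ and floored at $10^{-12}$
   to keep $\Sigma_\delta = \mathrm{diag}(\sigma^2_{\mathrm{base}} S)$
   invertible.

Everything here depends only on column-wise means and variances, so the
estimate — and hence the denoised output — is invariant to pixel order
up to floating-point summation order (verified to $10^{-10}$ relative in
the tests; the end-to-end ordered-vs-shuffled difference is at machine
precision).

**Calibration scalar.** Equation-level, the base variance is a
*derivative* variance: for iid noise of variance $\sigma^2$ at unit band
spacing the window-5/order-2 derivative returns $0.1\,\sigma^2$ (the sum
of squared filter coefficients $(-2,-1,0,1,2)/10$). A global scalar on
the noise covariance scales the eigenvalues and leaves eigenvectors,
component ordering and the denoised output unchanged — the
scalar-invariance property test — so the choice is free.
`estimate_noise_imnf(calibrate = TRUE)` (the default) divides by the sum
of squared (spacing-scaled) coefficients so that `base_variance` is
expressed in absorbance-variance units; with that convention the profile
on phantoms matches the delta-method prediction
$(\sigma_T/(\bar T \ln 10))^2$ band by band (within 20 % at $10^4$
spectra, tested), which makes the stored numbers physically
interpretable. `calibrate = FALSE` reproduces the raw derivative-variance
convention.

**Window selection and QC.** The silent window may be given explicitly
(`silent_region()`; defaults in this field are 1750–1800 cm⁻¹ for QCL
and 1750–2200 cm⁻¹ for FTIR) or found automatically:
`select_silent_window()` slides a window of fixed width (default
50 cm⁻¹ — no canonical value exists, so it is exposed as configuration)
across a candidate interval at one-band stride and picks the window with
the lowest mean first-derivative variance. The criterion is the
*derivative* variance, not the raw variance, for the same high-pass
reason as above. `qc_spike_check()` then flags bands whose derivative
variance exceeds `factor` (default 5, also configuration) times the
region median — narrow-band contaminants that should prompt inspection.
Note that a contaminant confined to a single band is flagged at the
neighbouring bands inside the filter window, because the central
coefficient of an SG first derivative is zero; the flags localise the
contaminant to within one window either way.

## Patch-wise and streaming operation

Each denoised spectrum depends only on its own input row, so a fitted
model can be applied to any subset of pixels in any order. The
operational rule for patch-wise work is: estimate the noise covariance
**once**, then either

* apply one global model to every patch (`signal_mode = "global"`), or
* refit the signal eigendecomposition inside each patch with the same
  static noise covariance (`signal_mode = "per_patch"`), the
  memory-bounded mode.

Noise is never re-estimated per patch: that reintroduces
composition-dependent variation, and the package exposes it only as an
explicitly labelled anti-pattern flag (`refit_noise_per_patch`) so the
degradation can be demonstrated (smaller patches, larger deviation from
the clean truth — tested on phantoms).

A subtle numerical point: optimised BLAS matrix multiplication chooses
kernels by matrix shape, so "denoise a patch" and "denoise the whole
image, then slice" do not agree bitwise if both use plain `%*%`. All
denoising paths therefore share a projection kernel whose arithmetic per
row is independent of batch shape, making the guarantees *global
patch-wise output $\equiv$ whole-image output* and *streamed output
$\equiv$ in-memory output* exact (`identical()`), not approximate.
`stream_denoise()` reads, denoises and writes one patch at a time over
pixel-interleaved ENVI files, keeps at most one patch resident,
checkpoints after each patch, and resumes after interruption. A float32
output mode halves storage at ~$10^{-7}$ relative error.

Edge patches are remainders — there is no overlap, reflection or
blending. The global noise model is what prevents seams, and stitching
artifice would mask exactly the effect under study. When a global-model
fit would exceed `fit_sample` spectra (default 50 000) it is fitted on a
uniform random pixel subset under a fixed seed.

## The phantom generator

`make_phantom()` emulates a QCL-style acquisition of heterogeneous
tissue: axis 952–1800 cm⁻¹ at 2 cm⁻¹ (425 bands), four classes
(stroma-like, epithelium-like, blood-like, background) whose spectra are
sums of Gaussian absorbance bands — Amide I at 1656 cm⁻¹ and Amide II at
1546 cm⁻¹ with per-class peak ratios of roughly 1.25, 1.67 and 2.2 so
ratio-preservation metrics have spread — plus fingerprint bands, on
stripe, blob or concentric-core layouts. The 1750–1800 cm⁻¹ interval is
kept chemically empty by construction (band centres must sit at least
three widths away), so silent-region estimation is honest.

Noise is injected in the **transmittance** domain:
$T' = 10^{-A} + \varepsilon$, $\varepsilon \sim N(0, \sigma_T^2)$ iid,
$A' = -\log_{10}\max(T', 10^{-6})$. This is the load-bearing design
choice: the inverse-square law the estimator assumes then *emerges* from
the logarithm, instead of being baked into absorbance directly — the
generator tests the estimator against the physics, not against itself.
The default $\sigma_T = 0.005$ is a choice, not a measured instrument
constant (none is published for this setting); it puts the silent-region
SNR in the 10–50 range where denoising is visibly nontrivial, and keeps
$\sigma_T \ll T$ at the strongest bands (peak absorbance ≈ 1.2,
$T \approx 0.06$) so the delta-method linearisation used in the
parameter-recovery tests holds.

`add_correlated_noise()` adds per-pixel random-slope baselines and
random-phase sinusoidal fringes — spectrally *correlated* noise that a
diagonal covariance cannot represent. This is the documented failure
mode: with severe fringing on well-ordered data the dense
adjacent-difference model captures the correlation and wins (tested,
direction only). What the generator does **not** emulate: Mie/resonant
scattering distortions, atmospheric vapour lines, detector nonlinearity,
instrument line-shape effects, spatial noise correlation. Passing tests
on phantoms therefore demonstrate correctness of the algorithms under
the stated noise model, not performance on any particular instrument's
artefacts.

## Numerical choices

* **Eigenvector signs** are fixed by flipping each vector so its
  largest-magnitude entry is positive; factor images and regression
  tests are then reproducible. Eigenvalue ties below $10^{-12}$
  separation keep SVD output order and are the one documented source of
  nondeterminism.
* **Degenerate inputs**: transmittance clamp $10^{-6}$; profile floor
  $10^{-12}$; zero spectra are an error in `vector_normalise()` and
  `adjacent_cosine()` naming the offending pixel; singular dense
  covariances are an error in `whiten()` (naming the eigenvalue index)
  and a warned rank reduction in `mnf()`.
* **Interval conventions** are closed on both ends in wavenumber space
  (so truncation to 1000–1800 cm⁻¹ of a 2 cm⁻¹ axis keeps 401 bands, and
  removing 1360–1490 cm⁻¹ drops 66); all user-facing band selection is
  by wavenumber, never index.
* **Linear baseline** is endpoint-anchored (the minimal reading of
  "linear baseline subtraction"); an ordinary least-squares line is
  available via `method = "lsq"`.
* **$R^2$** for ratio preservation is the squared Pearson correlation:
  the comparison is between denoised and raw ratios, where a
  fit-to-identity definition would conflate scale bias with noise; the
  identity-line definition is available via `identity_line = TRUE`.
* **Second-derivative preprocessing** defaults to window 19, order 4;
  the iMNF base-variance derivative defaults to window 5, order 2, and a
  sweep over windows 5–11 and orders 2–4 changes the denoised output by
  less than 0.001 in mean spectral cosine (tested).

## Problem sizes

The test suite and the acceptance script run entirely on phantoms built
at run time: $16^2$–$24^2$ pixels for algebraic property checks,
$64\times64\times425$ for the end-to-end spatial-invariance check,
$50\times50$ for the ratio-preservation comparison (500-pixel
unstructured patches), and $100\times100$ ($10^4$ spectra) for
Monte-Carlo parameter recovery. These sizes were chosen so the full
suite completes in well under a minute on one core while keeping
Monte-Carlo error comfortably inside the stated tolerances.

## Known limitations

* The diagonal covariance deliberately ignores inter-band noise
  correlation; under strong fringing or drift on ordered data the dense
  adjacent-difference model can denoise better. The trade-off is
  spatial invariance, and it is the point of the method.
* The inverse-square transmittance scaling is a first-order model of
  signal-dependent noise; detector-regime changes across the spectrum
  are not modelled.
* No scatter (EMSC/RMieS) or atmospheric correction is included; those
  belong upstream of this pipeline.
* ENVI and CSV are the interchange formats; proprietary instrument
  formats are assumed converted upstream.
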