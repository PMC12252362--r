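---
title: "Wavelet-based detection and quantification of weak fluorescence bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based detection and quantification of weak fluorescence bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flfaquant)
```

## The problem

Fluorescence lateral-flow assays (FLFA) read out analyte concentration from
the brightness of capture lines (or printed spots) on a test strip, imaged
with a CMOS/CCD camera. Readers that drop the emission filter collect far
more light — valuable near the detection limit — but pay for it with an
elevated, spatially varying stray-light background on which weak bands are
barely visible. `flfaquant` implements the image-analysis side of such a
filter-free reader: finding low-contrast fluorescent bands, delimiting them,
and turning them into a quantitative signal that calibrates against analyte
concentration.

## The method

**Projection.** A strip image `f(x, y)` (row `y`, column `x`; the column
axis runs along the strip, crossing the test/control lines) is collapsed
into a 1D profile by summing gray values: `Y_j = sum_i y_ij`. Sums are used
rather than means; every later threshold is positional, so the scale of the
curve is irrelevant, and integer input stays exact
(`project_profile()`).

**Wavelet transform.** The profile is convolved with Mexican Hat (Ricker)
kernels `psi(t) = (1 - t^2/sigma^2) exp(-t^2 / 2 sigma^2)` at scales 30-37,
each normalized by `1/sqrt(s)`, and the per-scale responses are averaged
(`cwt()`). The Mexican Hat has no positive side lobes, so it cannot
manufacture spurious positive peaks next to a real one, and its zero mean
suppresses the background while amplifying band-shaped structure. Scale `s`
is identified with the `sigma` of the kernel formula; the 128-sample kernel
support is configurable.

**Peak seeking.** On the transformed curve a symmetric first derivative
`W'_j = (W_{j+n} - W_{j-n}) / (2n + 1)` is computed (default `n = 2`;
the unconventional `2n + 1` denominator is kept as a faithful reproduction —
zero-crossing *positions*, the only thing used downstream, do not depend on
it). Apexes are positive-to-negative derivative zero crossings; the nearest
negative-to-positive crossings on each side delimit the peak, with the curve
ends as fallback troughs. The baseline is the mean of the reference-curve
values at the two troughs, `baseval = (Y(j_left) + Y(j_right)) / 2`, and a
peak is *valid* only if its trough separation exceeds `mu = 32` samples —
the guard against narrow spikes (`find_peaks()`, `delimit_peak()`).

**Region extraction.** Valid peaks on the X projection give column slabs;
each slab is projected in Y. No valid Y peak means the slab holds a
full-height strip band; valid Y peaks split it into one spot ROI each
(dot-matrix format) (`extract_rois()`).

**Per-scan-line quantification.** Each ROI is scanned row by row with the
same wavelet peak locator; row `y` contributes its trough-delimited,
baseline-subtracted area, and the statistic is the average background-free
gray value per pixel:

```
avePix = sum_y sum_{x = dp_l(y)}^{dp_r(y)} (f(x, y) - baseval_y)
         / sum_y (dp_r(y) - dp_l(y))
```

over rows where a valid peak was found (`quantify_roi()`). Rows without a
valid peak are excluded from numerator *and* denominator: spreading
ROI-wide boundaries over undetected rows would dilute exactly the weak
signals the method exists for. `avePix / max_gray` is also reported as a
0-1 relative fluorescence intensity.

**Calibration.** Mean `avePix` per concentration is fit with the
four-parameter logistic `y = D + (A - D) / (1 + (x/C)^B)` (`fit_4pl()`,
Levenberg-Marquardt via `minpack.lm`, log-C parameterization so the
inflection concentration stays positive); `invert_4pl()` is the closed-form
inverse. Sandwich (increasing) and competitive (decreasing) assays differ
only in curve orientation, which the A/D-swap-with-negated-B symmetry
absorbs.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `scales` | 30:37 | samples | band half-widths the transform is matched to; optimal for bands of width sigma ~ 21-26 px |
| `support_len` | 128 | samples | discrete kernel length; truncates the Ricker at ~2.1 scale units |
| `aggregate` | mean | — | averaging across scales stabilizes the response; `max` and `single_scale` are available for sensitivity analysis |
| `boundary` | reflect | — | mirror extension avoids the edge steps zero-padding creates on bright backgrounds |
| `n` | 2 | samples | derivative half-width; smooths single-sample jitter |
| `mu` | 32 | samples | minimum trough separation of a real band |
| `min_snr` | 4 | — | minimum ratio of apex prominence (and apex value) to the estimated noise sd of the detection curve |
| `min_prominence` | 0 | curve units | absolute floor, disabled by default |
| `exclude_boundary` | TRUE | — | drop apexes inside the boundary cone of influence |

## Numerical choices

*Kernel balancing.* At scales 30-37 with a 128-sample support the truncated
Ricker samples sum to a substantially non-zero value, which would leak the
(huge) projection baseline into the detection curve. Subtracting the kernel
mean restores the zero sum but acts as a boxcar filter whose sharp window
edges create rebound bumps at half a support from a strong band. The kernels
are instead balanced by subtracting a scaled copy of their own Gaussian
envelope: exactly zero sum, smooth correction, no window artifacts.
`mexican_hat()` itself returns the raw closed-form samples; balancing
happens inside `cwt()`.

*Validity of a peak.* The trough-separation rule alone cannot reject smooth
noise: noise filtered at scale `s` undulates with trough separations of
order `2 sqrt(3) s ~ 100`, far above `mu`. A valid peak must therefore also
clear a noise-scaled amplitude test, as CWT peak pickers conventionally
require: both its topographic prominence (height above the *higher*
flanking trough) and its apex value must exceed `min_snr` times the
estimated noise sd of the detection curve. Using the higher trough — and
testing the apex value itself — prevents flat stretches next to a deep side
lobe of a strong band from inheriting a large prominence. The noise sd is
estimated robustly from the raw input curve (median absolute deviation of
first differences divided by `sqrt(2)`) and propagated through the exact L2
norm of the aggregated kernel; for integer-valued sources a quantization
floor of `sqrt(n_summed / 12)` is imposed, because a deterministic rounding
staircase is invisible to the difference-based estimate. With `min_snr = 4`
a blank, noise-only strip yields no valid peak at the defaults.

*Boundary cone of influence.* Within half a kernel support of either curve
end the coefficients mix data with its mirror image; a sloped stray-light
background then produces a kink response. Apexes in that zone are discarded
during ROI extraction (not during scan-line quantification, where the ROI
is already a selected region and its edges legitimately serve as fallback
troughs). Consequently bands — and especially dot-matrix spots along the
short axis — must sit at least half a support (64 samples at the defaults)
inside the image to be detectable. This is a genuine property of the
method, not of the implementation.

*Scan-line scale.* Quantifying a narrow band with the detection scales
would be wrong: the response minima of a Ricker at scale `s` applied to a
Gaussian band of width `sigma_b` sit at `+/- sqrt(3) sqrt(s^2 + sigma_b^2)`,
which for `s >> sigma_b` is kernel width, not band width. `quantify_roi()`
therefore estimates the band width from the ROI's own background-subtracted
X projection (iterative truncated second moments with the truncated-Gaussian
variance correction) and scans rows at the matched scale
`s = sqrt(2) sigma_hat`, for which the minima land at `+/- 3 sigma_hat` —
the band's effective support, and the window over which the generator's
analytic ground truth is defined. The scan window is the ROI expanded to
`center +/- (3 sigma_hat + 4 s)` so the kernel sitting at a trough never
reaches the window's own mirrored extension, and the kernel is never longer
than the window (it would otherwise see tiled reflections of the band and
drag the troughs to the window edges). `row_scales` overrides the matched
scale.

*Curve length.* Boundary extension is a tiled reflection, valid for any
curve of length >= 8; scan lines are routinely shorter than the 128-sample
detection support and must still transform.

*Ties.* A flat apex plateau reports its center sample, left-biased for even
plateaus.

*4PL degeneracies.* Fewer than four distinct doses, non-positive doses and
non-finite signals are rejected up front; non-convergence raises a classed
processing error carrying the starting values.

## The synthetic generator

No public image data exist for this instrument class, so `scene_spec()` /
`simulate_scene()` render the imaging regime the method targets: a dark
strip with a smooth stray-light gradient (default base 40 gray, ~15 gray
rise across a 600-px strip), 1-3 full-height transverse Gaussian bands
(width sigma 18-28 px, matching the detection scales via
`s ~ sqrt(2) sigma_b`), or a grid of 2D Gaussian spots; additive Gaussian
sensor noise (default sd 2 gray on 8-bit) and optional saturated impulse
("salt") pixels; quantization to 8 or 16 bits. Everything is deterministic
given the spec's seed, and each scene carries analytic ground truth: band
centers, 3-sigma boundaries, per-row integrals and the closed-form `avePix`
over the 3-sigma window, `amplitude * sqrt(2 pi) * erf(3/sqrt(2)) / 6`.

`weak_signal_suite()` reproduces the evaluation design used throughout the
package: 50 random scene geometries x 5 noise replicates with band peak
contrast drawn from 2-4x the noise sd (weak-signal regime — bands at the
edge of visibility), or 6x contrast with doubled noise and 0.5% impulses
(noise-robustness regime). `run_eval()` scores an image as correct when
every true band is matched within 5 px by a valid detection and nothing
spurious is reported.

What the generator deliberately does *not* emulate: optics (PSF, vignetting,
color-filter demosaicing), Poisson shot noise, strip rotation or skew (the
instrument class uses a fixed strip chamber), membrane texture, and
non-Gaussian band profiles (a flat-top profile can be approximated by
raising `sigma` but is not modeled). Passing the synthetic suites therefore
demonstrates the algorithm's statistical behavior under the stated noise
model, not end-to-end instrument performance.

For spot ground truth, note that the analytic `ave_pix` is the mean over
the full 3-sigma box, while the scanner averages only rows with a valid
peak — which weights the bright central rows; the two agree for full-height
bands but differ by construction for spots.

## Problem sizes and runtime

The bundled checks run at desk scale on one CPU: two 250-image accuracy
suites (~15 s each), a 100-curve convolution-oracle comparison, and a
monotonicity study of 100 replicates x 5 amplitudes on 120 x 320 strips
(~40 s). The whole test suite completes in about a minute.

## Known limitations

- Bands or spots closer than half a kernel support to the image edge fall
  in the cone of influence and are not detected at the default scales.
- On *exactly* noise-free synthetic gradients, quantization staircases can
  align across an entire slab and momentarily imitate spot structure in the
  Y projection (real sensors always carry >= 1 LSB of noise, which breaks
  the alignment); the strip/dot decision is most reliable at realistic
  noise levels, and a `mode` hint can force either interpretation.
- Two bands closer than roughly one kernel support merge into a single slab.
- `avePix` of spots is detection-weighted (see above).
- The four-parameter logistic assumes a monotone dose-response; hook-effect
  regimes are out of scope.
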