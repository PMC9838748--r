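---
title: "Methods: spectral and texture characterization of tattoo dyes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral and texture characterization of tattoo dyes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyespec)
```

## The problem

Laser removal of tattoos and permanent makeup relies on selective
photothermolysis: the treatment wavelength should be strongly absorbed by
the dye and weakly by the surrounding tissue. Under the usual working
assumption that absorption is inversely related to reflectance (with
little transmission through a thin dried smear), two in-vitro quantities
guide wavelength selection for a given pigment:

* the **wavelength of maximum reflectance** and the **height of that
  maximum**, measured from a calibrated hyperspectral cube
  (400–1000 nm) — a low overall reflectance (e.g. black pigments) marks a
  dye that will absorb laser energy efficiently, and the spectral peak
  marks wavelengths to avoid;
* the **spatial homogeneity** of the dried smear in visible light — a
  heterogeneous pigment (a mixture) can respond unevenly to treatment.

`dyespec` implements both measurements as a tested pipeline, plus the
synthetic-scene generators needed to exercise it, because the original
study imagery is not publicly deposited.

## Stage 1: hyperspectral calibration and peak extraction

### Acquisition model

A cube is a raster $I(m, n, \lambda_k)$ of digital numbers (DN) on a
12-bit scale, with 128 bands whose default centers are
$\lambda_k = 400 + k \cdot 600/128$ nm, $k = 0..127$ (spacing
4.6875 nm, quoted as 4.69 nm by the camera vendor). The published band
labels of the reference instrument cannot be reconciled exactly with a
uniform grid starting at 400 nm, so the grid is configuration: an
explicit band-center list in an ENVI header always overrides the
default.

Cubes are exchanged as ENVI header + band-sequential (BSQ) little-endian
binary. Values are stored as 64-bit doubles so that a write/read round
trip is the identity bit for bit, for raw DN and reflectance cubes
alike; 8/16-bit integer and 32-bit float cubes from other sources are
accepted on read.

### Gray-panel calibration

Every scene contains a fragment of a reference panel with known,
spectrally flat reflectance $\rho_p = 0.18$. Calibration flat-fields each
band against the panel:

$$\hat\rho(m,n,k) = \rho_p \,
  \frac{\mathrm{DN}(m,n,k)}{\overline{\mathrm{DN}}_{\text{panel}}(k)}$$

The illumination spectrum and the radiometric gain cancel in the ratio,
so calibrated reflectance is invariant to rescaling either — a property
the test suite checks to 1e-9 by generating the same scene at two gains.
The per-band panel statistic is the arithmetic mean by default (a median
is available for blemished panels). A panel mean at or near zero in any
band aborts with the band named; calibrating an already-calibrated cube
is likewise an error.

### ROI mean and parabolic peak refinement

The dye spectrum is the per-band arithmetic mean over the dye ROI — the
whole dye surface is aggregated *before* peak extraction, so the
reported maximum is that of the mean spectrum, not the maximum over
pixels. The band of maximum reflectance is found by argmax with ties
broken toward the lowest band (deterministic reporting); when the argmax
is interior, the peak is refined by the vertex of the parabola through
$(\lambda, \bar\rho)$ at bands $k-1, k, k+1$. The refinement is needed
because peaks are conventionally reported to integer nanometers from
~4.7 nm-spaced samples. The three-point vertex is exact for a quadratic,
is unmoved by any constant baseline, and for a Gaussian peak of
$\sigma \ge 30$ nm on this grid its residual bias is below 0.01 nm in
position and $2\times10^{-5}$ relative in height — comfortably inside
the 0.5 nm / 0.5 r.u. recovery tolerance the tests assert. At a grid
edge, or when the three points are not strictly concave, the raw band
maximum is reported unrefined and flagged.

### Relative units

Spectra are reported in the study's "relative units". The unit is never
defined there; this package fixes **1 r.u. = 1e-4 absolute reflectance**
(so the 18% panel sits at 1800 r.u.), which keeps all seven reported
maxima (85–3222 r.u.) below reflectance 1. The scale is a
`calibration_config()` parameter, not a constant.

## Stage 2: visible-light texture metrics

Photographs of dried smears are reduced to gray by the truncating
integer mean $\lfloor (R+G+B)/3 \rfloor$ — deliberately not the
luminance-weighted conversion, so every gray level is exactly
reproducible integer arithmetic — then min–max normalized to span 0–255
(`round` half away from zero; a constant image has no defined stretch
and is an error).

The gray-level co-occurrence matrix (GLCM) counts ordered pairs of each
pixel with its **right-hand neighbour in the same row** (offset (0, +1),
256 levels, no symmetrization — the metrics depend only on $|i-j|$, so
symmetrizing would change nothing, and the ordered counts are kept for
fidelity). From the normalized matrix $p(i,j)$:

$$\text{contrast} = \sum_{i,j} p(i,j)\,(i-j)^2, \qquad
  \text{homogeneity} = \sum_{i,j} \frac{p(i,j)}{1 + |i-j|}$$

The homogeneity definition follows the study's formula with the absolute
value made explicit (without it the sum is not bounded by 1); the
contrast formula is the standard co-occurrence contrast, which the study
uses but does not write out — the printed example values are consistent
with it exactly. Homogeneity is 1 iff all mass is diagonal, which is
also the only case with contrast 0. When a region-of-interest mask is
supplied, pairs are enumerated within ROI row runs and no pair spans a
masked-out pixel. Reporting convention: contrast to 3 decimals,
homogeneity to 4.

Across dyes, contrast and homogeneity are anticorrelated (both are
monotone functionals of the neighbour-difference distribution, in
opposite directions); the cross-dye Pearson correlation is computed by
`pearson()`, which rejects constant inputs rather than returning `NA`.

## The synthetic generators

### Hyperspectral scenes

`generate_dye_cube()` renders the forward model
$\mathrm{DN} = g\, s(k)\, \rho(k) + \varepsilon$ with a per-dye Gaussian
reflectance model

$$\rho(\lambda) = 10^{-4}\left(b + A
  \exp\!\left(-\frac{(\lambda - \mu)^2}{2\sigma^2}\right)\right)$$

on a neutral slide background (reflectance 0.05) with an 18% panel
rectangle. The single-Gaussian-on-flat-baseline shape is the simplest
model consistent with the single broad visible peak the study's spectra
show; it is configuration, not a claim about pigment chemistry. The
packaged seven-dye library encodes the study's printed values verbatim
(red peak 634 nm / 751 r.u., brown peak 732 nm, dark pink 1304 r.u.,
black 85 r.u., white 3222 r.u.); the unprinted peaks and amplitudes are
fixed documented defaults chosen inside the reported 634–732 nm range
and ordered by the reported ease-of-removal ranking reversed. Baselines
default to 0 r.u. so that `amplitude` *is* the spectrum maximum; width
defaults to $\sigma = 40$ nm, comfortably above the 30 nm floor of the
refinement-bias bound. Defaults elsewhere: flat unit illumination
spectrum, gain 4000 DN per unit radiance (a reflectance-1 target stays
inside the 12-bit range), `noise_sd = 0`. Noise is additive Gaussian DN
noise from a single seeded stream per cube; the real sensor's noise is
uncharacterized, so 0 is the reference condition and positive values are
for robustness experiments only. DN are kept real-valued (quantizing to
integers would put a quantization floor under the ground-truth
round-trip checks); a DN that would exceed 4095 raises a saturation
error rather than clipping silently, while sub-zero noise excursions
clip to 0.

What passing these tests shows — and does not. The generator emulates
flat illumination, a uniform panel, and i.i.d. Gaussian noise. Real
acquisitions add spatially structured illumination, panel
non-uniformity, specular glints, chromatic focus shift and sensor
nonlinearity, none of which are modelled; noiseless parameter recovery
here validates the *pipeline arithmetic*, not the instrument.

### Exact-histogram textures

Both texture metrics depend on an image only through its multiset of
absolute horizontal neighbour differences $d = |g_{r,c} - g_{r,c+1}|$.
`generate_texture_image()` therefore takes a difference histogram as the
specification and constructs a `rows × cols` image realizing it
*exactly*: the first row is constant 255 (pinning the upper extreme and
consuming `cols − 1` zero-difference pairs), and each remaining row
draws `cols − 1` differences from the pool, sorts them descending and
lays them out as a zigzag walk from 0 (alternately adding and
subtracting). With non-increasing step magnitudes the walk is confined
to $[0, d_{\max}] \subseteq [0, 255]$ for **any** difference multiset,
every such row touches 0, and row boundaries contribute no pairs — so
feasibility reduces to two checkable conditions (pair budget matches
`rows · (cols − 1)`; at least `cols − 1` zeros for the pin row) and the
histogram is reproduced with zero discrepancy. Because 0 and 255 are
always attained, min–max normalization is the identity on generated
images and the downstream metrics are exact rational numbers known in
advance.

The packaged suite encodes the study's two printed worked examples
exactly — dark pink `{d=0: 45192, d=2: 38275, d=3: 16533}` over 100,000
pairs (contrast 301897/100000 = 3.019, homogeneity 0.620836 → 0.6208)
and white `{d=0: 1990175, d=1: 9300, d=2: 525}` over 2,000,000 pairs
(contrast 0.0057, homogeneity 0.9975 exactly) — plus five documented
synthetic histograms for the dyes whose values are only published as bar
charts. Those five are stand-ins: their absolute metric values carry no
information about the real pigments, only the suite-level property that
contrast rises as homogeneity falls. The study's cross-dye correlation
of −0.8835 depends on the undeposited imagery and is *not* a
reproduction target; only the sign of the correlation is asserted.

## Problem sizes and numerical choices

The reference scene is 48 × 64 pixels × 128 bands (1024-pixel dye ROI,
512-pixel panel), which makes a full seven-dye run — simulate, ENVI
round trip, calibrate, extract, texture suite — complete in seconds
while leaving every quantity at its asymptotic value (the pipeline is
exact at `noise_sd = 0`, so larger scenes change nothing but runtime).
Variance-reduction and degradation properties are checked on smaller
grids (16–24 bands) with 200 replicate seeds. Ties at equal spectrum
maxima break toward the lowest wavelength; comparisons against
brute-force pair enumeration are asserted to 1e-12; calibration
invariances to 1e-9.

## Known limitations

* The spectral model is phenomenological; it cannot say anything about
  pigment chemistry, layered skin optics or laser–tissue interaction.
* The ENVI dialect is deliberately narrow: BSQ, little-endian, one data
  file + `.hdr`. BIL/BIP interleaves are rejected, not converted.
* The gray conversion follows the study's truncating mean; images
  converted with standard luminance weights will give slightly
  different metrics.
* `pearson()` over seven dyes is descriptive, not inferential — no
  confidence intervals are attached, matching the original analysis.
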