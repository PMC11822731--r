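---
title: "Evaporated volume analysis: models, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaporated volume analysis: models, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evacount)
```

## The measurement

Evaporated volume analysis (EVA) turns nanoparticle counting into an
absolute concentration measurement. A droplet of volume $V$ (a few µL) of a
dispersion diluted $D$-fold from its stock is deposited on glass and dried;
every particle it contained now sits on the substrate. A microscope scans
the deposit as an overlapping grid of frames, every diffraction-limited spot
is localized and counted, and the stock number concentration follows from

$$C = \frac{N \, D}{V},$$

with $N$ the total count over all analysed droplets and $V$ their total
volume in mL. Because the estimate is a ratio of three measured quantities,
the uncertainty budget has exactly three relative components — counting,
volume, and dilution — combined in quadrature, and the combined standard
uncertainty converts to a 95 % coverage interval with $k = 1.96$.

`evacount` implements the full chain: a ground-truthed synthetic micrograph
generator, radial-distortion calibration, correlation-based stitching with a
global layout solve, matched-filter spot detection with subpixel Gaussian
fitting, nearest-neighbour statistics against complete spatial randomness
(CSR), and the counting metrology (limits, working range, dilution-series
linearity).

## Image formation model (synthetic data)

The generator emulates a dried droplet of radius $R$ (default 1.5 mm)
imaged as a 6 × 6 grid of 1024 px frames, 674 µm × 674 µm at
0.658 µm/px, on 500 µm stage steps, so adjacent frames overlap by 174 µm.
The frame geometry and the spot width are instrument facts; the pixel
count of the sensor is a free choice and both are configurable.

* **Particle placement.** The particle count is Poisson with mean
  $C_\mathrm{drop} V$; under the `csr` model positions are uniform on the
  droplet disk. This is the pattern a well-dispersed, non-aggregating sample
  should leave, and it is exactly the null hypothesis the downstream spatial
  test checks. An `edge_ring` model (density concentrated in a Gaussian
  annulus at 0.9 R, width 0.06 R) serves purely as a negative control for
  that test — a coffee-ring caricature, with invented parameters.
* **Optics.** Each particle renders as a *pixel-integrated* symmetric 2-D
  Gaussian of FWHM 1.8 px, scaled to its intensity. Diffraction-limited
  spots have an Airy profile; the Gaussian is the standard surrogate and the
  only width the instrument reports is the FWHM.
* **Brightness.** Single-particle intensities are lognormal
  (median 8000 counts, $\sigma_{\log} = 0.25$) — a single-mode distribution,
  matching an aggregate-free dispersion. An optional aggregate fraction
  doubles the intensity of flagged particles, giving the second histogram
  mode the aggregate screen looks for.
* **Camera.** Constant offset (100 counts), optional Poisson shot noise on
  signal + offset, Gaussian read noise (10 counts), quantization to 16 bits
  with saturation. The real camera's bit depth, gain, and QE are unknown;
  these defaults are placeholders chosen so that a median particle has
  SNR ≈ 200 — upconversion imaging is nearly background-free, which is the
  regime the method is designed for.
* **Stage and lens.** Per-tile stage jitter (SD 2 µm) displaces each frame
  from its nominal grid position; optional radial distortion
  ($r' = r(1 + k_1 r^2 + k_2 r^4)$ about the frame centre) displaces spots
  as a pincushion lens would.
* **Randomness.** One seed is split into independent substreams (count,
  positions, intensities, aggregates, jitter, per-tile pixel noise), so
  disabling noise never shifts particle positions, and identical spec + seed
  reproduce tiles bit for bit.

What the generator does **not** emulate: evaporation physics and gel
mechanics, wavelength-dependent optics, 3-D defocus, flat-field variation,
or spatially correlated background. Passing the synthetic validation
therefore demonstrates the correctness of the *analysis* under the stated
imaging model, not robustness to every real-world artefact.

## Distortion calibration

The two-coefficient radial model is fitted to dot-grid correspondences by
Levenberg–Marquardt with the centre fitted jointly. Two coefficients
suffice for a distortion described as small and pincushion-only; tangential
terms are deliberately omitted. Points are corrected by fixed-point
inversion of the radial polynomial (converges in a handful of iterations
for $|k_1| r_\max^2 \le 0.05$; round-trip error < 0.05 px), images by
inverse-mapped bilinear resampling. Both routes agree on detected centroids
to 0.1 px, so the cheap point-space correction can replace image resampling
in bulk processing.

## Stitching

Pair offsets between adjacent tiles come from normalized cross-correlation
of the nominal overlap, searched over ±14 px (covering > 3 SD of the
relative jitter of two tiles at the 2 µm stage jitter the generator
assumes) and refined to subpixel by a quadratic fit to the correlation
peak. The global layout minimises the confidence-weighted squared
inconsistency of all pair offsets on the grid graph — not a spanning tree —
with the top-left tile as gauge anchor pinned to its nominal position;
pairs whose confidence falls below 0.3 are demoted to their nominal offsets
at a small weight so the system always stays connected. An empty overlap is
thus a flagged degradation, never a failure.

Counting is always per tile followed by deduplication in global
coordinates (radius 2 px ≈ 1.3 µm, the spot-FWHM scale; brightest
detection wins, same-tile detections are never merged). The stitched mosaic
image itself is never counted; it exists for human inspection only.

## Detection

The classical path is a matched filter (Gaussian kernel,
$\sigma = \mathrm{FWHM}/2.3548$) over a robust background estimate
(median + MAD), local maxima above background + 5 filtered-noise SDs,
non-maximum suppression at 2 px, then a damped Gauss–Newton fit of a
**pixel-integrated** Gaussian plus constant per candidate. Fitting the
integrated model rather than a sampled Gaussian matters at these widths:
pixel integration inflates an apparent sampled-Gaussian width by
$\sqrt{\sigma^2 + 1/12}/\sigma \approx 7\,\%$ at FWHM 1.8 px, which would
break the width recovery the validation demands. The threshold of 5 SDs
keeps the expectation of false maxima per 1024² frame well below one.
Non-converged fits fall back to centre-of-mass plus aperture sum and are
flagged. The neural segmentation path is exposed as an interface only; no
deep-learning backend ships with the package, and the classical detector is
the reference implementation of the same task.

Aggregate screening uses the intensity histogram with $\sqrt{N}$ counting
errors: a second mode is reported only when it rises above the deepest
valley separating it from a higher mode by more than $3\sqrt{\text{valley}}$
— the same Poisson significance logic as the error bars. The per-spot flag
(intensity > 1.6 × the population median) tags probable doublets.

## Spatial randomness

For a homogeneous Poisson pattern of density $\rho$ the nearest-neighbour
distance CDF is $F(r) = 1 - e^{-\rho \pi r^2}$. The test estimates
$\rho = n/A$ (convex-hull area by default, or the configured droplet disk),
computes the Kolmogorov–Smirnov statistic of the empirical NN-distance CDF
against $F$, and obtains its p-value by parametric bootstrap — resimulating
CSR patterns of the same size on a disk of equal area and re-estimating
$\rho$ each time — because the classical KS tables are invalid when the
parameter is estimated from the data. No analytic edge correction is
applied; an optional guard buffer exists (default 0). At the densities of
interest ($\rho \gtrsim 10^{-3}\,\mu m^{-2}$, $n > 1000$) the edge bias is
well below the KS noise floor, and because the bootstrap replicates carry
the same bias, the p-value stays calibrated regardless (verified: the
false-positive rate at $\alpha = 0.05$ over 200 synthetic droplets falls in
[0.03, 0.08]). NN distances use a uniform-grid index with ring expansion
that provably returns the exact all-pairs answer.

## Counting metrology

* **Counting uncertainty.** With $n \ge 3$ droplets the between-droplet
  scatter $\mathrm{sd}(N)/(\bar N \sqrt n)$ is used — it captures real
  droplet-to-droplet variation beyond Poisson noise; with fewer droplets
  the Poisson bound $\sqrt{\Sigma N}/\Sigma N$ applies.
* **Limits.** The detection limit asks for at least one particle in the
  whole evaporated volume with 99 % probability:
  $\lambda_{LOD} = -\ln(0.01) = 4.6$ particles. The quantification limit
  pins Poisson noise at 10 %: $N_{LOQ} = 1/0.1^2 = 100$ particles. Both
  convert to concentrations by $D/V_\mathrm{total}$.
* **Working range.** The lower end keeps counting noise at a target
  $u$ ($N \ge 1/u^2$); the upper end limits the undercount from spot
  merging. A pair closer than $r_{\min}$ (default 1.2 µm, the FWHM in
  object space) merges and loses one of its two members, so the expected
  undercount fraction at surface density $\rho$ is
  $\tfrac12 (1 - e^{-\rho \pi r_{\min}^2})$, and the admissible density
  solves this equal to $u$ in closed form:
  $\rho_{\max} = -\ln(1 - 2u)/(\pi r_{\min}^2)$.
* **Dilution series.** The proportional fit $y = kx$ uses constant
  *relative* variance (weights $1/x^2$, i.e. $k = \overline{y/x}$): over a
  series spanning decades this is the error structure counting actually
  produces, and it is what a zero-intercept fit viewed on the log–log scale
  implies. An unweighted linear-scale fit would let the top point set the
  slope unilaterally and mask its own overlap suppression. $R^2$ is still
  reported on the linear scale. Points deviating below $-3u$ are flagged
  as overlap-suppressed, automating the by-eye exclusion of
  overlap-affected concentrations.

## Validation design and problem sizes

All validation is synthetic and self-contained; every number below is
computed by the test suite or `scripts/acceptance.R` at run time.

The central check is end-to-end interval calibration: seven droplets at a
known concentration are generated, imaged, detected, counted and
quantified, and the fraction of 500 replicate measurements whose 95 %
interval covers the truth must sit in [0.93, 0.97]. The replicate scale was
chosen — before any pipeline code ran, from an estimator-level
simulation — to mirror the uncertainty *composition* of a real measurement
rather than its raw size: ~400 particles per droplet in a single
1160 px frame (droplet radius 371 µm), volume uncertainty 2.5 % shared
across droplets, dilution 0.65 %. Two deliberate consequences: the counting
term ($\approx 1.9\,\%$) stays subdominant to the calibrated volume term,
as in practice, and the deposit density (≈ 4 × 10⁻⁴ px⁻²) keeps the
spot-merge undercount near 0.3 %, well inside the working range. Because
the counting component is estimated from only 7 droplets, a normal
$k = 1.96$ interval is expected to cover slightly under 95 % (about 94 %);
the acceptance band anticipates this. Shot noise is disabled (read noise
only) in these replicates — at spot SNR ≳ 100 it does not change a count —
which keeps the 500 replicates near ten minutes on one CPU.

Other problem sizes: stitching is validated on the full-scale 6 × 6,
1024 px mosaic at ~4400 particles with 2 µm jitter (layout error < 0.5 px,
gauge removed); the CSR calibration uses 200 droplets of ~250 particles
with 400 bootstrap replicates each; NN distances are checked for exact
equality with an $O(n^2)$ oracle at $n = 2000$; the dilution series spans
three decades with two droplets per point.

## Numerical choices and degenerate inputs

Spot fits clamp $\sigma$ to [0.25 px, window] and fall back to
centre-of-mass when Gauss–Newton stalls; fits are initialised at the
matched-filter peak with the nominal width. Correlation peaks at the search
boundary refine to at most ±0.5 px. The fixed-point undistortion reports
the first non-converged point after 50 iterations. Zero-count droplets
yield a flagged one-sided Poisson upper bound instead of an interval.
Constant (featureless) overlap strips have undefined correlation and return
the nominal offset with confidence 0. Histogram plateaus count as a single
mode; an empty detection table gives an empty histogram with undefined
modality.

## Known limitations

Merged spots are counted as one (with a doubled-intensity signature) —
multi-emitter fitting is out of scope, and the working-range upper bound
exists precisely because of this; real coffee-ring deposits violate CSR and
are detected, not corrected; the gravimetric reference carries no
uncertainty model; the stitcher estimates translations only, which is
correct for stage grids but not for rotated or scaled acquisitions.
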