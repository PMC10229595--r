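---
title: "Distortion-compensated gigapixel mosaicking and virtual H&E rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distortion-compensated gigapixel mosaicking and virtual H&E rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gigamosaic)
```

## Scope

`gigamosaic` reimplements, hardware-free, the software core of a
two-channel nonlinear-microscopy digital-pathology pipeline: tiles acquired
with a resonant-scanned microscope over a motorized stage are corrected for
the scanner's cosinusoidal pixel spacing and the objective's radial
field-of-view (FOV) distortion, aligned into a gigapixel mosaic by a
σ-scored coarse-to-fine search around the stage estimate, rendered in
hematoxylin-and-eosin (H&E) colors from the THG (nuclei) and TPEF (stroma)
channels, and stored in an uncompressed large-image container. A synthetic
scan simulator supplies ground truth for every stage, so the whole pipeline
is testable without instrument data.

## The radial FOV-distortion model

A tile of C×R pixels (x = column, y = row, 0-based) is remapped through two
coordinate maps. With spatial scaling parameters $S_x = S_y = 60$ (fixed
throughout) and offsets $X_{off}, Y_{off}$, the distortion center is

$$c_1 = \tfrac{1}{2} C \left(1 + |X_{off}|/S_x\right), \qquad
  c_2 = \tfrac{1}{2} R \left(1 + |Y_{off}|/S_y\right).$$

For normalized coordinates $r_x = (x - c_1)/c_1$, $r_y = (y - c_2)/c_2$ and
radius $r_u = \sqrt{r_x^2 + r_y^2}$, the distorted radius under the angle
parameter $A$ (degrees) is

$$r_d = \frac{360}{A\pi}\,
        \tan^{-1}\!\left[2\,r_u \tan\frac{A\pi}{720}\right],$$

and the sampling maps scale the centered coordinates by $f = r_u/r_d$
(pincushion) or $r_d/r_u$ (barrel), $f \equiv 1$ at the center (a removable
singularity):

$$M_x = c_1\,[1 + r_x f], \qquad M_y = c_2\,[1 + r_y f].$$

`compensate()` resamples the tile at $(M_x, M_y)$ with bilinear
interpolation (border fill 0). A **negative** offset stores a flip: the
image is mirrored along that axis before remapping and mirrored back after,
which lets the same maps express distortion centers in all four quadrants.

**The forward model is the exact inverse.** `induce()` — used by the
simulator and by the self-consistency tests — applies the exact numerical
inverse of the compensation remap: the radial gather map
$g(r) = r\,f(r)$ is monotone and is inverted through a dense table. A
tempting shortcut, remapping with the opposite mode (pincushion↔barrel
swapped), is *not* the inverse: the scale factor is then evaluated at the
output rather than input radius, leaving a residual radial error of about
1% at $A = 51°$ — several pixels at the tile border, which is enough to
displace the parameter-estimation minimum away from the true triple. With
the exact inverse, `compensate(induce(img))` returns the image to within
bilinear-interpolation error (central-region MAE well under 2 intensity
levels on smooth images).

### Estimating the parameters

`estimate_params()` grid-searches $(A, X_{off}, Y_{off},\text{flip})$,
scoring each candidate by the mean absolute difference $d_k$ between the
two remapped tiles over their overlap region. Defaults bracket both
realistic operating points: $A \in [5°, 60°]$ and offsets $\in [0, 60]$ at
unit steps with all four flip variants, scanned coarse-to-fine (step ×5,
then unit steps around the five best coarse candidates). Two numerical
choices matter:

* **Valid-area normalization.** Near the tile border the compensation
  samples outside the FOV; those pixels carry no data. $d_k$ is therefore
  averaged over the pixels where *both* remaps are in-bounds, and a
  candidate leaving less than 25% of the region valid scores `Inf`.
  Averaging the literal zero-filled differences instead lets the fill
  penalty dominate and migrates the minimum at strong asymmetric offsets.
* **Preprocessing.** For noise robustness each tile is opened with a 5×5
  square structuring element and binarized at the Otsu threshold before
  scoring (the copies are used for scoring only). On clean synthetic
  targets the raw intensities discriminate more finely, so the unit tests
  of random-parameter recovery disable the binarization; the
  printed-triple recovery keeps it.

Identifiability from a *single* overlap strip is marginal: $A$ and
$X_{off}$ trade off along a shallow valley. The calibration target used in
the tests is therefore a dense grid (50-px spacing, 5-px lines on 600-px
tiles), which puts several line crossings inside the ~54-px strip; with a
100-px grid a rival basin genuinely scores below the truth. An instrument
calibration would use several overlapping pairs in both orientations and
average, which is how the operating triple is meant to be obtained.

## Resonant-scan resampling

A resonant mirror sweeps the fast axis with phase-uniform sampling;
position follows $x(\theta) = (1 - \cos\theta)/2$. `correct_resonant()`
treats the input columns as uniform in $\theta$ over the central `beta`
fraction of the half period and resamples each row to uniform positions
(1-D linear interpolation, same width). The default `beta = 0.9` excludes
the mirror turnarounds. `induce_resonant()` is the inverse resampling, so
the simulator and the correction are self-consistent. Row sums are
conserved only approximately: near the sweep edges many phase-uniform
columns compress into few position-uniform ones, so mass sitting at the
turnarounds is not preserved — with `beta = 1` conservation to 1% holds
only for images whose edge signal stays near its mean, one more reason the
usable fraction is kept below 1 in practice.

## Tile alignment (σ-scored coarse-to-fine search)

Tiles are processed in row-major grid order; the first tile anchors the
mosaic origin. For each subsequent tile the stage displacement predicts an
offset, and candidates in a ±30-px window (`range_x_px`, `range_y_px`;
the window must exceed the stage repeatability) are scored: for each placed
neighbor (left and top), the overlap regions of tile and canvas are
block-mean downsampled 2×, and σ — the *population* standard deviation of
their per-pixel absolute difference, in 8-bit units so the 1.5 threshold is
meaningful — is summed over the neighbors. The coarse scan steps 10 px; if
the spread $\sigma_{max} - \sigma_{min} \ge 1.5$ the placement is refined
at 2-px steps within one coarse step of the coarse minimum, otherwise the
stage estimate is kept and flagged (`fallback`), e.g. on featureless
overlaps. Ties prefer the smallest displacement from the stage estimate,
then row-major order.

Three robustness rules keep the score comparable across candidates:

* a candidate must overlap **every** scored neighbor — σ sums one term per
  neighbor, so dropping a term would favor far-shifted candidates;
* a candidate must retain at least **half the overlap depth** seen at the
  stage estimate (the dispersion of a few-pixel strip is downward-biased).
  At production geometry (≈540-px overlaps, ±30-px window) both rules are
  vacuous; they matter only at the reduced scales used in testing;
* compensated tiles are **cropped by the common invalid border band**
  (identical for all tiles, since all share the maps), so zero fill cannot
  bias the score; relative placements are unchanged.

Compositing is overwrite (newest wins) by default — artifact compensation
rests on the distortion correction, not on blending — with an optional
linear feather across the overlap. A 2-px fine step leaves ±1-px parity
residuals relative to integer stage jitter; the reconstruction test that
demands a near-exact mosaic therefore runs the search at a 1-px fine step,
while placement-accuracy checks keep the 10/2-px production stepping.

## Virtual H&E rendering

Following a Beer-Lambert transillumination model, 256-entry lookup tables
turn each channel intensity $i$ into a transmitted color per component $c$:

$$\mathrm{LUT}[i] = \mathrm{round}\!\left(255\,
   e^{-(255 - c)\,i\,k/255}\right),$$

with dye colors $(B, G, R) = (180, 0, 90)$ for hematoxylin (fed by THG,
nuclei) and $(210, 165, 250)$ for eosin (fed by TPEF), and contrast
$k = 2.5$. The two remapped images combine multiplicatively,
$HE = \mathrm{round}(H \cdot E / 255)$, computed in floating point and
quantized once. Entries are stored 8-bit (scaled by 255) so the
combination recovers the printed arithmetic; zero signal renders white
(bright-field background) and every LUT column is non-increasing below
saturation. The dye colors and $k$ were tuned visually against
pathologist feedback; there is no quantitative color-fidelity target to
test, so the tests pin the closed form instead.

Before remapping, channels can be enhanced: `dce()` estimates the
background by grayscale opening (disk radius 31 px by default), subtracts
it, and rescales by $\min(\alpha_{max},\ 255/p_{99})$ with the
conventional caps $\alpha_{max} = 8$ (THG) and $5$ (TPEF). This is a
compact background-suppress-then-gain enhancer exposing the standard
single-parameter control; it is deliberately pluggable behind a
one-operation interface. Optional gamma correction (default 1, off) and a
bilateral filter (off) complete the chain.

## The `.rfpb` container

Gigapixel mosaics are stored uncompressed for display speed: a frozen
4096-byte little-endian header (magic `RFPB`, version 1, dimensions, tile
counts, pixel pitch, preview geometry and byte offsets), then a 10×
block-mean preview, then the payload, both row-major with each pixel's
three 8-bit values interleaved **B, G, R**. Preview dimensions use ceiling
division; partial edge blocks average over the pixels they contain. The
total size is exactly
$4096 + 3\lceil W/10\rceil\lceil H/10\rceil + 3WH$ bytes — about 2.8 GiB
for one gigapixel. `read_roi()` serves arbitrary rectangles by row-wise
seeks without touching the rest of the payload. Export to PNG is capped at
100 MP (use TIFF beyond); neither path recompresses the data.

## The synthetic scan simulator

`make_tissue_scene()` emulates what the two channels see in stained soft
tissue: channel 1 holds anti-aliased elliptical nuclei (default 1500 per
mm², radii 4–9 px, intensities 120–220) over a low haze; channel 2 holds
smooth sinusoidal vessel ribbons and band-limited texture. Densities are
physical (per mm²) so scenes scale with the pixel pitch; the compact test
scenes use a 1-µm pitch. `simulate_scan()` tiles a scene with the standard
9% overlap, crops each tile at its nominal grid position **plus a hidden
uniform integer jitter** (stage repeatability error — the stage log reports
only the nominal positions, which is exactly why the aligner searches a
window around the stage estimate), then applies the forward distortion,
the inverse resonant resampling, and Gaussian noise (default σ = 5;
Poisson optional). All randomness flows from one seed; identical seeds
give bit-identical scenes and scans.

What the simulator does *not* model: optical point-spread blur, photon
statistics tied to dwell time, staining chemistry, autofluorescence, or
non-translational stage errors (rotation, z-drift). Passing tests
demonstrate the algorithms' correctness under the stated error model, not
instrument-level image quality.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a single CPU: 600-px tiles
for the printed-triple recovery (coarse-to-fine over ~8k coarse candidates,
under a minute), 300–400-px tiles and 2×3 grids for stitching properties,
and property-based random images under 100×100 for the container. These
sizes keep every property at full strength — the estimator runs over its
complete default grid, and the alignment oracle comparison is exhaustive —
while the production-scale arithmetic (3.6 Gpx/cm², 86 Gbit, 2.8 GiB) is
checked in closed form.

## Known limitations

* Parameter estimation from one overlap strip is weakly identifiable at
  small distortion angles; calibrate from several pairs when possible.
* σ-scoring assumes translational misalignment only.
* The greedy row-major placement has no global bundle adjustment; errors
  do not accumulate at test scales but could over very long strips.
* The DCE stand-in shares the `alpha_max` parameterization but is not the
  published algorithm it approximates.
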