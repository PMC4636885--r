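---
title: "Models and methods behind sonopore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sonopore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonopore)
```

sonopore implements the computational workflow of a sonoporation
experiment on adherent cell cultures: acoustic field simulation and
treatment-plane selection, exposure dosimetry, fluorescence-image
quantification, detachment scoring, and a routed statistical analysis.
This vignette explains the models, their assumptions, the tunable
parameters, and the design choices made where the problem was genuinely
open. It states no empirical result beyond what the package's tests and
acceptance script themselves compute.

## The piston field model

The device's transducers are flat circular piezoelectric crystals
(nominal diameter 20 mm) driven continuously at 1 MHz. We model each as
an ideal baffled piston with uniform surface velocity radiating into a
lossless free field. The pressure amplitude is the magnitude of the
Rayleigh integral over the source disc,

$$ p(\mathbf{r}) \;\propto\; \Big| \frac{k}{2\pi}
   \int_{\mathrm{disc}} \frac{e^{ikR}}{R}\, \mathrm{d}S \Big| , $$

with $R$ the source-to-field distance and $k = 2\pi/\lambda$. On the
axis this reduces to the classical closed form
$p(0, z) = 2\,\lvert \sin\!\big(\tfrac{k}{2}(\sqrt{z^2+a^2} - z)\big)\rvert$,
which both fixes the quadrature normalization and serves as an
independent oracle for it. The free-field idealization is appropriate
because the culture chamber membrane is minimally reflective and an
absorber sits in the far field, so standing waves are deliberately
outside the model. Pulse transients, nonlinearity, microbubble dynamics
and heating are likewise out of scope: the field is only used to choose
a treatment plane and to bound array cross-talk, both CW questions.

**Discretization.** The disc is divided into concentric rings of
roughly square elements. The default element side is $\lambda/20$
(`elementSize` argument): at $\lambda/10$ the quadrature already agrees
with the closed form to a fraction of a percent away from axial nulls,
but near a null (where the closed form approaches zero) the *relative*
error of any fixed quadrature blows up; $\lambda/20$ keeps the on-axis
relative error under 1 % over the whole characterized range
$z \in [8, 70]$ mm, at about 55 000 elements for $ka \approx 41$.
Requests coarser than $\lambda/5$ are refused as a configuration error.
Planar grids are built symmetric about the axis
(`(-n:n) * spacing`, $n = \lfloor \text{halfWidth}/\text{spacing}
\rfloor$), so the simulated maps inherit the mirror symmetry of the
source exactly and always contain an on-axis pixel.

**Parameters.** `radius` (mm, default 10), `frequency` (Hz, 1e6),
`soundSpeed` (m/s, 1524 — water at 37 °C; set 1532 to emulate a 42 °C
bath, a ~0.5 % change), `amplitudeScale` (dimensionless, 1). All
pressures are relative: absolute pascal calibration is bound to
hydrophone hardware and out of scope. Note that measured transducers
can show a near/far-field transition below the ideal-piston prediction
$a^2/\lambda - \lambda/4$ (~65 mm here) because the effective aperture
of a real crystal is smaller than nominal; the simulator deliberately
uses the nominal geometry and does not fit an effective aperture.

## Treatment-plane selection

Within the explored range (default 10–20 mm; the 13–17 mm sub-range is
a common presentation window) each slice is scored by its
*heterogeneity*: the standard deviation of the pressure over grid
points inside a circular mask centred on the axis. Three choices are
deliberate:

* **Mask radius** defaults to the half-extent of the scan — the circle
  inscribed in the scanned square (5.25 mm for a 10.5-mm scan). This is
  the natural reading of "the circular area encompassed by the scan".
* **Population SD** (divide by $N$): the quantity is a descriptive
  statistic of a fixed grid, not an estimate from a random sample.
* **Pressure, not intensity**: heterogeneity is computed on the
  pressure amplitudes themselves.

The optimal distance is the argmin of the curve, ties broken toward the
smaller $z$ (shorter path, higher peak intensity). The calibration
point is the grid point whose relative intensity $(p/p_{\max})^2$ is
closest to 0.9; ties are broken by smaller radius, then smaller $x$,
then smaller $y$, making the choice deterministic on symmetric maps.
Cross-talk is the worst-case intensity at or beyond a radial offset,
$10 \log_{10} (I(\text{offset})/I_{\max})$ dB; the 16-mm default offset
is the geometric distance from a transducer's axis to the nearest edge
of a neighbouring crystal (26-mm housing pitch minus the 10-mm crystal
radius). dB values are defined on intensity ($10\log_{10}$ of the
intensity ratio, equal to $20\log_{10}$ of the pressure ratio).

## Exposure dosimetry

All printed session quantities derive from the protocol object: duty
cycle $= 100 \cdot (\text{cycles}/f)/T_{\text{burst}}$ (4.8 % for 30
cycles at 1 MHz every 625 µs), PRF $= 1/T_{\text{burst}}$ (1.6 kHz),
microbubble:cell ratio (660 for 33 µL of 1.2×10¹⁰ mL⁻¹ agent over
6×10⁵ cells), volume concentration (0.33 %, dividing by the stated
media volume alone — the reporting convention, not media + agent), and
submersion time. Two timing conventions matter: the 30-s operator
switch is counted after *every* site including the last, which is what
makes $1 + 6\times1 = 7$ min; and the concurrent scheme (all sites
driven together) needs only equalization + exposure = 1.5 min. The
sound-speed change between 37 and 42 °C is reported with the
low-temperature denominator (0.5249 % for 1524 vs 1532 m/s, commonly
rounded to 0.53 %); the value is flagged approximate since the
denominator convention is not universal.

## Image quantification

Nuclei are segmented from the blue channel by a global Otsu threshold
(exhaustive minimization of the weighted intra-class variance over the
image histogram; the returned threshold is the midpoint between the two
levels spanning the optimal cut, so the criterion is deterministic and
ties resolve toward the smaller cut), followed by 8-connected component
labelling and removal of components below `minObjectArea` (default
30 px at the synthetic generator's scale — the original workflow names
no size filter, but one is necessary to suppress noise specks).

One further filter is deliberate: a candidate nucleus is kept only if
its mean blue intensity exceeds the below-threshold background by
`minContrastSigma` (default 3) background standard deviations — the
same inclusive background-referenced criterion used for positivity
scoring, applied at detection time. Without it, a structureless noise
image would be split by Otsu near its mean and yield one giant
"object"; with it, such images produce an empty object set, which is
the sensible answer. Setting `minContrastSigma = 0` disables the
filter.

Cell boundaries are segmented from the pixelwise maximum of the
min–max-normalized blue and green channels — the maximum (rather than a
sum or product) keeps reporter-negative cells visible through their
nuclei — thresholded by Otsu, and split between touching cells by
propagation seeded at the nuclei (Voronoi-style geodesic region
growing, the same algorithm family CellProfiler uses for secondary
objects; EBImage's `propagate` provides it). Each cell object is a
superset of its nucleus, one per nucleus.

Positivity uses the inclusive criterion
$\bar I_{\mathrm{obj}} \ge \bar I_{\mathrm{bg}} + n\,\sigma_{\mathrm{bg}}$
with $n = 3$; transfection is scored on cell-boundary objects against
the green channel (reporter signal fills cytoplasm and nucleus),
apoptosis on nuclei against the red channel (nuclear marker).
Background statistics are computed per channel over all pixels not
occupied by any object of the relevant set — whether the original
workflow excluded the *other* object set's pixels too is unknowable
from its description; we use per-set non-object pixels. The criterion
is invariant under affine intensity rescaling of a channel, and the
positive set at larger $n$ nests inside the set at smaller $n$; both
are property-tested. Per-FOV fractions are counts relative to the
number of cells (missing, not zero, when a field is empty) and are
averaged per replicate as an unweighted mean of fractions, not pooled
counts.

Detachment is computed from marker ("dot") images — each cell marked
manually, dots counted automatically — as
$100\,(\bar c_{\text{after}} - \bar c_{\text{before}})/\bar c_{\text{before}}$,
negative meaning loss. Raw phase-contrast detection is out of scope,
mirroring the manual-dot workflow.

## Statistical decision tree

Responses are replicate-level (FOV fractions already averaged), nine
cells of $n = 3$. Normality is tested by Shapiro–Wilk *on residuals
from the cell means*: with three observations per cell, per-cell
testing is impossible, and pooling raw data would confound group-mean
differences with non-normality. Homogeneity is tested by Bartlett
across the nine cells. Both passing at $\alpha = 0.05$ routes to a
balanced two-way ANOVA with interaction (balance makes the
sum-of-squares type immaterial) and Tukey HSD on significant effects;
otherwise each factor is tested marginally by Kruskal–Wallis (the test
cannot assess interactions, so the interaction is reported as *not
assessed* on that branch) with Holm-adjusted pairwise Wilcoxon tests on
significant factors. Holm is our choice; the original analysis does not
state an adjustment. No multiplicity correction is applied across the
three response variables, matching per-response reporting. Degenerate
inputs (constant within all cells, or all-tied ranks) raise explicit
errors rather than returning undefined p-values, and zero residual
variance with a real effect reports $p = 0$ rather than NaN.

A caveat the tests make explicit: with residual-based Shapiro–Wilk at
27 observations, moderately skewed (e.g. exponential) noise is routed
nonparametric in a minority-to-half of random datasets — the test has
limited power at this size. The suite therefore asserts an *elevated*
switching rate relative to normal data rather than a majority.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their parameters and a seed; the
caller's RNG state is restored afterwards.

* **Scans** are quadrature fields plus iid zero-mean Gaussian noise
  truncated at zero (amplitudes are nonnegative).
* **Micrographs** place non-overlapping cells (rejection sampling;
  exceeding the attempt budget raises a capacity error) as disks:
  bright nuclei in blue, a green offset over cytoplasm and nucleus for
  transfected cells, a red offset over the nucleus for apoptotic cells.
  The medium outside cells fluoresces at the background level in every
  channel (unbound dye/autofluorescence) while unstained cell interiors
  are dark — this contrast is what makes negative objects fall strictly
  below the positivity threshold even in the noiseless limit, so exact
  round-trip recovery is well defined. Defaults (320 × 320 px, 80
  cells, background 100 ± 10 counts, signal offsets 600–2900 counts,
  12-bit clipping, 5 % true transfected fraction) are fixed once at the
  reporter-fraction regime of a typical validation experiment.
  Positive flags are deterministic — the first
  `round(fraction * nCells)` cells of a seeded shuffle — so integral
  requested fractions are exact by construction. The generator does
  *not* emulate uneven illumination, focus drift, overlapping or
  partially imaged cells, staining variability, or debris; passing
  round-trip tests therefore demonstrates correctness of the criterion
  and segmentation logic, not robustness to real-microscopy artifacts.
* **Dot images** place non-touching 3×3 dots and remove a programmed
  fraction for the after image.
* **Replicate tables** draw each replicate from
  $\mathcal{N}(\mu_g, \sigma_g)$ per group — the minimal assumption
  consistent with mean ± SD reporting and ANOVA use. Presets carry the
  per-group means/SDs of the three response variables (transfection %,
  cell-count change %, apoptotic ratio %) from the validation study's
  reported summaries.

## Numerical choices and problem sizes

Tie-breaks are deterministic everywhere (first minimum for Otsu and
heterogeneity argmins; radius-then-x-then-y for calibration points).
Grid membership uses a small absolute tolerance so boundary points are
not lost to floating-point noise. The test suite and acceptance script
run at deliberately modest sizes chosen for statistical adequacy:
quadrature checks over $z \in [8, 70]$ mm at 2-mm steps, a 57 × 57
wide scan for cross-talk, 50 seeded fields of view for recovery bias,
100 seeded tables for the headline ANOVA p-value, and 1000 null tables
per branch for type-I error (asserted within 0.05 ± 0.02).

## Known limitations

* The piston model is linear CW with nominal geometry; it cannot
  reproduce a measured transducer's effective aperture, element
  non-uniformity, or housing diffraction.
* Segmentation assumes roughly convex, non-overlapping cells at the
  generator's scale; heavily confluent cultures would need
  shape-aware splitting beyond seeded propagation.
* The statistical layer tests replicate-level summaries only; nested
  (FOV-within-replicate) variance is deliberately not modelled.
* Absolute acoustic pressure, electrical power and W/cm² intensities
  are hardware-calibrated quantities and are not computed.
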