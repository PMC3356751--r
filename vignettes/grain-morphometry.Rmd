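---
title: "Morphometric, fractal and texture characterization of grain cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric, fractal and texture characterization of grain cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

During grain filling, a cereal endosperm changes shape in ways that a
transverse cross-section captures well: the section grows, rounds, its
border smooths, and the starchy tissue becomes more regularly packed.
`grainmorph` quantifies these changes from calibrated 8-bit grayscale
micrographs of single grain sections, following the classical
digital-image-analysis workflow: binarize, isolate the grain, measure
shape, then summarize across experimental groups (here: maturation
stage in days after flowering, DAF, crossed with position along the
panicle from apex to base).

Because the original field micrographs of such studies are rarely
deposited, the package ships a synthetic generator that produces
grain-like binary masks and endosperm texture patches with known
ground truth. Every downstream stage is validated against that ground
truth and against independent analytic or brute-force oracles.

# Shape descriptors

For a foreground region with area $A$ (mm²), outer perimeter $P$ (mm),
maximum Feret length $ML$ and the perpendicular extent $mL$ (mm), the
package computes

$$\mathrm{EF} = \frac{ML}{mL}, \qquad
  \mathrm{SF} = \frac{4\pi A}{P^2}, \qquad
  \mathrm{CF} = \frac{P^2}{A}.$$

A circle has $\mathrm{EF} = \mathrm{SF} = 1$ and
$\mathrm{CF} = 4\pi \approx 12.57$; elongation raises EF and CF and
lowers SF. The algebraic identity
$\mathrm{SF}\cdot\mathrm{CF} = 4\pi$ holds for every record and is
asserted in the tests.

Conventions, stated so that tests can be exact:

* **Area** is the foreground pixel count times the squared pixel size.
* **ML** is the maximum distance between two foreground *pixel
  centers*. The diameter of a point set is attained at vertices of its
  convex hull, so the search runs over hull vertices
  (`grDevices::chull`); an exhaustive all-pairs search is the test
  oracle. **mL** is the extent of the projection of all foreground
  pixel centers onto the direction perpendicular to the ML axis — the
  perpendicular Feret extent at the ML orientation, not the global
  minimum Feret.
* **Coordinates** are (row, column) with origin at the top-left;
  physical units in records are always mm.

## The perimeter estimator

Counting pixel edges along a digital boundary overestimates the length
of smooth curves badly (about +27% for the naive count, and a measured
+5.5% even for a subpixel marching-squares trace of raw binary data on
a disk, because the level set of 0/1 data is a staircase of axis and
diagonal steps). Since SF, CF and the perimeter fractal dimension all
take $P$ squared or logged, that bias would dominate the biology.

`grain_perimeter()` therefore smooths the binary indicator with a small
isotropic Gaussian (default $\sigma = 1.5$ px) and traces the 0.5-level
contour of the *smoothed* field with marching squares
(`grDevices::contourLines`). For a straight edge at any orientation the
0.5-level set of the blurred indicator coincides with the true edge, so
the estimator is asymptotically unbiased on smooth boundaries; measured
bias is +0.13% on a disk of radius 200 px and −1.3% on a 100-px square
(corner rounding of radius roughly $\sigma$). Boundary wiggles shorter
than a couple of pixels are smoothed away, which sets the resolution
floor for roughness measurements. Objects so small that the smoothed
field never reaches 0.5 fall back to the raw binary contour; a single
pixel yields its level-0.5 diamond, length $2\sqrt{2}$ px, a documented
small-positive convention rather than an error.

# Fractal dimensions

Edge irregularity and plane occupation are summarized by the log-ratio
forms

$$\mathrm{FDP} = 2\,\frac{\ln(P/4)}{\ln A}, \qquad
  \mathrm{FDA} = \frac{\ln A}{\ln ML},$$

with natural logarithms and $P$, $ML$ in mm, $A$ in mm². A smooth
square of side $L$ gives $\mathrm{FDP} = 1$ at every size; a
plane-filling object with $A = ML^2$ gives $\mathrm{FDA} = 2$.

Two numerical consequences of these definitions deserve emphasis:

* **They are not scale-invariant.** Logarithms of dimensional
  quantities change value with the unit. The package fixes mm / mm² as
  the only permitted units and refuses inputs in the *log-singular
  guard band* $|\ln x| < 0.05$ (i.e. $A$ within about 5% of 1 mm², or
  $ML$ of 1 mm), where the ratio blows up. In batch use
  (`fractal_records()`) guard-band grains get `NA` with a warning
  instead of aborting the cohort — real populations whose group means
  sit near 1.4 mm² genuinely straddle the band.
* **FDP is size-dependent for every shape except the square.** For a
  smooth circle FDP ranges from about 0.44 at $A = 1.5$ mm² to 0.87 at
  $A = 5$ mm². "FDP near 1 means smooth" is therefore a statement
  about square-like baselines, not a universal constant; the package's
  test oracle for smooth shapes is the closed-form FDP of an ellipse
  via the Ramanujan perimeter approximation, which the raster
  measurement must reproduce within 2%. What *is* robust, and what the
  trend analyses rely on, is the ordering: at fixed geometry FDP
  strictly increases with boundary roughness, and along the filling
  series it decreases as borders smooth and areas grow.

`ensemble_exponents()` fits the population power laws
$P \propto ML^{b_P}$ and $A \propto ML^{b_A}$ by ordinary least squares
in log-log space (reduced major axis available by option; OLS is the
default as the plainest reading of a power-law fit). Geometrically
similar smooth shapes give $b_P = 1$, $b_A = 2$ exactly.

# GLCM texture

Endosperm packing is summarized by the gray-level co-occurrence matrix
$p(i, j)$: the probability that gray levels $i, j$ co-occur at a fixed
pixel offset. From it,

$$E = -\sum_{p > 0} p \ln p, \qquad \mathrm{ASM} = \sum p^2 .$$

$E$ (nats) is high for disordered neighborhoods; ASM is 1 for a
constant patch and $1/N_g^2$ at the uniform limit; $E = 0$ iff
$\mathrm{ASM} = 1$. Defaults are $N_g = 8$ levels (uniform binning of
0–255 by $\lfloor v N_g / 256 \rfloor$), offset $(1, 0)$ (distance 1,
0°), symmetric counting — the common defaults of GLCM plugins in
image-analysis suites, since no single convention is canonical; all
three are arguments and are recorded in every output row. Symmetric
counting equals the average of the one-directional count matrix and
its transpose, an identity the tests assert.

# Group statistics

The grouped summary follows the descriptive-plus-letters format of
agronomic tables: per (stage, interval, descriptor) cell `n`, mean,
median, sd ($n-1$ denominator), se, min, max, plus compact letters.

The omnibus gate pairs a rank-based post hoc with a rank-based gate:
**Kruskal–Wallis by default**, with one-way ANOVA available by flag.
Pairing an ANOVA gate with Dunn's rank test, as older reports did, is
internally inconsistent — Dunn's statistic presupposes the joint
ranking — so the package defaults to the coherent pair and records the
choice in the output. Dunn's z for groups $i, j$ uses joint mid-ranks
and the standard tie correction:

$$z_{ij} = \frac{\bar R_i - \bar R_j}
  {\sqrt{\left(\frac{N(N+1)}{12} -
   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}.$$

Unequal group sizes are handled naturally (the reason this test suits
field samples with empty cells — "vain grains"); empty groups are
dropped with a logged note. By default no multiplicity adjustment is
applied beyond the omnibus gate (Bonferroni and Holm are flags),
matching common practice for gated Dunn comparisons; the simulated
global-null calibration in the acceptance suite shows the gated
procedure holds its familywise error at $\alpha$. Letters come from the
insert-and-absorb algorithm; a property test reconstructs the full
decision matrix from the letters on random decision patterns.

# The synthetic generator

**Grain masks.** The boundary is a truncated Fourier series on the
radius of a base ellipse,
$r(\theta) = r_e(\theta)\,(1 + \sum_k a_k \cos(k\theta + \varphi_k))$,
with $\sum_k |a_k| =$ `roughness_amp` split randomly across modes
$k = 2 \ldots H{+}1$ and random phases (mode 1 is skipped as it mostly
translates the outline). A single amplitude knob thus spans the
smooth-to-rough continuum; amplitude 0 is an exact rasterized ellipse,
so generated geometry is recoverable ground truth. Rasterization uses
the pixel-center rule: a pixel is foreground iff its center lies
inside the continuous boundary. Identical parameters and seed give
bit-identical masks; all per-grain seeds fan out from one global seed
by a stable string hash, so cohorts are reproducible end to end.

**Filling series.** Stage targets (mean area, EF, roughness)
interpolate linearly between endpoints; per-grain jitter is
multiplicative log-normal with the stated CV (keeping all parameters
positive), and semi-axes derive from the jittered $A$ and EF as
$a = \sqrt{A\,\mathrm{EF}/\pi}$, $b = \sqrt{A/(\pi\,\mathrm{EF})}$.
The defaults are the package's standing emulation of a rice maturation
series: area 2.36 → 4.60 mm² and EF 2.91 → 1.38 across DAF 7 → 35
(the apical-interval endpoints of the motivating study's summary
table), roughness 0.15 → 0.02, jitter CV 0.15 (the table's sd/mean
ratios run 0.1–0.35), 15 grains per group, raster scale 0.01 mm/px.
`make_filling_cohort()` adds the panicle dimension: toward the base
the mean area shrinks by a stage-dependent fraction (40% early
narrowing to 28% late, the apex/base ratios of the same table) and EF
and roughness run slightly higher, reproducing the apex-first filling
gradient and its late-stage convergence.

**Texture patches.** Each pixel independently takes a fixed mid-gray
level with probability `organization` and an i.i.d. uniform level
otherwise: organization 0 is maximal disorder (GLCM entropy near
$\ln N_g^2$), 1 is a constant patch ($E = 0$, ASM = 1), and $E$/ASM
move monotonically in between. The pipeline runs dorsal patches along
an organization path rising with stage (0.25 → 0.85) and ventral
("white belly") patches 0.15 lower — the ventral region organizes
later and less.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: absolute perimeter roughness of real
grain borders (real sections are rougher than a low-order Fourier
boundary, so synthetic $P$ and FDP levels sit below field values even
though all orderings match); illumination gradients, debris and
multi-grain scenes (segmentation is tested on clean bimodal images);
starch-granule microstructure (the texture model reproduces the
entropy/ASM axis, not SEM morphology); and any quantitative
white-belly geometry, which the motivating study did not state — the
ventral/dorsal contrast is carried by the organization offset alone.

# Problem sizes and other fixed choices

The validation cohort is 5 stages × 4 intervals × 15 grains
(300 masks at 0.01 mm/px), the package's standard compromise between
statistical resolution of the trend tests (all six stage trends reach
$p < 10^{-16}$ at this size) and quick iteration; the field study's
~45 grains per cell is available by argument. The null calibration of
the gated Dunn procedure uses 1000 simulated four-group tables of
n = 10. Oracle suites use 100 random blobs (Feret), 30–50 random
histograms (Otsu) and 2000-permutation references (Dunn).

Other fixed choices: 8-connectivity for foreground components
(matching the contour-tracing convention); largest-component
extraction with hole filling on by default (interior endosperm cracks
would corrupt $A$ and $P$; disable with `fill_holes = FALSE`); ties
between equal-area components break to the lexicographically smallest
(row, column) foreground coordinate and are recorded in provenance;
Otsu thresholding with bright-grain polarity by default and an
`invert` override; interactive brightness/contrast standardization is
reduced to optional min-max rescaling (`standardize_contrast()`), the
only reproducible core of that manual step; manual region-of-interest
selection is replaced by largest-component extraction plus an optional
crop box. PNG and TIFF are the supported raster formats. CSV artifacts
are written at 6 significant digits so reruns diff cleanly.

# Known limitations

* FDP/FDA values are only comparable between studies that use the same
  units and the same perimeter estimator; the guard band refuses the
  worst cases but values with $A$ within, say, 20% of 1 mm² remain
  numerically delicate.
* The perimeter estimator's $\sigma$ trades corner fidelity against
  staircase bias; polygonal objects are measured slightly short.
* Compact letter displays are not unique; the insert-absorb output is
  deterministic but other valid letterings exist.
* The interval gradient of the synthetic cohort is a two-parameter
  caricature (area gap, EF/roughness excess); it reproduces the
  qualitative letter structure, not any specific field table.
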