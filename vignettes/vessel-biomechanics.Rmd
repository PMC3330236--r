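---
title: "Quantifying vascular graft remodeling from pressure-strain loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular graft remodeling from pressure-strain loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselastica)
library(dplyr)
```

## The problem

A cell-free biodegradable scaffold implanted into a vein remodels in vivo
into a living vessel (an in-situ tissue-engineered vasculature, iTEV).  The
question that matters clinically is not whether tissue forms but whether the
new wall *behaves* like the native vessel: a graft that stays much stiffer
than its host vein disturbs flow and invites stenosis.  Intravascular
ultrasound (IVUS) plus a catheter pressure transducer let this be asked in
the living animal: the lumen cross-section is imaged over the pulsation
cycle while intraluminal pressure is recorded simultaneously.

`vesselastica` implements the analysis chain from those raw signals to a
single remodeling score, together with the scaffold-degradation kinetics and
the statistical protocol such studies use, and a synthetic-data module that
generates ground-truth-known inputs so every stage can be validated
end-to-end.

## From contours to strain

Each imaging frame contributes a closed lumen contour.  Its circumferential
length $L_i$ is the perimeter of the traced polygon (closing edge included),
and wall distension is summarised by the engineering strain against a
reference frame,

$$\varepsilon_i = \frac{L_i - L_{\mathrm{ref}}}{L_{\mathrm{ref}}}.$$

Two choices here were genuinely open and are worth recording:

* **Reference frame.** When a pressure trace is available the reference is
  the minimum-pressure (diastolic) frame, so strain is non-negative over the
  cycle and has the conventional "distension from diastole" reading; without
  pressure, frame 1 is used.  The modulus estimators below depend only on
  strain *differences*, so this choice shifts, but never rescales, the loop.
* **Perimeter, not area-equivalent circle.** $L$ is measured on the traced
  contour itself.  For circular lumens the two agree exactly (and the test
  suite asserts circumferential strain equals radius strain to $10^{-9}$);
  for non-circular lumens the perimeter is the quantity the strain
  definition names.

Uniform arc-length resampling of contours is available
(`resample_contour()`) for acquisitions whose vertex placement is
ray-determined, but the perimeter itself is computed on the polygon as
given: linearly resampled vertices lie *on* the polygon, so resampling can
only shorten a perimeter by clipping corners, and a polygon perimeter is
already independent of vertex density.

**Contour denoising.** Per-vertex tracing noise does not average out of a
polygon perimeter: each noisy edge adds a positive second-order length term,
which both biases $L$ and, more damagingly, fluctuates frame to frame with a
magnitude comparable to the strain signal of a stiff vessel.
`strain_series()` therefore projects each contour's radius-vs-angle profile
onto its first 8 Fourier harmonics (least squares) before measuring length.
Band-limited shapes — circles, ellipses, any smooth lumen — are reproduced
exactly, so the denoising is invisible on clean data; it can be disabled
with `smooth_harmonics = NULL`.  The default of 8 harmonics keeps every
plausible lumen shape while removing the high-frequency half of the noise
spectrum of a 64-vertex trace.

## The pressure-strain loop and the elastic modulus

Pressure is sampled far faster than frames, so it is linearly interpolated
onto the frame timestamps (never the reverse — strain is the scarce signal)
and the pairs $(\varepsilon_i, p_i)$ form the P-S loop.  Over a cycle the
loop is a closed trajectory; wall viscoelasticity opens it into an ellipse.
The elastic modulus is the pressure change per unit circumferential strain,
in mmHg per unit strain.  Two estimators are implemented:

* **`extrema`**: $E = (p_{\max} - p_{\min}) / (\varepsilon_{\max} -
  \varepsilon_{\min})$.  Transparent, but it uses only four samples, so a
  single noisy frame at either extreme corrupts it.
* **`loop-fit`** (default): the slope of the total-least-squares principal
  axis of the point cloud, computed in *standardized* coordinates and
  mapped back, i.e. the reduced-major-axis slope
  $\mathrm{sign}(\rho)\, s_p / s_\varepsilon$.  Principal axes of the raw
  $(\varepsilon, p)$ cloud depend on the measurement units — pressures are
  numerically thousands of times larger than strains — and for a loop opened
  by a pure phase lag $\varphi$ the raw axis is biased by roughly
  $1/\cos\varphi$.  The standardized axis is invariant to the units of
  either coordinate and recovers the generating slope of a phase-lag
  ellipse exactly.  On noiseless, lag-free loops the two estimators agree
  exactly, which the suite asserts to $10^{-6}$.

Multi-cycle recordings are pooled into one cloud before fitting rather than
averaged per cycle; pooling uses every sample and needs no cycle
segmentation.  Whether the underlying modulus is better read on a linear or
log pressure scale cannot be settled from loop data alone; the linear
$\Delta p / \Delta\varepsilon$ form is used, and only scale-free quantities
(ratios and the regeneration score) feed the downstream remodeling claims.

## The regeneration score

With graft and native moduli $E_T, E_N$ at follow-up and $E_{T0}, E_{N0}$
immediately after implantation,

$$RS = \left(1 - \frac{|E_T - E_N|}{|E_{T0} - E_{N0}|}\right) \times 100\%.$$

100% means the graft's modulus matches the native vessel; 0% means the
mismatch is what it was at implantation.  Three decisions are deliberate:

* **Absolute differences** (default): the published definition normalises
  "the difference" without fixing its sign; absolute values make the score
  symmetric in over- vs under-stiffness.  `signed = TRUE` retains the raw
  differences for sensitivity analyses.
* **No clamping**: a graft whose mismatch *grows* scores negative, which is
  information worth keeping; the 0% and 100% anchors are unaffected.
* **Per-implant baselines**: `cohort_rs()` scores each animal against its
  own month-0 pair.  Because RS is a nonlinear function of four moduli,
  the mean of per-animal scores is *not* the score of the group means — the
  suite carries a regression test demonstrating the two only coincide at
  zero variance, which is why a ratio trajectory and an RS trajectory
  published for the same cohort cannot be derived from one another.

## Scaffold degradation kinetics

Hydrolytic degradation is modeled as first-order decay, fit as a straight
line on $(t, \ln v)$; `v0`, the rate `k` (per week) and the half-life
$\ln 2 / k$ are reported with the log-space RMSE.  The packaged published
series (tensile strength, weeks 0-9; molecular weight, weeks 0-25) behave
differently on purpose: strength is well described by a single exponential,
while the molecular weight plateaus after week 13 and the fit's RMSE says
so — the module reports misfit rather than asserting fit quality.
`time_to_fraction()` answers "when is half the strength gone" either by
linear interpolation between the two bracketing measurements (default —
this is how a bracket like "2-3 weeks" reads off a measurement table) or
from the fitted rate; `first_time_below()` is the conservative tabular
read-off for absolute thresholds.

## The statistical protocol

Two-group comparisons are variance-screened: an equality-of-variances test
at $\alpha = 0.05$ routes to Student's unpaired t-test (equal) or the
Mann-Whitney U test (unequal).  Many-group comparisons route between
one-way ANOVA followed by Dunnett's many-to-one post-hoc tests against a
named control (critical values from the single-step multivariate-t
formulation, via multcomp) and the Kruskal-Wallis test.  Because the
original protocol does not pin the screen down, the screen is an explicit,
configurable, *logged* part of every result object (`glance()` exposes it);
the F test backs the two-group screen and Bartlett the many-group one by
default, with Levene and an explicit `"none"` override available.  The
suite calibrates the dispatcher end-to-end: its two-group type-I error over
2000 equal-mean normal replicates must stay within [0.03, 0.07].

One subtlety: the cohort generator's noise is multiplicative (lognormal),
so group SDs scale with group means and stiffness *ratios* have homogeneous
variance on the log scale, not the raw scale.  Comparisons of ratio
trajectories are therefore run on $\log$ ratios, where the parametric
Dunnett route is the correct one.

## What the synthetic data do and do not emulate

`generate_phantom()` builds a pulsating circular lumen with sinusoidal
pressure $p(t) = \bar p + A \sin(2\pi t / T)$, a linear pressure-radius law
$r = r_0 (1 + (p_{\mathrm{lag}} - p_{\min})/E)$, an optional pure phase lag
(which opens the loop, as wall viscoelasticity does), i.i.d. radial vertex
noise, and pressure noise.  Defaults are a venous regime: 8 mm lumen,
10 ± 3 mmHg, 1 s period, 30 Hz for two cycles, 64 vertices (frame rate and
duration are not constrained by any published acquisition, so they are
configurable).  `rasterize_frames()` renders B-mode-like frames (dark
lumen, bright wall, multiplicative speckle) and `segment_lumen()` recovers
contours by casting rays from the intensity-weighted lumen centroid to the
maximum outward gradient, with parabolic subpixel refinement.

`generate_cohort()` draws per-animal moduli lognormally (moduli are
positive; scatter is multiplicative) around a specified ratio trajectory,
defaulting to 7 animals at 0, 1, 2.5, 6, 12, 24 months with ratio means
7.3, 2.3, 1.1, 1.0, 1.4, 1.1 — the remodeling regime of a caval graft whose
stiff scaffold resorbs within months.  Default CVs (15% between animals, 5%
measurement) are ordinary biological and instrumental scatter for such
measurements and were fixed once at those values.

What this machinery does *not* emulate: RF-level speckle physics,
non-circular or locally remodeling lumens, 3-D geometry, catheter motion,
or respiratory modulation of venous pressure.  Passing the recovery suite
therefore shows the estimators are correct for star-shaped pulsating lumens
under realistic point noise — not that segmentation would survive genuine
IVUS image quality.

## Numerical choices and degenerate inputs

* Strain-to-modulus recovery is validated on a seeded grid
  ($E \in \{10, 50, 200\}$ mmHg/strain, lag $\in \{0, 0.3\}$ rad, 2% vertex
  noise, 20 seeds each; frames at 40 Hz so the grid hits the exact
  diastolic phase); the median relative error must stay below 5%.
* Zero strain range raises a degenerate-loop error rather than returning
  `Inf`; equal baseline moduli raise an undefined-score error (the RS
  denominator vanishes); thresholds never crossed raise not-crossed errors.
* A constant decay series fits $k = 0$ and reports an undefined (`NA`)
  half-life.
* Segmentation declares failure when ≥ 10% of rays find no gradient above
  10% of the frame's intensity range; isolated ray failures are filled by
  angular interpolation.
* All generators take mandatory seeds and never touch the global RNG
  state (`withr::with_seed`).
* Problem sizes in the shipped tests (80-frame phantoms, 160 px frames,
  200-replicate variance comparisons, 2000-replicate calibration) were
  chosen as the smallest sizes at which the asserted properties are stable.

## Units

mm (contours and radii), mmHg (pressure), mmHg per unit strain (moduli),
seconds (acquisition time), weeks (degradation), months (cohort
follow-up), percent (RS).

## A worked run

```{r, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "vesselastica")
manifest <- run_pipeline(cfg, output_dir = "run1")
manifest

deg <- load_printed_degradation()
time_to_fraction(deg$strength, 0.5)   # ~2.20 weeks to half strength
first_time_below(deg$strength, 0.1)   # week 9: strength effectively gone

rs <- cohort_rs(generate_cohort(cohort_spec(seed = 1)))
rs_summary(rs)
```
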