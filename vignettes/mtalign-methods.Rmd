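---
title: "Microtubule self-organization and image-based alignment quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microtubule self-organization and image-based alignment quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtalign)
```

## The scientific question

Interphase microtubules (MTs) in many epithelial cells form arrays aligned
with the cell's long axis.  `mtalign` implements, in one package, the two
computational halves of the argument that *cell shape alone* can organize
such arrays:

1. a stochastic simulator of MT growth in a 2D cell of prescribed
   eccentricity, with angle-dependent collision rules, which asks whether
   purely physical interactions suffice to align MTs; and
2. an automated image-analysis pipeline that quantifies MT alignment (MTSD)
   and its deviation from the cell axis (MTDEV) from fluorescence images
   and per-cell label masks, so the same statistics can be extracted from
   experiments, from simulations, and from synthetic ground-truth images.

A synthetic-data generator connects the two: images with known angular
statistics validate the quantifier, and rendered simulation snapshots close
the simulate-then-quantify loop.

## The dynamic-instability model

Each MT is a 1D polymer of 8.2-nm tubulin dimers nucleated at a fixed seed
on the cell periphery, evolving as a continuous-time Markov chain.  A
growing MT of length $n$ (state $A_n$) adds a dimer at rate $\alpha$ or
switches to shrinking at the catastrophe rate $\beta'$; a shrinking MT
(state $B_n$) loses a dimer at rate $\beta$ or is rescued at rate
$\alpha'$.  Default non-dimensional rates are $\alpha = 1000$,
$\beta = 3500$, $\alpha' = 4$, $\beta' = 1$.  The dimensional factor $R$
(s$^{-1}$) is fixed by matching the model growth speed
$\alpha \cdot 8.2\,\mathrm{nm} \cdot R$ to the observed $0.15\,\mu$m/s,
giving $R = 0.01829\,$s$^{-1}$; `dimensionalize()` reports the per-second
rates and converts simulation time to seconds (non-dimensional time 10
corresponds to about 550 s).

A fully depolymerized MT sits at its seed in the shrinking state until a
rescue event re-nucleates it, whereupon it grows in a fresh direction drawn
uniformly from the inward half-plane.  This is the strict reading of the
$B_0$ state.  We also implemented the alternative (immediate regrowth after
reaching zero) and found it makes the standing mass of young,
randomly-oriented MTs scale with cell size, so that the MTSD-versus-
eccentricity relations of 492-nm and 984-nm cells separate by about 5
degrees; with the strict $B_0$ dynamics the two cell sizes follow
statistically indistinguishable relations, which matches the observed
size-invariance of MT alignment.  This choice is therefore part of the
model, not a tuning knob.

### Geometry

The sub-apical domain is a rectangle whose short side (`width_nm`, default
492 nm = 60 dimers) is fixed while the long side is
$\mathrm{width}/\sqrt{1-e^2}$, the moment-equivalent-ellipse aspect ratio
at eccentricity $e$.  An isosceles-trapezoid variant of equal area is
available (`shape_kind = "trapezoid"`).  `n_seeds` (default 220) seed
sites are placed at equal arc length along the perimeter; each stores its
wall tangent and inward normal.  Seeds are inset 0.5 nm into the domain so
that a wall-parallel MT is never exactly collinear with the wall — without
the inset, floating-point coincidences let wall-hugging MTs step through
the boundary undetected.

### Collision rules

When a growing tip's one-dimer step crosses another MT or the boundary,
the acute axial angle $\theta$ between the tip direction and the target
tangent decides the outcome.  Under the full `angle_dependent` rules:

* $\theta < \theta_{\mathrm{critical}}$ (30°): catastrophe with probability
  $P = \theta/\theta_{\mathrm{critical}} \times p_{\mathrm{cat}}$
  ($p_{\mathrm{cat}} = 0.01$), otherwise the MT *zips*, bending to grow
  parallel to the target (the polyline gains a segment; bundles form);
* $\theta \ge \theta_{\mathrm{critical}}$, MT target: catastrophe with
  probability $p_{\mathrm{cat}}$, otherwise the MT crosses over;
* $\theta \ge \theta_{\mathrm{critical}}$, boundary: catastrophe, always.

$\theta$ exactly at the critical angle takes the steep branch.  Three
reduced rule sets reproduce the model-development sequence:
`stabilize_no_cross` (MT–MT catastrophe, boundary stabilization — arrays
align with the *short* axis), `cross_stabilize` (crossover + boundary
stabilization — a stable mesh), and `cross_boundary_cat` (crossover +
boundary catastrophe — improved alignment but no bundles).  A stabilized
("paused") tip stops polymerizing but remains subject to spontaneous
catastrophe; `frozen_pause = TRUE` freezes it entirely.

### Event scheme and numerics

The simulator is an exact Gillespie algorithm over the aggregate rate
(growing: $\alpha + \beta'$; shrinking: $\beta + \alpha'$; paused:
$\beta'$), implemented in C++.  Each growth event advances one dimer and
tests the traversed sub-segment against the four boundary edges and every
other MT's segments.  Because wall-hugging bundles stack within a dimer of
the wall, a single step frequently crosses *several* targets; intersections
are resolved in order of distance along the step, a crossover proceeding to
the next intersection.  Resolving only the nearest intersection is not
merely inaccurate — it lets a crossover tunnel through the wall behind a
bundle, and escaped MTs grow without bound.  Two further numerical guards
matter on the exact 8.2-nm lattice that wall bundles live on: intersection
parameters are accepted up to $1 + 10^{-9}$ of the step (a crossing landing
within floating-point epsilon of a step end must be caught in that step),
and a containment backstop resolves any residual outside-tip as the
boundary collision it geometrically is.  Collisions at axial angles below
$10^{-6}$ degrees are ignored as parallel.  Zipping redirects the tip
without advancing it; ties at exactly 90° take the tangent representative
in $[0, 180)$.

### Outputs and statistics

The length-weighted axial direction histogram (180 one-degree bins) is
sampled every 0.01 time units until `t_end = 10`.  The final MTSD is the
axial Von Mises $\sigma$ of the histogram averaged over the trailing 2.5
units (250 samples).  The MTSD *time series* is, by default, computed on a
trailing 2.5-unit pooled histogram as well — a single 0.01-unit snapshot
is a shot-noise-dominated estimate whose fluctuations exceed ±10% of the
mean indefinitely, so a convergence analysis on raw snapshots measures the
last noise excursion rather than array relaxation
(`series_window = sample_dt` recovers the raw series).
`detect_convergence()` reports the first time the series enters and
remains within ±10% of its long-run stable value (the mean over the final
window); with default settings full-rule runs at eccentricities 0.7–0.9
converge within roughly 100–400 s.  `sweep_eccentricity()` runs the
width × eccentricity grid (three runs per point by default, deterministic
per-run seed offsets) and, when two widths are given, compares the
MTSD–eccentricity relations with the extra-sum-of-squares shared-line test
at run level, so the test sees the run-to-run variance.

Simulated MTSD decreases monotonically with eccentricity (about 50° at
$e = 0.7$ down to about 33° at $e = 0.95$ with default parameters), the
main direction lies along the long axis, and the relation is shared
between 492-nm and 984-nm cells.  The absolute levels sit somewhat above
the values reported for comparable in-vivo arrays; the trend, orientation,
rule-set contrasts, convergence window and size-invariance are the
reproducible content.  The collision event log, tabulated by
`collision_angle_summary()` into the 10–30°, 31–60° and 61–90° classes
used for live-imaging collision calls, provides the in-silico analogue of
observed boundary-collision statistics.

## The image-quantification pipeline

`quantify_cells()` maps a grayscale image plus an integer label mask to one
row per cell:

1. optional maximum-intensity projection of a z-stack;
2. percentile contrast stretch (0.5% of pixels clipped at each end);
3. convolution with two separable 5×5 Sobel operators (smoothing
   $[1,4,6,4,1]$ ⊗ derivative $[-1,-2,0,2,1]$), giving the gradient
   magnitude $M = \sqrt{G_x^2 + G_y^2}$ and direction
   $D = \operatorname{atan2}(G_y, G_x) \bmod 180°$;
4. per cell: the mask is eroded by the kernel half-width (2 px) so mask
   boundaries do not inject spurious directions (gradients are computed
   once on the full frame); pixels with $M$ below 22% of the within-cell
   maximum are discarded; the remaining directions are rotated by 90°
   (gradients are perpendicular to filaments), binned at 4°, and weighted
   by $M$;
5. the axial Von Mises fit of that histogram gives the MT main direction
   $\mu$ and the MTSD $\sigma$; the cell's moment-equivalent ellipse gives
   eccentricity, aspect ratio and orientation; MTDEV is the acute axial
   angle between $\mu$ and the ellipse orientation.

Cells with fewer than 50 usable pixels are flagged.  `quantify_field()`
runs the identical pipeline with the whole frame as one mask (threshold
relative to the field maximum), and `quantify_timelapse()` applies the
per-cell analysis frame by frame for plus-end trajectory movies.
`fourier_directionality()` is the independent cross-check: spectral energy
of the Hann-windowed power spectrum binned by orientation (rotated 90° to
real space, restricted to the inscribed circle of the spectrum so white
noise is flat).

### Axial circular statistics

All direction data are axial (period 180°).  `fit_axial_von_mises()`
doubles the angles, computes the weighted circular moments over bin
centres, and reads the fit off in closed form:
$\mu = \tfrac12\operatorname{atan2}(S, C)$ and
$\sigma = \min(90, \tfrac{90}{\pi}\sqrt{-2\ln \bar R})$, with $\kappa$
from the standard moment inverse.  The moment estimator exactly inverts a
wrapped-normal generator, which is what makes the validation design
recoverable; an empty histogram reports the unaligned convention
($\sigma = 90$, $\mu$ undefined).  Deterministic closed-form fitting was
preferred to iterative maximum likelihood: it has no convergence failures
and is equivalent at the tolerances used.

## The synthetic-data generator

`generate_line_image()` renders `n_lines` (default 100) anti-aliased
straight lines through anchors drawn uniformly inside an elliptical cell,
at angles from a normal distribution with chosen s.d., wrapped to
$[0,180)$.  The default line length is fixed (the geometric mean of the
cell semi-axes, clipped to the cell): a fixed length keeps line length
uncorrelated with angle, so the length-weighted ground truth
(`ground_truth_mtsd()`) is an unbiased estimate of the generating s.d.
Full chords (`line_length = "chord"`) are available, but chords in an
elongated cell are systematically longer along the long axis, which
narrows the length-weighted distribution by up to a third at $e = 0.98$.
Every image ships with its label mask and machine-readable line table, so
quantifier error is always computable.  Ten-seed averages of the pipeline
MTSD at the validation design (eccentricity/s.d. pairs (0.7, 40°),
(0.8, 30°), (0.92, 22°), (0.98, 22°) — pairs chosen so MTSD falls as
eccentricity rises; the design table is user-replaceable) recover the
generating s.d. within a few percent, and the Fourier cross-check agrees
with the Sobel pipeline within 15%.

`render_simulation()` rasterizes final MT polylines additively (bundled
MTs are proportionally brighter), convolves with a 1-px Gaussian
point-spread function (which also suppresses an axis-ward rasterization
bias of thin lines), and applies a detector-saturation step, by default
auto-exposed to the 90th percentile of occupied-pixel intensity.  The
saturation step matters: with unbounded dynamic range the quantifier's
relative magnitude threshold sees only the brightest bundles.  The
matching internal statistic for a rendered final state is `mtsd_frame`
(the final snapshot's MTSD), not the trailing-window average.
`generate_cell_field()` tiles cells with controllable long-axis
orientation dispersion, emulating young (dispersed) versus late
(co-aligned) epithelial fields: with dispersed cell axes the whole-field
MTSD exceeds the cell-by-cell mean, which is the argument for cell-by-cell
analysis.

## What the synthetic data do and do not show

The generator emulates straight filaments of uniform brightness with
ideal masks and optional Gaussian read noise.  It does not emulate SIM
reconstruction artefacts, out-of-focus background, intensity
inhomogeneity, curved filaments, or segmentation errors in the masks.
Passing recovery tests therefore demonstrate correctness of the gradient
statistics and fitting, not robustness to every imaging artefact; on real
data the eroded masks and magnitude threshold are the main defences, and
the whole-field/cell-by-cell and Sobel/Fourier agreements are the
practical sanity checks.

## Problem sizes used in the tests

Module-level tests run reduced simulations (typically 40–60 seeds, 1.5–3
time units); the headline behavioural checks run the full default
conditions (220 seeds, `t_end = 10`, three runs per point, both cell
widths), which complete in a few minutes.  The quantifier checks use
256-px images with 100 lines, ten seeds per condition.

## Known limitations

* The simulator's absolute MTSD level depends on implementation details
  the underlying model leaves open (exact domain outline, zip geometry,
  re-nucleation); comparisons should be made on trends and contrasts.
* Bundle occupancy is not tracked as an explicit counter; it is expressed
  through additive rendering.
* Zipped MTs never unzip, and bundle members are treated individually in
  collision detection.
* The trapezoid domain is provided for shape exploration but the default
  analyses use the rectangle; printed areas of a trapezoidal sub-apical
  domain are not reproduced by either primitive.
* The pipeline assumes one label per cell; segmentation itself is out of
  scope.
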