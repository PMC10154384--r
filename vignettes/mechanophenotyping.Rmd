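---
title: "Single-cell mechanophenotyping: models, estimators and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell mechanophenotyping: models, estimators and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechphen)
```

mechphen implements four single-cell mechanophenotyping pipelines — traction
force microscopy on elastic micropillars, magnetic-tweezers mechanosensing,
AFM nanoindentation with a spherical probe, and basement-membrane
transmigration — together with the group-comparison statistics conventional
in this field, and a ground-truthed synthetic-data generator for all four
assays. This vignette explains the underlying models, the estimators and
their numerical choices, what the generator does and does not emulate, and
the design decisions that were genuinely open.

## Micropillar traction force microscopy

Each PDMS micropillar behaves as an independent linear spring: a cell pulling
on a pillar top deflects it by $\delta$ and exerts force
$F = k\,\lVert\delta\rVert$, with the calibrated spring constant
$k = 1.36$ nN/µm as the package default. The pipeline has four stages.

**Detection.** Pillar tops appear as diffraction-blurred bright spots,
modelled as symmetric Gaussians with $\sigma =$ diameter/4. Candidate spots
are strict local maxima above `median + max(0.25·(max − median), 5·MAD)`;
the MAD term suppresses spurious noise maxima. Each candidate is refined by
an *iterative Gaussian-windowed centroid*: intensity-weighted centroid with
Gaussian weights recentred at the current estimate. The fixed point of that
iteration is the true centre for a Gaussian spot, so the estimator is
unbiased, and it empirically attains the per-axis information bound
$(\text{noise}/\text{amplitude})\sqrt{2/\pi}$ px — about 0.08 px per axis at
a peak signal-to-noise of 10. Note that the corresponding *radial* error
bound is $\sqrt{2}$ larger (≈0.11 px); no estimator can do better radially,
which is why the package quotes per-axis precision.

**Reference lattice.** A cell is attached from the first frame, so no
force-free frame exists. Undeflected reference positions are instead
extrapolated from pillars *outside* the cell mask: a 1-D rotation search on
wrapped fractional-coordinate residuals, followed by linear least squares for
the lattice origin and basis vectors on the integer node assignment. At least
6 free pillars are required. Nodes under the cell keep their ideal positions
— never the observed (deflected) ones.

**Tracking.** Every frame is detected independently and centroids are linked
to lattice nodes by nearest-reference assignment within half a pitch.
Missed detections are recorded as missing and never interpolated. During
tracking the minimum-separation rule for accepted maxima is relaxed from half
a pitch to the optical resolution limit (2.5 σ), because pillars deflecting
towards the cell centre legitimately approach each other.

**Summary.** "Mean maximum traction" is computed as the per-frame maximum
pillar force over pillars under the cell, averaged over frames — one scalar
per cell, matching summaries reported per cell over one-minute videos at
1 frame/s. The alternative (a cell's single global maximum) is available
from the per-frame series; the time-averaged default is used everywhere.

The pillar pitch and spot diameter are not universal constants; the defaults
(6 µm pitch, 2 µm spots, 0.3 µm/px) are configurable assumptions chosen so
that cohort-scale deflections (up to a few µm at nN-scale forces) stay within
the half-pitch assignment radius.

## Magnetic-tweezers mechanosensing

The force protocol is a 3 s, 6 nN pulse followed by 4 s rest, repeated 12
times (~100 s including margins). A cell that stiffens under repeated load
("reinforcement") shows decreasing per-pulse bead displacement; the
12th-to-1st amplitude ratio is the mechanosensing readout.

The amplitude of pulse $i$ is defined as the maximum bead displacement
projected on the force axis during the on-window minus the median projected
displacement over the final 1 s of the preceding rest, clipped at zero.
Peak-minus-baseline with a median baseline is robust to tracking noise and to
slow drift; the clip encodes that movement against the applied force is
noise. The force axis is taken from the tweezers geometry (recorded by the
generator); no axis estimation is attempted. The first-pulse onset $t_0$ is
metadata, not detected.

Two properties follow directly: relative amplitudes are invariant to scaling
the trajectory, and drift ≤ 0.01 µm/s moves the extracted ratio by well under
5%. One caveat is quantified in the tests rather than assumed: with ~31
samples per on-window, the max-based amplitude of a *pure-noise* window is
≈ 2 × the tracking noise SD in expectation and exceeds 3 SD in ~7% of
windows, so amplitudes at the few-nm scale should not be over-read.

The cohort-level test pairs each cell's 1st and 12th absolute amplitudes in a
two-sided Wilcoxon signed-rank test; all-zero differences return the
degenerate p = 1.

## AFM nanoindentation (spherical Hertz model)

For a rigid sphere of radius $R$ on an elastic half-space,

$$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

with indentation $\delta = z - z_c$ past the contact point $z_c$. With $E$
in Pa and lengths in µm the force is in nN after a factor $10^{-3}$. The
defaults are $R = 7.5$ µm (half of a 15 µm polystyrene bead) and $\nu = 0.5$
(incompressible cell); both are arguments.

The fit proceeds in three stages. (1) *Baseline correction*: a straight line
fitted to the leading pre-contact fraction of samples (default 20%) is
subtracted — this removes instrument drift and is idempotent. (2) *Contact
detection*: candidate contact points on the sample grid are scored with a
piecewise model — zero force before contact, Hertz after — with the modulus
profiled out by least squares on the small-indentation window and the model
extrapolated over the full post-contact range so all candidates score on the
same domain. A coarse-then-fine grid search returns the minimiser, or a
no-contact flag when no candidate with positive modulus beats the flat
model. Grid minimisation was chosen over derivative thresholding because it
stays robust at ~1 nN force set points. (3) *Modulus fit*: the model is
linear in $E$, so the windowed least-squares estimate is closed-form; the
window is capped at 10% of the probe radius to respect the small-indentation
validity of the Hertz form. Fits with fewer than 20 window samples or
non-positive modulus report `converged = FALSE`.

On noiseless synthetic curves the fit recovers the generating modulus
exactly and the contact point within one z-step (0.01 µm default); at 5%
force noise the estimator is unbiased within ~1% with an SD of roughly 1.3%
per curve.

## Basement-membrane transmigration

Percent invasion of one cell is

$$100 \times \mathrm{clip}\!\left(\frac{z_{\text{bilayer}} - z_{\text{bottom}}}
{z_{\text{top}} - z_{\text{bottom}}},\, 0,\, 1\right),$$

the fraction of the cell's axial extent below the laminin bilayer, clipped
for cells entirely above or below the plane. The z axis increases from the
invaded side towards the seeding side; "below the bilayer" means smaller z.

The bilayer position is the intensity-weighted centroid of the laminin
z-profile within a window around its global maximum (exact for a symmetric
peak; profiles without a dominant peak are rejected). The cell extent comes
from the actin z-profile: background-subtracted, thresholded at a fraction
of its maximum, with linear interpolation between slices.

**Threshold choice.** The default threshold is 0.5 (half-maximum). For any
symmetric edge-spread profile the half-maximum crossing is the unbiased edge
estimator; a low threshold such as 0.1 systematically widens the extent by
~1.3 edge-widths per side, which alone would push a cell at 75% true
invasion more than one percentage point off. Half-maximum keeps the
end-to-end error below 0.1 points on noiseless stacks across the full
0–100% range. The threshold remains a user argument for profiles with
asymmetric tails.

**Cortical-shell rendering.** The synthetic actin channel renders the cell
as a spherical *shell*, because f-actin concentrates at the cortex. This is
not merely cosmetic: the surface-band area of a sphere per unit z is
constant, so the lateral-mean z-profile of a cortical shell is a top-hat
with soft (erf) edges whose half-maximum crossings sit exactly at the cell
top and bottom — precisely the geometry the half-maximum estimator assumes,
and a good description of how a real phalloidin cross-section reads out. A
solid-ellipsoid rendering would instead give a parabolic profile whose
apparent extent depends strongly on the threshold.

Cumulative invasion is a per-ROI running sum of daily counts (missing days
are rejected, never imputed). Condition slopes come from per-condition OLS
of cumulative count on day; pairwise slope differences are tested via the
day × condition interaction of a pooled linear model, which is what "testing
the difference between regression slopes" means operationally.

## Group-comparison statistics

The decision scheme mirrors standard practice in this literature: Shapiro–
Wilk per group at α = 0.05 (the normality test is rarely named in papers;
Shapiro–Wilk is the default choice), Levene's test for variance homogeneity,
then: two groups — t-test (Welch if variances differ) or Mann–Whitney; three
or more — ANOVA (Welch/Brown–Forsythe correction if variances differ) or
Kruskal–Wallis. Post-hoc procedures follow the branch: Tukey over all pairs,
Dunnett against a designated reference, or Dunn's rank-based comparisons
(implemented in-package with tie correction) Holm-adjusted. Because figure
legends sometimes prescribe the procedure explicitly, both the branch and
the post-hoc method can be forced rather than inferred.

Two behavioural notes, both covered by tests: the probability that $k$
truly-normal groups all pass the Shapiro gate is $0.95^k$ (≈ 86% for three
groups), and the paired Wilcoxon applied to lognormally distributed
amplitude ratios centred on mean 1 rejects slightly above nominal (~8% at
n = 41) because such ratios have median below 1 — a real property of the
paired design, not an implementation artefact.

## The cohort generator and what passing tests mean

Published cohort summaries (mean ± SEM, n) parameterise per-cell truths:
lognormal with matched mean and SD = SEM·√n for forces, moduli and amplitude
ratios (guaranteeing positive support — at the published dispersions a
Gaussian would generate negative forces), and a moment-matched beta for
below-bilayer fractions, which live in [0, 1]. Per-pulse amplitude schedules
interpolate linearly between the 1st and 12th pulse, the only two points the
summaries constrain. The acquisition frame rate (10 Hz), creep exponent,
rest-phase recovery fraction, spot intensities and noise levels are
realistic defaults, stated in the function signatures and configurable.

Every generator draws from one explicitly seeded stream and stores the exact
simulated truths (deflection fields, amplitude schedules, modulus and
contact point, geometric invasion fraction) alongside the data, so each
pipeline stage can be scored against ground truth; identical seeds reproduce
datasets bit-exactly.

Cohort sizes in the recovery experiments are the published ones (70/53/87
cells for traction, 91/58 for stiffness, 41/22 for mechanosensing), with
single-cell videos of 128 × 128 px × 60 frames; a full traction cohort
analyses in about a minute on one CPU.

Limits to keep in mind: the generator emulates the *statistical* structure
of the assays, not their physics — no PDMS finite-element mechanics, no
optical point-spread function, no cell-shape morphodynamics, no bead-cell
coupling model. Recovery of a generated cohort therefore demonstrates that
the estimators are unbiased and correctly calibrated under the stated noise
model; it does not validate, e.g., pillar bending beyond the linear spring
law or viscoelastic corrections to the Hertz fit on real cells. Because the
per-cell spread model is lognormal with CV near 1 for some conditions, a
cohort's *sample* mean scatters around the published value with SD equal to
the published SEM — recovered means should be read against that band, and
the acceptance checks do exactly that.
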