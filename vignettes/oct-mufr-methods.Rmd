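---
title: "Computing muQFR and OCT-muFR: model, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing muQFR and OCT-muFR: model, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(octmufr)
```

# The problem

Wire-based fractional flow reserve (FFR) — the ratio of distal coronary to
aortic pressure under hyperemia — is the reference standard for deciding
whether a coronary stenosis limits flow (FFR of 0.80 or below), but it
needs a pressure wire and a vasodilator. Computational surrogates estimate
the same ratio from imaging alone. This package implements two of them on
a common one-dimensional core:

* **muQFR** — from a single angiographic projection: a lumen-diameter
  profile along the vessel centerline, with side branches summarised by
  their ostial diameters.
* **OCT-muFR** — the same computation after the segment covered by an
  optical coherence tomography (OCT) pullback replaces the angiographic
  lumen. OCT resolves the lumen far better than angiography (and images
  the vessel wall), so the geometry feeding the pressure model is more
  trustworthy where the pullback reaches.

Both return a *pullback curve*: the modelled pressure ratio at every
arc-length position, 1.0 at the ostium and non-increasing distally; the
value at the distal evaluation position is what gets compared with FFR.

# Model

## Reference vessel and Murray step-downs

The "reference" diameter `d_ref(s)` is the caliber the vessel would have
without disease. We model it as one linear taper per inter-bifurcation
segment, stepping down across each bifurcation by Murray's fractal law

    d_prox^e = d_dist^e + d_sb^e,     e = 3 by default,

where `d_sb` is the side-branch ostial diameter. Healthy evidence comes
from two sources: samples whose diameter reaches the local upper envelope
(window 10 mm, quantile 0.75, with a 2% caliber tolerance absorbing taper
across the window and measurement noise; windows are clipped at
bifurcations), and — where OCT media is available — samples whose plaque
burden is low (`lumen/media >= 0.6`). Where media exists it contributes
the *media-derived* diameter as reference evidence: the external elastic
lamina encloses the non-diseased lumen, which is exactly the extra
information OCT adds over angiography.

Rather than fitting each segment independently (which cannot satisfy
Murray's relation exactly at the steps), the fit normalises every healthy
diameter by the cumulative Murray factor of its segment, fits **one**
robust line to the normalised data, and multiplies back; the factors are
iterated to a fixed point. Every segment stays linear, segments without
healthy evidence inherit the propagated reference automatically, and each
step is Murray-exact by construction.

The robust line itself is a high-breakdown upper-envelope fit: candidate
lines through pairs of well-separated points are scored by how many
samples they collect within a 3% band *minus* twice the number of samples
above them (an envelope has nothing above it), and the best candidate is
polished by least-absolute-deviation regression on its inliers, with
one-sided trimming iterated alongside the Murray factors. Plain L1
regression is not enough here: a diffuse lesion wider than the detection
window flags its own interior as locally healthy and, sitting at one end
of the vessel, acts as leverage contamination.

## Flow

Contrast velocity comes from the TIMI frame count: `v = L / (n / fps)`,
with `L` the ostium-to-evaluation-point length and `n` the (possibly
fractional) frame count. Conversion to hyperemic velocity is a single
configurable multiplier (default 1.33, capped at 500 mm/s); the published
conversion is empirical and not reproducible from its description, so the
multiplier is exposed and documented as a stand-in — none of the package's
numerical guarantees depend on its value. Inlet flow is the hyperemic
velocity times the reference area at the ostium. At each bifurcation the
side branch takes the Murray fraction `d_sb^e / (d_sb^e + d_dist^e)`
computed against the distal-main *reference* diameter, so a stenosis next
to a branch does not distort the split; flow is exactly conserved.

## Pressure loss

Over the fused geometry resampled at `grid_step` (0.1 mm default) the
cumulative drop is

* **viscous** (Poiseuille): `int 128 mu Q(u) / (pi D(u)^4) du`, integrated
  in closed form over each conical cell of the measured profile, so the
  result does not depend on the reporting grid;
* **separation** (Borda-Carnot): lesions are maximal runs with
  `lumen area < 0.98 x reference area`, bounded by bifurcations; at each
  run's distal shoulder the drop jumps by
  `(rho K / 2) (Q_jet/A_min - Q_rec/A_rec)^2` with `K = 1` by default.

The pullback value is `(Pa - dP(s)) / Pa` at the configured aortic
pressure. Side-branch values are the main-vessel value at the bifurcation
minus one ostial separation element (side-branch ostial lumen against its
Murray-implied reference).

Defaults the underlying publications do not state and that are therefore
package parameters: aortic pressure 90 mmHg, blood viscosity 0.0035 Pa s,
density 1060 kg/m^3 — conventional values, all configurable.

# Numerical choices

Three details matter for grid-independence and for agreement with a
fine-grid oracle, all visible in `pressure_drop_profile()`:

* the viscous integral is evaluated on the *original* geometry nodes
  (plus flow-segment boundaries), exactly per conical cell;
* the minimal lumen area of a lesion is refined by a parabola through the
  three measurement samples around the discrete minimum (a sampled
  profile cannot dip below its nodes, biasing `A_min` high for deep
  narrow lesions), restricted to the run's own flow segment, and — for
  runs cut by a bifurcation — compared against the area at the exact
  boundary;
* the recovery area is interpolated at the exact lesion-threshold
  crossing (or the exact bifurcation position), not read off the grid.

With these, halving the grid step moves the distal value by well under
1e-4, and the whole pipeline tracks a 0.01 mm-grid oracle to a few 1e-4
on noise-free synthetic vessels.

Degenerate inputs: a run reaching the distal end of the vessel recovers
nowhere and contributes no separation loss; the reference is clipped
below at half the largest observed diameter; values are floored at 1e-6;
ties in the envelope-fit candidate search resolve to the first (the
search is fully deterministic).

# Coregistration and fusion

The OCT pullback axis is mapped onto the angiographic centerline by a
monotone piecewise-linear warp through the matched landmarks (linear
extrapolation at the ends); image-based coregistration is out of scope,
and landmark editing stands in for manual correction. Inside the mapped
interval the lumen is the OCT circular-equivalent diameter; outside, the
angiographic diameter; within a 1 mm blend window of each junction the
two are linearly cross-faded, which avoids spurious separation losses at
the junctions while preserving true stenosis edges (a zero window is
allowed and produces a step the loss model treats like any abrupt
expansion). One pullback per case is supported.

# What the synthetic generator emulates

`vessel_spec()` / `make_case()` build vessels with a linearly tapering
reference, Murray-consistent bifurcations whose caliber steps down
smoothly across the branch ostium (a linear transition as wide as the
side branch — real arteries do not change caliber discontinuously),
Gaussian diameter dips as stenoses (`severity` maps directly to true
DS%), angiographic samples every 0.2 mm with optional Gaussian diameter
noise, OCT frames every 0.2 mm with area noise and media at the true
reference size, landmarks at the coverage ends and interior bifurcations,
and a TIMI frame count derived from an assumed contrast velocity. The
ground truth comes from a 0.01 mm-grid oracle evaluated on the true
geometry with the true reference and flow — bypassing sampling, fusion,
healthy detection and reference fitting, which is exactly what makes it a
useful oracle for those stages. The pressure integrator itself is shared
between oracle and pipeline; it is validated separately against
closed-form Poiseuille and Borda-Carnot solutions.

`random_vessel_spec()` draws lengths 40-70 mm, inlet diameters
2.8-3.8 mm, tapers 0.005-0.025 mm/mm, 0-2 bifurcations, 1-2 stenoses of
severity 0.2-0.7 (tandem stenoses kept apart by normal segments, matching
how tandem lesions are defined clinically) and contrast velocities
150-300 mm/s. `make_cohort()` draws a positive/negative class per vessel
(prevalence 0.45 by default), then a target true distal value from a
two-component mixture around the 0.80 cutoff chosen to mimic an FFR
distribution of roughly 0.81 +/- 0.11, and solves the stenosis severity
by bisection against the oracle; the wire reference is the oracle value
plus Gaussian noise (sd 0.03, the scale of reported wire-vs-computation
SDs of difference). Every stochastic element derives from one seed.

What the generator deliberately does **not** emulate: image artifacts,
eccentric or non-circular lumina, coregistration error beyond what the
landmark warp can express, vessel curvature, pulsatility, or any
plaque-morphology realism beyond the plaque-burden ratio. Passing tests
on this generator therefore demonstrate the internal consistency and
numerical fidelity of the method, not clinical accuracy on real images.

# Problem sizes used by the tests and the acceptance script

Fifty random specs for oracle agreement; twenty single-lesion specs for
DS% recovery; a 60-vessel noise-free cohort for the AUC sanity check and
a 120-vessel noisy cohort for the Table-3-style evaluation; 10^4
replicates per operating point for the Clopper-Pearson coverage
simulation. These sizes give stable results at desk scale while keeping
a full run in the low minutes.

# Statistical machinery

All estimators are written out in `R/diagnostics.R`: exact binomial
(Clopper-Pearson) CIs for the proportion metrics, log-method CIs for the
likelihood ratios, Mann-Whitney AUC with tie correction and DeLong
structural-component variance (cross-checked in the tests against pROC
and a brute-force grouped jackknife), Bland-Altman with an F-test on the
SDs of paired differences, ICC(A,1) from the two-way mean-squares
decomposition, and Steiger's z for dependent overlapping correlations.
The published ICC comparison used an unnamed online tool; Steiger's test
is the standard equivalent and is not claimed identical. Accuracy
comparison defaults to the chi-squared test on correct/incorrect counts
(as published) with a paired McNemar variant exposed, since the designs
being compared are applied to the same vessels.

# Worked example

```{r example, fig.width = 7, fig.height = 5}
spec <- vessel_spec(
  length = 50, inlet_diameter = 3.3, taper = 0.015,
  stenoses = data.frame(center = 24, width = 2.5, severity = 0.55),
  bifurcations = data.frame(s = 15, sb_diameter = 1.8),
  oct_coverage = c(2, 46), angio_noise_sd = 0.02, oct_noise_sd = 0.05,
  seed = 7)
cs <- make_case(spec)

fit_oct <- mufr(cs$case, mode = "fused")
fit_ang <- mufr(cs$case, mode = "angio_only")
fit_oct
c(oct_mufr = fit_oct$distal_value, muqfr = fit_ang$distal_value,
  oracle = cs$truth$distal_value)
plot(fit_oct)
```

# Known limitations

* The pressure model is 1-D and steady; diffuse disease with no healthy
  segment anywhere leaves the reference underdetermined (an explicit
  error), and severely diseased vessels without OCT media rely entirely
  on the envelope heuristics.
* The hyperemic multiplier is a stand-in for an empirical conversion.
* Side-branch values use a single ostial separation element — a minimal
  interpretation that is exact only when the ostium itself is the only
  branch lesion.
* Subocclusive vessels (true distal values below about 0.1) push the
  separation term into a regime where any finite measurement sampling
  visibly limits accuracy.
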