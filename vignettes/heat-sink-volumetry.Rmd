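---
title: "Quantifying vascular cooling of microwave ablation zones: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular cooling of microwave ablation zones: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwacool)
```

## The measurement model

`mwacool` analyses serial cross sections of a hepatic microwave ablation
performed next to a perfused vessel running parallel to the antenna. Each
2 mm section contributes one traced white-zone (WZ) contour — the pale core
of irreversibly destroyed tissue, the clinically relevant ablation margin —
given as a polygon in millimetre coordinates with the antenna at the
in-plane origin and the vessel centre on the +x axis. The red zone (a
hyperaemic rim of mixed viable and ablated tissue) is carried through I/O
but deliberately excluded from all volumes.

Three ideas define the quantification:

1. **Truncated-cone volumetry.** A stack of areas $A_1 \dots A_n$ measured
   every $d = 2$ mm reconstructs the volume
   $V = \sum_i \tfrac{A_i + A_{i+1}}{2}\, d$ (a trapezoidal sum, exact for
   linearly varying cross sections). For an ellipsoid the cross-sectional
   area is quadratic in the offset, so the composite error is exactly
   $O(d^2)$; at the protocol spacing it is ~0.3% of a half-ellipsoid with
   semi-axes 18 x 16 mm (the nominal 3.6 x 3.2 cm ablation).
2. **The idealized ablation.** Cooling deforms the contour locally, so a
   per-slice reference is rebuilt from the shape itself: the half-disc of
   radius $r_\max$ (the maximum boundary distance from the antenna point).
   Only the vessel-containing half-plane enters the analysis — cooling is
   expected around the vessel, and halving isolates it from contralateral
   shape irregularities. The **cooling volume** is the truncated-cone volume
   of the idealized half-areas minus that of the measured half-areas; both
   use the same ordered slices, so ablation + cooling = idealized holds
   exactly. The **cooling portion** divides cooling volume by ablation
   volume (the convention consistent with tabulated integer percentages of
   this analysis), reported to the nearest percent.
3. **Semi-quantitative grading.** Each slice is graded Type 0 (none),
   I (minor), II (moderate, vessel still partly enclosed) or III (major,
   vessel outside the ablation). The visual scheme is operationalized with
   the indentation ratio $\iota = 1 - r(\theta_{vessel})/r_\max$ and the
   enclosure fraction $f$ (area of vessel disc inside the WZ / disc area):
   $\iota < \tau_{minor}$ is Type 0; $\tau_{minor} \le \iota <
   \tau_{moderate}$ is Type I; deeper notches grade III when $f = 0$, II
   when $0 < f < 1$, and I when the vessel remains fully enclosed (a deep
   indentation far from the vessel is not vessel cooling). Defaults
   $\tau = (0.05, 0.20)$ are a design choice — the original grading was
   visual and publishes no thresholds — so they are exposed as arguments and
   the suite requires grading to move at most one level when both thresholds
   shift by +-50% (on noise-free phantoms; see the noise caveat below).
   Type profiles are binned against $\rho = \sqrt{d^2 + z^2}$, the 3D
   distance from the vessel to the ablation centre point, because the
   vessel runs parallel to the antenna and the relevant geometry is how
   close it passes to the ablation border.

The statistical layer mirrors a small-sample bench study: exact two-sided
Mann–Whitney U tests (n = 6 per cell; the exact null distribution is
computed by dynamic programming over the pooled midranks, equivalent to
enumerating all $\binom{n+m}{n}$ assignments and valid under ties),
Kruskal–Wallis for multi-group comparisons, and a Bonferroni-adjusted
significance level of $0.05/6 \approx 0.008$ — six perfused flows compared
against the no-flow baseline within one distance — with $p \in (0.008,
0.05]$ reported as a trend. LOESS (tricube weights, local degree 1, span
0.5, 100-point grid by default) smooths type profiles; none of these
smoothing constants is canonical, so all are arguments.

The coolant energy balance is calorimetric: $m = Q \cdot t \cdot \rho_c$,
$\Delta Q = m\, c_{aqua} \Delta T$, and the absorbed fraction divides by
the applied energy (power x duration). $c_{aqua} = 4.186$ kJ/(kg K) and a
density of 1.0 g/ml are the standard water values, both overridable.

## What the phantom generator emulates

No deposited data accompany this kind of ex vivo experiment, so the package
ships a generative stand-in with analytic ground truth. One phantom is an
ellipsoidal WZ (semi-axes $a = 18$, $b = 16$ mm) whose slice at offset $z$
has the boundary

$$ r(\theta, z) = r_0(z)\,\bigl[1 - \kappa(z)\, e^{-\Delta\theta^2 / 2\sigma_\theta^2}\bigr] + \varepsilon,
\qquad r_0(z) = b\sqrt{1 - (z/a)^2}, $$

an azimuthal Gaussian notch facing the vessel, with i.i.d. radial vertex
noise $\varepsilon$. The notch depth follows

$$ \kappa(z) = \kappa_0 \cdot L\!\bigl(Q;\, Q_{50}(\rho)\bigr) \cdot
   e^{-(\rho - \rho^*)^2 / 2\sigma_\rho^2}, \qquad \rho = \sqrt{d^2 + z^2}, $$

a logistic flow response in log-flow ($L(0) = 0$, $L \to 1$ for
$Q \gg Q_{50}$, midpoint $Q_{50}(\rho) = Q_c e^{-\rho/\rho_c}$ falling with
distance from the antenna) times a Gaussian peak where the vessel passes
near the ablation border ($\rho^* = 7.5$ mm). This law is generative, not
biophysical: it encodes the qualitative behaviour the analysis must be able
to detect — no cooling without perfusion; peripheral cooling from low flows
but central cooling only at high flow when the vessel is close to the
antenna; a maximal effect near the border and decay beyond it.

The two constants the law leaves free were fixed once, by an analytic scan
against those qualitative targets before any pipeline code ran, and then
frozen: $\kappa_0 = 0.70$ and a logistic width of 0.45 in log-flow. With
the remaining defaults ($\sigma_\theta = 0.45$ rad, about the angular
extent of the vessel at mid-distance; $Q_c = 20$ ml/min, $\rho_c = 4$ mm,
$\sigma_\rho = 3$ mm) these reproduce: minor-at-most cooling at 1 ml/min,
moderate cooling near $\rho^*$ from 2 ml/min at every distance, central
cooling at $d = 2.5$ mm only from 10 ml/min, and a pooled mean-type profile
peaking within 7.5 +- 2 mm.

Realism features, and their rationale:

* **Boundary noise** (sd 0.25 mm per vertex) models sub-millimetre hand
  tracing on photographed sections calibrated with millimetre paper. A
  useful emergent property: the maximum of 128 noisy radii exceeds the true
  radius by ~0.65 mm on average, inflating the idealized half-disc and
  producing a nonzero baseline cooling portion (~10%) even at zero flow —
  exactly the behaviour real uncooled ablations show, because no real
  contour fills the half-disc of its own maximum radius.
* **Replicate scale jitter** (isotropic, linear sd 2%) gives
  ablation-to-ablation volume variability of ~6%. Without it, replicate
  volumes differ only through vertex noise (fractions of a percent) and
  every systematic difference, however tiny, becomes significant — the
  directional pattern (volume reduction detectable only for a close vessel
  at maximal flow) could not exist. The chosen level is deliberately modest
  for homogeneous ex vivo tissue; in vivo variability is larger.
* **Traceability cutoff** (`min_traceable_radius_mm`, default 5 mm): polar
  sections whose WZ falls below ~5 mm radius are not emitted. A contour of
  a couple of millimetres cannot be reliably identified and traced on a
  photographed section, and serial-section studies of this design record
  notably fewer slices per ablation than the nominal +-20 mm range allows.
  Numerically, such slices are also where vertex noise dominates the
  indentation ratio and would masquerade as major cooling at large $\rho$.

**Ground truth** for each phantom is computed from the noise-free boundary
law by numerical integration on a 0.1 mm axial x 4001-point angular grid —
independent of the measurement pipeline — over the axial span actually
sectioned. The span convention matters: serial sectioning cannot see the
polar caps beyond the outermost slice (~1.8% of a half-ellipsoid at 2 mm
spacing), and truth restricted to the sectioned span isolates method error
(trapezoidal + polygonal discretization, ~0.3%) from protocol truncation,
which is shared by any real study of this design. Enclosure ground truth is
decided exactly (all/none of a dense polar sample of the vessel disc clears
the analytic boundary with margin) and sampled only in genuinely partial
cases.

What the phantoms do *not* model: heat conduction (no bioheat/FEM), the red
zone as anything but a fixed radial margin, diffuse parenchymal-perfusion
cooling (only directional single-vessel cooling), correlated tracing errors
(noise is i.i.d. per vertex), and repeat/exclusion bookkeeping of failed
ablations. Passing the recovery tests therefore demonstrates that the
pipeline measures what the generator encodes — not that the generative law
is tissue-accurate.

## Numerical choices

* Polygons are ordered vertex matrices, implicitly closed, any orientation;
  areas are absolute shoelace values. Simplicity is certified cheaply by
  star-shapedness about the vertex centroid, with a quadratic
  segment-intersection test as fallback, so validating generated contours
  costs O(n).
* The polygon–disc intersection area (enclosure fraction) is computed in
  closed form as a signed sum of per-edge triangle and circular-sector
  contributions, not by sampling; the suite checks it against closed-form
  cases at 1e-9 and Monte-Carlo on irregular contours.
* Half-plane clipping keeps points exactly on the dividing line (the
  antenna point belongs to the vessel side); clips that leave no area are
  geometry errors.
* The boundary radius along an azimuth takes the nearest crossing and warns
  if a (slightly folded) contour yields several; only a missing crossing is
  an error. "Vessel outside" / "fully enclosed" are decided at a 1e-6
  tolerance on the enclosure fraction.
* Measured indentation on an exact circle is not exactly zero: a polygon
  chord dips below the arc by $1 - \cos(\pi/m)$ (~3e-4 at 128 vertices).
  Tests assert against this discretization floor, not against zero.
* Negative cooling areas (noise pushing the traced half beyond the
  idealized half-disc is impossible by construction, but user-supplied
  data may violate it) clamp to zero with a warning above 1e-6 relative.
* Exact Mann–Whitney p-values double the smaller tail (capped at 1), the
  same convention as `wilcox.test`'s exact path, and are computed for
  pooled sizes up to 40 by default; midranks are doubled to keep the
  dynamic-programming sums integral. The normal fallback applies the tie
  correction and a continuity correction. Fully tied Kruskal–Wallis input
  (rank variance zero) returns H = 0, p = 1 by convention.
* Slice-table CSV stores polygons as JSON arrays at 17 significant digits,
  which round-trips doubles bit-exactly; report files round floats to 6
  significant digits and add the integer cooling-portion column used for
  tabulation.

## Problem sizes in the test suite

The suite validates the full 3 x 7 x 6 factorial (126 phantom runs, ~2100
traced contours at 128 vertices, fixed seed) for the profile-peak and
directional-significance checks; parameter-recovery tests use noise-free
512-vertex phantoms across three distances and three notch depths;
Monte-Carlo oracles use 1e6 points for areas and 2e5 for enclosure
fractions; the exact-test oracle enumerates all group sizes up to 7 + 7.
These sizes keep the default test run to well under a minute of numerical
work while exercising every code path at the study's real scale.

## Known limitations

* The Type 0–III thresholds are a published-threshold-free
  operationalization; with realistic boundary noise, slices near the grade
  boundaries can shift by more than one level under extreme threshold
  choices (a noise-driven $\iota \in [0.1, 0.2)$ with the vessel outside
  grades I by default but III under $\tau_{moderate} = 0.1$). Threshold
  sensitivity should therefore be assessed on smoothed profiles, not single
  slices.
* The cooling portion convention (cooling/ablation, not cooling/idealized)
  follows the tabulated percentages it reproduces; both are defensible and
  the full-precision columns allow either to be derived.
* `r_max` and azimuthal radii are measured from the antenna point, not a
  shape centroid — the idealized ablation is antenna-centred by
  construction. For strongly eccentric real contours the two conventions
  diverge; the reference point is an explicit argument throughout.
* Volumes are vessel-half volumes by design (the analysis convention);
  full-ablation volumes can be derived by measuring both halves.
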