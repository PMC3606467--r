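---
title: "Knee force distribution by static optimization: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knee force distribution by static optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeload)
```

## The model

At each instant of the gait cycle the net intersegmental load at the knee
joint center — a force `R` (N) and a moment `M` (N·m), expressed in the
tibia-embedded frame with x anterior, y superior and z to the right, moments
taken about the midpoint of the inter-condylar line — must be supplied by
the joint's force-bearing structures. Each structure `i` transmits an
unknown nonnegative magnitude `F_i` along a unit line of action `l_i`
applied at a point located by the lever-arm vector `d_i` (m) from the joint
center. Equipollence of the two force systems gives six linear equations:

* force rows: `sum_i F_i l_i = R`
* moment rows: `sum_i F_i (d_i × l_i) = M`

The structure set is fixed: twelve muscles (the four quadriceps acting
through the patellar tendon, four hamstring heads, both gastrocnemius
heads, and gluteus maximus and tensor fasciae latae acting through the
iliotibial tract), the four major ligaments, and the medial and lateral
tibiofemoral contacts. Directions always express the force applied *to* the
shank — muscle and ligament tension points toward the femoral attachment,
contact compression points the way the femur pushes the tibia — so every
magnitude is nonnegative, which encodes tension-only soft tissue and
compression-only contact as simple bounds.

Key modeling assumptions inherited from this formulation: rigid segments,
inextensible ligaments, frictionless point contacts, pure force generators
(no force–length–velocity muscle dynamics), and frame-by-frame independence
(static optimization; no activation dynamics across frames).

Three formulations are compared. `RM` ignores ligaments and enforces only
the three moment rows on 14 unknowns; `RML` adds the four ligament
magnitudes (3 × 18); `RFML` enforces all six rows on 18 unknowns. For the
moment-only formulations the residual of the force rows — the *unbalanced
force* `e` — and the *total ligament force* `L = sum_j F_j l_j` are the
diagnostics of interest; `rms_over_cycle()` summarizes them per axis over
the cycle, in body weights.

## The optimization criteria

Redundancy is resolved by minimizing one of eight criteria over the twelve
muscle magnitudes only (ligament and contact variables never carry objective
cost): sums of linear, quadratic or cubic muscle *forces* (J1–J3), the
maximum muscle force (J4), and the same four forms on muscle *stresses*,
i.e. force divided by physiological cross-sectional area (J5–J8). PCSA
defaults (`default_pcsa()`, cm²) lie in the range of published anatomical
tables and are configurable; the gluteus maximus entry is deliberately the
ITB-transmitted fraction (18 cm²), not the whole muscle, because only that
fraction loads the knee. Stress units are N/cm²; any consistent unit leaves
the argmin unchanged.

Muscle and ligament magnitudes are bounded above by 5000 N — a deliberately
loose cap so that unphysiological predictions (the point of comparing
formulations) reveal themselves instead of being clipped. Contacts, which
must absorb the summed compressive action of all muscles, get their own
configurable bound, 10 000 N by default.

## Numerics

All problems here are convex. `solve_program()` dispatches on the criterion:

* **Linear (J1, J5)** — a simplex solve. Because ligament and contact
  variables are objective-free, the optimal face is typically degenerate; a
  second **minimum-norm polish** (a QP minimizing `||x||²` over the optimal
  face, with the primary objective held within a relative slack of 1e-7)
  makes the reported forces unique and deterministic and excludes arbitrary
  internal preloads (ligaments pulling against contacts at zero cost).
* **Minimax (J4, J8)** — the epigraph reformulation (`min t` subject to
  `c_i F_i ≤ t`) followed by the same polish with `t` fixed at its optimum.
* **Quadratic (J2, J6)** — one QP; variables with zero curvature receive a
  ridge of 1e-9 × the largest diagonal entry, which is the same minimum-norm
  tie-break in infinitesimal form.
* **Cubic (J3, J7)** — a feasible-descent SQP: the start point is the
  projection of the previous frame's solution (else the origin) onto the
  feasible set, then Newton-type steps from analytic gradients
  (`3 c³ F²`) and diagonal Hessians (`6 c³ F`) with an Armijo line search.
  A vanishing quadratic regularizer (1e-9 · `||x||²`) keeps the Hessian
  positive and the minimizer unique along the directions the cubic objective
  leaves flat (idle muscles, objective-free variables); its effect on
  objective values is many orders below reporting precision. Convergence is
  declared at a relative step norm of 1e-10, capped at 60 iterations.

Force rows are order-one (unit direction components) while moment rows are
in meters; before solving, moment rows are divided by a characteristic lever
arm of 0.05 m so the equality system is comparably conditioned, and
residuals are reported unscaled. A frame is labeled `optimal` only if its
scaled equality residual is within 1e-8 · max(1, ‖b‖∞); otherwise it is
`max_iter`, or `infeasible` when the subproblem itself has no solution, in
which case the bounded least-squares point closest to the equalities is
reported along with its residual — infeasibility is never silently relaxed,
because downstream unbalanced-force logic must see it.

Warm starting from the previous frame gives continuity across the cycle and
faster SQP convergence; with all inputs deterministic the whole pipeline is
reproducible bit for bit, which the test suite asserts by rerunning it.

## The synthetic trial

No subject data ship with the package, so `gen_trial()` generates the study
conditions: a 101-sample grid over 0–100 % gait cycle and a 56.4 kg subject
(body weight = mass × 9.81 N). Load waveforms are Gaussian-bump mixtures —
chosen over Fourier series because peak locations, widths and counts are
directly controlled and testable:

* compressive (−y) force: bumps of −0.90 BW at 15 % GC and −1.00 BW at
  45 % GC over a −0.08 BW baseline, giving the canonical two-peak stance
  pattern with small swing values;
* anterior/posterior and medial/lateral forces an order of magnitude
  smaller;
* a biphasic sagittal (extensor/flexor) moment: +22 N·m at 14 %, −16 N·m at
  45 %, −4 N·m at 74 % GC (≈ 0.4 N·m/kg peak, typical of level walking);
* a two-peaked frontal moment (−24, −27 N·m). Under these axes with
  structure-side (internal) moments and contacts acting along −y, a
  *negative* x moment loads the medial compartment, so the familiar
  medial-dominant contact split corresponds to a negative two-peak
  waveform;
* a small transverse (internal/external rotation) moment (−0.5, +0.8 N·m).

The flexion angle has a stance wave (≈ 20° near 15 % GC) and a swing peak
(≈ 60° near 72 % GC). Geometry comes from a smooth closed-form template
parameterized by flexion — not a mechanism solution, since the analysis
consumes only lines of action and lever arms. Sagittal direction angles
rotate linearly with flexion; lever arms are constants per structure. The
patellar tendon gives the quadriceps an extensor moment arm of ≈ 0.042 m
near extension, rotating posteriorly with flexion; hamstrings and
gastrocnemius carry flexor moment arms of ≈ 0.029–0.031 m.

Two template properties deserve emphasis because they are load-bearing for
the formulation comparison:

1. **Passive structures carry frontal-plane moment arms only.** The
   cruciates cross through the joint center (lever arm along the line of
   action), and the collaterals and contacts are sagittally vertical with
   medial/lateral offsets. If a ligament or contact had even a millimeter of
   sagittal or transverse moment arm it would act as an objective-cost-free
   moment generator, and every criterion would drive it (and a canceling
   partner) to its force bound, producing internal preloads of thousands of
   newtons under *all* formulations. Real cruciate sagittal moment arms are
   small but nonzero; setting them to zero is the template's idealization of
   "small enough not to be exploitable".
2. **Flexor effective moment arms are near-equal while medial/lateral
   levers and PCSAs differ.** Criterion choice then changes *which* muscles
   fire (force-based criteria spread over the equal-arm flexors, stress-based
   ones concentrate on the large-PCSA medial flexors) far more than the
   total muscle pull. Under moment-only formulations the recruitment
   pattern's frontal-moment contribution is balanced by the contacts at
   roughly 40× leverage (1 / 0.025 m), so RM and RML contact predictions
   vary visibly across criteria, while under RFML the force rows pin the
   contact force to the total pull plus the compressive load, which is
   nearly criterion-independent.

With zero noise (the default) trials are pure functions of their parameters,
and the waveform peak structure is exact; a seeded Gaussian-noise mode
exists for robustness experiments. `inconsistent_load_params()` provides a
deliberately infeasible trial — a lateral force of several body weights that
the nearly sagittal lines of action cannot supply — used to exercise the
infeasibility reporting path.

What the generator does *not* emulate: soft-tissue artefact, measurement
noise structure, inter-subject geometry variation, femoral rollback of the
contact points, patellofemoral mechanics, and any coupling between frames.
Tests passing on this trial therefore demonstrate the correctness and the
qualitative formulation-dependence of the method, not quantitative accuracy
on any real subject.

## Postprocessing conventions

* Body weight is mass × 9.81 m/s²; all reported forces are in BW.
* The reported knee contact force is the sum of the medial and lateral
  magnitudes; the compartment split remains in the solution tables.
* Contact peaks are window maxima: first peak in 0–30 % GC, second in
  30–62 %, swing maximum in 62–100 % (stance–swing transition at 62 % GC);
  windows are configurable via `peak_windows()`.
* RMS summaries run over the full 0–100 % cycle, and the RML-vs-RFML
  ligament comparison is the componentwise difference of the total ligament
  force vectors.

## Known limitations

* With equality-constrained nonnegative forces, linear and minimax criteria
  have non-unique force vectors; the package guarantees objective *values*
  and makes the reported vector unique only through the minimum-norm
  secondary criterion. Comparisons of individual muscle forces under J1/J4/
  J5/J8 should be read with that in mind.
* The geometry template is synthetic. Absolute BW magnitudes depend on its
  arm lengths and on the load amplitudes, which are order-of-magnitude
  choices; only the relative behavior of formulations and criteria is
  designed to be meaningful.
* Infeasible frames report a least-squares diagnostic, not a relaxed
  solution; pipelines consuming the outputs must check `status`.
* Each frame is solved independently; there is no guarantee of temporal
  smoothness of the force trajectories beyond what warm starting induces.
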