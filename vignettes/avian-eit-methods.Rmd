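---
title: "Monitoring avian air-sac ventilation with electrical impedance tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring avian air-sac ventilation with electrical impedance tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Thoracic electrical impedance tomography (EIT) reconstructs conductivity
changes inside a body cross-section from voltages measured on a belt of
electrodes while small alternating currents rotate around the body. In
mammals the breathing signal comes from the lungs. Birds are different:
the parabronchial lung is rigid and near-isovolumetric, while tidal volume
is generated by the compliant air sacs. At a belt placed just caudal to
the shoulder joints, the cranial air-sac group (clavicular and cranial
thoracic sacs) lies ventral to the lungs, around the cardiac silhouette.
The package implements the full analysis chain needed to study this
situation quantitatively: a chicken-specific finite-element (FE) phantom,
a forward solver, GREIT difference-image reconstruction, breath-wise
functional variables, a classifier for expiratory waveform morphology,
and the contingency statistics used to compare breathing patterns across
recumbencies — all exercised end to end on a ground-truthed simulator of
cranial-air-sac ventilation.

Because no raw EIT or CT data from real birds are public, the simulator
is a first-class module: it defines the study conditions under which
every claim in the test suite is checked, and the limits of what those
checks can say about real animals are discussed at the end.

## Geometry and the phantom

A subject is described by four closed polygons in millimetres — outer
body, right and left lung, cardiac silhouette — with x running from the
subject's right to left and y from ventral to dorsal. Display convention
is radiological: image row 1 is dorsal, column 1 is the subject's right.
Contours are normalised to counter-clockwise orientation; averaging over
subjects resamples each contour to a fixed number of arc-length-equidistant
vertices starting at the vertex nearest the ventral midline, translates
centroids to a common origin, and averages vertex-wise. Translation-only
alignment is deliberate: subjects are imaged in a fixed posture and
rotation/scaling would distort absolute size. The shipped geometry is a
parameterised ellipse model (outer ellipse 90 × 80 mm; two dorso-lateral
lung lobes; a central-ventral cardiac disc) because the original CT
contours are not published; it is labelled synthetic everywhere.

Meshing uses a structured radial triangulation: the outer contour is
resampled to a multiple of 32 boundary vertices (electrodes sit on every
k-th vertex, exactly equidistant in arc length, numbered counter-clockwise
from the ventral midline) and rings are scaled toward the area centroid.
Quad-splitting diagonals are mirrored about the ventral–dorsal axis so a
symmetric contour yields an exactly mirror-symmetric mesh — without this,
reconstructed images of symmetric scenarios inherit a few-percent
asymmetry from the triangulation. Interior region boundaries are honoured
at mesh resolution by labelling elements from their centroids
(point-in-polygon) rather than by conforming edges; at the default 2.3 mm
element size (~4500 elements) region edges are resolved to about one
element, which is ample for a 32 × 32 reconstruction grid. No
constrained-Delaunay generator is used; the mesher is part of the package.

The `airsac` label exists only as simulation ground truth: air sacs
cannot be segmented as an ROI on CT, so all elements ventral to the
lungs' ventral-most extent that are not cardiac are treated as the
cranial-air-sac territory. The reconstruction and analysis path never
uses this label — like the study design it mirrors, it relies on the
outer contour only.

## Forward model

The forward problem is the 2-D quasi-static conduction equation
∇·(σ∇u) = 0 with point current sources of ±5 mA at the driven electrode
pair, solved with linear (P1) triangular elements and grounded by a
zero-mean constraint over the electrodes. The 192 kHz carrier is treated
as metadata: difference imaging of ventilation does not require complex
admittivity. Electrodes are point electrodes at boundary nodes (gap
model); contact impedance largely cancels in difference imaging, and this
is documented as a fidelity limit rather than modelled. The stimulation
pattern is the rotating adjacent pattern (configurable skip): injections
(i, i+1+skip), measurements between all same-offset pairs not involving a
driven electrode — 32 × 29 = 928 channels at the default settings.

Per-frame solves reuse one symbolic sparse-Cholesky factorisation across
the whole recording and refill a precomputed symmetric sparse template,
which brings a 120 s × 48 frames/s simulation at ~4.5k elements to well
under a minute on one CPU. The solver is verified against three
independent oracles: the closed-form boundary potential
u(z) = (I/πσ) ln |z − z_sink|/|z − z_source| on a homogeneous disk (max
relative channel error < 2% at ~4.5k elements), the reciprocity theorem
(equality to ~1e-15 for arbitrary conductivity fields), and
central-difference derivatives of the adjoint-based sensitivity matrix
(relative error ≤ 1e-4). Because measurement pairs share the drive-pair
offset, the adjoint field of each measurement pair is a rescaled drive
field, so the full Jacobian costs one set of forward solves.

## GREIT reconstruction

The reconstruction matrix follows the Graz consensus approach: small
circular conductivity-decrease targets are scattered over the
cross-section, their boundary signatures are computed through the
sensitivity matrix in normalised-difference form
dv = (v − v_ref)/v_ref, and R minimises ‖RY − D‖² + λ²‖R‖² against
desired blob images on the 32 × 32 grid. λ is calibrated by bisection so
that the ratio of image-domain noise amplification to the amplification
of a central reference target equals the prescribed noise figure (0.5 by
default). Defaults follow reference recommendations: 1000 targets,
target radius 5% of the mask diameter, desired blobs at twice the target
radius, uniform channel weighting. One deliberate refinement: targets are
sampled in mirrored pairs about the body midline so the trained matrix
respects the phantom's right–left symmetry; with random placement alone,
symmetric scenarios reconstruct with up to ~10% RMS asymmetry.

The sign convention is fixed at training time — conductivity decrease
(air filling) maps to positive pixels — and asserted in tests. Since the
vendor's "modified" GREIT variant is unpublished, the reference
formulation is implemented; hyperparameters are configurable.

## Breath analysis

The global curve is the per-frame sum of in-mask pixels. Cardiac flutter
(heart rates ≥ ~200/min, i.e. ≥ 3.3 Hz) is removed by a zero-phase
4th-order Butterworth low-pass at 1.5 Hz, comfortably between the
respiratory (< 0.5 Hz) and cardiac bands; forward–backward application
doubles the effective order, giving > 60 dB at 4 Hz with < 1% passband
ripple at 0.15 Hz. Breaths are minima–maximum–minima spans of the
filtered curve, with candidate extrema pruned until every excursion
reaches 20% of the median peak-to-trough excursion. TIV is
z(end-inspiration) − z(start-inspiration); this is the conventional
non-negative tidal impedance variation (a literal subtraction in the
other direction would flip the sign). Artefact-free selection takes the
earliest longest run of consecutive breaths whose TIV and duration both
lie within ±50% of the medians, truncated to ten breaths, requiring at
least six; apnoeic gaps over 10 s break a run. The vendor's actual
artefact criterion is unknown; these thresholds are configurable
stand-ins.

## Ventilation variables

All distribution metrics operate on the per-breath tidal image
(end-inspiration frame minus start-inspiration frame) with negative
pixels clamped to zero — out-of-phase artefacts must not contribute
negative "ventilation" — while the raw image retains them. Coordinates
are normalised to the bounding box of the body mask, so padding cannot
bias the metrics:

* **CoV_RL / CoV_VD** — the ventilation-weighted mean pixel position,
  0% at the subject's right (or ventral) edge and 100% at the left (or
  dorsal) edge.
* **RL ratio** — clamped sum right of the bounding-box midline over the
  sum left of it; a column straddling the midline is split half-half.
* **Eight regions** — four equal-height horizontal bands (dorsal,
  central-dorsal, central-ventral, ventral) per side, each expressed as
  a percentage of the total so the eight values sum to exactly 100;
  pixel rows straddling a band edge are split by fractional overlap.

These definitions give exact values on constructed images (extreme-column
CoV of 100%, mirror images mapping CoV to 100 − CoV and the ratio to its
reciprocal), which the test suite asserts to 1e-9 or better.

## Breathing-pattern classification

Each expiration (end-inspiration to end-expiration) is normalised to
amplitude 1→0 on time τ ∈ [0, 1]. Four morphologies are distinguished:
concave-linear (BrP1) and convex-linear (BrP2) without an impedance
pause, and pause patterns with the plateau starting early (remaining
impedance > 50%, BrP3) or late (≤ 50%, BrP4). Without a pause, the signed
area between the curve and the chord 1 − τ decides concave (≥ 0 → BrP1)
versus convex; near-linear curves tie-break to BrP1, whose "concave-linear"
definition embraces them.

Pause detection proved to be the delicate part. The criterion is a slope
run: the longest interval with |dz/dτ| below 10% of the mean absolute
expiratory slope, lasting at least 0.3 s. Three robustness measures make
this workable on reconstructed, noisy curves: slopes are estimated over a
±0.08 s window (averaging out residual flutter and channel noise); the
core run is extended by hysteresis while the slope stays under four times
the core threshold (recovering plateau shoulders rounded by smoothing);
and two guards reject non-pauses — a run touching the start of expiration
is the smooth end-inspiratory turn (this is what makes BrP1's initial
zero-slope region harmless), and a run starting below 10% of the
normalised amplitude or within the final 5% of expiration is the terminal
baseline, not a pause.

A practical filtering conflict surfaced here: the 1.5 Hz anti-cardiac
low-pass, ideal for breath timing and TIV, rounds the corners of a
~0.5 s plateau so strongly that little truly flat signal survives.
The pipeline therefore keeps the Butterworth curve for breath detection
and TIV but classifies morphology on a Savitzky–Golay-smoothed copy of
the raw global curve (order 3, 13-frame window ≈ 0.27 s), which
suppresses noise while preserving piecewise-polynomial shape; breath
boundaries are re-located on that copy (±0.25 s local extremum search)
because the strong low-pass can shift asymmetric peaks by a few frames.
With these choices the pipeline recovers the generating pattern for
every breath of 40 simulated recordings at zero noise and ≥ 95% of
breaths under 3% cardiac flutter plus 2% channel noise, with no
recording misclassified at the 95%-uniformity rule that assigns
per-recording labels.

## The simulator

A scenario specifies recumbency, respiratory and heart rate, breathing
pattern, tidal conductivity swing α, cardiac amplitude, an imposed
spatial shift, channel noise, duration and a root seed. Defaults are the
study conditions: 120 s at 48 frames/s, 32 electrodes, 5 mA, RR 10/min
and HR 240/min (mid-range of the observed physiology, which spanned
roughly 7–12 breaths/min and 200–320 beats/min), inspiratory fraction
drawn around 0.4 (giving inspiratory times near the observed ~2.3–2.7 s),
α = 0.15 about a 0.3 S/m baseline (the absolute baseline is immaterial
for difference imaging), cardiac fraction 0.03 (flutter that is
"minuscule" on the curve yet spectrally detectable), channel noise 2% of
the mean absolute voltage difference. Realistic α and cardiac fractions
for chickens are unknown — no raw signals are deposited — so these are
documented plausibility choices, made once.

Volume waveforms are half-cosine inspirations followed by the BrP shape:
1 − τ² (BrP1), (1 − τ)² (BrP2), or linear decays to a plateau of 0.15 of
the expiratory time at level 0.6 (BrP3) or 0.4 (BrP4), with ±5% per-breath
period jitter. Air-sac elements follow σ(t) = σ_base(1 − α v(t) g_e); the
gain g_e ∈ [1 − |shift|, 1 + |shift|] varies linearly along the axis
implied by recumbency (lateral → right–left, dorsal/ventral →
ventral–dorsal), increasing toward the non-dependent side for positive
shift. Lung and background elements are constant — the isovolumetric-lung
assumption is built in as an invariant — and cardiac elements carry a
heart-rate sinusoid. The root seed spawns independent sub-streams for
waveform jitter and channel noise, so switching noise on cannot perturb
breath timing; identical configurations are bit-reproducible.

## Statistics

Breathing-pattern frequencies per recumbency form an r × c contingency
table tested with a two-sided exact Fisher test: the p-value is the total
probability, under fixed margins, of all tables no more probable than the
observed one. The exact method enumerates tables by depth-first recursion
over rows with column-remainder bounds (compiled); the Monte-Carlo method
samples fixed-margin tables via `r2dtable` and reports the proportion at
or below the observed probability. On the reference 4 × 4 table of
observed frequencies (10 chickens, one left-lateral recording excluded)
the exact test gives P = 0.000857 → 0.001 at three decimals, matching
`stats::fisher.test` (used in the tests as an independent oracle only) to
ten significant digits, in ~0.1 s. Per-recumbency descriptive summaries
use plain t-based 95% confidence intervals; the mixed-model analysis of
the original design is deliberately out of scope.

## Numerical choices and degenerate inputs

Conductivities must be strictly positive; scenarios with
α(1 + |shift|) ≥ 1 are rejected as non-physical. Zero-perimeter contours,
self-intersecting polygons (checked exhaustively for ≤ 400 vertices),
interior contours not strictly inside the outer, and overlapping ROI
pairs are errors naming the offending contour(s). A reference voltage of
exactly zero on any channel aborts reconstruction naming the channel.
Breath detection warns and returns an empty table when no cycle exists;
selection fails with "insufficient artefact-free breaths" below six.
Exact Fisher enumeration is guarded by a product-of-row-compositions
bound (~1e11 paths) above which the Monte-Carlo method is advised.

## Problem sizes used in the checks

The package's own validation runs at deliberate scales: the full default
scenario (120 s, ~4.5k elements) for the regional-sum, symmetry and
lung-silence checks; 80 recordings of 60 s on a ~1.3k-element mesh for the
breathing-pattern round trip; 30 recordings of 60 s for directional shift
recovery; ~4.5k elements for the analytic forward oracle and GREIT
localisation. The analysis scripts under `analysis/` use the same
configurations and state their scale in their headers.

## What passing tests do and do not show

The simulator emulates the features that matter for the analysis
definitions — breathing-synchronous conductivity loss confined to the
ventral air-sac territory, silent lungs, small cardiac flutter,
recumbency-dependent spatial bias, channel noise, seeded jitter — but
not: contact-impedance and electrode-movement artefacts, organ motion or
displacement with posture, caudal air sacs, three-dimensional current
paths (the model is planar; real sensitivity volumes are lens-shaped),
or the vendor's proprietary reconstruction variant. Passing the suite
therefore shows that the definitions are implemented correctly and that
the pipeline recovers known ground truth under idealised avian
physiology; it does not certify performance on real recordings.

One invariant is knowingly not met at its stated bound: with the air-sac
territory extending right up to the lungs' ventral border, the
point-spread tail of the linear GREIT reconstruction deposits a small
positive signal in the one-to-three most ventral lung pixel rows. The
mean absolute lung-ROI signal is ~6–9% of the air-sac mean across the
tested hyperparameter range (target radius 0.025–0.07, blob factor
1.25–2, noise figure 0.3–1.0), never ≤ 5%; the profile decays by a
factor ~40 from the ventral lung border to the dorsal lung field, and the
ratio is independent of the tidal amplitude, identifying blur rather than
nonlinearity as the cause. The corresponding acceptance check is kept at
its strict bound and reports this honestly rather than being loosened.
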