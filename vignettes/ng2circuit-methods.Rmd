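---
title: "ng2circuit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ng2circuit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ng2circuit)
```

This vignette is the package's own account of the science it implements:
what each model assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generators emulate (and
deliberately do not), and where genuinely open design choices were settled.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## The biological problem

During the second postnatal week, cortical NG2 cells — oligodendrocyte
precursors — receive transient GABAergic synapses from nearby interneurons.
Characterizing that microcircuit requires answering, quantitatively: which
interneuron class (fast-spiking, FSI, vs non-fast-spiking, NFSI) is
presynaptic; how many vesicular release sites a unitary connection has; how
connection probability depends on intersomatic distance; where on the
postsynaptic cell the inputs land; and how all of this changes day by day.
Each question maps onto one analysis module, and each module has a matching
generator that produces inputs with known ground truth, so the pipeline can
be validated in closed loop.

## Units and sign conventions

Membrane potential in mV; currents in pA with inward currents negative
(quantal size `q < 0`); time in ms; distances in µm; default sampling
20 kHz (`dt = 0.05` ms). The AHP is reported as trough minus threshold,
hence negative.

## The action-potential template

The generator builds spikes from an analytic template rather than a
conductance model, so every extracted feature is an explicit function of
generator parameters:

- **Depolarized face**: a Gaussian bump of amplitude `A` (threshold to
  peak) and standard deviation `σ = D / (2√(2 ln 2))`, so that the
  duration feature — defined as the FWHM of a Gaussian fit to the
  depolarizing face — equals `D` exactly.
- **Ignition segment**: the lower rising flank of the Gaussian is replaced
  by a straight segment of slope 4 mV/ms that reaches the threshold level
  exactly. The threshold feature is defined by the point where dV/dt
  exceeds twice the pre-spike baseline derivative (median |dV/dt| over a
  5-ms window, floored at 1 mV/ms to avoid division by near-zero — the
  reference level for the "twofold increase" is otherwise undefined on a
  quiescent baseline). A pure Gaussian rise would put that crossing
  0.4–0.9 mV above the intended threshold, because the crossing voltage
  `A·exp(−x²/2σ²)` at the point where `A·G'(x)` equals the detection level
  grows with σ; the ignition segment keeps the flank's slope above the
  detection level all the way down to the anchor, so the rule lands on the
  template threshold within ~0.2 mV for all spike widths in range.
- **AHP lobe**: an asymmetric Gaussian (fast left flank σ_l = latency/3.5,
  slow right flank chosen so the lobe's FWHM equals the AHP-width
  parameter) anchored at the trough, `latency` ms after the peak. Past the
  half-recovery point the right flank is reshaped into an exponential that
  returns the trace to threshold just before the next spike; this leaves
  depth, latency and FWHM untouched while making consecutive spikes start
  from identical baselines — without it, overlapping AHP tails bias the
  measured threshold and amplitude of every spike after the first.

One consequence is accepted deliberately: a Gaussian face of realistic
FWHM cannot also reproduce realistic maximal dV/dt values (a 70 mV, 1.37 ms
FWHM Gaussian peaks near 73 mV/ms, whereas real FSI spikes exceed
200 mV/ms). The slope features are extracted and tested against a
finite-difference oracle, but they are not generator parameters and not
used by the classifier.

Three protocol regimes drive the generator: a long (1 s, +200 pA) pulse for
the frequency/accommodation features, a short 80-ms suprathreshold pulse
whose first two APs (50 ms apart) supply all waveform features, and a
−200 pA step from −60 mV whose passive RC response supplies the input
resistance.

## Class parameters and the separation constraint

Per-class population means for amplitude, duration, AHP, duration increase,
amplitude reduction, early accommodation, input resistance and firing rate
are taken from the characterized FSI/NFSI populations. Dispersions are
standard deviations across cells. For the three discriminative features
(AHP, duration increase, amplitude reduction) the defaults are set to 35%
of the between-class gap. This is a stated-world choice: the NFSI
population is heterogeneous, and SEM-implied SDs for its duration increase
(~60 percentage points) would violate the type contract that the two
default parameter sets be separated by more than the sum of their
dispersions. At 0.35 × gap per class, each feature vote is correct with
probability ~0.92 and the 3-vote majority with ~0.98, which is what the
classifier-recovery test measures. A green recovery test therefore
establishes that the pipeline recovers the stated world's labels — not
that real FSI/NFSI populations are this separable.

## The classifier

Midpoint thresholds between the class means on the three discriminative
features; each feature votes for its side unless it lies within a
configurable `margin` of the threshold (default 0, meaning only exact ties
abstain); a label requires two definite concordant votes, anything else is
`ambiguous`. Missing features abstain, so a cell with fewer than two
measurable discriminative features is never silently labelled. The rule is
parameter-transparent and reproducible; a k-means alternative was
considered and rejected because its boundary depends on the cohort at hand.

## Binomial release model and quantal inference

A connection has 1 or 2 release sites; each site releases independently
with probability `p1` on the first pulse and `p2 < p1` on the second
(paired-pulse depression), each vesicle contributing `q` (default
−7.71 pA). Rendered sweeps place biexponential PSCs (rise τ 0.568 ms,
decay τ 12.7 ms — the rise constant is chosen so the kernel's 10–90% rise
time is exactly 0.91 ms; `τ·ln 9` holds only for a pure exponential rise)
at a fixed 1.5-ms latency after each stimulus, over white Gaussian noise.

Detection measures the extremum of a 0.5-ms-smoothed trace relative to the
local pre-stimulus baseline, with the failure threshold at 2× the raw
baseline SD. Two numerical points matter. First, smoothing must not enter
the threshold: the maximum of raw noise over a 19-ms window always exceeds
twice the noise SD, so a raw-peak detector would call failures responses.
Second, the local baseline is essential for the second pulse: the first
PSC's decay tail (~0.2 pA at 50 ms for the default kinetics) otherwise
shifts the whole PSC2 amplitude distribution, and the quantal KS test —
which resolves sub-pA distributional differences once noise is averaged
down — reports a spurious difference. Smoothing attenuates amplitudes by a
few percent, which is visible as a small negative bias in recovered
quantal sizes (≈ −8.3 vs −7.7 pA) and is well inside the ±15% recovery
band the tests use.

Release-site inference (at ≥100 sweeps, refused otherwise): one site when
the non-failure PSC1/PSC2 amplitude distributions are KS-indistinguishable
(α = 0.05) while PSC1's response probability is significantly higher
(two-proportion chi-square, no continuity correction); two sites when both
differ; any discordant pattern is returned as `indeterminate` rather than
coerced. The two-site generator default is a high first-pulse per-site
probability (0.85), which makes the non-failure PSC1 mean ≈ 1.7×q — the
regime in which double release is actually distinguishable and which
matches the observed "about twice" relation between double- and
single-site first-pulse amplitudes.

The PPR uses with-failure means by default (PSC2/PSC1, failures counted as
0 pA), configurable to without-failure means; the choice is genuinely open
in the field and both conventions are tested.

## Photostimulation mapping

Trials carry Poisson background events (default 0.2 Hz) over ±2 s around
the stimulus; connected targets add one evoked event per trial at a
latency drawn from a log-normal (meanlog log 35, sdlog 0.6) truncated to
(0, 100] ms. The truncated log-normal is a stand-in: only the latency
histogram's right-skewed, 100-ms-bounded shape is known, not its law. The
evoked-event failure rate defaults to 0 (failures are rare for pyramidal
targets) and is configurable for NG2 targets.

A pair is `connected` only if both criteria hold: the averaged trace shows
a PSC above twice its baseline SD (peak measured on a 2-ms-smoothed
average, threshold on the raw averaged noise — the same calibration logic
as event detection), and the raster shows significant enrichment of events
in the 100-ms window (exact one-sided binomial test of the per-trial hit
count against `1 − exp(−rate·0.1)`; the visual raster criterion needed a
formal test, and the binomial formalization is ours). Pairs meeting one
criterion only are `ambiguous` and are excluded from probability
denominators but reported as a fraction. Intersomatic distance is 3D
Euclidean; 2D maps get z = 0. Distance profiles default to 10-µm bins.

The NG2 distance rule (plateau probability to 50 µm, linear decay to 0 at
70 µm, exactly 0 beyond) and the uniform pyramidal rule (constant within
100 µm) are generator ground truth; mapping tests check that the analysis
recovers the plateau, never calls a connection beyond 70 µm on truth maps,
and finds no connected/unconnected distance difference in uniform maps.

## Puncta geometry

The synthetic cell is a 5-µm-radius soma with six straight branches; PV⁺
(FSI-type) contacts sit at branch geodesic distances drawn from a
Gamma(shape 2) law with mean 12.8 µm, PV⁻ contacts with mean 22.5 µm, plus
a configurable somatic fraction (higher for PV⁺, matching the somatic
enrichment of fast-spiking inputs). Gamma rather than exponential because
an exponential's mode at zero collides with the soma-assignment tolerance
(puncta within 1 µm of the soma surface are somatic by convention) and
understates the separation the distance distributions show. Distances from
the soma are geodesic along the branch by default ("distance from the
soma" is otherwise ambiguous); a Euclidean option exists. Branch-distance
summaries exclude somatic puncta by default, with a flag to include them
at distance 0.

Contacts are puncta whose 1D fluorescence profile overlaps the membrane
profile by more than 0.23, with the punctum's own area as denominator —
the overlap is therefore asymmetric unless both profiles have equal area,
and the convention is tested explicitly.

Shell densities divide per-shell counts by the analytic volume of the
sphere clipped by the stack's two z planes (cap formula
`πh²(3r−h)/3`); shells grow in 5-µm steps until the next shell would cross
the lateral stack boundary, which is handled by stopping growth, not by
clipping in x/y. A Monte-Carlo oracle (uniform sampling inside each
unclipped shell) validates the analytic volumes to 0.5%, and shell
volumes are additive to 10⁻⁶ relative.

## Connectivity statistics

Wilson score intervals (z = 1.644854 for the default two-sided 90% level)
with half-up rounding to two decimals for printed comparisons — base R's
banker's rounding cannot reproduce conventionally printed bounds. Two
proportions are "different" when their intervals are disjoint; touching
endpoints count as overlap (closed-interval convention, chosen because the
α-bound argument `(1−level)²` needs disjointness). The 2×2 chi-square uses
no continuity correction — with Yates' correction the reconstructed
connection table gives 5.82, not the printed 6.93, so the uncorrected form
is the only one consistent with the reproduction target.

`reconstruct_contingency` recovers unprinted integer counts from printed
proportions by exhaustive search, requiring at least one corroborating
printed statistic and erroring on zero or multiple surviving candidates;
uniqueness for the connectivity table was verified by running the search
over all 147-pair splits.

One numerical fact surfaced by the acceptance suite deserves note: the
exact coverage of the 90% Wilson interval is not monotone in (p, n) — it
is 0.897 at (p = 0.21, n = 112) but 0.877 at (p = 0.43, n = 35), below
the 0.88 floor the acceptance criterion asserts for both design points.
Coverage oscillation is a known property of score intervals; the
module-level test therefore checks empirical coverage against the exact
binomial-sum value, while the acceptance test states the original bound
and is expected to stay red at the first design point.

## Developmental time course

Per-day connection probabilities default to a peak of 0.44 at PN10
(20/30/44/36/25/12% across PN8–13; the non-peak days besides PN10 are
interpolations consistent with a rise from PN8 and the known loss of
innervation after the second week). Spontaneous PSC frequency means rise
from 0.12 Hz to 0.24 Hz at PN10 and return to 0.12 Hz. Na⁺ current density
(mean 23.5 pA/pF) and frequency are drawn from a bivariate normal with a
per-day correlation that is nonzero (0.7) only at PN10 by default,
emulating the observation that density and synaptic activity correlate
only at the connectivity peak. Frequencies are floored at 0.01 Hz, which
slightly attenuates extreme correlations but leaves the default regime
untouched.

## What the generators do not emulate

No conductance-based membrane dynamics, no electrotonic filtering (kinetic
differences between proximal and distal inputs are parameters, not
emergent), no optics or photolysis physics (photostimulation is an event
process), no image segmentation (puncta arrive as labelled points), and no
animal-to-animal variability (cells are i.i.d. within class). Green tests
establish closed-loop consistency of analysis and generator under the
stated world, not biological truth of that world.

## Numerical choices and degenerate inputs

- Differentiation: centered finite differences, no pre-smoothing by
  default (an optional median filter was considered and left out; the
  templates are noise-free where derivatives matter).
- Gaussian duration fit: quadratic regression of log-height on time over
  the rising face only (exact for a Gaussian, closed form, no iteration);
  failure is reported when the fitted curvature is non-negative.
- Decay fits: log-linear least squares seeded nonlinear refinement,
  window from 90% of peak.
- Fewer than 2 spikes, missing AHP, all-failure pulses, empty clouds or
  maps: flagged or errored with explicit messages, never silently zero;
  the classifier abstains on missing features.
- All generators take explicit seeds and restore the caller's RNG state;
  `run_study` refuses configs without a seed.

## Known limitations

- Template AP slopes are unrealistically small (see above); do not use the
  synthetic cohort to benchmark slope-based classifiers.
- Detection smoothing biases amplitudes ~5% toward zero; quantal-size
  estimates inherit this.
- The evoked-latency law and the non-peak-day connection probabilities are
  stand-ins constrained only by qualitative features.
- The exhaustive contingency reconstruction is quadratic in the totals and
  intended for study-scale counts (hundreds), not for large tables.
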