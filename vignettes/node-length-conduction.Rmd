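---
title: "Node of Ranvier length as a tuner of conduction speed: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node of Ranvier length as a tuner of conduction speed: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranvier)
```

## The scientific question

Myelinated-axon conduction speed is usually discussed in terms of myelin
thickness and internode length. The node of Ranvier itself is a third
geometric knob: lengthening a node increases its membrane capacitance and
the axial resistance into the internode (both slow conduction), while — if
channel density is fixed — it also adds voltage-gated Na⁺ channels (which
speeds conduction). Because measured node lengths span a several-fold range
across CNS axons while being tightly conserved *along* each axon,
node-length adjustment is a candidate mechanism for per-axon tuning of
spike arrival times, at a membrane-area cost orders of magnitude below
remodelling the myelin sheath.

`ranvier` implements the machinery needed to quantify this idea:

1. a **double-cable compartmental model** of a myelinated CNS axon
   (`build_axon()`, `simulate_axon()`), with presets for rat optic-nerve
   and layer-V cortical axons;
2. the **in-silico experiments**: sweeps of node length, internode length
   and wrap count under two channel-scaling assumptions
   (`sweep_node_length()`, `sweep_internode_length()`, `sweep_wraps()`,
   `alternating_node_axon()`, `speed_matched_equivalents()`);
3. **morphometry** of confocal line profiles — the half-maximum node-length
   measurement and the along- vs between-axon variability statistic
   (`node_length_from_profile()`, `along_vs_between_reduction()`);
4. a **synthetic-data generator** producing axon populations and
   confocal-like profiles with the measured statistical structure
   (`sample_population()`, `render_profile()`, `end_to_end_fixture()`),
   so the whole analysis is testable without microscopy data.

## The electrical model

Each axon is a chain of 51 nodes of Ranvier alternating with internodal
regions. A node is one compartment; each internodal region is divided into
66 (optic nerve) or 86 (cortex) compartments, the outermost of which
represent the paranodes, where the myelin attaches (the counts are chosen
so an integral number of compartments spans each 2.11 µm / 1.90 µm
paranode; for other internode lengths the paranodes keep their exact
length and the interior grid keeps the baseline resolution).

Under the myelin the model is a *double cable*: each compartment carries an
intracellular potential and a periaxonal potential (the thin fluid layer
between axolemma and innermost myelin membrane). The axolemma (0.9 µF/cm²,
leak 0.1 mS/cm² internodally) separates the two; the myelin sheath
separates the periaxonal space from grounded extracellular fluid.
Longitudinal current flows both axoplasmically (70 Ω·cm) and through the
periaxonal space (70 Ω·cm across a 15 nm annulus internodally). At the
paranode the periaxonal pathway is the spiral between the myelin end-loops:
a pathway of cross-section A = 170 nm² winding once around the axon per
wrap has the same axial resistance as a uniform space of effective width

$$w = \frac{A\,L}{(\pi d)^2 N_{wraps}}$$

(≈ 0.0077 nm optic nerve, 0.0123 nm cortex; `paranodal_effective_width()`),
which electrically seals the internodal periaxonal space at both ends.
Nodes have no myelin; their periaxonal potential is pinned to ground.

**Myelin admittance.** The 2·N_wraps myelin membranes (0.9 µF/cm² and
1.0 mS/cm² *per membrane*) are combined in series, each evaluated at its
own lamella radius: the innermost membrane sits one periaxonal-space width
(15 nm) outside the axolemma and successive membranes are spaced by half
the 15.6 nm wrap periodicity. This radius-resolved convention was chosen
over referencing all membranes to the axolemma circumference because it
reproduces the nodal capacitance fractions (≈ 8 % optic, ≈ 14 % cortex,
`nodal_capacitance_fraction()`) and is geometrically self-consistent: the
outermost lamella radius it implies coincides with the radius implied by
the g-ratio.

**Wrap count.** From the g-ratio, the sheath's radial thickness is
(d/g − d)/2; setting aside the 15 nm periaxonal space, the remaining
thickness is filled by wraps of 15.6 nm periodicity, a partial outer wrap
counting as a wrap (`wraps_from_gratio()`, giving the 7 and 5 wraps of the
presets). Rounding down instead does not reproduce the preset wrap counts,
so the ceiling convention is used and documented here.

**Nodal channels.** Nodes carry fast Na⁺ (m³h), persistent Na⁺ (p³) and
slow K⁺ (s) conductances (3000, 5 and 80 mS/cm² at the mean node length)
plus an 80 mS/cm² leak. The source model for the nodal channels does not
print its gating rate equations; `channel_kinetics()` transcribes the
standard rate table of this model family (the MRG/SRB lineage of CNS node
models), defined at 36 °C, and rescales to the 37 °C operating temperature
with per-gate Q10 factors of 2.2 (m, p), 2.9 (h) and 3.0 (s). Q10 scaling
multiplies forward and backward rates equally, so steady-state activation
curves are temperature independent. Juxtaparanodal K⁺ channels are omitted
(the myelin voltage divider leaves them essentially unactivated), as are
stochastic gating and extracellular fields.

**Resting state.** The tabulated leak potential (−83.38 mV) was tuned by
the source model so that −82 mV is stationary; under the transcribed
kinetics a residual nodal current of ≈ +63 µA/cm² (outward) remains at
−82 mV. Rather than silently re-tuning the leak potential, the package
finds the model's true stationary state by a damped fixed-point iteration
(`resting_state()`, converging to ≈ −82.9 mV at the nodes) and reports the
residual. With the voltage-gated conductances removed the stationary point
is the leak potential exactly, which the test suite asserts.

## Numerics

The coupled equations are advanced by a backward-Euler step on the linear
membrane and axial terms — a 2×2-block tridiagonal solve per step,
implemented in C++ — with the gating variables updated by the standard
exponential integrator evaluated at the current membrane potential. The
default step is 0.25 µs. The scheme is unconditionally stable, and the
suite checks stationarity without a stimulus, bitwise reproducibility,
mirror symmetry when the far end is stimulated, convergence of the
conduction delay under dt refinement, and agreement of the conduction
delay with an independent stiff ODE solver (`deSolve::lsoda`) to better
than 1 %.

Conduction speed is the centre-to-centre distance between nodes 20 and 30
(counting the stimulated node as 0) divided by the difference in spike
times, where a spike time is the linearly interpolated upward crossing of
−20 mV; a peak-time-based speed is attached and agrees within ~1 %. The
stimulus is an intracellular 1 nA, 0.1 ms pulse at the first node —
several times threshold (`threshold_amplitude()` reports ≈ 0.11 nA for the
optic preset); because speed is measured 20+ internodes away, percent
changes are insensitive to the stimulus (asserted in the suite), so
amplitude is fixed rather than re-calibrated to a multiple of threshold
for every geometry.

Simulation durations are sized from the axon length at a conservative
0.8 m/s and the integration stops shortly after the last measured node
spikes, which keeps a full 51-node run to a few seconds. The test suite
uses reduced axons (9–11 nodes, measurement between nodes 3 and 8, and a
coarser 0.5–1 µs step) for scale-free shape properties, and the full
51-node protocol for all quantitative comparisons.

## The two channel-scaling assumptions

Experimentally, summed nodal Na_V immunofluorescence is approximately
proportional to node length, but with scatter; the package therefore
implements the two bracketing assumptions as modes of
`scale_nodal_channels()`/`build_axon()`:

- **constant density**: conductance densities stay at their tabulated
  values, so channel number grows with node length;
- **constant number**: nodal densities (including the nodal leak, per the
  parameter table's footnote) scale as (mean node length)/(node length),
  freezing channel number at the mean-length value.

At the mean node length the two modes coincide by construction. Under
constant number, speed decreases monotonically with node length; under
constant density the speed/length curve has an interior maximum near
1.7 µm that shifts to longer nodes for longer internodes.

## Known limitations and fidelity to the published model

The package reproduces the published *analytic* quantities exactly
(effective paranodal widths, wrap counts, capacitance fractions,
membrane-area ratios) and the published *constant-number* and
wrap-removal percent speed changes to within ~0.3 percentage points.
Two systematic deviations remain, documented rather than tuned away:

- absolute baseline speeds are ~10 % above the published 2.95 m/s (optic)
  and 2.61 m/s (cortex);
- constant-density percent changes are compressed by roughly a quarter
  (e.g. −10.9 % rather than −14.1 % for the shortest optic nodes), and
  consequently the node-length speed spread for 154 µm internodes is
  ~28 % rather than ~42 %.

Both are consistent with the model's spike being slightly "hotter" (peak
≈ +29 mV versus the ≈ +18 mV implied by the published ~100 mV amplitude),
which traces to the nodal gating kinetics — the one model ingredient not
printed in the source and therefore transcribed from the model family's
standard table. The integrator itself was ruled out by the independent
ODE-solver cross-check and refinement studies, and alternative admittance
and wrap conventions were examined and rejected because they broke the
quantities that *are* printed. Ratios of simulated speeds are markedly
more robust than absolute speeds, which is why the experiment functions
report percent changes against an internally computed baseline.

## The synthetic data generator

`population_model()` encodes a hierarchical node-length population
calibrated to the cortical/callosal measurements: axon mean node lengths
are lognormal (positive, right-skewed) with population mean 1.50 µm and a
between-axon s.d. of √(0.58² − 0.25²) ≈ 0.523 µm — back-computed from the
pooled s.d. (0.58 µm) and the within-axon s.d. (0.25 µm), since the
between-axon component is not reported directly. Node lengths along an
axon are normal about the axon mean (s.d. 0.25 µm, truncated at 0.1 µm);
node counts per axon are Poisson with mean 6.7 (truncated at 2);
internode lengths are normal (82.7 ± 34.5 µm, clipped to the observed
27–154 µm range, the s.d. back-computed from the reported s.e.m. of
6.3 µm over 30 internodes); summed nodal-marker intensity is proportional
to node length with 20 % lognormal multiplicative noise.

`render_profile()` renders a node as two paranodal boxcar bands flanking
the gap, convolved analytically with a Gaussian PSF (default σ = 110 nm)
and sampled at the confocal pixel size (default 52.7 nm, the acquisition
setting for along-axon measurements), plus background and optional
additive noise. What this emulates — and what it does not — matters for
interpreting green tests: profiles are 1-D, nodes lie exactly in the
imaging plane (no tilt foreshortening, which biases real measurements by
~2 %), paranodes have uniform brightness, and noise is white. Passing
closure tests therefore show the *pipeline* is unbiased under these
conditions (< 2 % for gaps ≥ 0.4 µm), not that real microscopy is free of
systematic error.

## Morphometry conventions

`node_length_from_profile()` subtracts a modal background (mean of the
lowest intensity decile; the background-subtraction method used on the
original images is not specified, so a deterministic one was chosen), finds the two paranodal peaks as the two highest local
maxima separated by the deepest valley (ties broken toward the outermost
pair, so the rule is deterministic), and measures the distance between
the node-facing half-maximum crossings, each referenced to *its own*
paranode's peak and interpolated linearly between samples (pixels are
40–100 nm, a large fraction of a short node). Profiles are measured raw
by default; a 3-point smoothing flag exists but is off, matching the
uncertainty about whether the original analysis smoothed.

`along_vs_between_reduction()` compares each axon's coefficient of
variation of node length with the CoV pooled over all nodes of all axons
and reports the mean per-axon percent reduction with its s.e.m. and a
one-sample t-test. On populations calibrated as above (18 axons, ~7 nodes
each) the statistic falls in a 40–60 % band, matching the reported
≈ 49 % reduction; the small-sample CoV bias makes the null case (no
between-axon component) come out a few percent above zero, which the test
suite pins down.

## Reproducing the headline numbers

`scripts/acceptance.R` rebuilds every headline quantity from scratch with
the installed package — geometry analytics, both baseline speeds, the
node-length/wrap percent changes and the 154-µm-internode sweep — and
writes them to JSON; see the README for invocation.
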