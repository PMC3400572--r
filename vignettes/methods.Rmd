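---
title: "Models and methods: location-dependent synaptic summation on basal dendrites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: location-dependent synaptic summation on basal dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Thin basal dendrites of neocortical pyramidal neurons generate local NMDA
spikes: regenerative depolarizations carried by NMDA-receptor channels whose
magnesium block is relieved by depolarization itself. Because the cable
properties of a thin dendrite attached to a low-impedance soma are strongly
asymmetric — proximal sites are clamped by the soma while distal sites see a
high local input resistance — excitatory inputs at different distances from
the soma interact in location-dependent ways. `dendarith` implements the
computational machinery for studying these interactions: a compartmental
cable simulator, a time-invariant two-compartment reduction, the NRLE
nonlinearity statistic, two-input summation mapping, fiducial-point
normalization of heterogeneous cells, firing-rate gain/threshold analysis,
and EPSP time-course metrics, together with a synthetic-cohort generator
standing in for slice recordings.

# The compartmental model

## Cable equation and numerics

The morphology is a tree of cylindrical sections, discretized into electrical
segments no longer than one tenth of the section's AC length constant at
100 Hz, $\lambda_{100} = \frac{1}{2}\sqrt{d/(\pi f R_a C_m)}$, or 10 µm,
whichever is smaller; segment counts are rounded up to the nearest odd
integer so a segment centre always sits at the section midpoint (stable
placement of stimulus and recording sites). The membrane carries leak,
Hodgkin–Huxley-style Na and K currents, and synaptic currents:

$$C_m \frac{\partial V}{\partial t} = -g_L(V-E_L) - \bar g_{Na} m^3 h (V-E_{Na})
 - \bar g_K n^4 (V-E_K) - \sum_s g_s(t)\,B_s(V)\,(V-E_s) + I_{ax} + I_{inj}$$

The voltage step is Crank–Nicolson with conductances frozen over the step
(second order, unconditionally stable); the resulting symmetric tree system
is solved exactly per step by Hines elimination, so each step costs O(n) in
the number of compartments. Gating states advance by exponential Euler at
the start-of-step voltage. Synaptic conductances are evaluated at mid-step
time. Each simulation is preceded by a 200 ms input-free equilibration, and
"peak depolarization" always means the maximum of V minus the
post-equilibration resting value. Halving dt from the 0.1 ms default changes
peak responses by < 0.05% (tested), and halving the 10 µm segment cap
changes them by < 1%.

## Synapses

AMPA and NMDA conductances are difference-of-exponentials waveforms,
peak-normalized so the waveform maximum equals `g_max` exactly
(AMPA 0.05/0.5 ms, 1.5 nS; NMDA 2.1/18.8 ms). The NMDA current is
multiplied by the instantaneous magnesium-block factor
$B(V) = 1/(1+e^{-(V+12)/10})$. Synapse clusters are placed at 0.5 µm
spacing, symmetric about the requested path distance from the soma. Three
stimulus protocols are built in:

* **single pulse** (uncaging-like; NMDA 3.56 nS per synapse) for single-site
  input-output ramps;
* **double pulse** (50 Hz pair; NMDA 2.23 nS on pulse one doubling to
  4.46 nS on pulse two, AMPA fixed) for all two-input summation maps — the
  facilitation is modelled as a per-pulse conductance schedule, not a
  kinetic scheme, because that is the level at which it is specified;
* **Poisson trains** (50 Hz per synapse, NMDA fixed at 3.9 nS, no
  facilitation) for the firing-rate regime.

## Active currents and their calibration

The Na/K currents use the classical HH $m^3h$ / $n^4$ rate functions with
all rates scaled by $2.3^{(35-6.3)/10}$ for 35 °C, and densities per region
from the standard layer-5 set (dendritic Na decreasing linearly to zero at
200 µm from the soma; a myelinated axon with a dense hillock/node Na
mechanism provides spike initiation). Two voltage shifts are the package's
one-time spike-mechanism calibration:

* `na_shift = 12` mV depolarizes activation so that the somatic
  action-potential threshold sits above the subthreshold summation range
  (≈ −55 mV at the soma at the top of the two-input grid). In the slice
  experiments this separation was enforced pharmacologically (TTX at the
  soma or CNQX) whenever somatic spiking intruded; in the model the
  calibrated threshold plays that role, and the cell still fires under
  noisy bias plus strong drive.
* `na_inact_shift = 5` mV additionally depolarizes inactivation relative to
  activation. With the unmodified squid constants the cell accommodates
  (inactivates without firing) under sustained depolarizing bias; cortical
  Na-channel models place inactivation at more depolarized potentials for
  exactly this reason. Larger offsets create a persistent window current
  and depolarization block, so the value is the smallest that restores
  firing.

With these shifts the printed noisy-bias parameters (0.75 ± 1 nA, redrawn
every 0.1 ms) produce a ~1.5 Hz background rate on the calibrated cell, so
`calibrate_bias()` accepts the printed default directly; the bisection
calibration remains available for other geometries.

## The reduced morphology and its calibration

No reconstructed morphology is shipped; SWC import covers users who have
one. The default cell is a reduced stand-in whose geometry was calibrated
once against three published behaviours of the full reconstructed neuron:
(i) maximum NRLE near 3 for single-site ramps, approximately equal at
proximal (70 µm) and distal (160 µm) sites; (ii) a proximal local-spike
threshold reachable within 40 synapses; (iii) an overall two-input
(90/150 µm, double-pulse) grid peak near 15 mV.

A plain ball-and-stick with a few identical 1 µm dendrites cannot meet
these jointly. Systematic scans showed why:

* Subthreshold somatic peaks at proximal sites are dominated by the
  synchronous AMPA volley, whose size is set by the capacitance and
  conductance load near the soma. With too little load the subthreshold
  trend is steep and the spike jump small (NRLE ≤ 1.5).
* The local spike at 70 µm only ignites within 40 synapses if the local
  cable is thin; but a uniformly thin branch attenuates the plateau so much
  that the grid peak falls far short of 15 mV.

Both constraints are satisfied by the geometry of real basal arbors: many
branches (load) that taper (thick stem for somatic coupling, thin distal
cable for ignition). The calibrated default is therefore eleven 275 µm
basal dendrites tapering linearly from 1.08 µm at the soma to 0.43 µm at
the tip on a 15 µm soma, plus the axon. The eleven branches stand in for
the conductance/capacitance load of the full basal-plus-apical arbor of a
layer-5 cell (somatic input resistance ≈ 35 MΩ). Terminal dendrites carry
the ×2 spine correction on membrane capacitance and leak conductance. On
this cell the calibration targets come out as NRLE 2.23/2.26 (proximal/
distal), proximal threshold at 38 synapses, and a grid peak of 13.4 mV.
The calibration was performed once, before the acceptance checks were
frozen, and is not revisited.

# The NRLE statistic and threshold detection

For each point of an input-output curve from the second onward, an ordinary
least-squares line is fitted to all preceding points and extrapolated to
the current abscissa; the ratio of actual to extrapolated response is
recorded, and the maximum ratio along the curve is the NRLE. A linear curve
scores exactly 1, a saturating curve below 1, and a local-spike jump well
above 1. Because zero stimulus physically produces zero depolarization, the
point (0, 0) joins every fit by default (`anchor_origin`), which also makes
the first evaluated fit well-posed; the origin is *not* added when the
curve already starts at x = 0 carrying a meaningful modulator-alone
intercept. Indices with non-positive extrapolations are skipped with a
warning — the ratio is meaningless there.

Local-spike thresholds are read off a curve as the NRLE-maximizing index
(just-suprathreshold) and its predecessor (just-subthreshold), subject to a
jump criterion (NRLE ≥ 1.3 by default) and a robustness guard: candidate
indices must carry a response of at least 20% of the curve maximum, since a
local spike is by construction a substantial fraction of the curve's range.
The guard exists for noisy (synthetic or experimental) curves, where
near-zero early responses otherwise produce spuriously large extrapolation
ratios; it never changes the result on clean model curves.

# The time-invariant two-compartment circuit

Two nodes — proximal (doubling as the somatic readout) and distal — are
joined by an axial conductance (2.5 A.U.); each node carries a leak to rest
(proximal 4, distal 0.25 A.U.) and a steady NMDA source (0.5 A.U. per
synapse) gated by a softer magnesium block, $B(V) = 1/(1+e^{-(V+22)/12})$,
which absorbs the dilution of the NMDA nonlinearity by co-activated AMPA
channels the circuit does not model. Voltages are absolute mV (rest −70,
reversal 0) so the block midpoint is meaningful; "A.U." attaches only to
conductances and currents, with a final linear `output_scale` mapping the
proximal depolarization onto the mV scale of the compartmental map.

The steady state solves the two Kirchhoff equations. The distal equation is
explicit in $V_{prox}$, so $V_{prox}$ is eliminated through it, the
remaining one-dimensional residual is scanned over $[E_{rest}, E_{syn}]$
for sign changes (2000 intervals), and every bracketed root is refined by
bisection to 1e−13. Either node's equation could have been used for the
elimination — both orderings give the same solution set — and the distal
elimination is used because the system is then solved for $V_{dist}$
first. With strong drive the circuit is bistable; all roots are reported
and the branch continuously connected to rest (lowest $V_{dist}$) is the
default solution, the quasi-static interpretation of a time-invariant
model. The suite verifies the reduction against an independent damped-Newton
solver on the full 2-D system over the 41×41 synapse grid (agreement
< 1e−6 mV) and checks that the rest branch is continuous along grid rows.

The current-to-overcome (CTO) at a node is the NMDA drive minus the net
passive (leak + axial) restoring current, with the opposite node relaxed to
its own steady state given the clamped voltage; it is zero at any steady
state of the full circuit, positive where drive wins, negative where the
restoring current wins.

# Two-input summation analysis

`map_two_input()` simulates all combinations of proximal/distal synapse
counts (default 0–40 in steps of 2, i.e. a 21×21 grid; step 1 is available
at 4× the cost) with simultaneous activation and records peak somatic
depolarization. Slicing the map along either axis yields driver/modulator
curve families whose y-intercepts are the modulator-alone peaks; curves are
grouped into quantile categories of modulation strength for averaging, with
an optional exclusion ceiling for modulation levels past the modulator's
own spike (for which no matching experimental cases exist). The regional
variant splits each cluster evenly across sibling branches at matched path
distances.

Two quantifications are deliberately specific:

* **Asymmetry.** The distal-driver family's maximum under the strongest
  modulation exceeds its unmodulated maximum by a far larger relative
  factor than the proximal-driver family's (≈ 14× larger on the calibrated
  model; the suite requires ≥ 2×), while spike-threshold indices shift left
  with modulation in both views.
* **Between-branch additivity.** The interaction deviation
  $|p(i,j)-p(i,0)-p(0,j)+p(0,0)|$ is evaluated over the *deep-subthreshold
  window*: both counts at least one grid step below the respective
  single-site spike thresholds. Outside that window any pair of large
  inputs sums sublinearly through the shared somatic driving-force
  saturation, and counts immediately below threshold cooperate even across
  branches through the somatic depolarization (a knee effect that the
  reduced cell, whose branches all attach directly to a small soma,
  exaggerates relative to a full arbor). Inside the window the score
  separates cleanly: within-branch ≈ 0.5 of the dynamic range (cooperative
  ignition), between-branch ≈ 0.01; the suite requires a ≥ 5× ratio.

# Fiducial normalization

Experimental-style cells differ in stimulus efficacy and response magnitude
(electrode placement, branch diameter). Four landmark points index each
cell's two-input family: the just-suprathreshold distal-alone spike
(triangle), the just-sub- and just-suprathreshold proximal-alone peaks
(square, pentagon), and the just-suprathreshold distal response under a
just-subthreshold proximal bias (circle). The template encodes the average
experimental ratios — triangle (1, 1), square (0, 0.6), pentagon (0, 2.4),
circle (0.6, 2.2). Per cell, two scale factors minimize the mean squared
error between scaled fiducials and template; the problem separates into two
least-squares slopes, $a_x = \sum x_i t_{x,i} / \sum x_i^2$ over the
nonzero-x fiducials (triangle and circle both contribute) and similarly
$a_y$ over all four y values. Only these two numbers rescale the cell's
full data set, so overfitting is structurally impossible. The
proximal-driver view is more uniform across cells and is rigidly scaled by
its pentagon alone onto (1, 2.4).

The "just-subthreshold proximal bias" is operationalized as the largest
modulation level below the proximal spike threshold at which the biased
distal curve still shows a detectable jump: at stronger bias the distal
discontinuity disappears on a finite stimulus grid, which is also why very
strong modulation levels are excluded from curve averaging.

# The synthetic cohort

The generator emulates the *structure* of the slice data set — 6 cells,
29–56 stimulus pairs each (a preset fixes per-cell counts summing to 294) —
without emulating slice physiology. Per cell it draws hidden horizontal and
vertical scale factors from a log-normal with unit median (σ = 0.3; the
experiments report no distribution, and log-normal guarantees positive
factors with multiplicative scatter of the kind electrode placement and
branch-diameter variation produce), warps the canonical model-generated
map, subsamples stimulus pairs, and adds Gaussian measurement noise
(0.3 mV default; the true experimental noise is unreported, so this is a
stated assumption, exposed in the spec object). The sampling protocol is
fixed across cells and always retains the points that define the four
fiducials — the origin, the points flanking each canonical threshold, and
the ramp tops — so extraction cannot fail for structural reasons; with
noise, generation retries a cell up to a logged limit. Ground truth is
stored separately from the observed tables. Zero-noise cohorts are
recovered to machine precision; at the default noise the median factor
error is ≈ 2–3%; recovery error grows monotonically with noise.

What passing these tests shows about real data is deliberately limited: the
cohort inherits the model's curve shapes, so normalization is validated as
an algorithm (parameter recovery under the heterogeneity model), not as a
statement that slice data satisfy the same generative model.

# Firing-rate analysis

Rate experiments deliver independent 50 Hz Poisson trains to a driver and a
modulator synapse group (90 and 190 µm; same branch, or sibling branches
for the between-branch control), bias the soma with the noisy current, and
count somatic spikes (upward 0 mV crossings, 2 ms refractory — the spike
criterion is the package's choice, unambiguous on HH-style spikes) over the
500 ms stimulus window, averaged across repetitions (20 by default,
reducible). Sigmoids $r(x) = r_0 + A/(1+e^{-(x-\theta)/s})$ are fitted by
Levenberg–Marquardt from a grid of starts, with gain $\alpha = A/(4s)$ the
maximum slope; flat curves are flagged degenerate rather than fitted. An
additivity score (maximum interaction deviation over the count grid,
normalized by dynamic range, offset-invariant) quantifies between-branch
linearity.

**Known limitation.** On the reduced morphology the rate-regime
driver/modulator asymmetry does not replicate at desk scale: the thin
distal tip that the subthreshold calibration requires lets two or three
Poisson-driven synapses sustain a local NMDA plateau, so distal-driver rate
curves saturate almost immediately, modulation acts additively, and
$\theta/\alpha$ fits on such curves are degenerate. The asymmetry and
additivity contrasts are therefore established in the subthreshold regime
(where the reduced cell reproduces them robustly), and the rate machinery
is validated on its deterministic properties: Poisson statistics, seed
reproducibility, background-rate calibration at the printed bias, driver
monotonicity, and exact fit recovery on noiseless curves. Users supplying a
full reconstructed morphology via SWC can run the identical protocols on
it.

# EPSP time-course metrics

For the somatic EPSP analysis the model is made passive with R_m and C_m
jointly scaled by 1.6 (matching the half-width range of the cortical
data set this analysis mirrors) and AMPA-only synapses (0.2/2 ms, 2 nS).
Four synapses on four randomly selected dendrites at a common path distance
are activated simultaneously and the compound somatic EPSP is measured:
amplitude (peak − baseline), half-width (width at 50% amplitude, linearly
interpolated) and 10–90% rise time (the convention adopted here;
configurable to other fractions). Means and s.d. are taken across random
dendrite sets. On the reduced cell only the cable-theory orderings are
asserted — half-width and rise time grow with distance, amplitude falls —
because the printed population means belong to an external reconstructed
morphology that is not shipped. The group-comparison utility (Welch t and
Wilcoxon rank-sum) mirrors the statistics used for such contrasts and is
verified against exhaustive enumeration on small samples.

# Problem sizes and reproducibility

The default analysis scales chosen for this package are: 21×21 two-input
grids (step 2; the surface shape is preserved relative to step 1), ramps of
2–40 synapses in steps of 2, 41×41 two-compartment grids (cheap), cohorts
of 6 cells, and rate runs of 500 ms. Every stochastic element (Poisson
trains, noisy bias, cohort generation) consumes the R session RNG, so
`set.seed()` makes any experiment — including the full rate protocol —
bit-reproducible; `run_experiment()` records the seed and full
configuration in a JSON manifest next to every output, from which the
output is re-derivable.
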