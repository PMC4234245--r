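---
title: "Shannon entropy mapping of rotor electrograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shannon entropy mapping of rotor electrograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rotorShEn)
```

## The problem

Rotors -- self-sustained spiral waves of electrical excitation -- are a
candidate driver of cardiac fibrillation, and the pivot of a rotor (its
phase singularity) is a candidate ablation target. Clinical mapping
records *bipolar electrograms* (EGMs): differences between two closely
spaced extracellular electrodes. A bipolar EGM encodes both the timing
and the *direction* of each passing wavefront, because the difference of
the two unipolar potentials depends on the wavefront's angle to the
bipole axis.

At the pivot, wavefronts leave in constantly varying directions; at the
periphery they pass in essentially one direction. The Shannon entropy

$$ H \;=\; -\sum_{i\,:\,p_i>0} p_i \log_2 p_i $$

of the *amplitude histogram* of a bipolar EGM (bin width 1% of the
maximum EGM amplitude, so ~200 bins over $[-\max|w|, +\max|w|]$) is a
morphology-diversity measure: direction-diverse wavefronts generate many
distinct deflection shapes, spread the amplitude histogram, and raise
$H$. This package builds the full computational chain needed to study
that claim: membrane kinetics, 2-D monodomain tissue, spiral-wave
initiation, extracellular forward modelling, filtering, entropy mapping,
tip tracking and wavefront-direction analysis, plus an analytic
(model-free) rotating spiral.

## Cell models and their parameters

Three kinetics are implemented in C++ behind one interface
(`cell_model()`, `model_rhs()`, `pace_cell()`):

* **FitzHugh--Nagumo** (cubic form), $dv/dt = v(v-a)(1-v) - w$,
  $dw/dt = \epsilon(\beta v - \gamma w - \delta)$. Defaults
  $a=0.1,\ \epsilon=0.01,\ \beta=0.5,\ \gamma=2,\ \delta=0$. The
  recovery slope $\gamma$ was chosen by experiment: with $\gamma = 1$
  the spiral *meanders* strongly (circle-fit residual near the core
  radius itself), while $\gamma = 2$ gives the textbook rigidly rotating
  spiral -- the regime the FHN experiments are meant to illustrate. The
  period is then constant to better than 1% across rotations.
* **Luo--Rudy 1991** (8 states), with the slow-inward Ca$^{2+}$
  conductance `gsi` (mS/cm$^2$) exposed; the published model is the
  default (`gsi = 0.09`, APD$_{90}\approx 360$ ms). Single-cell
  APD$_{90}$ grows monotonically over the sweep
  `gsi` $\in \{0, 0.02, 0.03, 0.043\}$. For *tissue* spiral waves the
  nominal kinetics never complete a re-entrant circuit at desk scale
  (the returning front always meets refractory tissue), so the rotor
  experiments use the parameter set of the spiral-meander literature,
  `lr_spiral_params()`: $G_{Na}=16$, $G_K = 0.423$ and the Ca-gate time
  constants $\tau_d, \tau_f$ halved. With it the meander sequence is
  reproduced: a tight circular core at `gsi = 0`, growing to a broad
  rosette at `gsi = 0.043` (convex-hull areas 438 / 970 / 2750 / 5927
  nodes$^2$ in the shipped profile).
* **Courtemanche--Ramirez--Nattel 1998** (21 states). Scale factors
  `s_cal`, `s_to`, `s_kur` multiply $I_{CaL}, I_{to}, I_{Kur}$; all
  default to 1 (the published cell, resting $-81.2$ mV,
  APD$_{90}\approx 300$ ms). `af_remodeling()` returns the electrical
  remodelling used for the rotor experiments
  ($I_{CaL}\times 0.3$, $I_{to}\times 0.5$, $I_{Kur}\times 0.5$), which
  shortens the AP enough for a stable rotor in a 4 cm sheet. The
  headline conclusions do not depend on this particular choice; any
  parameterization that sustains a rotor will do.

Every model's resting state is obtained by relaxing a quiescent cell
numerically, so it is a genuine fixed point of the right-hand side
(max-norm $< 10^{-3}$) for *any* parameter values.

## Tissue, initiation and the phase library

`simulate_tissue()` integrates the monodomain system
$\partial_t \mathbf{s} = \mathbf{f}(\mathbf{s}) + D\nabla^2 v$ with
forward-Euler time stepping, Rush--Larsen exponential updates for all
gating variables, a 5-point Laplacian and no-flux boundaries. Time steps
are 0.05 t.u. (FHN; the diffusion stability bound
$dt \le dx^2/4D = 0.0625$ rules out larger steps) and 0.02 ms
(LR91/CRN), validated by dt-halving. Voltage-dependent rates are
tabulated on a 0.05 mV grid at integration start; reversal potentials
that drift on a seconds timescale are refreshed every 1 ms.

Spirals are initiated by painting a phase field
$\theta(r,\phi) = \mathrm{frac}(k\phi/2\pi + r/\lambda)$ and assigning
each node the full kinetic state of a *cycle library*
(`build_cycle_library()`): one action-potential cycle of a paced single
cell, indexed by $\theta\in[0,1]$ with $\theta=1$ at the maximal
$dv/dt$ (wavefront) and $\theta=0$ at rest. After a settling window the
re-entrant wave has forgotten the initiation details.

Shipped simulation profiles (`experiment_config()`, `"ci"` vs
`"paper"`): FHN 120$\times$120 ($dx=0.5$, $D=1$); LR91 192$\times$192
and CRN 160$\times$160 at $dx = 0.025$ cm with $D = 3\times10^{-4}$
cm$^2$/ms. This diffusion gives conduction velocities of 25--30 cm/s --
appropriate for remodelled myocardium -- and, more importantly, a
re-entrant wavelength that fits the sheet; at the often-quoted
$10^{-3}$ cm$^2$/ms both physiological models have S1 wavelengths of
5--9 cm and every desk-scale rotor self-terminates within one rotation
(verified systematically). The EGM sampling interval is 0.5 ms (2 kHz)
so that a 500 Hz low-pass remains below Nyquist.

## The extracellular forward model

`unipolar_field()` computes, per node and frame,
$u_{i,j}(t) = c\sum_{k,l} S_{k,l}(t)/r_{k,l}$ with $c=1$ and
$r = dx\sqrt{(i-k)^2+(j-l)^2+h^2}$; the electrode sits $h$ node
spacings above the sheet ($h = 1$ by default, which regularizes the
self-term). Two source conventions are implemented, because the
literature uses both and the difference matters:

* `source_mode = "laplacian"` (package default): $S = -\nabla^2 v$, the
  standard current-source-density kernel. Local activity dominates;
  periphery EGMs are sharp spikes, the pivot broad and fractionated.
* `source_mode = "voltage"`: $S = v$ itself, the literal
  inverse-distance sum of transmembrane voltage. Far-field activity
  dominates; all EGMs are smooth and the entropy map floor is high.

The double sum is evaluated exactly by FFT convolution and is verified
against a brute-force double loop to $10^{-10}$. `bipolar_field()`
takes spaced differences along either grid axis, crops the grid by the
spacing, and registers each bipole at the midpoint of its poles so maps
at different spacings stay co-registered.

Map statistics (max, min, median, arg-max) exclude a 5-site boundary
margin (`edge_margin`): edge electrograms see a truncated 1/r sum and
the no-flux boundary, and their entropies are not trustworthy. All site
values are still computed and returned.

### Which preset reproduces which result

The shipped experiments use two documented presets:

* **CRN experiments and the geometric spiral** (spacing, orientation,
  filtering sweeps): `voltage` + per-trace histograms. This is the
  literal reading of the unipolar equation and reproduces the printed
  entropy scale (map minima near 4.8--5.2 bits, maxima near 6.5--7.4).
  The high-entropy area overlies the rotor's meander region -- the
  arg-max lies on or inside the meander hull -- at every spacing and
  under every shipped filter except the 0.5 Hz high-pass (whose
  near-DC baseline droop delocalizes the map at desk scale); the
  stricter arg-max-to-trajectory-curve distance is within 3 sites in
  most, not all, cases because the rosette trajectory is a sparse
  curve.
* **FHN and LR91 experiments**: `laplacian` + map-global histograms.
  For the rigidly rotating FHN spiral the far-field mode develops
  stationary amplitude-null lines whose near-zero, noise-like traces
  get spuriously high per-trace entropy; the current-source kernel with
  a global amplitude reference is robust there (and for all LR91
  meander cases).

## Entropy

`amplitude_histogram()` implements the 1%-of-maximum bin rule; the
histogram default spans $[-\max|w|, +\max|w|]$ (200 bins;
`range_mode = "min_to_max"` is available). `reference = "per_trace"`
normalizes each trace by its own maximum (entropy becomes a pure
morphology measure); `"global"` uses one maximum per map (amplitude
information is retained). Empty bins contribute $0\log 0 = 0$; an
all-zero trace is assigned entropy 0 with a notice. Entropies are in
bits, consistent with map extrema bounded by $\log_2 200 = 7.64$. The
analysis window is the final 80% of the recording.

Note that the *absolute* entropy level depends on the number of samples
per trace (more samples occupy more bins): comparisons against printed
values from recordings of unknown length are only meaningful to a few
tenths of a bit.

## Tip tracking and wavefront directions

`track_tip()` intersects the marching-squares isolines of $v = v_{iso}$
and $dv/dt = 0$ (centered differences across frames) with exact
sub-grid segment--segment intersection, keeps per frame the candidate
nearest the previous tip, and rejects candidates whose local
(9$\times$9-node) voltage range is below 30% of the movie's range --
the pivot has all phases in close proximity, spurious crossings on weak
far-field wave crests do not. The default iso-level is the half-maximal
voltage of phase 0 ($-30$ mV for LR91/CRN, 0.5 for FHN): a $v=0$ rule
presumes the spike peak stays above 0 mV, which rate-adapted re-entrant
APs do not reliably satisfy, and the $v=0$ isoline then interleaves
with the spike-crest line all along the wavefront.

`wavefront_mask()` selects the depolarizing half-maximal band
($(v_{max}+v_{min})/2 \pm 10\%$ of the range, $dv/dt > 0$), with the
extrema taken over the whole movie: per-frame extrema fluctuate with
repolarization and destabilize the level. `propagation_direction()`
returns $\psi = \mathrm{atan2}(-\partial_y v, -\partial_x v)$ -- the
down-gradient direction, anchored by the planar-wave convention
$\psi = 0$ for $+x$ propagation. `meridian_direction_scatter()` collects
direction samples where the wavefront crosses a full-width line, and
`meridian_spread_profile()` computes the sliding-window (11-node)
circular spread $1 - R$, the quantitative form of "directional
diversity".

## The analytic geometric spiral

`geo_spiral_spec()` defines an Archimedean spiral (pitch $a = 4$,
period 100 t.u.) whose wavefront is a linear voltage ramp of constant
gradient $v_{amp}/\textit{front\_width}$. The published construction's
exact equations are not available; this reconstruction keeps the two
stated properties (rigid rotation, constant front gradient) and closes
the excited band with a second linear ramp (`back_width`) so the
profile is continuous -- a jump-discontinuous wave back would act as a
rotating dipole sheet that swamps every local deflection. The spiral is
sampled on a quadrature mesh (0.25 length units, finer than the front)
and fed through the *same* forward-model and entropy code as the
simulated tissues. Entropy at the core (maximum within one pitch of the
rotation center) exceeds the periphery value ten pitches out for every
spacing in $\{1,2,4,8,12,16\}$ units, and the central bipole shows more
zero crossings per rotation than a peripheral one.

## Filtering

Butterworth low-/high-pass IIR filters (3rd order by default) are
designed in-package by the analog-prototype + bilinear-transform route
and verified against the analytic magnitude response
$|H| = (1+(f/f_c)^{2n})^{-1/2}$. The default application is zero-phase
(forward--backward, squared magnitude, no phase shift -- deflection
morphology is what the entropy sees); `causal` single-pass application
is available. Zero-phase filtering uses odd-symmetric padding of three
cutoff time constants, processed in column blocks to bound memory on
whole-field filtering.

## What the generator does and does not emulate

The synthetic world is a homogeneous, isotropic, noiseless 2-D
monodomain sheet with ideal point electrodes. It deliberately omits:
measurement noise and baseline wander, electrode size/contact effects,
anisotropy and fiber rotation, 3-D wall thickness, tissue heterogeneity
and fibrosis, and torso volume conduction. A green test therefore
establishes that the entropy-at-pivot phenomenon is a property of
spiral-wave *kinematics plus the bipolar recording geometry* -- not
that it survives clinical signal quality, which the source literature
itself flags as the practical caveat.

Known desk-scale limitations, measured and accepted rather than hidden:

* Absolute map extrema differ from printed values by 0.3--1.5 bits
  (sample-count dependence above; the original recording length is
  unpublished). The d = 1 map minimum agrees to ~0.4 bits.
* The printed strong *rise of the map floor* with bipole spacing
  (min 5.20 to 6.26 bits) is not reproduced: at our domain size the
  far corners remain genuinely far from the rotor at every spacing and
  the floor stays near 4.8 bits. The map *maximum* does increase with
  spacing, as printed.
* For the widely meandering LR91 rotor (`gsi = 0.043`) the
  one-dimensional coincidence of the spread-maximizing and
  entropy-maximizing segments along a single fixed meridian breaks
  down: the pivot wanders over half the sheet and no single line
  represents it. The two-dimensional statement (map arg-max inside the
  meander hull) holds for every Gsi.

## Numerical bookkeeping

* Diffusion stability `dt <= dx^2/(4D)` is enforced before integration;
  voltage excursions outside plausible bounds abort with the offending
  frame index.
* Rate lookup tables: 0.05 mV grid, linear interpolation; gate updates
  are Rush--Larsen, so gates cannot leave [0, 1].
* The integrator is deterministic; re-running a configuration
  bit-reproduces the summary table. No randomness exists anywhere in
  the pipeline (the config seed is reserved for user-added electrode
  subsampling).
* Cycle-library pacing declares failure (with diagnostics) if two
  consecutive beats differ by more than the tolerance within the beat
  budget.
* Degenerate inputs: all-zero traces get entropy 0 with a notice;
  constant maps are rendered with a full-range fallback; empty tip
  trajectories are legal return values (planar and target waves).
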