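---
title: "A dynamic neural field model of somatotopic map formation and reorganization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic neural field model of somatotopic map formation and reorganization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

## The scientific problem

Primary somatosensory cortex (area 3b) holds an ordered map of the skin:
neighboring cortical neurons respond to neighboring skin locations. The
map is not wired once and frozen — it forms during the critical period
from sensory experience, is maintained by the same experience in
adulthood, and reorganizes after peripheral injury (silenced receptors)
or cortical damage (dead neurons). `somatomap` implements a deliberately
compact model of this process: the only plastic elements are the
feed-forward (thalamocortical) weights from a sheet of skin
mechanoreceptors onto a cortical sheet, while fixed lateral
cortico-cortical connections provide the competition that makes
self-organization possible.

## The model, piece by piece

**Skin.** The skin patch is the unit square carrying `n = rows × cols`
Merkel-ending receptors (default 16 × 16 = 256, the approximate count
for a ~1 mm² fingertip patch at natural Merkel density). Receptors sit
on a regular grid plus a small uniform position jitter (default
amplitude 0.01, clipped to the patch), giving the quasi-uniform
arrangement seen anatomically. A point press at **c** drives receptor
*i* by `exp(-d²/2σ²)` of its distance `d` to **c**, with σ = 0.15: skin
mechanics spread pressure to neighbors. Silenced (lesioned) receptors
transmit exactly zero.

**Cortex.** The sheet is an `m × m` lattice on the unit square
(default 32 × 32 = 1024 units). Membrane potential evolves as

τ ∂V/∂t = −V + α κ (w ⋆ f(V)) + I,

with rectified firing `f(V) = max(V, 0)` (the simplest firing function
that stabilizes such a field), a difference-of-Gaussians lateral weight
`w(Δ) = Ke·exp(-‖Δ‖²/2σe²) − Ki·exp(-‖Δ‖²/2σi²)`, and forward-Euler
integration. The inhibitory width σᵢ = 1.0 spans the whole normalized
sheet: inhibition is effectively global, excitation local (σₑ = 0.1),
which is what collapses activity into a single bump.

**Input.** Each unit `x` holds a feed-forward weight vector
`w_f(x) ∈ [0,1]^n`. Its input is a match score,
`I(x) = G(x)·(1 − mean|s − w_f(x)|)`: 1 for a perfect match, 0 for a
maximal mismatch. `G` is a fixed radial Gaussian gain (μ_c = 0,
σ_c = 2.1; 1.0 at the center, ≈ 0.945 at the corners) whose role is
boundary correction — see *Discretization* below.

**Plasticity.** After the field settles on a stimulus, every unit moves
its weights toward the receptor pattern at a rate set by the *lateral
excitation* it receives, `Le = κ (w_e ⋆ f(V))` with `w_e` the excitatory
lobe alone:

w_f(x) ← w_f(x) + γ · Le(x) · (s − w_f(x)), γ = 0.05.

The presynaptic difference term gives Hebbian growth below the stimulus
and anti-Hebbian decay above it, so weights are self-limiting (an
Oja-style rule); the postsynaptic factor `Le` — rather than the firing
rate itself — extends learning beyond the firing bump to its excited
neighbors, which is what drags neighboring units toward neighboring
stimuli and orders the map. A neuron below firing threshold still
learns if it is excited. While `γ·Le ≤ 1` each update is a convex move,
so weights provably stay in `[0,1]`; the package monitors this bound
(a warning in the overshoot regime) but never clips.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| Ke, Ki | DoG excitation / inhibition amplitude | 3.65, 2.40 | activity |
| σe, σi | DoG excitation / inhibition width | 0.1, 1.0 | sheet widths |
| μc, σc | corrective-gain offset / width | 0.0, 2.1 | sheet widths |
| σ | stimulus pressure spread | 0.15 | patch widths |
| dt, τ | Euler step, membrane time constant | 0.2, 1.0 | time |
| α | lateral-term scaling | 0.1 | — |
| γ | learning rate | 0.05 | — |
| m | cortical lattice side | 32 | units |
| κ | lattice-convolution gain | calibrated | — |

All spatial quantities are normalized: both sheets live on [0,1]², and
every Gaussian uses the `exp(-d²/2σ²)` convention.

## Discretization: the lattice gain κ and the circular convolution

Two discretization choices are genuinely open when putting this field
on a lattice, and the package fixes both against behavior the model
must show.

**The matching property fixes κ.** The continuous field's parameter set
has a signature property: for a uniform input of level `c`, the settled
field's maximum rectified activity is `c` — the field neither amplifies
nor attenuates what it is told, while still collapsing it into a bump.
On a lattice, the raw convolution sum scales with resolution, so a
single dimensionless gain κ multiplies it. Because the rectified
dynamics are positively homogeneous (scaling the input scales the whole
trajectory), the property holds at *every* level as soon as it holds at
level 1 — so κ is fully determined by one scalar equation, which
`calibrateLateralGain()` solves by bisection (settling the field on a
uniform unit input fed through `G`, as all input is). Calibrated
defaults ship for the standard lattices (2-D m = 32: κ ≈ 0.1739,
2-D m = 16: κ ≈ 0.8952, 1-D m = 32: κ ≈ 0.5862); any other geometry is
calibrated on first use. `matchPropertyCheck()` verifies the property —
with the shipped defaults the residual `|max − c|` is ~1e-8 at levels
0.25/0.50/0.75 in both 1-D and 2-D.

**Boundary handling.** The lattice convolution is circular (a plain FFT
product). This is a numerical device, not a claim that the cortex is a
torus — and it is precisely what the corrective gain `G` corrects: by
attenuating input near the sheet border it keeps activity bumps off the
wrap seam. The alternative, zero-padded convolution, was implemented
and rejected as the default for a structural reason: with zero padding,
border units receive systematically less inhibition than interior ones
(the inhibitory lobe spans the whole sheet), so the settled bump is
always pulled to a corner regardless of which stimulus is present, and
no topographic map can form. On the torus the competition is
translation-invariant and the bump position is controlled by the
stimulus match, as the model requires. Zero-padded convolution remains
available via `fieldParams(boundary = "linear")` for sensitivity
checks.

One asymmetry follows deliberately: the *learning* neighborhood does
not wrap. `lateralExcitation()` defaults to the zero-padded
convolution, because a wrapping `Le` lets border units learn from bumps
on the opposite edge of the sheet — anatomically meaningless, and in
practice the seed of occasional fold defects in the final map (about
one run in ten ends with one axis of the map partially folded if `Le`
wraps; none do otherwise, across the seeds we tested).

## The training protocol

Each epoch: draw one stimulus uniformly from a fixed 16 × 16 grid of
centers spanning `[0.1, 0.9]²` (the margin keeps the σ = 0.15 press
essentially on the patch); compute receptor activations and the input
map; integrate the field from rest for at most 50 Euler steps (10 τ) or
until `max|ΔV| < 1e-6`; apply the learning rule once on the settled
activity; reset the field to rest (pressure removed). Full-scale runs
default to 10,000 epochs; the reduced-scale experiments in the tests
and the acceptance script use an m = 16 field with 2000 epochs, which
train in ~15 s and show every qualitative behavior of the full model.

Two scheduling choices deserve their rationale:

* **Per-epoch learning (default).** Applying the rule once on the
  settled bump is deterministic and matches the rule's reliance on the
  *converged* competitive outcome. The alternative — applying it at
  every Euler step, scaled by `dt` — is implemented
  (`trainingConfig(per_step = TRUE)`) but demonstrably harmful as a
  default: during the pre-competitive transient the activity (and hence
  `Le`) is broad, so every unit is dragged toward every stimulus and
  the map collapses toward the mean stimulus.
* **Weight initialization** is i.i.d. uniform on [0,1], matching the
  range of receptor activations and weights.

Early in training the input map is nearly flat (random weights match
every stimulus about equally), so the field needs many steps to break
symmetry and the bump is broad; as weights differentiate, the input
sharpens and settling accelerates. This emergent coarse-to-fine
schedule — broad neighborhoods early, sharp ones late — is exactly what
classic self-organizing maps impose by hand through annealed
neighborhood radii, and here it falls out of the dynamics.

## Lesions

`lesionSpec()` / `makeLesionMask()` build axis-aligned masks of three
topological types, rasterized on a grid and applicable to skin
(receptors inside the region are silenced; the stimulus *set* is
unchanged, since real stimuli are larger than the lesion and still
recruit its neighbors) or cortex (units nullified at every integration
step). Type I is a border-touching rectangle (survivor region
topologically intact), type II a full-width band (survivor region split
in two), type III an interior rectangle (survivor region with a hole).
`maskTopology()` verifies the signature by 4-connected component
counting (4-connectivity avoids diagonal leakage at band corners).
Default fractions: 0.25 for types I/II, 0.10 for type III; extents and
placements are configurable, and masks use closed regions (boundary
cells lesioned) so membership is deterministic.

The mechanism of post-lesion reorganization needs no new machinery:
silenced receptors transmit `s_i = 0`, so the presynaptic difference
term actively decays the weights that point at dead skin — receptive
fields migrate off the lesion. Dead cortical units stop competing, so
their neighbors' excitation expands into stimuli that previously
belonged to them — surviving receptive fields grow and recapture the
orphaned skin. For this reason lesioned receptors must *not* be masked
out of the learning rule.

## Receptive-field analysis

`computeReceptiveFields()` probes the model with a 25 × 25 stimulus
grid (a compromise between receptive-field resolution and runtime;
configurable), with learning disabled — probing is side-effect free.
A unit's receptive field is its settled rectified activity across
probes; its center is the activity-weighted centroid of probe
positions, and its size the fraction of probes with a strictly positive
response. "Strictly positive" is taken relative to the unit's own
maximum (threshold 1e-6 × max) so that FFT round-off at the 1e-16 level
never counts; an all-zero receptive field has size 0 and a *missing*
center (flagged, not an error). Size histograms use 100 equal bins on
[0,1] and exclude nothing — the near-zero spike from mostly silent
border units is part of the reported distribution.

`topographicOrder()` quantifies "a map has emerged" as the per-axis
Pearson correlation between unit lattice coordinates and
receptive-field centers, over units with defined centers. A
self-organized map is free to come out in any of the eight orientations
of the square, so the metric evaluates both axis assignments (identity
and swapped — the diagonal reflections) and reports the signed
correlations of the better one plus an `axes_swapped` flag. Acceptance
checks use `|r|`.

## What the synthetic data emulate — and what they do not

All inputs are generated in code: the jittered receptor sheet, Gaussian
point presses on regular stimulus grids, and rectangular lesion masks.
These capture the geometry of the biological setting (quasi-uniform
Merkel density, overlapping pressure profiles, spatially contiguous
lesions) but deliberately idealize everything else: receptors are
noiseless and non-adapting, stimuli are single simultaneous point
presses of equal intensity, subcortical relays (dorsal root ganglion,
dorsal column nuclei, thalamus) are pass-through, and other
mechanoreceptor classes and modalities are absent. A passing test suite
therefore says the *mechanism* — competition plus excitation-gated
feed-forward plasticity — forms and reorganizes maps under these
idealized conditions; it does not certify quantitative agreement with
biological receptive-field measurements.

## Numerical choices

* Settling: `max_steps = 50`, `tol = 1e-6` during training and probing
  (stimulus-driven bumps converge well within 10 τ once training is
  underway). The matching-property check instead settles from a nearly
  uniform state, where symmetry breaking is slow, and uses up to 4000
  steps at `tol = 1e-10`.
* The FFT path of `latticeConvolve()` is verified against a direct
  O(m⁴) double loop to 1e-10 on small grids, for both kernels and both
  boundary rules.
* Divergent integrations (non-finite V, e.g. from a pathological
  `dt/τ`) abort with an error rather than propagate.
* Ties in `which.max` (bump location) follow R's first-index rule; the
  only place this matters is the response-map recapture diagnostic,
  where it is inconsequential.
* Bit-reproducibility: every stochastic step (patch jitter, weight
  init, stimulus draws) runs under a locally seeded RNG that restores
  the caller's RNG state, so identical seeds give byte-identical weight
  tensors and histories.

## Known limitations

* Lateral connections are fixed by design, so the model reproduces
  receptive-field *expansion* after cortical lesions but not the
  second, sharpening phase of biological recovery — with frozen
  competition there is no mechanism to re-refine expanded fields.
* At the reduced scale used for fast experiments (m = 16, 2000
  epochs), a small fraction of runs (roughly one in twenty across the
  seeds we examined) retains a partial fold on one axis of the map
  (|r| ≈ 0.8 instead of ≥ 0.95). The packaged experiments use fixed
  seeds and are deterministic.
* The calibrated gain κ depends on the lattice geometry; comparing
  simulations across resolutions means each carries its own κ.
* Receptive-field sizes are resolution-limited by the probe grid; with
  the default 25 × 25 probes the smallest nonzero size is 1/625.
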