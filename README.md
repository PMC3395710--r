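# somatomap

Formation, maintenance and lesion-induced reorganization of ordered
topographic maps in primary somatosensory cortex (area 3b), modeled as a
two-dimensional dynamic neural field driven by a patch of skin
mechanoreceptors.

The package is for computational neuroscientists who want a compact,
fully reproducible simulation of somatotopic map plasticity: how a
cortical sheet wires itself to a skin surface through experience, and
how the same learning rule reorganizes the map after sensory
deprivation (skin lesions) or cortical damage.

## The model

A 1 mm² fingertip skin patch carries n = 256 Merkel ending complexes on
a jittered 16 × 16 grid over the unit square. A point press at location
**c** activates receptor *i* at position **x**ᵢ as

  sᵢ = exp(−‖**x**ᵢ − **c**‖² / 2σ²),  σ = 0.15.

The cortical sheet is an m × m lattice (m = 32 by default) of units with
membrane potential V(**x**, t) obeying a rectified-firing neural field
equation, integrated by forward Euler with FFT lattice convolution:

  τ ∂V/∂t = −V + α κ (w ⋆ max(V, 0)) + I,

where w is a difference of Gaussians (short-range excitation, long-range
inhibition; Kₑ = 3.65, Kᵢ = 2.40, σₑ = 0.1, σᵢ = 1.0) and κ is a
calibrated lattice gain (see below). Each unit carries a feed-forward
weight vector **w**f(**x**) ∈ [0,1]ⁿ, and its input measures how well
those weights match the current stimulus:

  I(**x**) = G(**x**) · (1 − (1/n) Σᵢ |sᵢ − w f,i(**x**)|),

with G a fixed corrective Gaussian (σ_c = 2.1) that compensates the
boundary side-effects of the lattice convolution. The competition
between excitation and inhibition collapses activity into a single
localized bump; the bump's lateral excitation L_e = κ (w_e ⋆ f(V)) then
gates an Oja-style update of the feed-forward weights,

  **w**f(**x**) ← **w**f(**x**) + γ L_e(**x**) (s − **w**f(**x**)),  γ = 0.05,

so winners and their excited neighbors move toward the stimulus. This is
the only plastic pathway — lateral weights stay fixed. Repeated random
stimulation orders the map; the same rule reorganizes it after a lesion.

The parameter set has a characteristic *matching property*: the settled
field neither amplifies nor attenuates a uniform input — the maximum
settled activity equals the input level. The lattice gain κ is the one
free discretization constant, and the package fixes it by calibrating
against exactly this property (`calibrateLateralGain()`); calibrated
defaults for the standard lattices ship with the package.

Lesions come in three topological types, applicable to skin (silenced
receptors) or cortex (nullified units): type I touches the border and
preserves the domain's topology, type II is a band that splits it in
two, type III punches an interior hole.

## A worked example

Train a reduced-scale model (16 × 16 field, 2000 stimulus
presentations, ~15 s) and measure its map:

```r
library(somatomap)

params <- fieldParams(m = 16)
patch  <- buildSkinPatch(seed = 1)          # 256 receptors
model  <- newFieldModel(params, patch, seed = 2)
fit    <- trainModel(model, trainingConfig(epochs = 2000), seed = 3)

rfs <- computeReceptiveFields(fit$model)    # 25 x 25 probe stimuli
ord <- topographicOrder(rfs$centers, unitPositions(16))
round(ord$r, 3)
#>      x      y
#> -0.995 -0.995
mean(rfs$sizes[rfs$defined])
#> [1] 0.06857143
```

The per-axis correlations near ±1 say that neighboring cortical units
now listen to neighboring skin locations (signs and axis order are
arbitrary — a self-organized map is free to come out reflected or
rotated). The mean receptive-field size ≈ 0.07 means a typical unit
responds to about 7% of the probed skin locations.

Cut the skin in half with a band lesion and retrain:

```r
spec <- lesionSpec("skin", "II", grid_shape = c(16L, 16L))
fit2 <- runLesionExperiment(fit$model, spec, trainingConfig(epochs = 2000), seed = 4)
```

Receptive-field centers migrate out of the silenced band (in the run
above, the fraction of centers inside the band drops from 0.45 right
after the lesion to 0.19 after retraining), reproducing the
deprivation-induced reorganization seen in somatosensory cortex.

A command-line driver with `train`, `lesion`, `match-check` and
`analyze` subcommands is installed under `inst/cli/somatomap.R`.

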