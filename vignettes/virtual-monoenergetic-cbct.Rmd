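---
title: "Virtual monoenergetic micro-CBCT: model, simulation and network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual monoenergetic micro-CBCT: model, simulation and network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Preclinical irradiation cabinets image mice at low tube potentials
(about 60 kVp), where photoelectric absorption dominates and the linear
attenuation coefficient of tissue varies steeply with photon energy. A
polyenergetic beam therefore *hardens* as it penetrates: low-energy
photons are removed preferentially, the surviving spectrum becomes more
penetrating, and the measured line integral
$p = -\ln(I/I_0)$ grows sublinearly with path length. After filtered
backprojection this nonlinearity appears as cupping in uniform objects
and as spurious gradients at the periphery of the animal.

The effect is worst in the *pancake* geometry: source and detector are
stationary and the animal rotates about a vertical axis perpendicular
to its long (cranio-caudal) axis, so the beam alternates between short
lateral paths and very long longitudinal paths through the body. A
single water-based precorrection cannot linearize both regimes at once.

`monoct` implements the learning-based alternative: a projection-domain
U-Net that maps each measured polyenergetic projection to the *virtual
monoenergetic* projection that an idealized 35 keV beam would have
produced. For a monoenergetic beam the line integral is exactly
$\int \mu_{35}\,\mathrm{d}\ell$, so reconstructions of corrected
projections are free of spectral nonlinearity by construction. The
35 keV operating point sits just above the iodine K edge (33.2 keV),
which keeps the mapping applicable to contrast-enhanced protocols.

## Forward model

Projections are simulated by deterministic primary-beam transport
rather than Monte Carlo. For each detector pixel a single ray is traced
from the point source through the voxel grid with an exact Siddon
traversal, giving per-material intersection lengths $\ell_m$ (cm). The
detected signal is

$$ I = \sum_E w(E)\, D(E)\, \exp\Big(-\sum_m \mu_m(E)\,\ell_m\Big),
\qquad p = -\ln(I/I_0), \quad I_0 = \sum_E w(E) D(E), $$

with $w(E)$ the source spectrum and $D(E)$ the detector response on a
1 keV grid from 5 to 60 keV (bin centers; the lower edge matches the
energy below which photons are not tracked). This captures beam
hardening exactly while omitting scattered fluence, secondary
electrons, focal-spot blur and detector glare — the method under study
corrects spectral nonlinearity, not scatter, and the corresponding
reference simulations likewise transported no secondary electrons.
Because air contributes less than $10^{-3}$ to any line integral at
these path lengths, label 0 is treated as non-attenuating.

**Spectrum.** The 60 kVp tube spectrum is modelled as thick-target
(Kramers) bremsstrahlung, $w(E)\propto \max(0, \mathrm{kVp}/E - 1)$,
filtered through 0.8 mm beryllium and 1.0 mm aluminum by per-bin
Beer–Lambert attenuation. Tungsten K lines are not excited below
69 kVp, so filtered bremsstrahlung is adequate at this potential; the
anode angle and heel effect are ignored. An externally computed
spectrum can be loaded from two-column text (`read_spectrum()`) if a
dedicated tube model is preferred.

**Attenuation data.** Per-element mass attenuation tables (total, with
coherent scatter) for H, C, N, O, Na, Mg, Al, Si, P, S, Cl, K, Ca, Fe,
I, Cs and Be ship as plain TSV and are interpolated log-log.
Absorption edges are stored as duplicated energy rows (Fe, I, Cs);
energies are tabulated to 0.1 keV, so the iodine K edge sits at
33.2 keV, and a query exactly at an edge takes the above-edge branch.
L-edge fine structure below 6 keV is smoothed; those energies carry
negligible fluence after filtration. Materials combine elements by the
mixture rule $\mu(E) = \rho \sum_i w_i (\mu/\rho)_i(E)$.

**Detector.** The default response is energy-integrating behind the
panel's entrance stack:
$D(E) = E\,e^{-\mu_C(E) t_\mathrm{plate}}\,(1 - e^{-\mu_\mathrm{CsI}(E) t_\mathrm{scint}})$
with a 1 mm carbon plate and a 600 µm CsI scintillator. Whether the
physical panel scores deposited energy or counts is not observable
from outside; energy integration is the conventional assumption for
indirect flat panels, and ideal photon-counting and plain
energy-integrating modes are provided for analytic tests. The glass
substrate and aluminum backing sit behind the scintillator and do not
attenuate the detected signal.

**Geometry.** Source–isocenter 353.4 mm, isocenter–detector 271.0 mm,
full panel 176 × 128 mm² at 0.5 mm pitch. Simulation runs in the
rotating-phantom frame: at angle $a$ the beam direction is
$(\cos a, \sin a, 0)$ with the rotation axis along $z$ and the
phantom's long axis along $x$, so $a = 0$ looks down the long axis
(longest paths) and $a = 90^\circ$ crosses the animal laterally. A
`conventional` mode (long axis along the rotation axis) exists for
comparison. Projections for network training downsample the full panel
to 64 × 64 pixels (2.75 × 2.0 mm pitch) with the same distances: the
field of view — and hence which animals are truncated at the detector
edge — matches the full-resolution system, and the spatial size stays
divisible by the pooling depth of the desk-scale network. The training
corpus is rendered with 2 × 2 detector-aperture supersampling (sub-rays
averaged in the intensity domain), modelling the area-scoring pixels
of a real panel; single-ray tracing through pixel centers remains the
default analytic contract of `project_mono()`/`project_poly()` and is
what every closed-form oracle in the test suite uses. Noise is off by
default; optional Poisson noise at a configurable flood-level count is
seeded and reproducible.

## Synthetic phantoms and augmentation

Training data come from two procedural generators, not from an atlas:

* **Mouse-like phantoms** — an elongated ellipsoidal body with skin
  shell, a head (optionally lifted out of the body axis, as happens
  when the snout rests in an anesthesia cone), brain, cortical skull
  shell, a connected trabecular (spongiosa) spine — modelling the
  vertebral column as solid cortical bone would let axial rays
  traverse centimetres of dense bone that no real mouse presents —
  paired lungs and kidneys, heart, liver, intestine and a fat depot:
  at least 10 tissue labels drawn from a 15-tissue reference
  composition library (ICRU-style compositions). An optional
  water-filled tube below the body mimics a uniformity insert. Sampled
  body dimensions default to 55–75 mm length and 22–28 mm width —
  typical of young adult laboratory mice.
* **Mathematical cylinders** — diameter 5–20 mm, length 20–50 mm,
  random orientation, position and tissue; these diversify path-length
  and composition statistics exactly as in the reference corpus design.

Each projection pair is augmented with a per-axis anisotropic voxel
size drawn uniformly from [0.17, 0.29] mm (rescaling the phantom about
the isocenter), a ±10 mm translation per axis, an integer projection
angle in [0, 359]°, an independent ±5% relative perturbation of every
elemental mass fraction (renormalized to unit sum afterwards — the
renormalization convention is ours; perturbation-then-renormalize
preserves the mass-fraction invariant), and a ±5% density
perturbation. The per-element-independent reading of the ±5%
composition variation is an assumption; a single common scale factor
would cancel under renormalization, so the independent reading is the
only one that produces composition diversity. The full-scale corpus
bookkeeping is 9 mouse phantoms × 105 pairs + 945 cylinder pairs
= 1890 pairs, split 1512/378 at the pair level (80/20). Pairs of one
phantom may appear on both sides of the split, matching the printed
corpus counts; a phantom-held-out mode is available
(`split_dataset(..., by_phantom = TRUE)`) for stricter generalization
studies.

What the generator does *not* emulate: real anatomy (organ shapes are
ellipsoids), cardiorespiratory motion, scatter, detector blur and
electronic noise. Passing tests therefore demonstrate that the network
removes the spectral nonlinearity of the forward model — the mechanism
the method targets — not that it transfers to a physical scanner
unchanged.

## Network and training

The network is a standard single-channel U-Net: `depth` levels of two
3 × 3 same-padded convolutions + ReLU, 2 × 2 max pooling between
levels, a mirrored expansion path using bilinear ×2 upsampling with
channel-wise concatenation of the matching contraction output, and a
linear 1 × 1 output convolution. Feature widths double per level; the
full-scale configuration (depth 7, base 16) has a 1024-wide
bottleneck. No batch normalization is used anywhere: the inputs and
outputs live on the physical $-\ln(I/I_0)$ scale and must not be
renormalized. Weights use He fan-in initialization from a seeded,
platform-independent generator. The loss is the mean absolute error;
the optimizer is Adam with $\beta_1 = 0.900$, $\beta_2 = 0.999$ and
batch size 18. Training checkpoints the best-validation weights and
can stop early on a validation plateau.

Because no R deep-learning framework is available as a dependency, the
network — convolutions (im2col + GEMM, single precision), pooling,
bilinear resampling, backpropagation and Adam — is implemented in
compiled code inside the package. Inference is deterministic;
training is bit-reproducible for a fixed seed.

**Desk scale.** Tests and the acceptance benchmark run a scaled-down
configuration: depth 4, base 8, 64 × 64 projections, 200 pairs
(4 mice × 25 + 100 cylinders, preserving the 50/50 mouse/cylinder mix
of the full corpus), up to 100 epochs. The full-scale schedule
performs ~25 000 optimizer updates at learning rate $10^{-5}$; the
desk-scale run has only ~900 updates, so the same rate cannot move the
weights appreciably. The desk configuration therefore raises the
initial rate to $10^{-2}$ — selected by validation MAE among candidate
rates spanning $10^{-3}$ to $3\times 10^{-2}$ — ramps it up linearly
over the first 5% of epochs (a short warmup that prevents early
dead-ReLU collapse at the high rate), and then anneals it with a
cosine schedule (down to $10^{-4}$ over the run): with an MAE loss,
Adam's steady-state weight dithering is proportional to the learning
rate, so a constant high rate floors the achievable error, while the
cosine schedule keeps the rate high while the mapping is being learned
and quiets the tail. The full-scale configuration keeps the constant
$10^{-5}$ rate.

## Reconstruction

`fdk_reconstruct()` is a textbook Feldkamp–Davis–Kress implementation
operating in the rotating-phantom frame, where the pancake geometry is
an ordinary circular orbit: cosine pre-weighting
$\mathrm{SDD}/\sqrt{\mathrm{SDD}^2+u^2+v^2}$, row-wise ramp filtering
on the isocenter-scaled detector grid (spatial-domain Ram–Lak kernel,
zero-padded to the next power of two, Nyquist cutoff, optional Hann
apodization), and voxel-driven backprojection with bilinear detector
interpolation and distance weighting $\mathrm{SAD}^2/U^2$. Full 360°
orbits are assumed; the two-fold ray redundancy is absorbed by halving
the kernel, and coverage below 180° plus the fan angle is rejected.
Output stays in physical units (cm⁻¹) rather than rescaled CT numbers,
so reconstructions from different inputs are directly comparable.
The default grid matches the full-scale 256 × 256 × 600 matrix at
0.2 mm; tests reconstruct 64³ at 0.4 mm from 180 angles, which is
sufficient for the interior of a 16 mm cylinder to converge to the
ground-truth $\mu_\mathrm{water}(35\,\mathrm{keV})$ within the stated
3%.

## Metrics

* **Percentage error**: $100\,|p_\mathrm{pred} - p_\mathrm{ref}|/p_\mathrm{ref}$,
  pooled over pixels whose reference exceeds an air threshold of 0.01
  line-integral units. The exclusion of air trajectories is part of
  the metric's definition; the specific threshold is ours (the
  reference leaves it unstated) and also guards the division against
  near-zero references. Pooled-pixel means are reported, with a
  per-projection breakdown in `cmd_evaluate()`.
* **MAE**: plain pixel mean of $|p_\mathrm{pred} - p_\mathrm{ref}|$,
  no exclusion — identical to the training loss.
* **UNAAD**: $100 - \frac{100}{N\bar Y}\sum_i |Y_i - \bar Y|$ over an
  ROI; 100 means perfectly uniform, and the value is invariant under
  positive scaling, so it compares reconstructions in different units.
* **Difference maps**: per-voxel percentage difference between raw and
  corrected reconstructions inside a body mask, for visual QA of
  peripheral gradients.

## Reproducibility

A single master seed drives everything through the derivation
`stage_seed(master, stage) = (master·100003 + stage·7919) mod (2³¹−1) + 1`
(stage 1 corpus, 2 split, 3 network, 4 noise), so stages can be rerun
independently. Corpus rendering, augmentation, training and inference
are deterministic given their derived seeds.

## Known limitations

* The pooled air-excluded percentage error is a harsh summary at desk
  scale: pixels whose reference line integral sits just above the
  0.01 air threshold — the one-pixel penumbra ring around the object
  silhouette — contribute large relative errors even when the absolute
  prediction error is at the network's overall error floor, so the
  pooled mean is substantially higher than the interior-body relative
  error. The desk-scale network (depth 4, base 8, ~900 optimizer
  updates) underfits relative to a full-scale training run; its MAE is
  the more robust desk-scale summary, with the percentage error
  reported alongside per-projection breakdowns.

* Primary-beam transport only: no scatter kernels, no detector MTF,
  no focal-spot blur. Cupping attributable to scatter is out of scope.
* The embedded attenuation tables are compiled reference values with
  Z-interpolated entries for trace elements and smoothed L edges;
  they reproduce standard water attenuation to well under 2% in the
  imaging band but are not a metrology-grade database.
* The trained desk-scale model is specific to the simulated 60 kVp
  spectrum, filtration and detector stack; a different spectrum
  requires retraining, as the mapping is spectrum-conditional.
* Procedural phantoms span realistic path lengths and compositions but
  not realistic anatomy; performance on real projections should be
  validated before quantitative use.
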