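---
title: "Methods: difference EIT reconstruction with neural post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: difference EIT reconstruction with neural post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and numerical choices behind
`eit3d`, in the spirit of a methods section: what is computed, under which
assumptions, and where the genuinely open design decisions were settled.

## The imaging problem

Difference EIT reconstructs the change in conductivity $\Delta\sigma$
between two measurement instants from the change in boundary voltages
$\Delta v$. Working with differences cancels the static part of the
modelling error (electrode placement, contour mismatch, contact impedance),
which is why linear difference solvers are the clinical workhorse despite
the severe ill-posedness of the underlying nonlinear problem.

### Forward model

The forward operator is a Galerkin FEM discretisation of
$\nabla\cdot(\sigma\nabla u) = 0$ with the complete electrode model (CEM):
each electrode $l$ is a surface patch with contact impedance $z_l$
(default 100 $\Omega\,\mathrm{cm}^2 = 0.01\;\Omega\,\mathrm{m}^2$; the
value is a convention, as published tank studies rarely state it), carries a
prescribed net current, and is an equipotential. The discrete system couples
nodal potentials with electrode potentials; a Lagrange-multiplier row
enforcing $\sum_l V_l = 0$ removes the constant null space
deterministically. 2D models are unit-thickness slices; linear simplices
are used throughout, so element gradients are constant and both the
stiffness matrix and the adjoint sensitivity have closed-form element
integrals.

*Element order 2.* Quadratic elements are deferred: requesting `order = 2`
returns a refined linear mesh (flagged with a message) with at least four
times the elements. What matters for honest synthetic experiments is that
forward data are never generated on the discretisation used for inversion
(the "inverse crime"); the package enforces distinct meshes in
`build_training_set()` and additionally re-perturbs the thorax contour for
every training sample.

*Meshing.* Cylinders are meshed by extruding a structured polar disk into
prisms and splitting each prism into three tetrahedra with the
minimum-global-index rule, which guarantees conforming faces. Contours
$\rho(\theta)$ (truncated Fourier series, 8 harmonics) are meshed by scaling
the rings of a polar mesh; boundary nodes are equispaced in arc length so
that electrodes are too. Any generator satisfying the validity invariants
(positive volumes, disjoint boundary electrode patches) would do; this one
is dependency-free and deterministic.

*Validation.* The solver is checked against the analytic series solution
for a homogeneous disk with (near-)point drive electrodes (2% on a fine
mesh, converging under refinement), reciprocity (\<1e-6), and the adjoint
Jacobian against central finite differences (\<1e-3 relative).

### Inverse solvers

**One-step Gauss-Newton.** $\hat x = (J^TJ + \lambda^2 R)^{-1}J^T\,\Delta v$
with the NOSER prior $R = \mathrm{diag}(J^TJ)^p$, $p = 0.5$ by default.
$\lambda$ is calibrated so that the *noise figure* — input SNR over output
SNR for a small central target under unit white measurement noise — equals
0.5, solved by bisection on $\log\lambda$ (the noise figure is monotone in
$\lambda$). A fixed $\lambda$ from configuration always takes precedence.
Measurement weighting is the identity: no error covariance is modelled.

**PDIPM.** The comparison solver minimises
$\|Jx-\Delta v\|_1 + \lambda x^TRx$ with the same NOSER $R$ (for
comparability), via primal-dual interior point iterations: dual variable
clamped to $[-1,1]$, complementarity smoothed with
$\beta = 10^{-6}\,\mathrm{median}|\Delta v|$, Newton steps safeguarded by
backtracking (factor 0.5) on the exact primal objective, at most 100
iterations, relative-change tolerance $10^{-6}$. Because the L1 data term
scales linearly where the GN data term scales quadratically, the pipeline
uses $\lambda_{L1} = \lambda_{GN}^2/\mathrm{median}|\Delta v|$ to keep the
two solvers comparably regularised.

**RBF network, two roles.** A single hidden layer of Gaussian units
$\phi_k(x) = \exp(-\|x-c_k\|^2/2w_k^2)$ and a linear output layer. As an
*inverse solver* the input is the difference frame (208 or 928 values); as
a *post-processor* the input is the node-basis GN image, and the output is
always the nodal conductivity change — layer sizes follow node count, which
is why `element_to_node()` (volume-weighted averaging, a partition of
unity) is part of the canonical pipeline.

Training: inputs standardised per dimension, targets centred; centers
chosen from the training inputs by greedy max-residual selection, grown one
unit at a time up to the cap `H` with the prefix of best validation MSE
retained (90/10 deterministic split). All units share a constant width,
`spread = 1` times the median pairwise distance of the training inputs —
the constant-spread convention of constructive RBF toolboxes. The output
layer is ridge-regularised least squares (`ridge = 1e-8`). Two lessons from
development are worth recording: with `H = n` and a tiny ridge the net
interpolates and extrapolates catastrophically (validation-stopped growth
is what makes the desk-scale nets generalise), and widths tied to
nearest-center distances shrink as centers are added, destabilising the
greedy growth — hence the fixed data-scale width. An optional particle
swarm step (30 particles, 50 iterations, inertia 0.7, cognitive/social
1.5/1.5, seeded) refines a global width multiplier and a center scale
against validation MSE, then the output layer is refit; whether the
original work's PSO replaced or supplemented least squares is unreported,
so PSO here never replaces the linear output fit.

### Noise model

The acquisition chain is simulated at carrier level: a 100 kHz sine, 20
samples per period, amplitude equal to the clean channel voltage; additive
white Gaussian noise scaled to the channel's target pre-filter SNR; an
order-10 Butterworth bandpass centred on the carrier (half-power bandwidth
10% of the centre frequency), applied zero-phase as the analytic magnitude
response in the frequency domain (no signal-processing package exists in
the target environment, and zero-phase filtering avoids demodulation bias);
demodulation by taking the highest filtered peak. The per-channel SNR falls
linearly in dB from 50 dB at zero angular separation between injection-pair
and measurement-pair midpoints to 10 dB at separation $\pi$ — the two
extremes reported for serial systems; the linear interpolation between them
is a package convention. The matching estimator fits an ideal sine by least
squares and reports $10\log_{10}$ of the power ratio; a noise-free channel
is capped at 300 dB.

For physiological (lung) data the disturbances are not white Gaussian: the
heavy-tailed variant adds Laplacian noise (same power, excess kurtosis 3)
shaped by a $1/f$ envelope below the carrier. The exact non-Gaussian
construction used with real lung recordings is under-specified in the
literature this emulates; only the Gaussian carrier model is anchored, and
the Laplacian/$1/f$ choice is recorded here as a default, not a claim.

### Figures of merit

Reconstructions are rasterised on a $64\times64$ grid per cross-section
(heights 25/50/75% of a 3D model; the single plane of a 2D model). The
mask is the meshed region — pixels between the polygonal mesh boundary and
the analytic contour are excluded rather than imputed. The *quarter
amplitude set* (pixels reaching 25% of the maximum, signed consistently
with the dominant amplitude) is the operational target. Per true target,
after matching connected components by nearest centre of gravity:

* **PE** = CoG displacement / model radius x 100;
* **|dRES|** = |RES(recon) − RES(truth)| x 100 with
  RES = sqrt(set area / mask area), on the total sets;
* **SD** = fraction of reconstructed quarter-set pixels outside the circle
  centred at the *true* CoG with the *true* component's area, x 100.

Conventions fixed here: the SD circle is anchored at the truth (so SD reads
as deformation relative to ground truth; anchoring at the reconstruction is
the other defensible choice), unmatched reconstructed components count
entirely as "outside", and the circle radius carries a half-pixel tolerance
so that an exactly reproduced circular target scores SD = 0. Note that SD
is a circularity measure: a jagged mesh-painted disc, or an elliptical
lung, has SD \> 0 even against itself. Metrics are invariant to positive
scaling of the reconstruction; a grid-doubling check keeps the $G = 64$
choice honest.

## The synthetic world

The generator emulates two experiments. *Phantom*: a saline tank
(default 4 rings x 8 electrodes; desk scale uses a single-ring 16-electrode
section) containing one or two insulating cylinders — random radius
10–25% of the tank radius, conductivity 2–50% of the background, background
itself log-uniform within a factor 2 of nominal across samples. *Lungs*: a
thorax-like Fourier contour with two elliptical cylinders, resistivity
uniform in 700–2500 $\Omega\cdot$m over a 700 $\Omega\cdot$m background
(tissue values at 100 kHz across the breathing cycle), contour coefficients
re-perturbed by up to 10% per sample. Sizes and positions of the lung
ellipses (semi-axes roughly 28–58% of the mean radius, centred laterally)
are package choices of a plausible anatomy; none of the tank dimensions or
thorax coefficients reproduce any specific physical setup, so green tests
establish the *method ordering* under this stated world, not agreement with
any physical measurement.

What the generator deliberately omits: electrode drift, temperature,
crosstalk, breathing-induced boundary motion between the two frames of one
difference pair, and 3D lung anatomy. The desk-scale experiment (200
training scenes, cap of 200 hidden units, 20 noisy test scenes, a
few-hundred-element inverse mesh) finishes in about a minute on one CPU;
the full-scale configuration (2000 scenes, 1000 units, 4x8-electrode 3D
tank) is reachable through the same configuration object but is not run in
tests.

## Reproducibility

Every stochastic operation takes an explicit seed; composite operations
derive child seeds (kept below $2^{31}$) from their master seed, so a
configuration plus one seed reproduces scenes, noise draws, training splits
and PSO trajectories bit-for-bit on one platform. In-memory indices are
1-based (R); all files written by the package (MSH, VTK, frame CSV,
containers) use 0-based indices. Units are metres, S/m and
$\Omega\,\mathrm{m}^2$; resistivities are converted on input. YAML and HDF5
interfaces of comparable toolchains are realised as JSON and CSV+JSON
containers, as the target environment ships no R bindings for either.

## Known limitations

* Quadratic elements are substituted by mesh refinement (flagged).
* The contour family is star-shaped ($\rho(\theta) > 0$); genuinely
  non-star-shaped thoraces are out of reach of the polar mesher.
* PDIPM re-linearises nothing: it solves the linearised L1 problem, not the
  full nonlinear one, and total-variation image priors are out of scope.
* A trained network is bound to the node set of its inverse model; there is
  no transfer across meshes.
* The noise-robustness ordering is a statement about aggregate SD and
  |dRES| at desk scale under fixed seeds; individual scenes can and do
  deviate.
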