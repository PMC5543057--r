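# eit3d

Simulation and reconstruction toolkit for difference **electrical impedance
tomography** (EIT) in two and three dimensions, built around one question:
how much robustness to measurement noise does a nonlinear neural
post-processor add to a linear reconstruction, compared with using a neural
network as the inverse solver itself?

EIT drives small alternating currents through electrodes on the body (or a
saline tank) and images the interior conductivity change from the boundary
voltages. The package implements the full chain:

* **Finite element models** of cylindrical tanks (rings of electrodes on the
  lateral surface, tetrahedral meshes) and thorax-like planar contours
  (Fourier-series boundary, triangular meshes), with complete-electrode-model
  boundary conditions (contact impedance, prescribed net currents).
* **Adjacent protocols**: injection and measurement on neighbouring
  electrode pairs; the 4-ring x 8-electrode tank yields 32 injections x 29
  kept measurements = 928 values per frame, the 16-electrode ring yields 208.
* **Forward solver and adjoint Jacobian** for difference imaging.
* **Inverse solvers**:
  * one-step Gauss-Newton, `x = (J'J + lambda^2 R)^-1 J' dv` with the NOSER
    prior `R = diag(J'J)^p` — a single precomputable matrix product;
  * primal-dual interior point method (PDIPM) minimising
    `||Jx - dv||_1 + lambda x'Rx`;
  * a radial basis function (RBF) network mapping voltages directly to nodal
    conductivity;
  * the combined method: the RBF network applied as a *post-processor* to
    the one-step GN image.
* **Carrier-level noise model**: 100 kHz drive sine sampled 20x per period,
  white Gaussian (or Laplacian, 1/f-coloured) noise at a per-channel SNR
  falling from 50 dB (measurement near the injection) to 10 dB (opposite
  side), order-10 zero-phase Butterworth bandpass, peak-detection
  demodulation, and the matching `SNR = 10 log10(mean(signal^2) /
  mean(residual^2))` estimator.
* **GREIT-style figures of merit** on rasterised cross-sections: position
  error (PE, % of model radius), resolution difference (|dRES|, %), shape
  deformation (SD, %), with per-target matching by centre of gravity.

## Worked example

Reconstruct a conductive anomaly in a 16-electrode disk section:

```r
library(eit3d)

inv  <- build_contour_model(list(a = c(0.15, rep(0, 8)), b = rep(0, 8)), 16, "coarse")
fwd  <- build_contour_model(list(a = c(0.15, rep(0, 8)), b = rep(0, 8)), 16, "fine")
prot <- adjacent_protocol(1, 16)
prot
#> EIT protocol 'adj_1x16_ex': 16 injections, frame length 208 (drive 1 mA)

J <- jacobian(inv, rep(1, nrow(inv$elements)), prot)
M <- build_gn_matrix(J, choose_lambda(J))   # noise figure calibrated to 0.5

scene <- scene_spec(1, list(list(shape = "circular-cylinder",
                                 center = c(0.05, 0.02, 0),
                                 semi_axes = 0.03, conductivity = 0.2)))
f_hom <- solve_forward(fwd, rep(1, nrow(fwd$elements)), prot)$frame
f_inh <- solve_forward(fwd, paint_scene(fwd, scene), prot)$frame
rec   <- reconstruct_gn(M, difference_frame(f_inh, f_hom), inv)

truth <- element_to_node(paint_scene(inv, scene), inv)
r     <- rasterize(element_to_node(rec, inv), inv, G = 64)
```

The full comparison experiment (trains the networks, corrupts the test
frames with carrier noise, scores every method):

```r
res <- run_comparison(experiment_config(seed = 1))
res
#> EIT solver comparison (tank_section, phantom scenes, n_train = 200, H = 200):
#>      method  pe_1  pe_2  dres    sd missing_targets
#>          gn 11.11   NaN 11.57 43.08               2
#>       pdipm  9.62  5.68 12.86 44.69               1
#>   ann_clean 12.14  6.44  8.09 37.77               1
#>  post_clean  7.58 15.63  7.47 32.09               0
#>   ann_noisy 13.77 25.03  6.66 35.64               1
#>  post_noisy  7.33  3.55  7.97 34.33               1
```

Rows are the mean metrics over 20 held-out noisy test scenes: `gn` is the
one-step Gauss-Newton solver, `pdipm` the L1-data interior point solver,
`ann_*` the network used as the inverse solver and `post_*` the network
post-processing the GN image, trained without (`_clean`) or with (`_noisy`)
noise. Smaller is better everywhere. The pattern of interest: with
noise-free training, the post-processor (`post_clean`) keeps both SD and
|dRES| below the direct network (`ann_clean`), and both post-processed
variants beat the plain linear solver on |dRES| — the post-processor needs
far less noise modelling to stay accurate.

A thin CLI wraps the same functions
(`Rscript inst/cli/eit.R compare --out outdir`); configurations are JSON
(`write_config`/`read_config`), meshes round-trip through Gmsh MSH v2 and
legacy VTK, frames through CSV.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full desk-scale comparison from scratch (200 training scenes,
200 hidden units, 20 noisy test scenes, all seeds derived from `--seed`),
prints the comparison table, and writes the target report to `--out`.
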