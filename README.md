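# voxreg

Tools for studying how the choice of **interpolation kernel** and
**intensity cost function** affects upsampling quality and automatic
affine registration of 3D head images.

When a volumetric image is resampled — to upsample an anisotropic
acquisition, or thousands of times inside a registration optimizer — every
sample is an interpolation, and the interpolation error propagates into
whatever is computed downstream. `voxreg` provides a controlled test bench
for that propagation:

* a **synthetic multi-tissue head phantom** (nested ellipsoids: skull,
  grey/white matter, ventricles, an off-center lesion) with a reproducible
  degradation chain — slice decimation, rigid motion, Gaussian blur,
  Gaussian noise — each step separately switchable;
* **eight separable interpolation kernels** behind one C++ sampling core:
  nearest neighbour, trilinear, Lagrange (4-, 6-, 8-point), cubic and
  quartic B-spline (the smoothing, non-prefiltered variant), and
  Hann-windowed sinc;
* the **four classic intensity costs** as minimized quantities: least
  squares (LS), correlation ratio (CR), normalized cross-correlation
  (NCC), normalized mutual information (NMI);
* a **coarse-to-fine 12-DOF affine registration** in the FLIRT mould:
  center-of-mass initialization, a 125-configuration rotation grid with
  local 4-DOF optimization and top-20% candidate retention (125 → 25 → 5)
  on the coarsest pyramid level, perturbed 7-DOF refinement, a 7 → 9 → 12
  DOF chain, and a full-resolution polish;
* **evaluation metrics**: MSE, PSNR, Shannon and joint entropy, joint
  histograms, subtraction images; and
* two packaged **experiments** comparing kernels and costs, with YAML
  configuration and CSV/JSON reports.

Everything is deterministic given the seeds carried in the specs.

## Worked example

Degrade a phantom with a known motion, register it back, and compare
recovered to true parameters:

```r
library(voxreg)

ref <- generate_phantom(c(64, 64, 64), spacing = c(1, 1, 1.3), seed = 1,
                        texture_sd = 0)
moving <- degrade(ref, degradation_spec(
  subsample_factor = 1,            # keep full resolution ...
  rotation_deg = 5,                # ... but rotate 5 degrees about x
  translation_mm = c(2, 3, 0),     # and translate
  noise_sd = 0, blur_radius = 0))

fit <- register_volumes(ref, moving,
                        cost = cost_spec("NMI"),
                        kernel = kernel_spec("trilinear"),
                        max_dof = 12)
fit$final_params
```

```
#> <dof_params> 12 DOF: t = ( 2.000000,  3.006995, -0.003216) mm, r = (5.025, 0.000, 0.000) deg, s = (1.0000, 1.0000, 0.9975), h = (0, 0, 0)
```

The estimated transform maps reference world coordinates to target
sampling positions, so its parameters are directly comparable to the
motion handed to `degrade()` — here the 5-degree rotation and the
(2, 3, 0) mm translation are recovered to a fraction of a degree/voxel.
Reformat the moving image onto the reference grid and score it:

```r
registered <- apply_registration(fit, moving, ref, kernel_spec("trilinear"))
c(mse_before = mse_3d(ref, moving),
  mse_after  = mse_3d(ref, registered),
  joint_entropy_after = joint_entropy(ref, registered, 64))
```

```
#>          mse_before           mse_after joint_entropy_after 
#>         2957.903161          126.848514            2.336803
```

Compare upsampling kernels on a decimated phantom:

```r
cfg <- experiment_config(shape = c(64, 64, 64), seed = 1, axes = "z")
run_upsampling_experiment(cfg)
```

```
#>   axis        kernel      mse  psnr_db
#> 1    z     trilinear 223.0932 24.28274
#> 2    z       nearest 464.9773 21.09329
#> 3    z      bspline3 322.5034 22.68226
#> 4    z      bspline4 368.2591 22.10607
#> 5    z     lagrange4 229.3515 24.16259
#> 6    z     lagrange6 235.6874 24.04424
#> 7    z     lagrange8 240.2573 23.96084
#> 8    z windowed_sinc 246.9605 23.84133
```

Two findings are stable across sizes: every kernel beats nearest
neighbour, and plain trilinear attains the lowest MSE — the decimated
signal is aliased, so wide kernels faithfully reconstruct an already-wrong
signal while trilinear's smoothing is mildly protective. See the vignette
(`vignettes/interpolation-and-registration.Rmd`) for the methods and the
reasoning behind the optimizer's design choices.

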