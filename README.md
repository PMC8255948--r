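# gctrecon

PET-enabled dual-energy CT in R: reconstruct a 511 keV "γ-ray CT" (GCT)
attenuation image from time-of-flight PET emission data by joint
maximum-likelihood attenuation and activity estimation (MLAA), guide it
with a kernel representation built from the X-ray CT prior, and pair
the result with the low-energy CT for multi-material decomposition.

The package is aimed at image-reconstruction researchers who want a
self-contained, desk-scale testbed for anatomically guided MLAA: it
ships a procedural chest phantom, a 2D parallel-beam TOF simulator,
four reconstruction methods, and the full evaluation protocol.

## The model

TOF sinogram counts are Poisson with expectation

```
ybar_{i,m} = c_{i,m} exp(-[A mu]_i) [G_m lambda]_i + r_{i,m}
```

where `lambda` is the activity image, `mu` the 511 keV attenuation
image, `A` the transmission operator, `G_m` the emission operator of
TOF bin `m` and `r` a uniform background. MLAA alternates a
multiplicative MLEM update of `lambda` with a safeguarded separable
paraboloidal surrogate (SPS) update of `mu`, maximizing the joint
Poisson log-likelihood. Kernel MLAA represents `mu = K alpha` with `K`
a row-stochastic kNN Gaussian similarity matrix over per-pixel features
of the CT prior — raw 3×3 intensity patches, or penultimate-layer
activations of a RED-CNN- or Unet-style autoencoder trained
unsupervised on that single image — and updates `alpha` through the
composed projector `A K`. The GCT estimate and the CT prior then
decompose pixel-wise into air / soft tissue / bone fractions by
constrained least squares (fractions summing to one).

## Worked example

```r
library(gctrecon)

ph   <- make_phantom(image_grid(64, 64, 0.35), seed = 1)
geom <- scanner_geometry(60, 96, radial_spacing = 0.35, n_tof = 5)
sys  <- build_system(ph$grid, geom)
scan <- simulate_scan(ph, sys, total_events = 2e5, seed = 2)
init <- convert_ct_to_511(ph$xct80)

# standard MLAA vs patch-kernel MLAA, 200 outer iterations
st  <- mlaa_reconstruct(scan$y, scan$r, sys, init, 200)
K   <- build_kernel_matrix(
         normalize_features(extract_patch_features(ph$xct80, 3)), k = 50)
stk <- kernel_mlaa_reconstruct(scan$y, scan$r, sys, K, init, 200)

mse_db(st$mu,  ph$mu511)
#> [1] -2.458769
mse_db(stk$mu, ph$mu511)
#> [1] -16.60204
```

The numbers are image mean squared errors in dB relative to the true
attenuation map (`10 log10(||est - truth||^2 / ||truth||^2)`; more
negative is better): at this count level the unguided MLAA estimate is
dominated by noise, while the CT-guided kernel representation recovers
the attenuation map about 14 dB more accurately. The autoencoder
kernels are built the same way via `train_autoencoder()` and
`extract_cnn_features()`, and `run_experiment(desk_config())` runs the
whole four-method, multi-realization comparison with metrics, ROI
bias/SD statistics and material decomposition in one call.

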