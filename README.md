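# fimicdepth

Robust depth-map estimation for **Fourier integral microscopy (FiMic)**
light fields. A FiMic places the microlens array at the Fourier plane of
the objective, so a single sensor exposure records seven perspective views
of the specimen — one central, six peripheral — on a hexagonal grid with
three epipolar axes (0°, 60°, 120°). Biological samples make depth
estimation hard: little texture, repetitive structure, and (for
fluorescence) a dark background that records no signal. This package
implements a full pipeline that turns one such capture into a per-pixel
depth (disparity) map, for microscopists and image-analysis developers who
need 3-D structure from single-shot light-field acquisitions.

## Method

1. **Two cost volumes.** A *correspondence* volume
   `C_cor = α_c · TAD + (1 − α_c) · census` is built per central–peripheral
   pair along its epipolar direction (truncated absolute differences +
   census-transform Hamming distance, adaptive support weights
   `w ∝ exp(−(|ΔI|/σ_c + ‖o‖/σ_d))`), merged over the six pairs with
   direction-failure weights and guided-filtered. A *defocus* volume
   `C_def = α_d · TAD + (1 − α_d) · (1 − NCC)/2` compares the central view
   with a shift-and-sum focal stack whose integer shift `s` indexes depth
   through `z_R(s) = s · (f_MO² f_L f_2 / f_1²) · (δ/p)`.
2. **Priors.** A difference-of-Gaussians frequency map (quantile-quantized),
   three steered-Sobel failure-prediction maps (one per epipolar axis), and
   an alpha matte from a three-level trimap that masks the dark background.
3. **Aggregation.** Frequency-weighted multi-scale blending over scales
   {1, 2, 4} with weights `(γ1, γ2, γ3) = (0.6, 0.3, 0.1)`, and SLIC
   superpixel shaping that adds `ρ(1 − z(t))` where `z` is a tent of
   half-width σ = 3 labels around each superpixel's top `Np = 3` histogram
   peaks (`ρ = 0.2`).
4. **Fusion and optimization.** Winner-takes-all maps of both volumes give
   a disagreement map `Mad = |l_def − l_cor| / K`; exact agreements become
   ground control points with a linear label-distance penalty (β = 0.5).
   The fused data term plus a linear pairwise prior
   `λ Σ |l_p − l_q|` is minimized *exactly* by a multi-layer graph cut
   (Boykov–Kolmogorov max-flow backend); a weighted median and a guided
   filter post-process the result, and the matte masks it.

A synthetic-scene module renders hexagonal light fields from textured
phantoms with known per-pixel disparity (planes, steps, fluorescent-style
fibers, disks) and scores estimates by the mean absolute disparity error
inside the matte mask.

## Worked example

```r
library(fimicdepth)

# a 128x128 depth-step phantom, disparities 0..8 px, strong read noise
spec  <- scene_spec(c(128L, 128L), "step", disparity_range = c(0, 8),
                    texture = "noise", noise_sigma = 0.1, seed = 7)
scene <- generate_scene(spec)

res <- run_pipeline(scene$eis, pipeline_config())
res$depth
#> <depth_map> 128 x 128, labels 2..6, 100% valid

evaluate_depth(res$depth, scene$truth, scene$mask)
#> <depth_error_report> mean 0.1023, std 0.3762 over 16384 pixels (ground_truth)

# the naive winner-takes-all baseline on the same two cost volumes
evaluate_depth(res$intermediates$wta_baseline, scene$truth, scene$mask)
#> <depth_error_report> mean 0.1085, std 0.4206 over 16384 pixels (ground_truth)

round(res$intermediates$energies, 2)   # graph-cut energy, WTA init -> optimum
#> [1] 2883.23 2861.55
```

The phantom has two fronto-parallel regions at disparities 2 and 6. The
pipeline's residual error (0.10 labels) is concentrated at the depth
discontinuity and stays essentially flat as read noise grows, while the
naive winner-takes-all baseline degrades with noise (at this noise level it
is already behind, both in mean and spread); the logged energies certify
that the graph cut only ever lowers the objective. On a clean
fronto-parallel plane the final label map is exact for more than 99 % of
pixels. Optical quantities are available as closed forms, e.g.
`resolution_limit(optics_params(wavelength = 0.52, na = 0.4, microlens_count = 3))`
→ 1.95 µm.

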