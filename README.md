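# particlecut

Seeded graph-cut segmentation and single-particle characterization of
metallic micro- and nanoparticles in scanning electron microscopy (SEM)
images, for anyone quantifying bright compact deposits on a dark noisy
background — counts, sizes, shapes, and elemental composition from
energy-dispersive X-ray (EDS) spectra.

## Method

A rectangular ROI becomes a directed, capacitated graph: one vertex per
pixel plus a source *s* (object) and sink *t* (background). t-links encode
regional likelihood from the mean intensities of user-marked seeds,

    c(s,p) = λ (M − |I_obj − I_p|),    c(p,t) = λ (M − |I_bg − I_p|),

n-links encode boundary smoothness between neighbours *p, q*,

    N(p,q) = exp(−(I_p − I_q)² / 2σ²) · 1/dist(p,q),

and seed pixels are pinned with hard capacities K_max = 1 + Σ(all other
capacities), so no minimum cut can violate a seed. The minimum s-t cut —
computed via its dual maximum flow with a C++ implementation of Dinic's
algorithm (BFS level graphs + current-arc blocking flows) — labels S-side
pixels as object. The mask is post-processed (hole filling, speckle
removal, optional opening/closing), then each 8-connected particle is
measured: area, perimeter, centroid, intensity statistics, circularity
4πA/P², equivalent-ellipse axes and orientation, minimum-bounding-rectangle
sides and aspect ratio, and maximum/minimum Feret diameters with their
ratio. Masks validate against ground truth with Dice, IoU, and pixel
accuracy; EDS spectra get peak detection (prominence above a local linear
background), element assignment by characteristic line energy (Fe 6.40, Cr
5.41, Ni 7.47/0.85, Zn 8.64/1.01 keV, ...), and peak-height composition
ratios. A synthetic scene and spectrum generator with exact ground truth
makes the whole chain testable end to end.

See `vignettes/particlecut-methods.Rmd` for the full model description,
parameter guidance, and design rationale.

## Worked example

```r
library(particlecut)

# a synthetic SEM-like scene: one blob-shaped particle with an interior
# hole artifact, Gaussian noise and bright speckles; exact ground truth
scene <- generate_particle_image(
  size = 256,
  particles = list(particle_spec("blob", center = c(128, 128),
                                 axes = c(45, 30), rotation = 25,
                                 holes = list(list(center = c(120, 135),
                                                   radius = 8)),
                                 rng_seed = 11)),
  noise = noise_spec(gaussian_sigma = 10, speckle_count = 25,
                     speckle_size_px = 3),
  rng_seed = 11)

mask <- segment_roi(scene$image, seeds = scene$seeds)
evaluate_masks(mask, scene$truth)
#> IoU 1.0000 | Dice 1.0000 | pixel accuracy 1.0000 (tp 4241 fp 0 fn 0 tn 61295)

measure_mask(mask, scene$image)[[1]]
#> particle: area 4241 px (6.627e+05 nm^2), perimeter 236.82 px,
#>           circularity 0.950, MBR aspect 0.666, Feret ratio 0.652
```

The segmentation recovers the particle exactly despite the hole and the
speckle noise (hole filling and the 5-px size threshold repair both), and
the morphometry reads a moderately elongated, fairly round particle: 4241
px ≈ 663,000 nm² at the 12.5 nm/px calibration, circularity 0.95, MBR
aspect ratio 0.67.

```r
# EDS: an iron-zinc particle's spectrum, detected and ratioed
sp <- generate_spectrum(data.frame(energy = c(6.40, 8.64),
                                   amplitude = c(400, 200)), rng_seed = 7)
ratio <- element_ratio(assign_elements(detect_peaks(sp, 50)), c("Fe", "Zn"))
format_ratio(ratio)
#> [1] "2.0:1"
```

A command-line interface wrapping the same functions ships in
`inst/cli/particlecut.R` with `segment`, `measure`, `validate`, `spectra`
and `synth` subcommands.

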