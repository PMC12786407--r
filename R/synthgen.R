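#' Synthetic particle specification
#'
#' Describes one bright particle for the synthetic SEM scene generator:
#' disks, ellipses, or "blobs" (ellipses whose boundary radius is perturbed
#' by low-order sinusoids, up to 20% in amplitude, giving circularities in
#' roughly the 0.6-0.9 range seen in real metallic deposits).  Optional
#' interior holes emulate particles that image hollow under SEM: a hole
#' darkens the rendered image to background level but the ground-truth
#' particle stays solid (hollowness is an imaging artifact, which is exactly
#' why the segmentation pipeline fills holes).
#'
#' @param shape `"disk"`, `"ellipse"` or `"blob"`.
#' @param center `(row, col)` center in pixels.
#' @param axes semi-axes in pixels: one value for a disk, two (major, minor)
#'   otherwise.
#' @param rotation rotation in degrees (counter-clockwise from the column
#'   axis, toward increasing rows).
#' @param object_intensity,background_intensity grey levels in `[0, 255]`;
#'   the object must exceed the background by at least 1 (the contrast).
#' @param holes list of `list(center = c(r, c), radius = px)` rendered at
#'   background intensity inside the particle (image only, not ground
#'   truth).
#' @param rng_seed seed for the blob boundary perturbation (deterministic).
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(shape = c("disk", "ellipse", "blob"),
                          center, axes, rotation = 0,
                          object_intensity = 180, background_intensity = 60,
                          holes = list(), rng_seed = 1L) {
  shape <- match.arg(shape)
  if (length(axes) == 1) axes <- c(axes, axes)
  if (any(axes <= 0)) stop("axes must be > 0")
  if (object_intensity < 0 || object_intensity > 255 ||
      background_intensity < 0 || background_intensity > 255)
    stop("intensities must lie in [0, 255]")
  if (object_intensity - background_intensity < 1)
    stop("object intensity must exceed background by at least 1 grey level")
  blob_coeffs <- NULL
  if (shape == "blob") {
    blob_coeffs <- with_local_seed(rng_seed, {
      k <- 2:4
      amp <- runif(3, 0.02, 0.066)   # total perturbation <= ~20% of radius
      phase <- runif(3, 0, 2 * pi)
      list(k = k, amp = amp, phase = phase)
    })
  }
  structure(list(shape = shape, center = center, axes = axes,
                 rotation = rotation, object_intensity = object_intensity,
                 background_intensity = background_intensity, holes = holes,
                 rng_seed = rng_seed, blob_coeffs = blob_coeffs),
            class = "particle_spec")
}

#' Noise specification for synthetic scenes
#'
#' @param gaussian_sigma additive Gaussian noise standard deviation (grey
#'   levels; default 10).
#' @param speckle_count number of small bright artifacts (default 25), there
#'   to exercise small-component removal.
#' @param speckle_size_px maximum speckle diameter in pixels (default 3).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sigma = 10, speckle_count = 25,
                       speckle_size_px = 3) {
  if (gaussian_sigma < 0 || speckle_count < 0 || speckle_size_px < 0)
    stop("noise parameters must be >= 0")
  structure(list(gaussian_sigma = gaussian_sigma,
                 speckle_count = as.integer(speckle_count),
                 speckle_size_px = as.integer(speckle_size_px)),
            class = "noise_spec")
}

rasterize_particle <- function(spec, size) {
  h <- size[1]; w <- size[2]
  rr <- matrix(rep(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  th <- spec$rotation * pi / 180
  dx <- cc - spec$center[2]
  dy <- rr - spec$center[1]
  # rotate into the particle frame
  ux <- cos(th) * dx + sin(th) * dy
  uy <- -sin(th) * dx + cos(th) * dy
  rho <- sqrt((ux / spec$axes[1])^2 + (uy / spec$axes[2])^2)
  lim <- 1
  if (spec$shape == "blob") {
    ang <- atan2(uy, ux)
    bc <- spec$blob_coeffs
    lim <- 1 + bc$amp[1] * sin(bc$k[1] * ang + bc$phase[1]) +
               bc$amp[2] * sin(bc$k[2] * ang + bc$phase[2]) +
               bc$amp[3] * sin(bc$k[3] * ang + bc$phase[3])
  }
  inside <- rho <= lim
  holes <- matrix(FALSE, h, w)
  for (hole in spec$holes) {
    hd <- sqrt((rr - hole$center[1])^2 + (cc - hole$center[2])^2)
    holes <- holes | (inside & hd <= hole$radius)
  }
  list(solid = matrix(as.integer(inside), h, w),
       holes = matrix(as.integer(holes), h, w))
}

#' Generate a synthetic SEM-like particle scene
#'
#' Rasterizes bright particles on a darker background, captures the exact
#' ground-truth mask *before* any artifact, then renders imaging artifacts:
#' interior holes (particles often appear hollow under SEM because of
#' surface charging — the hole darkens the image, the true particle stays
#' solid), bright speckles, and Gaussian noise.  Suggested seeds are an
#' eroded sample of the bright particle interiors (object) and a sample of
#' pixels well away from any particle (background) — always strict subsets
#' of the respective ground-truth classes.
#'
#' @param size image size in pixels, `c(height, width)` or a single value.
#' @param particles list of [particle_spec()]s (all sharing one background
#'   intensity).
#' @param noise a [noise_spec()].
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return List: `image` ([image2d()]), `truth` (0/1 matrix), `seeds`
#'   ([seed_set()]).
#' @export
generate_particle_image <- function(size, particles, noise = noise_spec(),
                                    rng_seed = 1L) {
  if (length(size) == 1) size <- c(size, size)
  if (length(particles) == 0) stop("need at least one particle")
  bg <- particles[[1]]$background_intensity
  for (p in particles) if (p$background_intensity != bg)
    stop("all particles in a scene must share one background intensity")
  h <- size[1]; w <- size[2]
  truth <- matrix(0L, h, w)
  img <- matrix(bg, h, w)
  bright <- matrix(0L, h, w)   # image-level foreground (holes carved out)
  for (p in particles) {
    m <- rasterize_particle(p, size)
    truth[m$solid == 1L] <- 1L
    img[m$solid == 1L] <- p$object_intensity
    img[m$holes == 1L] <- bg
    bright[m$solid == 1L & m$holes == 0L] <- 1L
    bright[m$holes == 1L] <- 0L
  }
  if (sum(truth) == 0) stop("particles do not intersect the image")

  obj_max <- max(vapply(particles, `[[`, numeric(1), "object_intensity"))
  with_local_seed(rng_seed, {
    # speckle artifacts (noise, not ground truth)
    if (noise$speckle_count > 0 && noise$speckle_size_px > 0) {
      for (i in seq_len(noise$speckle_count)) {
        sz <- sample.int(noise$speckle_size_px, 1)
        pts <- matrix(c(sample.int(h, 1), sample.int(w, 1)), 1)
        while (nrow(pts) < sz) {    # grow a connected cluster of sz pixels
          base <- pts[sample.int(nrow(pts), 1), ]
          stp <- base + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
          if (stp[1] >= 1 && stp[1] <= h && stp[2] >= 1 && stp[2] <= w)
            pts <- unique(rbind(pts, stp))
        }
        img[pts] <- obj_max
      }
    }
    if (noise$gaussian_sigma > 0)
      img <- img + rnorm(h * w, 0, noise$gaussian_sigma)
    img <- pmin(pmax(round(img), 0), 255)

    # seed hints: object seeds come from the eroded *bright* interior so they
    # sample object-typical intensities, never the dark hole artifact
    er <- EBImage::erode(bright, EBImage::makeBrush(5L, "disc"))
    obj_cand <- which(er != 0, arr.ind = TRUE)
    if (nrow(obj_cand) == 0) obj_cand <- which(bright != 0, arr.ind = TRUE)
    if (nrow(obj_cand) == 0) obj_cand <- which(truth != 0, arr.ind = TRUE)
    di <- EBImage::dilate(truth, EBImage::makeBrush(11L, "disc"))
    bg_cand <- which(di == 0, arr.ind = TRUE)
    if (nrow(bg_cand) == 0) bg_cand <- which(truth == 0, arr.ind = TRUE)
    pick <- function(cand, k) cand[sample.int(nrow(cand), min(k, nrow(cand))), , drop = FALSE]
    seeds <- seed_set(object = pick(obj_cand, 200), background = pick(bg_cand, 300))
    list(image = image2d(matrix(as.integer(img), h, w), pixel_size_nm = 12.5),
         truth = truth, seeds = seeds)
  })
}

#' Generate a batch of synthetic validation scenes
#'
#' Emulates a validation set of SEM images: `n` independent scenes with 1-4
#' randomly shaped, sized and placed particles each, at a stated contrast and
#' noise level.  Reproducible from a single seed.
#'
#' @param n number of scenes.
#' @param size image size in pixels (default 256).
#' @param contrast object-background grey-level difference (default 120;
#'   must be > 0).
#' @param noise a [noise_spec()].
#' @param rng_seed integer seed.
#' @param background_intensity scene background grey level (default 60).
#' @return List of `n` scene lists as returned by
#'   [generate_particle_image()].
#' @export
generate_validation_batch <- function(n, size = 256, contrast = 120,
                                      noise = noise_spec(), rng_seed = 42L,
                                      background_intensity = 60) {
  if (n < 1) stop("'n' must be >= 1")
  if (contrast <= 0) stop("'contrast' must be > 0")
  obj_int <- min(background_intensity + contrast, 255)
  if (obj_int - background_intensity < 1) stop("contrast collapses at this background")
  scene_seeds <- with_local_seed(rng_seed, sample.int(2^30, n))
  lapply(seq_len(n), function(i) {
    sseed <- scene_seeds[i]
    parts <- with_local_seed(sseed, {
      np <- sample(1:4, 1)
      lapply(seq_len(np), function(j) {
        a <- runif(1, 12, 40) * size / 256   # radii scale with scene size
        b <- a * runif(1, 0.4, 1)
        shape <- sample(c("disk", "ellipse", "blob"), 1)
        if (shape == "disk") b <- a
        margin <- ceiling(a) + 6
        ctr <- c(runif(1, margin, size - margin), runif(1, margin, size - margin))
        holes <- list()
        if (runif(1) < 0.3)
          holes <- list(list(center = ctr + runif(2, -0.3, 0.3) * b,
                             radius = 0.3 * b))
        particle_spec(shape, center = ctr, axes = c(a, b),
                      rotation = runif(1, 0, 180),
                      object_intensity = obj_int,
                      background_intensity = background_intensity,
                      holes = holes, rng_seed = sseed + j)
      })
    })
    generate_particle_image(c(size, size), parts, noise, rng_seed = sseed)
  })
}

#' Generate a synthetic EDS spectrum
#'
#' Sum of Gaussian peaks at characteristic line energies plus a constant
#' background, optionally with Poisson counting noise.  Channels cover the
#' 0.16-9.8 keV detector range.  Amplitudes are count *rates* (cps); the
#' counting noise model accumulates each channel for `integration_time_s`
#' seconds, draws Poisson counts at `rate * time`, and converts back to cps,
#' so relative noise follows `1 / sqrt(rate * time)` as in a real
#' acquisition.
#'
#' @param lines data frame (or two-column matrix) with columns `energy`
#'   (keV, within the detector range) and `amplitude` (cps, > 0).
#' @param peak_sigma_keV Gaussian peak width (default 0.05 keV, a typical
#'   silicon-drift-detector resolution scale).
#' @param background_level constant continuum level in cps (default 20).
#' @param channel_width channel spacing in keV (default 0.01).
#' @param rng_seed integer seed (used only when `poisson_noise = TRUE`).
#' @param poisson_noise apply Poisson counting noise (default `TRUE`).
#' @param integration_time_s acquisition time per channel in seconds
#'   (default 200).
#' @return An [eds_spectrum()] with unit `"cps"`.
#' @export
generate_spectrum <- function(lines, peak_sigma_keV = 0.05,
                              background_level = 20, channel_width = 0.01,
                              rng_seed = 1L, poisson_noise = TRUE,
                              integration_time_s = 200) {
  lines <- as.data.frame(lines)
  if (nrow(lines) == 0) stop("need at least one line")
  names(lines)[1:2] <- c("energy", "amplitude")
  rng <- eds_range()
  if (any(lines$energy < rng[1] | lines$energy > rng[2]))
    stop("line energies must lie within ", rng[1], "-", rng[2], " keV")
  if (any(lines$amplitude <= 0)) stop("amplitudes must be > 0")
  e <- seq(rng[1], rng[2], by = channel_width)
  y <- rep(background_level, length(e))
  for (i in seq_len(nrow(lines)))
    y <- y + lines$amplitude[i] *
      exp(-(e - lines$energy[i])^2 / (2 * peak_sigma_keV^2))
  if (poisson_noise) {
    if (integration_time_s <= 0) stop("'integration_time_s' must be > 0")
    y <- with_local_seed(rng_seed,
      rpois(length(y), y * integration_time_s) / integration_time_s)
  }
  eds_spectrum(e, y, unit = "cps")
}
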