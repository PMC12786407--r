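#' Cost parameters for the flow-network construction
#'
#' @param lam weighting coefficient \eqn{\lambda > 0} balancing regional
#'   (t-link) against boundary (n-link) information; it multiplies the
#'   t-link costs of non-seed pixels only.  Default 1.
#' @param sigma n-link intensity scale \eqn{\sigma} in grey levels, or
#'   `"auto"` to estimate it from the ROI (standard deviation of neighbour
#'   intensity differences, floored at 1).
#' @param neighborhood 4 or 8 (default 8): pixel adjacency used for n-links.
#' @param M maximum possible intensity value (default 255).
#' @return An object of class `cost_params`.
#' @examples
#' cost_params(lam = 1, sigma = 10)
#' @export
cost_params <- function(lam = 1.0, sigma = "auto", neighborhood = 8L, M = 255L) {
  if (!is.numeric(lam) || lam <= 0) stop("'lam' must be > 0")
  if (!identical(sigma, "auto") && (!is.numeric(sigma) || sigma <= 0))
    stop("'sigma' must be > 0 or \"auto\"")
  if (!neighborhood %in% c(4L, 8L)) stop("'neighborhood' must be 4 or 8")
  if (!is.numeric(M) || M <= 0) stop("'M' must be > 0")
  structure(list(lam = lam, sigma = sigma,
                 neighborhood = as.integer(neighborhood), M = as.integer(M)),
            class = "cost_params")
}

#' Mean seed intensities
#'
#' Arithmetic mean grey level of the object seeds (\eqn{I_{object}}) and of
#' the background seeds (\eqn{I_{background}}): the regional intensity models
#' used by the t-link costs.
#'
#' @param image an [image2d()].
#' @param seeds a [seed_set()].
#' @return Named list with `I_object` and `I_background`.
#' @export
seed_statistics <- function(image, seeds) {
  if (!inherits(seeds, "seed_set")) stop("'seeds' must be created with seed_set()")
  all_s <- rbind(seeds$object, seeds$background)
  if (any(all_s[, 1] < 1 | all_s[, 1] > image$height |
          all_s[, 2] < 1 | all_s[, 2] > image$width))
    stop("seed coordinates outside image bounds")
  list(I_object = mean(image$pixels[seeds$object]),
       I_background = mean(image$pixels[seeds$background]))
}

#' Regional t-link costs
#'
#' Likelihood-style costs tying a pixel of intensity `I_p` to the object and
#' background terminals: `R_s = M - |I_object - I_p|` (maximal when the pixel
#' matches the mean object-seed intensity) and
#' `R_t = M - |I_background - I_p|`.  `M` keeps both costs nonnegative.  The
#' balance coefficient lambda is applied later, at network build.
#'
#' @param I_p pixel intensity (vectorised).
#' @param I_object,I_background mean seed intensities.
#' @param M maximum possible intensity.
#' @return List with numeric vectors `R_s` and `R_t`, each in `[0, M]`.
#' @examples
#' regional_costs(120, 180, 40, 255)  # R_s = 195, R_t = 175
#' @export
regional_costs <- function(I_p, I_object, I_background, M = 255) {
  vals <- c(I_p, I_object, I_background)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > M))
    stop("intensities must lie in [0, M]")
  list(R_s = M - abs(I_object - I_p),
       R_t = M - abs(I_background - I_p))
}

#' Boundary n-link capacity
#'
#' Similarity-weighted capacity between neighbouring pixels:
#' `N(p, q) = exp(-(I_p - I_q)^2 / (2 sigma^2)) / dist(p, q)`.  Similar
#' neighbours get high capacity, making cuts through homogeneous regions
#' expensive and promoting smooth object boundaries.
#'
#' @param I_p,I_q neighbouring pixel intensities (vectorised).
#' @param sigma intensity scale in grey levels (> 0).
#' @param dist inter-pixel distance: 1 for axial, `sqrt(2)` for diagonal
#'   neighbours.
#' @return Capacities in `(0, 1/dist]`.
#' @examples
#' nlink_capacity(100, 110, sigma = 10, dist = 1)  # exp(-0.5)
#' @export
nlink_capacity <- function(I_p, I_q, sigma, dist = 1) {
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("'sigma' must be > 0")
  if (!is.numeric(dist) || any(dist <= 0)) stop("'dist' must be > 0")
  exp(-(I_p - I_q)^2 / (2 * sigma^2)) / dist
}

#' Hard-constraint constant K_max
#'
#' A finite stand-in for infinite capacity on seed t-links: one more than the
#' sum of all non-hard capacities, so no minimum cut can afford to sever a
#' hard constraint.
#'
#' @param capacities numeric vector of all non-hard edge capacities.
#' @return `1 + sum(capacities)`.
#' @examples
#' compute_kmax(c(1, 2, 3))  # 7
#' @export
compute_kmax <- function(capacities) {
  if (length(capacities) && (any(!is.finite(capacities)) || any(capacities < 0)))
    stop("capacities must be finite and nonnegative")
  1 + sum(capacities)
}

#' Estimate the n-link scale sigma from an ROI
#'
#' Standard deviation of the intensity differences over all neighbour pairs
#' inside the ROI (axial and, for 8-neighbourhood, diagonal), floored at 1
#' grey level so homogeneous ROIs stay well-defined.
#'
#' @param image an [image2d()].
#' @param roi an [roi()] (default: whole image).
#' @param neighborhood 4 or 8.
#' @return Estimated sigma in grey levels.
#' @export
estimate_sigma <- function(image, roi = full_roi(image), neighborhood = 8L) {
  check_roi(roi, image)
  I <- crop_to_roi(image$pixels, roi)
  d <- numeric(0)
  h <- nrow(I); w <- ncol(I)
  if (w > 1) d <- c(d, I[, -1] - I[, -w])
  if (h > 1) d <- c(d, I[-1, ] - I[-h, ])
  if (neighborhood == 8L && h > 1 && w > 1) {
    d <- c(d, I[-1, -1] - I[-h, -w], I[-1, -w] - I[-h, -1])
  }
  if (length(d) < 2) return(1.0)
  max(1.0, sd(d))
}

#' Build the pixel-grid flow network for seeded segmentation
#'
#' Transforms an image ROI plus object/background seeds into a directed,
#' capacitated graph: one vertex per ROI pixel plus source `s` (object
#' terminal) and sink `t` (background terminal).  Non-seed pixels get t-links
#' `c(s,p) = lambda R_s(p)` and `c(p,t) = lambda R_t(p)`; object seeds get
#' `c(s,p) = K_max`, `c(p,t) = 0` (reversed for background seeds); adjacent
#' pixel pairs get symmetric n-links with capacity [nlink_capacity()].
#'
#' Pixel vertices are numbered row-major within the ROI
#' (`(r - 1) * width + c` for 1-based ROI-local `(r, c)`); `s` and `t` follow
#' after all pixels.
#'
#' @param image an [image2d()].
#' @param roi an [roi()]; defaults to the whole image.
#' @param seeds a [seed_set()] whose coordinates lie inside the ROI.
#' @param params a [cost_params()].
#' @return An object of class `flow_network`: a list with vertex count `n`,
#'   terminal indices `s` and `t`, parallel arc vectors `from`, `to`, `cap`,
#'   the constant `kmax`, ROI geometry, and the parameters actually used
#'   (including the estimated sigma when `sigma = "auto"`).
#' @export
build_flow_network <- function(image, roi = full_roi(image), seeds,
                               params = cost_params()) {
  check_roi(roi, image)
  check_seeds(seeds, image, roi)
  sigma <- if (identical(params$sigma, "auto"))
    estimate_sigma(image, roi, params$neighborhood) else params$sigma
  M <- params$M
  lam <- params$lam

  I <- crop_to_roi(image$pixels, roi)
  h <- nrow(I); w <- ncol(I); npx <- h * w
  s <- npx + 1L; t <- npx + 2L
  vid <- function(r, c) (r - 1L) * w + c      # ROI-local, row-major

  st <- seed_statistics(image, seeds)
  rc <- regional_costs(as.numeric(I), st$I_object, st$I_background, M)
  pos <- matrix(seq_len(npx), h, w)   # column-major linear index per (r, c)
  # vertex ids aligned with the column-major pixel order of I
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  vids <- vid(rr, cc)

  cs <- lam * rc$R_s
  ct <- lam * rc$R_t

  # n-links: neighbour pairs inside the ROI (column-major index pairs)
  pair_idx <- function(r1, c1, r2, c2) {
    cbind(pos[cbind(r1, c1)], pos[cbind(r2, c2)])
  }
  pairs <- list(); dists <- list()
  if (w > 1) {  # horizontal
    g <- expand.grid(r = seq_len(h), c = seq_len(w - 1))
    pairs[[length(pairs) + 1]] <- pair_idx(g$r, g$c, g$r, g$c + 1); dists[[length(dists) + 1]] <- rep(1, nrow(g))
  }
  if (h > 1) {  # vertical
    g <- expand.grid(r = seq_len(h - 1), c = seq_len(w))
    pairs[[length(pairs) + 1]] <- pair_idx(g$r, g$c, g$r + 1, g$c); dists[[length(dists) + 1]] <- rep(1, nrow(g))
  }
  if (params$neighborhood == 8L && h > 1 && w > 1) {
    g <- expand.grid(r = seq_len(h - 1), c = seq_len(w - 1))
    pairs[[length(pairs) + 1]] <- pair_idx(g$r, g$c, g$r + 1, g$c + 1); dists[[length(dists) + 1]] <- rep(sqrt(2), nrow(g))
    pairs[[length(pairs) + 1]] <- pair_idx(g$r, g$c + 1, g$r + 1, g$c); dists[[length(dists) + 1]] <- rep(sqrt(2), nrow(g))
  }
  P <- do.call(rbind, pairs)
  dist <- unlist(dists)
  ncapu <- if (length(P)) nlink_capacity(I[P[, 1]], I[P[, 2]], sigma, dist) else numeric(0)

  # seed classification, ROI-local vertex ids
  loc <- function(m) vid(m[, 1] - roi$top + 1L, m[, 2] - roi$left + 1L)
  obj_v <- loc(seeds$object)
  bg_v <- loc(seeds$background)

  # K_max over all non-hard capacities (non-seed t-links + all n-links)
  seed_pos <- vids %in% c(obj_v, bg_v)
  kmax <- compute_kmax(c(cs[!seed_pos], ct[!seed_pos], 2 * ncapu))

  cs[match(obj_v, vids)] <- kmax; ct[match(obj_v, vids)] <- 0
  cs[match(bg_v, vids)] <- 0;    ct[match(bg_v, vids)] <- kmax

  from <- c(rep(s, npx), vids,         vids[P[, 1]], vids[P[, 2]])
  to   <- c(vids,        rep(t, npx),  vids[P[, 2]], vids[P[, 1]])
  cap  <- c(cs,          ct,           ncapu,        ncapu)

  structure(list(
    n = npx + 2L, s = s, t = t,
    from = as.integer(from), to = as.integer(to), cap = cap,
    n_pixels = npx, height = h, width = w, roi = roi,
    kmax = kmax, object_seeds = obj_v, background_seeds = bg_v,
    params = list(lam = lam, sigma = sigma,
                  neighborhood = params$neighborhood, M = M)
  ), class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf(paste0("flow_network: %d x %d ROI (%d pixel vertices + s, t), ",
                     "%d arcs, lambda = %g, sigma = %.3g, %d-neighborhood, K_max = %.4g\n"),
              x$height, x$width, x$n_pixels, length(x$from),
              x$params$lam, x$params$sigma, x$params$neighborhood, x$kmax))
  invisible(x)
}
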