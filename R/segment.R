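#' Post-processing parameters for segmentation masks
#'
#' @param min_component_px remove 8-connected object components smaller than
#'   this many pixels (default 5, low enough to keep small but significant
#'   nanoparticles while discarding background speckle).
#' @param fill_holes fill enclosed background holes (default `TRUE`);
#'   metallic particles often image hollow under SEM because of surface
#'   charging.
#' @param morph_open_radius,morph_close_radius disc structuring-element radii
#'   in pixels for optional morphological opening then closing; 0 = skip
#'   (default).
#' @return An object of class `postprocess_params`.
#' @export
postprocess_params <- function(min_component_px = 5L, fill_holes = TRUE,
                               morph_open_radius = 0L, morph_close_radius = 0L) {
  if (min_component_px < 0) stop("'min_component_px' must be >= 0")
  if (morph_open_radius < 0 || morph_close_radius < 0)
    stop("morphology radii must be >= 0")
  structure(list(min_component_px = as.integer(min_component_px),
                 fill_holes = isTRUE(fill_holes),
                 morph_open_radius = as.integer(morph_open_radius),
                 morph_close_radius = as.integer(morph_close_radius)),
            class = "postprocess_params")
}

#' Seeded graph-cut segmentation of an ROI
#'
#' The full segmentation path: build the flow network for the ROI, solve the
#' minimum s-t cut with Dinic's algorithm, label S-side pixels as object,
#' then post-process (hole filling, small-component removal, optional
#' morphological cleanup).  Hard seed constraints guarantee that object seeds
#' end up in the object and background seeds in the background of the raw
#' cut.
#'
#' @param image an [image2d()].
#' @param roi an [roi()]; defaults to the whole image.
#' @param seeds a [seed_set()] inside the ROI.
#' @param cost a [cost_params()].
#' @param post a [postprocess_params()].
#' @return Integer 0/1 matrix the size of the ROI (1 = object), with
#'   attribute `params` recording lambda, the sigma actually used, the
#'   neighbourhood, the flow value and the post-processing settings.
#' @examples
#' img <- image2d(matrix(c(rep(50, 40), rep(200, 24)), 8, 8))
#' sds <- seed_set(object = rbind(c(4, 7)), background = rbind(c(4, 2)))
#' segment_roi(img, seeds = sds)
#' @export
segment_roi <- function(image, roi = full_roi(image), seeds,
                        cost = cost_params(), post = postprocess_params()) {
  net <- build_flow_network(image, roi, seeds, cost)
  mf <- max_flow(net)
  part <- min_cut_partition(mf)
  mask <- cut_to_mask(net, part)
  if (post$fill_holes) mask <- fill_holes(mask)
  if (post$min_component_px > 0)
    mask <- remove_small_components(mask, post$min_component_px)
  mask <- morph_cleanup(mask, post$morph_open_radius, post$morph_close_radius)
  attr(mask, "params") <- c(net$params,
                            list(flow = mf$flow, phases = length(mf$phase_levels),
                                 post = unclass(post)))
  mask
}

#' Fill enclosed holes in a binary mask
#'
#' Background components (4-connected) that do not touch the mask border are
#' enclosed by the object and are set to 1; everything else is untouched.
#' Complementary connectivity (8-connected objects, 4-connected background)
#' avoids the digital-topology paradox of a diagonal "leak".
#'
#' @param mask binary matrix.
#' @return Binary matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- as_binary(mask)
  bg <- 1L - m
  lab <- cpp_label(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0]
  hole <- lab != 0 & !(lab %in% border)
  m[hole] <- 1L
  m
}

#' Remove small connected components
#'
#' Drops 8-connected object components with fewer than `min_component_px`
#' pixels; isolated bright speckle in SEM backgrounds segments as tiny
#' components and is removed here.
#'
#' @param mask binary matrix.
#' @param min_component_px minimum surviving component size in pixels.
#' @return Binary matrix.
#' @export
remove_small_components <- function(mask, min_component_px = 5L) {
  if (min_component_px < 0) stop("'min_component_px' must be >= 0")
  m <- as_binary(mask)
  if (min_component_px <= 1) return(m)
  lab <- cpp_label(m, 8L)
  if (max(lab) == 0) return(m)
  sizes <- tabulate(lab)
  drop <- which(sizes < min_component_px)
  if (length(drop)) m[lab %in% drop] <- 0L
  m
}

#' Morphological opening/closing cleanup
#'
#' Opening then closing with disc structuring elements; a radius of 0 skips
#' that step.
#'
#' @param mask binary matrix.
#' @param open_radius,close_radius disc radii in pixels.
#' @return Binary matrix.
#' @export
morph_cleanup <- function(mask, open_radius = 0L, close_radius = 0L) {
  if (open_radius < 0 || close_radius < 0) stop("radii must be >= 0")
  m <- as_binary(mask)
  if (open_radius > 0) {
    k <- EBImage::makeBrush(2L * open_radius + 1L, shape = "disc")
    m <- as_binary(EBImage::opening(m, k))
  }
  if (close_radius > 0) {
    k <- EBImage::makeBrush(2L * close_radius + 1L, shape = "disc")
    m <- as_binary(EBImage::closing(m, k))
  }
  m
}

as_binary <- function(mask) {
  if (!is.matrix(mask)) mask <- matrix(as.numeric(mask), dim(mask)[1], dim(mask)[2])
  out <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  out
}
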