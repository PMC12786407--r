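#' Calibrated 2D grayscale image
#'
#' Container for an 8-bit-style grayscale image: an integer matrix of grey
#' levels in `[0, max_intensity]` plus the physical edge length of one pixel.
#' Rows are image rows (top to bottom), columns are image columns (left to
#' right); all coordinates in the package are 1-based `(row, column)` pairs.
#'
#' @param pixels numeric or integer matrix of grey levels in
#'   `[0, max_intensity]`.
#' @param pixel_size_nm physical edge length of one pixel in nanometres
#'   (default 1).
#' @param max_intensity maximum representable grey level `M` (default 255).
#' @return An object of class `image2d`: a list with elements `pixels`
#'   (integer matrix), `height`, `width`, `pixel_size_nm`, `max_intensity`.
#' @examples
#' img <- image2d(matrix(0:249, 25, 10))
#' dim(img$pixels)
#' @export
image2d <- function(pixels, pixel_size_nm = 1.0, max_intensity = 255L) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("image must be nonempty")
  if (anyNA(pixels)) stop("image contains NA pixels")
  if (min(pixels) < 0 || max(pixels) > max_intensity)
    stop("pixel intensities must lie in [0, ", max_intensity, "]")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be > 0")
  structure(list(
    pixels = matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels)),
    height = nrow(pixels), width = ncol(pixels),
    pixel_size_nm = pixel_size_nm,
    max_intensity = as.integer(max_intensity)
  ), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d px, %.4g nm/px, grey levels [%d, %d] of [0, %d]\n",
              x$height, x$width, x$pixel_size_nm,
              min(x$pixels), max(x$pixels), x$max_intensity))
  invisible(x)
}

#' Rectangular region of interest
#'
#' 1-based inclusive pixel-index bounds of a rectangular ROI; segmentation
#' builds and solves the flow network only for pixels inside it.
#'
#' @param top,left,bottom,right 1-based inclusive row/column bounds.
#' @return An object of class `roi`.
#' @examples
#' roi(1, 1, 64, 64)
#' @export
roi <- function(top, left, bottom, right) {
  top <- as.integer(top); left <- as.integer(left)
  bottom <- as.integer(bottom); right <- as.integer(right)
  if (top < 1 || left < 1) stop("ROI indices are 1-based: top/left must be >= 1")
  if (bottom < top || right < left) stop("ROI is empty")
  structure(list(top = top, left = left, bottom = bottom, right = right),
            class = "roi")
}

#' ROI covering a whole image
#' @param image an [image2d()].
#' @return An `roi` spanning every pixel of `image`.
#' @export
full_roi <- function(image) roi(1, 1, image$height, image$width)

roi_height <- function(r) r$bottom - r$top + 1L
roi_width <- function(r) r$right - r$left + 1L

check_roi <- function(r, image) {
  if (!inherits(r, "roi")) stop("'roi' must be created with roi()")
  if (r$bottom > image$height || r$right > image$width)
    stop("ROI exceeds image bounds")
  invisible(r)
}

#' Object/background seed annotations
#'
#' Hard-constraint pixel sets: object seeds (set O, forced to the object) and
#' background seeds (set B, forced to the background).  Coordinates are
#' 1-based `(row, column)` pairs in image coordinates.
#'
#' @param object two-column matrix of `(row, col)` object-seed coordinates.
#' @param background two-column matrix of background-seed coordinates.
#' @return An object of class `seed_set`.
#' @examples
#' seed_set(object = rbind(c(2, 2)), background = rbind(c(1, 1)))
#' @export
seed_set <- function(object, background) {
  object <- as_coord_matrix(object, "object")
  background <- as_coord_matrix(background, "background")
  if (nrow(object) == 0 || nrow(background) == 0)
    stop("both object and background seed sets must be nonempty")
  key <- function(m) paste(m[, 1], m[, 2])
  if (any(key(object) %in% key(background)))
    stop("object and background seeds must be disjoint")
  structure(list(object = object, background = background), class = "seed_set")
}

as_coord_matrix <- function(x, what) {
  if (is.null(x)) return(matrix(integer(), 0, 2))
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("'", what, "' seeds must be a two-column (row, col) matrix")
  storage.mode(x) <- "integer"
  colnames(x) <- c("row", "col")
  unique(x)
}

check_seeds <- function(seeds, image, r) {
  if (!inherits(seeds, "seed_set")) stop("'seeds' must be created with seed_set()")
  all_s <- rbind(seeds$object, seeds$background)
  if (any(all_s[, 1] < r$top | all_s[, 1] > r$bottom |
          all_s[, 2] < r$left | all_s[, 2] > r$right))
    stop("all seeds must lie inside the ROI")
  invisible(seeds)
}

#' Build a seed set from binary seed masks
#'
#' @param object_mask,background_mask binary matrices (nonzero = seed) the
#'   same size as the image.
#' @return A [seed_set()].
#' @export
seeds_from_masks <- function(object_mask, background_mask) {
  seed_set(object = which(object_mask != 0, arr.ind = TRUE),
           background = which(background_mask != 0, arr.ind = TRUE))
}

#' Read seeds from a JSON coordinate file
#'
#' Expects `{"object": [[r, c], ...], "background": [[r, c], ...]}` with
#' 1-based coordinates.
#'
#' @param path path to the JSON file.
#' @return A [seed_set()].
#' @export
read_seeds_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$object) || is.null(x$background))
    stop("seed JSON must contain 'object' and 'background' arrays")
  seed_set(object = x$object, background = x$background)
}

# ---- image file I/O (PNG / TIFF, 8-bit grayscale) --------------------------

to_gray255 <- function(arr) {
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    else arr <- arr[, , 1]
  }
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' Color images are converted to grayscale by channel averaging; any alpha
#' channel is dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size_nm pixel calibration to attach (nm/px, default 1).
#' @return An [image2d()].
#' @export
read_image <- function(path, pixel_size_nm = 1.0) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  image2d(to_gray255(arr), pixel_size_nm = pixel_size_nm)
}

#' Write an 8-bit grayscale image (PNG or TIFF)
#' @param image an [image2d()] or a grey-level matrix in `[0, 255]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "image2d")) image$pixels else image
  arr <- px / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read a binary mask from an image file (nonzero = foreground)
#' @param path PNG/TIFF path.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  m <- img$pixels
  matrix(as.integer(m > 0), nrow(m), ncol(m))
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask binary matrix.
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  write_image(matrix(ifelse(mask != 0, 255L, 0L), nrow(mask), ncol(mask)), path)
}

crop_to_roi <- function(mat, r) mat[r$top:r$bottom, r$left:r$right, drop = FALSE]
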