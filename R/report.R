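report_fields <- function() {
  c("area_px", "area_nm2", "perimeter_px", "perimeter_nm",
    "centroid_row", "centroid_col", "mean_intensity", "mode_intensity",
    "min_intensity", "max_intensity", "circularity",
    "ellipse_major_nm", "ellipse_minor_nm", "ellipse_orientation_deg",
    "mbr_long_nm", "mbr_short_nm", "mbr_aspect_ratio",
    "feret_max_nm", "feret_min_nm", "feret_ratio", "pixel_size_nm")
}

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

#' Write the per-particle INFO.TXT-style report
#'
#' One `key = value` block per particle in a fixed field order with
#' locale-independent decimal points, plus an optional CSV twin carrying
#' identical values.  Files are written atomically (temp file then rename).
#'
#' @param measurements list of [measure_particle()] records (may be empty).
#' @param path output text file path.
#' @param csv_path optional CSV path (one row per particle).
#' @return `path`, invisibly.
#' @export
write_report <- function(measurements, path, csv_path = NULL) {
  lines <- c("# particlecut particle report",
             sprintf("n_particles = %d", length(measurements)))
  for (i in seq_along(measurements)) {
    m <- measurements[[i]]
    lines <- c(lines, "", sprintf("[particle %d]", i),
               vapply(report_fields(), function(f)
                 sprintf("%s = %s", f, fmt_num(m[[f]])), character(1)))
  }
  write_atomic(paste(lines, collapse = "\n"), path)
  if (!is.null(csv_path)) {
    df <- measurements_df(measurements)
    tmp <- paste0(csv_path, ".tmp")
    write.csv(df, tmp, row.names = FALSE)
    file.rename(tmp, csv_path)
  }
  invisible(path)
}

#' Parse a report written by [write_report()]
#' @param path report text file.
#' @return Data frame, one row per particle (empty for a header-only file).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  blocks <- grep("^\\[particle ", lines)
  fields <- report_fields()
  if (length(blocks) == 0)
    return(as.data.frame(setNames(rep(list(numeric(0)), length(fields) + 1),
                                  c("particle", fields))))
  rows <- lapply(seq_along(blocks), function(b) {
    start <- blocks[b] + 1
    end <- if (b < length(blocks)) blocks[b + 1] - 1 else length(lines)
    kv <- lines[start:end]
    kv <- kv[grepl("=", kv, fixed = TRUE)]
    keys <- trimws(sub("=.*", "", kv))
    vals <- as.numeric(trimws(sub(".*=", "", kv)))
    out <- as.list(setNames(vals, keys))
    data.frame(particle = b, as.data.frame(out[fields]))
  })
  do.call(rbind, rows)
}

write_atomic <- function(text, path) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wt")
  writeLines(text, con, sep = "\n")
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

# ---- drawing helpers -------------------------------------------------------

# Sample a segment densely and round to pixels (gives a connected raster line).
segment_pixels <- function(p0, p1, nr, nc) {
  len <- max(abs(p1 - p0))
  n <- max(2L, ceiling(2 * len))
  t_ <- seq(0, 1, length.out = n)
  r <- round(p0[1] + t_ * (p1[1] - p0[1]))
  c <- round(p0[2] + t_ * (p1[2] - p0[2]))
  keep <- r >= 1 & r <= nr & c >= 1 & c <= nc
  unique(cbind(r[keep], c[keep]))
}

gray_to_rgb <- function(pixels) {
  g <- pixels / 255
  array(rep(g, 3), c(nrow(pixels), ncol(pixels), 3))
}

paint <- function(arr, coords, color) {
  if (length(coords) == 0 || nrow(coords) == 0) return(arr)
  for (k in 1:3) arr[cbind(coords, rep(k, nrow(coords)))] <- color[k]
  arr
}

#' Render annotation overlays for segmented particles
#'
#' Writes five PNG views per call: a colored overlay of the object, the
#' traced contour, the minimum bounding rectangles, the fitted equivalent
#' ellipses, and the maximum Feret diameters.  Colors are fixed, so outputs
#' are deterministic.
#'
#' @param image an [image2d()] aligned with `mask`.
#' @param mask binary mask.
#' @param measurements list of [measure_particle()] records for `mask`.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix (default `"view"`).
#' @return Named character vector of the files written.
#' @export
render_overlays <- function(image, mask, measurements, out_dir,
                            prefix = "view") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nr <- image$height; nc <- image$width
  red <- c(1, 0.15, 0.15); green <- c(0.15, 1, 0.15)
  blue <- c(0.2, 0.4, 1); yellow <- c(1, 0.9, 0.1)
  base <- gray_to_rgb(image$pixels)

  ov <- base
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    for (k in 1:3)
      ov[cbind(idx, rep(k, nrow(idx)))] <-
        0.5 * ov[cbind(idx, rep(k, nrow(idx)))] + 0.5 * red[k]
  }

  contour <- base; mbr <- base; ell <- base; fer <- base
  for (m in measurements) {
    contour <- paint(contour, m$contour, green)
    cor <- m$mbr_corners
    for (i in 1:4) {
      j <- if (i == 4) 1 else i + 1
      mbr <- paint(mbr, segment_pixels(cor[i, ], cor[j, ], nr, nc), blue)
    }
    ps <- m$pixel_size_nm
    a <- m$ellipse_major_nm / ps / 2; b <- m$ellipse_minor_nm / ps / 2
    th <- m$ellipse_orientation_deg * pi / 180
    t_ <- seq(0, 2 * pi, length.out = max(32, ceiling(4 * pi * max(a, 1))))
    ex <- m$centroid_col + a * cos(t_) * cos(th) - b * sin(t_) * sin(th)
    ey <- m$centroid_row + a * cos(t_) * sin(th) + b * sin(t_) * cos(th)
    ec <- unique(cbind(round(ey), round(ex)))
    ec <- ec[ec[, 1] >= 1 & ec[, 1] <= nr & ec[, 2] >= 1 & ec[, 2] <= nc, , drop = FALSE]
    ell <- paint(ell, ec, yellow)
    ep <- m$feret_max_endpoints
    fer <- paint(fer, segment_pixels(ep[1, ], ep[2, ], nr, nc), red)
  }

  files <- c(overlay = file.path(out_dir, paste0(prefix, "_overlay.png")),
             contour = file.path(out_dir, paste0(prefix, "_contour.png")),
             mbr = file.path(out_dir, paste0(prefix, "_mbr.png")),
             ellipse = file.path(out_dir, paste0(prefix, "_ellipse.png")),
             feret = file.path(out_dir, paste0(prefix, "_feret.png")))
  png::writePNG(ov, files["overlay"])
  png::writePNG(contour, files["contour"])
  png::writePNG(mbr, files["mbr"])
  png::writePNG(ell, files["ellipse"])
  png::writePNG(fer, files["feret"])
  files
}

#' Run the full segmentation-and-measurement pipeline
#'
#' File-based end-to-end run: read the image and seeds, segment the ROI,
#' measure every particle, and write the mask, report, CSV, overlay views
#' and a JSON sidecar echoing every parameter actually used (including the
#' auto-estimated sigma).  Outputs are written atomically; a failed run
#' leaves no partial mask/report behind.
#'
#' @param config named list (or YAML file path) with entries: `image` (path),
#'   `object_seeds`/`background_seeds` (mask PNGs) or `seeds_json`; optional
#'   `roi` (`c(top, left, bottom, right)`), `lam`, `sigma`, `neighborhood`,
#'   `min_component_px`, `fill_holes`, `morph_open_radius`,
#'   `morph_close_radius`, `pixel_size_nm`, `out_dir`.
#' @return Invisibly, a list with the mask, measurements and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  need <- function(x) if (is.null(config[[x]])) stop("config entry '", x, "' is required") else config[[x]]
  grab <- function(x, default) if (is.null(config[[x]])) default else config[[x]]

  img <- read_image(need("image"), pixel_size_nm = grab("pixel_size_nm", 1))
  seeds <- if (!is.null(config$seeds_json)) read_seeds_json(config$seeds_json)
    else seeds_from_masks(read_mask(need("object_seeds")),
                          read_mask(need("background_seeds")))
  r <- if (is.null(config$roi)) full_roi(img)
    else do.call(roi, as.list(as.integer(config$roi)))
  cost <- cost_params(lam = grab("lam", 1), sigma = grab("sigma", "auto"),
                      neighborhood = grab("neighborhood", 8L))
  post <- postprocess_params(
    min_component_px = grab("min_component_px", 5L),
    fill_holes = grab("fill_holes", TRUE),
    morph_open_radius = grab("morph_open_radius", 0L),
    morph_close_radius = grab("morph_close_radius", 0L))

  mask <- segment_roi(img, r, seeds, cost, post)
  roi_img <- image2d(crop_to_roi(img$pixels, r), pixel_size_nm = img$pixel_size_nm)
  meas <- measure_mask(mask, roi_img)

  out_dir <- grab("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(out_dir, "mask.png")
  write_mask(mask, mask_path)
  info_path <- file.path(out_dir, "info.txt")
  csv_path <- file.path(out_dir, "particles.csv")
  write_report(meas, info_path, csv_path)
  views <- render_overlays(roi_img, mask, meas, out_dir)
  sidecar <- file.path(out_dir, "run.json")
  jsonlite::write_json(list(parameters = attr(mask, "params"),
                            roi = unclass(r),
                            n_particles = length(meas),
                            outputs = c(mask = mask_path, info = info_path,
                                        csv = csv_path, views)),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(mask = mask, measurements = meas,
                 outputs = c(mask = mask_path, info = info_path,
                             csv = csv_path, sidecar = sidecar, views)))
}
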