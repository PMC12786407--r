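#' EDS spectrum container
#'
#' Energy-dispersive X-ray spectrum: strictly increasing energies (keV)
#' restricted to the detector range 0.16-9.8 keV, with nonnegative
#' per-channel counts.
#'
#' @param energy numeric vector of channel energies (keV).
#' @param counts nonnegative counts per channel (raw counts or cps; record
#'   which in `unit`).
#' @param unit `"counts"` or `"cps"` (metadata only).
#' @return An object of class `eds_spectrum` (a data-frame-backed list).
#' @export
eds_spectrum <- function(energy, counts, unit = "counts") {
  if (length(energy) != length(counts)) stop("energy and counts lengths differ")
  if (length(energy) == 0) stop("empty spectrum")
  if (anyNA(energy) || anyNA(counts)) stop("spectrum contains NA values")
  o <- order(energy)
  energy <- energy[o]; counts <- counts[o]
  keep <- energy >= eds_range()[1] & energy <= eds_range()[2]
  if (any(!keep)) {
    warning(sum(!keep), " channel(s) outside the detector range ",
            eds_range()[1], "-", eds_range()[2], " keV dropped")
    energy <- energy[keep]; counts <- counts[keep]
  }
  if (length(energy) == 0) stop("no channels within the detector range")
  if (any(diff(energy) <= 0)) stop("energies must be strictly increasing")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(energy = energy, counts = counts, unit = unit),
            class = "eds_spectrum")
}

eds_range <- function() c(0.16, 9.8)

#' @export
print.eds_spectrum <- function(x, ...) {
  cat(sprintf("eds_spectrum: %d channels, %.3g-%.3g keV, max %.4g %s\n",
              length(x$energy), min(x$energy), max(x$energy),
              max(x$counts), x$unit))
  invisible(x)
}

#' Read an EDS spectrum from a two-column CSV
#'
#' Expects columns `energy_keV` and `counts` (or any two numeric columns in
#' that order).  Rows outside the 0.16-9.8 keV detector range are dropped
#' with a warning; rows are sorted by energy.
#'
#' @param path CSV file path.
#' @param unit `"counts"` or `"cps"`.
#' @return An [eds_spectrum()].
#' @export
read_spectrum <- function(path, unit = "counts") {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  df <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse spectrum file: ", conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2) stop("spectrum file must have two numeric columns")
  e <- suppressWarnings(as.numeric(df[[1]]))
  ct <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(e) || anyNA(ct)) stop("non-numeric values in spectrum file")
  eds_spectrum(e, ct, unit)
}

#' Default characteristic X-ray line table
#'
#' Line energies (keV) of the elements relevant to metallic particles in
#' hippocampal tissue: Fe K-alpha 6.40; Cr K-alpha 5.41; Ni K-alpha 7.47 and
#' L-alpha 0.85; Zn K-alpha 8.64 and L-alpha 1.01.
#'
#' @return Data frame with columns `element` and `energy_keV`, restricted to
#'   lines usable within the detector range.
#' @export
default_line_table <- function() {
  tab <- data.frame(
    element = c("Fe", "Cr", "Ni", "Ni", "Zn", "Zn"),
    energy_keV = c(6.40, 5.41, 7.47, 0.85, 8.64, 1.01))
  tab[tab$energy_keV >= eds_range()[1] & tab$energy_keV <= eds_range()[2], ]
}

#' Detect peaks in an EDS spectrum
#'
#' Local maxima with topographic prominence at or above `min_prominence`.
#' Peak height is measured above a linear local background interpolated
#' between the peak's two base minima — the lowest samples between the peak
#' and the nearest higher terrain (or the spectrum end) on each side, i.e.
#' the flanking minima that delimit the peak as a structure.  Anchoring the
#' background at these bases rather than at the nearest noise wiggle makes
#' the heights comparable to visually read peak heights on a sloping
#' continuum.
#'
#' @param spectrum an [eds_spectrum()].
#' @param min_prominence minimum prominence in counts (default 0 keeps all
#'   local maxima, including noise wiggles).
#' @return Data frame sorted by height (descending): `energy`, `height`
#'   (background-subtracted), `raw_counts`, `prominence`, `channel`.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0) {
  if (min_prominence < 0) stop("'min_prominence' must be >= 0")
  y <- spectrum$counts
  e <- spectrum$energy
  n <- length(y)
  empty <- data.frame(energy = numeric(0), height = numeric(0),
                      raw_counts = numeric(0), prominence = numeric(0),
                      channel = integer(0))
  if (n < 3) return(empty)
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(is_max) == 0) return(empty)
  res <- lapply(is_max, function(i) {
    h <- y[i]
    # base minima: on each side, walk until a strictly higher sample (or the
    # boundary) and take the argmin along the walk
    li <- if (any(y[seq_len(i - 1)] > h)) {
      j <- max(which(y[seq_len(i - 1)] > h))
      j - 1L + which.min(y[j:(i - 1)])
    } else which.min(y[seq_len(i - 1)])
    ri <- if (any(y[(i + 1):n] > h)) {
      j <- i + min(which(y[(i + 1):n] > h))
      i + which.min(y[(i + 1):j])
    } else i + which.min(y[(i + 1):n])
    prom <- h - max(y[li], y[ri])
    bg <- y[li] + (y[ri] - y[li]) * (e[i] - e[li]) / (e[ri] - e[li])
    data.frame(energy = e[i], height = h - bg, raw_counts = h,
               prominence = prom, channel = i)
  })
  out <- do.call(rbind, res)
  out <- out[out$prominence >= min_prominence & out$height > 0, , drop = FALSE]
  out[order(-out$height), , drop = FALSE]
}

#' Assign detected peaks to elements by line energy
#'
#' Each peak is matched to the nearest characteristic line within
#' `tolerance_keV`; unmatched peaks are reported with element `"unknown"`.
#' For an element with several lines in the spectrum, its tallest assigned
#' peak is flagged `primary`.
#'
#' @param peaks a [detect_peaks()] data frame.
#' @param table line table (default [default_line_table()]).
#' @param tolerance_keV assignment window (default 0.1, a typical
#'   silicon-drift-detector resolution scale).
#' @return Data frame: `element`, `line_energy`, `measured_energy`, `height`,
#'   `prominence`, `primary`.
#' @export
assign_elements <- function(peaks, table = default_line_table(),
                            tolerance_keV = 0.1) {
  if (tolerance_keV <= 0) stop("'tolerance_keV' must be > 0")
  if (nrow(peaks) == 0)
    return(data.frame(element = character(0), line_energy = numeric(0),
                      measured_energy = numeric(0), height = numeric(0),
                      prominence = numeric(0), primary = logical(0)))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    d <- abs(table$energy_keV - peaks$energy[i])
    k <- which.min(d)
    if (d[k] <= tolerance_keV)
      data.frame(element = table$element[k], line_energy = table$energy_keV[k],
                 measured_energy = peaks$energy[i], height = peaks$height[i],
                 prominence = peaks$prominence[i])
    else
      data.frame(element = "unknown", line_energy = NA_real_,
                 measured_energy = peaks$energy[i], height = peaks$height[i],
                 prominence = peaks$prominence[i])
  })
  out <- do.call(rbind, rows)
  out$primary <- FALSE
  for (el in unique(out$element)) {
    idx <- which(out$element == el)
    out$primary[idx[which.max(out$height[idx])]] <- TRUE
  }
  out
}

#' Element peak-height ratio
#'
#' Ratio vector of primary peak heights, normalized to the last requested
#' element — the semi-quantitative composition readout (e.g. Fe:Zn = 2:1).
#' Raw peak-height ratios are reported without ZAF/standards correction.
#'
#' @param assignments an [assign_elements()] data frame.
#' @param elements ordered character vector of element symbols; the last one
#'   is the reference.
#' @return Named numeric vector of ratios (last element = 1).
#' @examples
#' a <- data.frame(element = c("Fe", "Zn"), line_energy = c(6.4, 8.64),
#'                 measured_energy = c(6.4, 8.64), height = c(400, 200),
#'                 prominence = c(400, 200), primary = TRUE)
#' element_ratio(a, c("Fe", "Zn"))  # Fe = 2, Zn = 1
#' @export
element_ratio <- function(assignments, elements) {
  if (length(elements) < 2) stop("need at least two elements for a ratio")
  h <- vapply(elements, function(el) {
    rows <- assignments[assignments$element == el & assignments$primary, , drop = FALSE]
    if (nrow(rows) == 0)
      stop("element '", el, "' has no assigned peak in the spectrum")
    rows$height[1]
  }, numeric(1))
  h / h[length(h)]
}

#' Format a ratio vector as reported (one decimal, ":"-separated)
#' @param ratio result of [element_ratio()].
#' @return Character string such as `"2.0:1"`.
#' @export
format_ratio <- function(ratio) {
  paste(ifelse(seq_along(ratio) == length(ratio), "1",
               sprintf("%.1f", ratio)), collapse = ":")
}
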