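#' Wavelength grid
#'
#' A strictly increasing vector of wavelengths (nm) shared by every spectrum in
#' an analysis.  The default grid mirrors the acquisition instrument this
#' package emulates: 2047 channels spanning 560--1072 nm.
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing.
#' @return A numeric vector of class `wavelength_grid`.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("wavelength grid needs at least two finite values", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  structure(values, class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param n_channels Number of channels for the default instrument grid.
#' @export
default_grid <- function(n_channels = 2047L) {
  wavelength_grid(seq(560, 1072, length.out = n_channels))
}

#' Multi-point transmission scan
#'
#' One fruit's stack of per-position transmission spectra, recorded in conveyor
#' order as the sample moves past the detector.
#'
#' @param points K x P matrix of intensities (detector counts), one row per
#'   acquisition point.
#' @param grid [wavelength_grid] of length P.
#' @param sample_id Sample identifier.
#' @param orientation `"O1"` (stem-calyx axis perpendicular to the belt) or
#'   `"O2"` (parallel, stem toward the spectrometer).
#' @param saturation_level Detector cap in counts, if known; used as the
#'   default by [flag_saturated()].
#' @return An object of class `multipoint_scan`.
#' @export
multipoint_scan <- function(points, grid, sample_id = "sample",
                            orientation = c("O1", "O2"),
                            saturation_level = NULL) {
  orientation <- match.arg(orientation)
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("scan needs at least one point", call. = FALSE)
  if (ncol(points) != length(grid)) {
    stop("scan width does not match wavelength grid", call. = FALSE)
  }
  if (anyNA(points) || any(points < 0)) {
    stop("scan intensities must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), orientation = orientation,
         points = unname(points), grid = grid,
         saturation_level = saturation_level),
    class = "multipoint_scan")
}

#' @export
print.multipoint_scan <- function(x, ...) {
  cat(sprintf("<multipoint_scan> %s [%s]: %d points x %d channels\n",
              x$sample_id, x$orientation, nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Background spectrum
#'
#' Spectrometer reading with no sample in the beam, plus the standard
#' deviation of its channel noise around the smooth stray-light level.  The
#' noise SD anchors the signal-to-noise ratio used to weight acquisition
#' points.
#'
#' @param intensity P-vector of counts.
#' @param noise_sd Scalar SD (counts) of the background channel noise.
#' @param grid [wavelength_grid] of length P.
#' @return An object of class `background_spectrum`.
#' @export
background_spectrum <- function(intensity, noise_sd, grid) {
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(grid)) {
    stop("background length does not match wavelength grid", call. = FALSE)
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    stop("background noise_sd must be a non-negative scalar", call. = FALSE)
  }
  structure(list(intensity = intensity, noise_sd = noise_sd, grid = grid),
            class = "background_spectrum")
}

#' Single effective spectrum
#'
#' @param intensity P-vector on `grid`.
#' @param grid [wavelength_grid].
#' @param sample_id Sample identifier.
#' @param tags Character vector of processing provenance tags.
#' @return An object of class `ssc_spectrum`.
#' @export
ssc_spectrum <- function(intensity, grid, sample_id = "sample",
                         tags = character()) {
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(grid)) {
    stop("spectrum length does not match wavelength grid", call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("spectrum must be finite", call. = FALSE)
  }
  structure(list(intensity = intensity, grid = grid,
                 sample_id = as.character(sample_id), tags = tags),
            class = "ssc_spectrum")
}

#' Regression dataset of aggregated spectra
#'
#' Pairs an n x P predictor matrix (one effective spectrum per fruit) with the
#' reference SSC values measured by refractometry.
#'
#' @param X n x P matrix of (possibly pretreated) intensities.
#' @param y n-vector of SSC references in degrees Brix.
#' @param grid [wavelength_grid] of length P (or a plain numeric vector of
#'   wavelengths for a selected-channel subset).
#' @param sample_id Optional sample identifiers (default `S001`, ...).
#' @param orientation Scan orientation label carried for reporting.
#' @param variety Variety label carried for reporting.
#' @return An object of class `ssc_dataset`.
#' @export
ssc_dataset <- function(X, y, grid, sample_id = NULL,
                        orientation = "O1", variety = "synthetic") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  if (ncol(X) != length(grid)) stop("X width and grid length differ", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("dataset contains missing values", call. = FALSE)
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(nrow(X)))
  structure(list(X = unname(X), y = y, grid = grid,
                 sample_id = as.character(sample_id),
                 orientation = orientation, variety = variety),
            class = "ssc_dataset")
}

#' @export
print.ssc_dataset <- function(x, ...) {
  cat(sprintf("<ssc_dataset> %s/%s: %d samples x %d channels, SSC %.1f-%.1f Brix\n",
              x$variety, x$orientation, nrow(x$X), ncol(x$X),
              min(x$y), max(x$y)))
  invisible(x)
}
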