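#' Trim incomplete end points from a multi-point scan
#'
#' Online full-transmission acquisition records incomplete signals while the
#' fruit enters and leaves the beam.  Points in the maximal leading and
#' trailing runs whose total intensity falls below `rel_threshold` times the
#' median point total are removed; interior points are never touched.
#'
#' @param scan [multipoint_scan] with at least 3 points.
#' @param rel_threshold Fraction of the median point total below which an end
#'   point counts as incomplete (default 0.5).
#' @return The trimmed [multipoint_scan].
#' @export
trim_end_scans <- function(scan, rel_threshold = 0.5) {
  stopifnot(inherits(scan, "multipoint_scan"))
  K <- nrow(scan$points)
  if (K < 3L) stop("trim_end_scans needs at least 3 points", call. = FALSE)
  totals <- rowSums(scan$points)
  cut <- rel_threshold * stats::median(totals)
  keep <- totals >= cut
  if (!any(keep)) {
    stop(sprintf("degenerate scan '%s': every point below the trim threshold",
                 scan$sample_id), call. = FALSE)
  }
  first <- which(keep)[1L]
  last <- which(keep)[length(which(keep))]
  scan$points <- scan$points[first:last, , drop = FALSE]
  scan
}

#' Flag saturated acquisition points
#'
#' A point is dropped from the weighted average when strictly more than
#' `max_frac` of its channels sit at or above the detector cap
#' ("intensity supersaturation").
#'
#' @param scan [multipoint_scan].
#' @param saturation_level Detector cap in counts; defaults to the level
#'   recorded on the scan, else `Inf` (no flagging).
#' @param max_frac Tolerated fraction of clipped channels (strict inequality;
#'   a point with exactly `max_frac` clipped channels is retained).
#' @return Logical vector, `TRUE` for retained points.
#' @export
flag_saturated <- function(scan, saturation_level = NULL, max_frac = 0.01) {
  stopifnot(inherits(scan, "multipoint_scan"))
  saturation_level <- saturation_level %||% scan$saturation_level %||% Inf
  if (saturation_level <= 0) stop("saturation_level must be positive", call. = FALSE)
  frac <- rowMeans(scan$points >= saturation_level)
  frac <= max_frac
}

#' Signal-to-noise ratio of one acquisition point
#'
#' The mean net signal above the background, relative to the background
#' channel-noise SD: `mean(pmax(point - background, 0)) / max(noise_sd, 1e-12)`.
#' Linear scale; only the ordering matters for proportional weights.
#'
#' @param point P-vector of intensities.
#' @param background [background_spectrum] on the same grid.
#' @return Non-negative scalar SNR.
#' @export
estimate_snr <- function(point, background) {
  stopifnot(inherits(background, "background_spectrum"))
  point <- as.numeric(point)
  if (length(point) != length(background$intensity)) {
    stop("point and background lengths differ", call. = FALSE)
  }
  mean(pmax(point - background$intensity, 0)) / max(background$noise_sd, 1e-12)
}

#' SNR-proportional point weights
#'
#' Retained points receive weights proportional to their SNR, normalized to
#' sum to one; discarded points receive weight zero.  If every retained SNR is
#' zero the weights fall back to uniform over the retained points, with a
#' warning.
#'
#' @param snrs Numeric vector of per-point SNRs.
#' @param retained Logical vector of the same length (default all retained).
#' @return Numeric weight vector summing to 1 over retained points.
#' @export
compute_weights <- function(snrs, retained = rep(TRUE, length(snrs))) {
  stopifnot(length(snrs) == length(retained))
  if (!any(retained)) stop("no retained points to weight", call. = FALSE)
  w <- numeric(length(snrs))
  s <- snrs[retained]
  if (any(s < 0)) stop("SNRs must be non-negative", call. = FALSE)
  if (sum(s) <= 0) {
    warning("all retained SNRs are zero; using uniform weights")
    w[retained] <- 1 / sum(retained)
  } else {
    w[retained] <- s / sum(s)
  }
  w
}

#' Weighted average of a scan's points
#'
#' Channel-wise convex combination of the acquisition-point spectra; the
#' result is bounded by the retained points' channel-wise min and max.
#'
#' @param scan [multipoint_scan].
#' @param weights Weight vector from [compute_weights()] (length K, sums to 1).
#' @return An [ssc_spectrum].
#' @export
weighted_average <- function(scan, weights) {
  stopifnot(inherits(scan, "multipoint_scan"))
  if (length(weights) != nrow(scan$points)) {
    stop("weight and point counts differ", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  ssc_spectrum(drop(crossprod(scan$points, weights)), scan$grid,
               sample_id = scan$sample_id, tags = "weighted_average")
}

#' Aggregate a multi-point scan into one effective spectrum
#'
#' The full derivation of the effective spectrum: trim incomplete end points,
#' drop saturated points, score each remaining point's SNR against the
#' background, convert SNRs to normalized weights, and average.
#'
#' @param scan [multipoint_scan].
#' @param background [background_spectrum].
#' @param rel_threshold Passed to [trim_end_scans()] (skipped when K < 3).
#' @param saturation_level,max_frac Passed to [flag_saturated()].
#' @param verbose Log per-point SNRs and weights via `message()`.
#' @return An [ssc_spectrum] with the per-point SNRs and weights attached as
#'   attributes `"snr"` and `"weights"`.
#' @export
aggregate_scan <- function(scan, background, rel_threshold = 0.5,
                           saturation_level = NULL, max_frac = 0.01,
                           verbose = FALSE) {
  stopifnot(inherits(scan, "multipoint_scan"),
            inherits(background, "background_spectrum"))
  if (nrow(scan$points) >= 3L) {
    scan <- trim_end_scans(scan, rel_threshold)
  }
  retained <- flag_saturated(scan, saturation_level, max_frac)
  if (!any(retained)) {
    stop(sprintf("degenerate scan '%s': every point saturated", scan$sample_id),
         call. = FALSE)
  }
  snrs <- apply(scan$points, 1L, estimate_snr, background = background)
  weights <- compute_weights(snrs, retained)
  if (verbose) {
    message(sprintf("scan %s: %d points, SNR [%s], weights [%s]",
                    scan$sample_id, nrow(scan$points),
                    paste(sprintf("%.3g", snrs), collapse = ", "),
                    paste(sprintf("%.3g", weights), collapse = ", ")))
  }
  out <- weighted_average(scan, weights)
  attr(out, "snr") <- snrs
  attr(out, "weights") <- weights
  out
}
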