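#' Pretreatment specification
#'
#' The three pretreatment routes compared in the study grid: the raw
#' aggregated spectrum (`RAW`), 13-point Savitzky-Golay smoothing (`SG`), or
#' the standard normal variate transform (`SNV`).  Exactly one is applied;
#' they are alternatives, never chained.
#'
#' @param method `"RAW"`, `"SG"` or `"SNV"`.
#' @param sg_window Odd SG window length (default 13).
#' @param sg_polyorder SG polynomial degree, less than the window (default 2,
#'   the standard chemometric choice for smoothing).
#' @return An object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(method = c("RAW", "SG", "SNV"),
                              sg_window = 13L, sg_polyorder = 2L) {
  method <- match.arg(method)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L) stop("sg_window must be odd", call. = FALSE)
  if (sg_polyorder >= sg_window) {
    stop("sg_polyorder must be smaller than sg_window", call. = FALSE)
  }
  if (sg_polyorder < 0L) stop("sg_polyorder must be non-negative", call. = FALSE)
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder),
            class = "pretreatment_spec")
}

# Least-squares polynomial smoother coefficients.  For the symmetric interior
# window the center estimate is a fixed convolution; the first/last
# half-window channels are fit on their truncated (one-sided) window and the
# polynomial is evaluated at the edge channel itself, which keeps polynomial
# reproduction exact up to the fitted degree at the edges.
sg_coefficients <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  fit_at_zero <- function(d) {
    A <- outer(d, 0:polyorder, `^`)
    # first row of (A'A)^{-1} A': evaluates the fitted polynomial at 0
    drop(solve(crossprod(A), t(A))[1L, ])
  }
  left <- lapply(seq_len(h), function(i) fit_at_zero((1L:(i + h)) - i))
  list(h = h, interior = fit_at_zero(-h:h), left = left,
       right = lapply(left, rev))
}

sg_smooth_matrix <- function(X, window, polyorder) {
  P <- ncol(X)
  if (window %% 2L == 0L) stop("sg_window must be odd", call. = FALSE)
  if (window > P) stop("sg_window exceeds the number of channels", call. = FALSE)
  if (polyorder >= window) stop("sg_polyorder must be < sg_window", call. = FALSE)
  co <- sg_coefficients(window, polyorder)
  h <- co$h
  Y <- matrix(0, nrow(X), P)
  mid <- (h + 1L):(P - h)
  for (j in seq_len(window)) {
    Y[, mid] <- Y[, mid] + co$interior[j] * X[, mid + j - h - 1L, drop = FALSE]
  }
  for (i in seq_len(h)) {
    Y[, i] <- X[, 1L:(i + h), drop = FALSE] %*% co$left[[i]]
    Y[, P - i + 1L] <- X[, (P - i + 1L - h):P, drop = FALSE] %*% co$right[[i]]
  }
  Y
}

#' Savitzky-Golay smoothing
#'
#' Windowed least-squares polynomial smoothing of a spectrum.  Each channel is
#' replaced by the value at that channel of the degree-`polyorder` polynomial
#' fit over its window; edge channels are fit on the truncated one-sided
#' window, so polynomials up to the fitted degree are reproduced exactly
#' everywhere.
#'
#' @param spectrum An [ssc_spectrum] or plain numeric vector.
#' @param window Odd window length (default 13).
#' @param polyorder Polynomial degree < window (default 2).
#' @return Same type as the input.
#' @export
sg_smooth <- function(spectrum, window = 13L, polyorder = 2L) {
  if (inherits(spectrum, "ssc_spectrum")) {
    out <- spectrum
    out$intensity <- drop(sg_smooth_matrix(matrix(spectrum$intensity, 1L),
                                           as.integer(window),
                                           as.integer(polyorder)))
    out$tags <- c(spectrum$tags, sprintf("SG(%d,%d)", window, polyorder))
    return(out)
  }
  drop(sg_smooth_matrix(matrix(as.numeric(spectrum), 1L),
                        as.integer(window), as.integer(polyorder)))
}

#' Standard normal variate transform
#'
#' Centers a spectrum to mean zero and scales it to unit sample SD
#' (n-1 denominator), removing additive offsets and multiplicative scatter
#' gain.  A constant spectrum has no variance to scale and is rejected.
#'
#' @param spectrum An [ssc_spectrum] or plain numeric vector.
#' @return Same type as the input; mean 0, sample SD 1.
#' @export
snv <- function(spectrum) {
  x <- if (inherits(spectrum, "ssc_spectrum")) spectrum$intensity else
    as.numeric(spectrum)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero-variance spectrum: SNV undefined", call. = FALSE)
  }
  z <- (x - mean(x)) / s
  if (inherits(spectrum, "ssc_spectrum")) {
    out <- spectrum
    out$intensity <- z
    out$tags <- c(spectrum$tags, "SNV")
    return(out)
  }
  z
}

#' Apply one pretreatment to a spectra matrix
#'
#' Row-wise application of the chosen pretreatment; `RAW` is the identity.
#' Rows are independent, so permuting samples commutes with the operation.
#'
#' @param X n x P matrix, one spectrum per row (or an [ssc_dataset], in which
#'   case the pretreated dataset is returned).
#' @param spec [pretreatment_spec].
#' @return Pretreated matrix (or dataset) with unchanged dimensions.
#' @export
apply_pretreatment <- function(X, spec = pretreatment_spec("RAW")) {
  stopifnot(inherits(spec, "pretreatment_spec"))
  if (inherits(X, "ssc_dataset")) {
    out <- X
    out$X <- apply_pretreatment(X$X, spec)
    return(out)
  }
  X <- as.matrix(X)
  switch(spec$method,
    RAW = X,
    SG = sg_smooth_matrix(X, spec$sg_window, spec$sg_polyorder),
    SNV = {
      mu <- rowMeans(X)
      s <- apply(X, 1L, stats::sd)
      bad <- !is.finite(s) | s == 0
      if (any(bad)) {
        ids <- rownames(X)[bad] %||% as.character(which(bad))
        stop(sprintf("zero-variance spectrum in row(s): %s",
                     paste(ids, collapse = ", ")), call. = FALSE)
      }
      (X - mu) / s
    })
}
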