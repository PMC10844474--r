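#' Fit a PLSR model by NIPALS
#'
#' Single-response partial least squares regression.  X and y are centered
#' (columns are not variance-scaled: spectral channels share units); each
#' NIPALS factor takes the weight vector `w` proportional to `X'y`
#' (normalized), scores `t = Xw`, x-loading `p = X't / t't`, y-loading
#' `q = y't / t't`, then deflates `X <- X - t p'` and `y <- y - q t`.  The
#' regression vector is `b = W (P'W)^{-1} q`.
#'
#' @param X n x p predictor matrix.
#' @param y Response vector (degrees Brix).
#' @param n_lv Number of latent variables, at most `min(n - 1, p)`.
#' @return An object of class `plsr_model` with elements `n_lv`, `x_mean`,
#'   `y_mean`, `W`, `P`, `q`, `b` and `scores`.  If the response deflates to
#'   numerical zero before `n_lv` factors, the achieved count is returned with
#'   a warning.
#' @export
fit_plsr <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(y) != n) stop("X rows and y length differ", call. = FALSE)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  if (stats::var(y) == 0) stop("zero-variance response", call. = FALSE)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    stop("n_lv must lie in [1, min(n - 1, p)]", call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  tol <- 1e-12 * max(1, sum(yc^2)) / n
  W <- matrix(0, p, n_lv); Pl <- matrix(0, p, n_lv)
  q <- numeric(n_lv); Tm <- matrix(0, n, n_lv)
  a <- 0L
  Xd <- Xc; yd <- yc
  while (a < n_lv) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < tol) break
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
    a <- a + 1L
    W[, a] <- w; Pl[, a] <- p_; q[a] <- q_; Tm[, a] <- t_
  }
  if (a == 0L) stop("no usable latent variable (X'y vanishes)", call. = FALSE)
  if (a < n_lv) {
    warning(sprintf("rank exhausted after %d latent variables (requested %d)",
                    a, n_lv))
    W <- W[, 1:a, drop = FALSE]; Pl <- Pl[, 1:a, drop = FALSE]
    q <- q[1:a]; Tm <- Tm[, 1:a, drop = FALSE]
  }
  R <- crossprod(Pl, W)              # upper triangular in exact arithmetic
  b <- drop(W %*% solve(R, q))
  structure(list(n_lv = a, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = Pl, q = q, b = b, scores = Tm),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variables, %d channels\n",
              x$n_lv, length(x$b)))
  invisible(x)
}

# Regression vectors for every truncated factor count 1..n_lv (p x n_lv).
# Used by cross-validation: one NIPALS fit yields the whole LV path.
plsr_coef_path <- function(model) {
  A <- model$n_lv
  R <- crossprod(model$P, model$W)
  B <- matrix(0, length(model$b), A)
  for (a in seq_len(A)) {
    B[, a] <- model$W[, 1:a, drop = FALSE] %*%
      solve(R[1:a, 1:a, drop = FALSE], model$q[1:a])
  }
  B
}

#' Predict SSC from a fitted PLSR model
#'
#' `y_hat = (X_new - x_mean) b + y_mean`.
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix (or vector for a single sample) with the model's
#'   channel count.
#' @param ... Ignored.
#' @return Numeric vector of predictions in degrees Brix.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) {
    stop("newdata channel count does not match the model", call. = FALSE)
  }
  drop(sweep(newdata, 2L, object$x_mean) %*% object$b) + object$y_mean
}

#' Model evaluation metrics
#'
#' The calibration/prediction goodness-of-fit `R` and root-mean-square error
#' used throughout the study grid:
#' `R = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)` (the printed
#' coefficient-of-determination form, mode `"paper"`), or its square root
#' clipped at zero (mode `"sqrt"`); `RMSE = sqrt(mean((y - y_hat)^2))` in
#' degrees Brix.  The reference mean is taken over the evaluated set itself.
#'
#' @param y Measured values.
#' @param y_hat Predicted values.
#' @param mode `"paper"` (default) or `"sqrt"`; results quoted against
#'   study-style numbers must state the mode.
#' @return An object of class `eval_metrics`: list with `R`, `RMSE`, `n`,
#'   `mode`.
#' @export
compute_metrics <- function(y, y_hat, mode = c("paper", "sqrt")) {
  mode <- match.arg(mode)
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance response", call. = FALSE)
  ss_res <- sum((y - y_hat)^2)
  R <- 1 - ss_res / ss_tot
  if (mode == "sqrt") R <- sqrt(max(R, 0))
  structure(list(R = R, RMSE = sqrt(ss_res / n), n = n, mode = mode),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("R = %.4f, RMSE = %.4f Brix (n = %d, mode = %s)\n",
              x$R, x$RMSE, x$n, x$mode))
  invisible(x)
}

# Seeded k-fold assignment with fold sizes differing by at most one.
make_folds <- function(n, k, seed = NULL) {
  idx <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[idx] <- rep(seq_len(k), length.out = n)
  fold
}

#' Choose the latent-variable count by 5-fold cross-validation
#'
#' Samples are partitioned into `k_folds` seeded random folds (sizes differing
#' by at most one); for each candidate LV count the pooled out-of-fold
#' predictions give an RMSECV, and the count minimizing RMSECV is returned
#' (ties broken toward the smaller count).
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param max_lv Largest candidate LV count (default 20; capped with a
#'   warning if it exceeds the per-fold training rank).
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with `n_lv` (chosen count), `rmsecv` (RMSECV per candidate
#'   count), `max_lv` (effective cap) and `folds`.
#' @export
select_lvs_cv <- function(X, y, max_lv = 20L, k_folds = 5L, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < k_folds) stop("need at least k_folds samples", call. = FALSE)
  if (max_lv < 1L) stop("max_lv must be at least 1", call. = FALSE)
  fold <- make_folds(n, k_folds, seed)
  min_train <- min(vapply(seq_len(k_folds), function(f) sum(fold != f),
                          integer(1)))
  cap <- min(max_lv, ncol(X), min_train - 1L)
  if (cap < max_lv) {
    warning(sprintf("max_lv capped at %d by the per-fold training size", cap))
  }
  if (cap < 1L) stop("folds too small for even one latent variable", call. = FALSE)
  pred <- matrix(NA_real_, n, cap)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    m <- suppressWarnings(fit_plsr(X[tr, , drop = FALSE], y[tr],
                                   min(cap, sum(tr) - 1L)))
    B <- plsr_coef_path(m)
    Xc <- sweep(X[!tr, , drop = FALSE], 2L, m$x_mean)
    ph <- Xc %*% B + m$y_mean
    pred[!tr, seq_len(ncol(B))] <- ph
    if (ncol(B) < cap) {              # rank exhausted: reuse the deepest fit
      pred[!tr, (ncol(B) + 1L):cap] <- ph[, ncol(B)]
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  # ties (within numerical dust) break toward the smaller count
  thresh <- min(rmsecv) * (1 + 1e-10) + 1e-12
  list(n_lv = which(rmsecv <= thresh)[1L], rmsecv = rmsecv, max_lv = cap,
       folds = fold)
}
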