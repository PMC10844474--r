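#' Standardize predictors for a regression path
#'
#' Path algorithms compare correlations across columns, so candidate channels
#' are centered and scaled to unit sample SD and the response is centered.
#' Zero-variance columns cannot be scaled; they are excluded with a warning
#' that names their wavelengths (or indices).
#'
#' @param X n x p predictor matrix.
#' @param y Response vector.
#' @param wavelengths Optional wavelengths (nm) used to name excluded columns.
#' @return List with `Xs`, `ys`, `x_center`, `x_scale`, `y_center`, and
#'   `keep` (indices of retained columns in the original matrix).
#' @export
standardize_for_path <- function(X, y, wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  keep <- which(is.finite(sc) & sc > 0)
  if (length(keep) == 0L) stop("all columns have zero variance", call. = FALSE)
  if (length(keep) < ncol(X)) {
    dropped <- setdiff(seq_len(ncol(X)), keep)
    lab <- if (!is.null(wavelengths)) {
      sprintf("%.4g nm", wavelengths[dropped])
    } else as.character(dropped)
    warning(sprintf("excluding %d zero-variance column(s): %s",
                    length(dropped), paste(lab, collapse = ", ")))
  }
  Xs <- sweep(X[, keep, drop = FALSE], 2L, ctr[keep])
  Xs <- sweep(Xs, 2L, sc[keep], `/`)
  list(Xs = Xs, ys = y - mean(y), x_center = ctr[keep], x_scale = sc[keep],
       y_center = mean(y), keep = keep)
}

# Lasso-modified LARS.  With lambda2 > 0 the path is computed on the
# implicitly ridge-augmented design rbind(X, sqrt(n*lambda2) I), y' = c(y, 0),
# without materializing the p extra rows: the augmentation only adds
# n*lambda2 to the active Gram and -n*lambda2*b to the correlations.
# Knot penalties are max|correlation| / n_rows of the (augmented) design.
lars_core <- function(X, y, lambda2 = 0, max_steps = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite inputs to the LARS path", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  mu <- n * lambda2
  nr <- n + (lambda2 > 0) * p
  if (is.null(max_steps)) max_steps <- 8L * min(nr, p) + 10L
  b <- numeric(p)
  act <- integer(0)
  in_act <- logical(p)
  G <- matrix(0, 0L, 0L)               # active Gram, maintained incrementally
  saturated <- FALSE
  c0 <- drop(crossprod(X, y))
  Cmax0 <- max(abs(c0))
  lam <- Cmax0 / nr
  knots_lambda <- lam
  knots_beta <- list(b)
  knots_active <- list(integer(0))
  tol <- 1e-12 * max(Cmax0, 1)
  step <- 0L
  add_var <- function(j) {
    xj <- X[, j]
    gcol <- drop(crossprod(X[, act, drop = FALSE], xj))
    gjj <- sum(xj * xj) + mu
    G <<- rbind(cbind(G, gcol), c(gcol, gjj))
    act <<- c(act, j)
    in_act[j] <<- TRUE
  }
  repeat {
    r <- if (length(act) > 0L) {
      y - drop(X[, act, drop = FALSE] %*% b[act])
    } else y
    cvec <- drop(crossprod(X, r))
    if (mu > 0) cvec <- cvec - mu * b
    acvec <- abs(cvec)
    C <- max(acvec)
    if (C <= tol || step >= max_steps) break
    if (length(act) == 0L) {
      for (j in which(acvec >= C * (1 - 1e-12))) add_var(j)
    }
    sA <- sign(cvec[act])
    GA1 <- tryCatch(solve(G, sA), error = function(e) NULL)
    if (is.null(GA1) || sum(sA * GA1) <= 0) {
      # active set reached the design rank: the path cannot advance further;
      # knots recorded so far are exact, so end quietly and mark saturation
      saturated <- TRUE
      break
    }
    AA <- 1 / sqrt(sum(sA * GA1))
    w <- AA * GA1
    u1 <- drop(X[, act, drop = FALSE] %*% w)
    avec <- drop(crossprod(X, u1))
    if (mu > 0) avec[act] <- avec[act] + mu * w
    gamma_entry <- Inf; j_entry <- NA_integer_
    if (length(act) < p) {
      g1 <- (C - cvec) / (AA - avec)
      g2 <- (C + cvec) / (AA + avec)
      g1[g1 <= tol | in_act] <- Inf
      g2[g2 <= tol | in_act] <- Inf
      cand <- pmin(g1, g2)
      gamma_entry <- min(cand)
      if (is.finite(gamma_entry)) {
        j_entry <- which(cand <= gamma_entry * (1 + 1e-12))[1L]  # lowest index
      }
    }
    gd <- -b[act] / w
    gd[!(gd > tol)] <- Inf
    gamma_drop <- min(gd)
    k_drop <- if (is.finite(gamma_drop)) which.min(gd) else NA_integer_
    gamma_max <- C / AA
    gamma <- min(gamma_entry, gamma_drop, gamma_max)
    b[act] <- b[act] + gamma * w
    if (gamma == gamma_drop && gamma < gamma_max) {
      b[act[k_drop]] <- 0
      in_act[act[k_drop]] <- FALSE
      act <- act[-k_drop]
      G <- G[-k_drop, -k_drop, drop = FALSE]
    } else if (gamma == gamma_entry && gamma < gamma_max) {
      add_var(j_entry)
    }
    step <- step + 1L
    lam_new <- max((C - gamma * AA) / nr, 0)
    k <- length(knots_lambda)
    if (lam_new >= knots_lambda[k] - 1e-15 * max(1, knots_lambda[k])) {
      knots_lambda[k] <- lam_new       # zero-length move: overwrite the knot
      knots_beta[[k]] <- b
      knots_active[[k]] <- sort(act)
    } else {
      knots_lambda <- c(knots_lambda, lam_new)
      knots_beta <- c(knots_beta, list(b))
      knots_active <- c(knots_active, list(sort(act)))
    }
    if (gamma == gamma_max) break
  }
  structure(list(lambda = knots_lambda,
                 beta = matrix(unlist(knots_beta), nrow = p),
                 active = knots_active,
                 n_rows = nr, p = p, lambda2 = lambda2,
                 n_steps = step, saturated = saturated),
            class = "lars_path")
}

#' LARS path with the lasso modification
#'
#' Traces the full L1 (lasso) regularization path by least angle regression:
#' starting from all-zero coefficients, the variable most correlated with the
#' residual enters the active set, coefficients advance along the
#' equiangular direction until another variable's correlation catches up
#' (entry) or an active coefficient crosses zero (drop), and each event is
#' recorded as a path knot.  Solutions are piecewise linear in the penalty
#' `lambda = max|X'(y - Xb)| / n`, scaled for the objective
#' `(1/(2n)) ||y - Xb||^2 + lambda ||b||_1`.
#'
#' @param X Predictor matrix, typically from [standardize_for_path()].
#' @param y (Centered) response vector.
#' @param max_steps Optional cap on path steps.
#' @return An object of class `lars_path`: knot penalties `lambda` (strictly
#'   decreasing from `lambda_max` where the active set is empty), the p x K
#'   coefficient matrix `beta`, and the active set at each knot.
#' @export
lars_path_l1 <- function(X, y, max_steps = NULL) {
  lars_core(X, y, lambda2 = 0, max_steps = max_steps)
}

#' @export
print.lars_path <- function(x, ...) {
  cat(sprintf("<lars_path> %d knots, lambda %.4g .. %.4g, %d predictors%s\n",
              length(x$lambda), x$lambda[1], x$lambda[length(x$lambda)], x$p,
              if (x$lambda2 > 0) sprintf(" (ridge lambda2 = %g)", x$lambda2)
              else ""))
  invisible(x)
}

#' Coefficients at an arbitrary penalty value
#'
#' Lasso solutions are piecewise linear in the penalty, so the coefficient
#' vector at any `lambda` is the linear interpolation between the bracketing
#' path knots; above `lambda_max` the solution is zero, at `lambda = 0` it is
#' the path endpoint (the least-squares fit when reachable).
#'
#' @param path A `lars_path`.
#' @param lambda Non-negative penalty value.
#' @return Coefficient vector on the path's (standardized) scale.
#' @export
solution_at_lambda <- function(path, lambda) {
  stopifnot(inherits(path, "lars_path"), is_number(lambda), lambda >= 0)
  lam <- path$lambda
  if (lambda >= lam[1]) return(numeric(path$p))
  K <- length(lam)
  if (lambda <= lam[K]) return(path$beta[, K])
  i <- findInterval(-lambda, -lam)   # lam is decreasing
  t <- (lam[i] - lambda) / (lam[i] - lam[i + 1])
  (1 - t) * path$beta[, i] + t * path$beta[, i + 1]
}

#' Ridge augmentation of a design matrix
#'
#' Elastic-net-style augmentation `X' = rbind(X, sqrt(lambda * n) I_p)`,
#' `y' = c(y, 0_p)`: the least-squares fit on `(X', y')` -- the `lambda = 0`
#' end of a LARS path run on the augmented design -- equals ridge regression
#' with penalty `lambda`, i.e. `(X'X + n lambda I)^{-1} X'y`.
#'
#' @param Xs Standardized predictor matrix.
#' @param ys Centered response.
#' @param lambda Positive ridge penalty.
#' @return List with the augmented `X` and `y`.
#' @export
lars_l2_augment <- function(Xs, ys, lambda) {
  Xs <- as.matrix(Xs)
  if (!is_number(lambda) || lambda <= 0) {
    stop("ridge lambda must be positive", call. = FALSE)
  }
  n <- nrow(Xs); p <- ncol(Xs)
  list(X = rbind(Xs, sqrt(lambda * n) * diag(p)),
       y = c(as.numeric(ys), numeric(p)))
}

#' Lasso stationarity (KKT) violation
#'
#' For the objective `(1/(2n)) ||y - Xb||^2 + lambda ||b||_1` (plus an
#' optional ridge term realized by augmentation), the gradient
#' `g = X'(y - Xb)/n` must equal `lambda * sign(b_j)` on the active set and
#' satisfy `|g_j| <= lambda` elsewhere.  Returns the largest violation of
#' either condition; a correct solution gives a value at numerical zero.
#'
#' @param Xs,ys The (standardized) design and centered response.
#' @param beta Coefficient vector to certify.
#' @param lambda Penalty value.
#' @return Non-negative scalar, the maximum KKT violation.
#' @export
check_kkt <- function(Xs, ys, beta, lambda) {
  Xs <- as.matrix(Xs)
  n <- nrow(Xs)
  g <- drop(crossprod(Xs, ys - Xs %*% beta)) / n
  act <- beta != 0
  v_act <- if (any(act)) max(abs(g[act] - lambda * sign(beta[act]))) else 0
  v_in <- if (any(!act)) max(pmax(abs(g[!act]) - lambda, 0)) else 0
  max(v_act, v_in)
}

#' Select characteristic wavelengths by LARS
#'
#' Under the L1 penalty, the active set is read off the lasso path at the
#' requested `lambda`.  Under the L2 penalty -- which on its own never zeroes
#' a coefficient -- the path is traced on the ridge-augmented design
#' (see [lars_l2_augment()]) and the selection is the active set of the path
#' knot whose PLSR refit minimizes 5-fold cross-validated RMSE; this
#' augmentation-with-CV-stop rule is this package's interpretation of
#' "LARS-L2" selection and is documented in the methods vignette.
#'
#' @param X n x p predictor matrix (pretreated intensities).
#' @param y SSC response vector.
#' @param lambda Penalty value (L1: position on the lasso path; L2: ridge
#'   weight of the augmentation).
#' @param penalty `"L1"` or `"L2"`.
#' @param cv_seed Seed for the L2 knot-selection folds.
#' @param wavelengths Optional wavelengths (nm) reported alongside channels.
#' @param max_steps Optional cap on path steps (L2 paths are capped at
#'   `3 * n` steps by default to bound the augmented path length).
#' @param max_knots Largest number of candidate knots scored by CV (L2).
#' @return An object of class `selection_result`: `lambda`, `penalty`,
#'   `channel` (1-based column indices), `wavelength` (nm, when supplied),
#'   `coefficients` (original scale), `n_selected`.
#' @export
select_wavelengths <- function(X, y, lambda, penalty = c("L1", "L2"),
                               cv_seed = 1L, wavelengths = NULL,
                               max_steps = NULL, max_knots = 25L) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X); y <- as.numeric(y)
  std <- standardize_for_path(X, y, wavelengths)
  if (penalty == "L1") {
    path <- lars_core(std$Xs, std$ys, lambda2 = 0, max_steps = max_steps)
    beta_s <- solution_at_lambda(path, lambda)
    act <- which(beta_s != 0)
    if (length(act) == 0L) {
      stop(sprintf(paste0("empty selection: lambda = %g is at or above ",
                          "lambda_max = %g; use a smaller lambda"),
                   lambda, path$lambda[1]), call. = FALSE)
    }
  } else {
    if (lambda <= 0) stop("L2 penalty requires lambda > 0", call. = FALSE)
    n <- nrow(X)
    path <- lars_core(std$Xs, std$ys, lambda2 = lambda,
                      max_steps = max_steps %||% (3L * n))
    sizes <- lengths(path$active)
    cand <- which(sizes > 0L)
    if (length(cand) == 0L) {
      stop("empty selection: the augmented path produced no active set",
           call. = FALSE)
    }
    if (length(cand) > max_knots) {
      cand <- cand[unique(round(seq(1L, length(cand), length.out = max_knots)))]
    }
    fold <- make_folds(n, 5L, cv_seed)
    score <- vapply(cand, function(k) {
      cols <- std$keep[path$active[[k]]]
      err <- numeric(0)
      for (f in unique(fold)) {
        tr <- fold != f
        nlv <- min(10L, length(cols), sum(tr) - 1L)
        m <- suppressWarnings(fit_plsr(X[tr, cols, drop = FALSE], y[tr], nlv))
        err <- c(err, (stats::predict(m, X[!tr, cols, drop = FALSE]) - y[!tr])^2)
      }
      sqrt(mean(err))
    }, numeric(1))
    k_best <- cand[which.min(score)]
    beta_s <- path$beta[, k_best]
    act <- path$active[[k_best]]
    beta_s[setdiff(seq_len(path$p), act)] <- 0
  }
  channel <- std$keep[act]
  coefs <- beta_s[act] / std$x_scale[act]
  structure(list(lambda = lambda, penalty = penalty, channel = channel,
                 wavelength = if (!is.null(wavelengths)) wavelengths[channel],
                 coefficients = coefs, n_selected = length(channel)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s, lambda = %g: %d wavelengths selected\n",
              x$penalty, x$lambda, x$n_selected))
  invisible(x)
}

#' Choose the L1 penalty by cross-validation
#'
#' Builds a geometric `lambda` grid below the full-data `lambda_max` and
#' scores each value by 5-fold cross-validated RMSE of the lasso solution
#' itself (path computed per training fold, coefficients interpolated at each
#' grid value).  Ties break toward the larger (sparser) penalty.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param k_folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param n_lambda Grid size (default 30).
#' @param lambda_min_ratio Smallest grid value relative to `lambda_max`.
#' @return List with `lambda` (the choice), `grid` and `rmsecv`.
#' @export
select_lambda_cv <- function(X, y, k_folds = 5L, seed = NULL,
                             n_lambda = 30L, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  std <- standardize_for_path(X, y)
  lam_max <- max(abs(crossprod(std$Xs, std$ys))) / n
  grid <- exp(seq(log(lam_max * 0.999), log(lam_max * lambda_min_ratio),
                  length.out = n_lambda))
  fold <- make_folds(n, k_folds, seed)
  se <- matrix(NA_real_, n, length(grid))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    stdf <- suppressWarnings(standardize_for_path(X[tr, , drop = FALSE], y[tr]))
    path <- lars_core(stdf$Xs, stdf$ys)
    Xte <- X[!tr, stdf$keep, drop = FALSE]
    for (g in seq_along(grid)) {
      bs <- solution_at_lambda(path, grid[g])
      pr <- drop(sweep(Xte, 2L, stdf$x_center) %*% (bs / stdf$x_scale)) +
        stdf$y_center
      se[!tr, g] <- (pr - y[!tr])^2
    }
  }
  rmsecv <- sqrt(colMeans(se))
  best <- which(rmsecv <= min(rmsecv) + 1e-15)[1L]   # grid descends: sparsest
  list(lambda = grid[best], grid = grid, rmsecv = rmsecv)
}

#' Scan a penalty grid and report prediction performance
#'
#' For each `lambda` in the (deduplicated, order-preserving) grid: select
#' wavelengths on the calibration set, refit a PLSR model with a CV-chosen
#' latent-variable count on the selected channels, and evaluate on the
#' prediction set.  Penalty values yielding an empty selection are flagged
#' rather than dropped.
#'
#' @param X_cal,y_cal Calibration set.
#' @param X_pred,y_pred Prediction set.
#' @param lambdas Penalty grid (ascending or any order; duplicates removed).
#' @param penalty `"L1"` or `"L2"`.
#' @param cv_seed Seed for the internal cross-validations.
#' @param max_lv Cap for the latent-variable search.
#' @param wavelengths Optional wavelengths (nm).
#' @return Data frame with columns `lambda`, `n_selected`, `Rp`, `RMSEP`,
#'   `empty`.
#' @export
scan_lambda <- function(X_cal, y_cal, X_pred, y_pred, lambdas,
                        penalty = c("L1", "L2"), cv_seed = 1L, max_lv = 20L,
                        wavelengths = NULL) {
  penalty <- match.arg(penalty)
  lambdas <- lambdas[!duplicated(lambdas)]
  if (length(lambdas) == 0L) stop("empty lambda grid", call. = FALSE)
  rows <- lapply(lambdas, function(lam) {
    sel <- tryCatch(
      select_wavelengths(X_cal, y_cal, lam, penalty, cv_seed = cv_seed,
                         wavelengths = wavelengths),
      error = function(e) e)
    if (inherits(sel, "error")) {
      return(data.frame(lambda = lam, n_selected = 0L, Rp = NA_real_,
                        RMSEP = NA_real_, empty = TRUE))
    }
    cols <- sel$channel
    lv <- select_lvs_cv(X_cal[, cols, drop = FALSE], y_cal,
                        max_lv = min(max_lv, length(cols)),
                        seed = cv_seed)
    m <- fit_plsr(X_cal[, cols, drop = FALSE], y_cal, lv$n_lv)
    met <- compute_metrics(y_pred, stats::predict(m, X_pred[, cols, drop = FALSE]))
    data.frame(lambda = lam, n_selected = sel$n_selected, Rp = met$R,
               RMSEP = met$RMSE, empty = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(out$empty)) {
    warning("every lambda in the grid produced an empty selection")
  }
  out
}
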