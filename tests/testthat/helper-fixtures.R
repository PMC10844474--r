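# Shared fixtures, built in code.  Small wavelength grids keep module tests
# fast; the acceptance suite uses the full 2047-channel default world.

tiny_grid <- function(P = 64L) default_grid(P)

# A config on a reduced grid with bands wide enough to be resolved there.
tiny_config <- function(P = 64L, ...) {
  sim_config(grid = tiny_grid(P),
             ssc_bands = data.frame(center = c(700, 850, 980),
                                    width = c(20, 25, 22),
                                    absorptivity = c(0.05, 0.06, 0.05)),
             interferent_bands = data.frame(center = c(640, 1030),
                                            width = c(25, 20),
                                            absorptivity = c(0.15, 0.12)),
             ...)
}

# Deterministic forward-model config: every nuisance off, ends untouched.
exact_config <- function(P = 64L) noiseless_config(tiny_config(P))

tiny_profile <- function(n = 12L, kmin = 5L, kmax = 9L) {
  variety_profile("Tiny", 3.8, 8.7, 5.8, 1.1, n, kmin, kmax)
}

flat_background <- function(grid, level = 0, noise_sd = 1) {
  background_spectrum(rep(level, length(grid)), noise_sd, grid)
}

# Random regression instance for path/PLSR oracle tests.
linear_instance <- function(n, p, k = 4L, noise = 1, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b <- numeric(p)
  b[seq_len(k)] <- c(3, -2, 1.5, 1)[seq_len(k)]
  y <- drop(X %*% b) + noise * rnorm(n)
  list(X = X, y = y, b = b)
}

# Coordinate-descent lasso oracle (glmnet), matched to this package's
# objective (1/(2n))||y - Xb||^2 + lambda||b||_1 on pre-standardized data.
cd_lasso_oracle <- function(Xs, ys, lambdas) {
  lam_max <- max(abs(crossprod(Xs, ys))) / nrow(Xs)
  seq_lam <- sort(unique(c(lambdas, lam_max * exp(seq(0, -8, by = -0.05)))),
                  decreasing = TRUE)
  fit <- glmnet::glmnet(Xs, ys, lambda = seq_lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-20, maxit = 1e8)
  vapply(lambdas, function(l) {
    suppressWarnings(
      as.numeric(glmnet::coef.glmnet(fit, s = l, exact = TRUE, x = Xs, y = ys,
                                     thresh = 1e-20, maxit = 1e8))[-1L])
  }, numeric(ncol(Xs)))
}
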