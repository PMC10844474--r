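test_that("standardize_for_path scales, preserves, and excludes", {
  set.seed(20)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Xs0 <- scale(X)                     # already standardized input
  std <- standardize_for_path(Xs0, rnorm(40))
  expect_equal(unname(std$Xs), unname(Xs0[, ]), tolerance = 1e-12)

  # scale equivariance: rescaling a column leaves active sets unchanged
  y <- drop(X %*% c(2, -1, 0, 0, 1, 0)) + rnorm(40, sd = 0.2)
  s1 <- standardize_for_path(X, y)
  X2 <- X; X2[, 3] <- X2[, 3] * 10
  s2 <- standardize_for_path(X2, y)
  p1 <- lars_path_l1(s1$Xs, s1$ys)
  p2 <- lars_path_l1(s2$Xs, s2$ys)
  for (i in c(2, 4, 6)) {             # between-knot points: stable supports
    lam <- (p1$lambda[i] + p1$lambda[i + 1]) / 2
    expect_identical(which(solution_at_lambda(p1, lam) != 0),
                     which(solution_at_lambda(p2, lam) != 0))
  }

  # constant column excluded with its wavelength named
  Xc <- cbind(X, 7)
  expect_warning(s3 <- standardize_for_path(Xc, y,
                                            wavelengths = c(601:606, 999)),
                 "999")
  expect_identical(s3$keep, 1:6)
  expect_error(standardize_for_path(matrix(1, 10, 3), rnorm(10)),
               "zero variance")
})

test_that("orthonormal designs reduce the path to soft-thresholding", {
  set.seed(21)
  n <- 8L
  Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  y <- rnorm(n, sd = 2)
  z <- drop(crossprod(Q, y))          # univariate LS coefficients
  path <- lars_path_l1(Q, y)
  expect_identical(path$active[[1]], integer(0))
  expect_equal(path$lambda[1], max(abs(z)) / n)
  for (lam in c(path$lambda[1] * c(1.5, 1), max(abs(z)) / n * c(0.7, 0.3, 0.1, 0.01))) {
    soft <- sign(z) * pmax(abs(z) - n * lam, 0)
    expect_equal(solution_at_lambda(path, lam), soft, tolerance = 1e-8)
  }
  # sparsity monotone in lambda on orthogonal designs
  sizes <- vapply(seq(path$lambda[1], 0, length.out = 20),
                  function(l) sum(solution_at_lambda(path, l) != 0), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("path matches the coordinate-descent oracle on random instances", {
  skip_if_not_installed("glmnet")
  for (s in 1:10) {
    inst <- linear_instance(30, 60, noise = 1, seed = 200 + s)
    std <- standardize_for_path(inst$X, inst$y)
    path <- lars_path_l1(std$Xs, std$ys)
    lams <- path$lambda[1] * c(0.6, 0.3, 0.15, 0.07, 0.02)
    ref <- cd_lasso_oracle(std$Xs, std$ys, lams)
    for (j in seq_along(lams)) {
      mine <- solution_at_lambda(path, lams[j])
      expect_lt(max(abs(mine - ref[, j])), 1e-6)
      expect_lt(check_kkt(std$Xs, std$ys, mine, lams[j]), 1e-6)
    }
  }
})

test_that("solution_at_lambda interpolates exactly along the path", {
  inst <- linear_instance(30, 10, noise = 0.5, seed = 31)
  std <- standardize_for_path(inst$X, inst$y)
  path <- lars_path_l1(std$Xs, std$ys)
  K <- length(path$lambda)
  # at a knot: that knot's coefficients
  expect_identical(solution_at_lambda(path, path$lambda[3]), path$beta[, 3])
  # above lambda_max: zeros
  expect_identical(solution_at_lambda(path, path$lambda[1] * 2),
                   numeric(path$p))
  # midway between knots: piecewise-linear point certified by KKT
  for (i in c(2, 4, K - 1)) {
    lam_mid <- (path$lambda[i] + path$lambda[i + 1]) / 2
    bmid <- solution_at_lambda(path, lam_mid)
    expect_equal(bmid, (path$beta[, i] + path$beta[, i + 1]) / 2,
                 tolerance = 1e-9)
    expect_lt(check_kkt(std$Xs, std$ys, bmid, lam_mid), 1e-8)
  }
  # lambda = 0 on a full-rank design: the least-squares solution
  b0 <- solution_at_lambda(path, 0)
  bls <- drop(solve(crossprod(std$Xs), crossprod(std$Xs, std$ys)))
  expect_equal(b0, bls, tolerance = 1e-6)
  # knot penalties strictly decrease
  expect_true(all(diff(path$lambda) < 0))
})

test_that("ridge augmentation reaches the closed-form ridge solution", {
  inst <- linear_instance(20, 10, noise = 0.5, seed = 41)
  std <- standardize_for_path(inst$X, inst$y)
  n <- 20L; p <- 10L
  for (lam in c(0.05, 0.3, 2)) {
    aug <- lars_l2_augment(std$Xs, std$ys, lam)
    expect_identical(dim(aug$X), c(n + p, p))        # p extra rows
    expect_identical(aug$y[(n + 1):(n + p)], numeric(p))
    path <- lars_path_l1(aug$X, aug$y)
    endp <- path$beta[, length(path$lambda)]
    ridge <- drop(solve(crossprod(std$Xs) + n * lam * diag(p),
                        crossprod(std$Xs, std$ys)))
    expect_lt(max(abs(endp - ridge)), 1e-6)
  }
  # infinite-penalty limit
  aug <- lars_l2_augment(std$Xs, std$ys, 1e8)
  pb <- lars_path_l1(aug$X, aug$y)
  expect_lt(max(abs(pb$beta[, length(pb$lambda)])), 1e-6)
  expect_error(lars_l2_augment(std$Xs, std$ys, 0), "positive")

  # the implicit augmented path equals the explicit one
  aug2 <- lars_l2_augment(std$Xs, std$ys, 0.3)
  pe <- lars_path_l1(aug2$X, aug2$y)
  pim <- brixnir:::lars_core(std$Xs, std$ys, lambda2 = 0.3)
  expect_equal(pe$lambda, pim$lambda, tolerance = 1e-9)
  expect_equal(pe$beta, pim$beta, tolerance = 1e-8)
})

test_that("select_wavelengths recovers sparse truth and reports errors", {
  set.seed(51)
  n <- 60; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, c(5, 20, 35)] %*% c(2, -2, 1.5)) + rnorm(n, sd = 0.5)
  lam <- select_lambda_cv(X, y, seed = 3)$lambda
  sel <- select_wavelengths(X, y, lam, "L1", wavelengths = 560 + seq_len(p))
  expect_true(all(c(5, 20, 35) %in% sel$channel))
  expect_identical(sel$n_selected, length(sel$channel))
  expect_identical(sel$wavelength, 560 + sel$channel)
  expect_lte(sel$n_selected, n)

  std <- standardize_for_path(X, y)
  lam_max <- max(abs(crossprod(std$Xs, std$ys))) / n
  expect_error(select_wavelengths(X, y, lam_max * 1.01, "L1"), "empty")

  # L2 route returns a non-trivial active set with original-scale coefficients
  sel2 <- select_wavelengths(X, y, 0.1, "L2", cv_seed = 3)
  expect_true(all(c(5, 20, 35) %in% sel2$channel))
  expect_gt(sel2$n_selected, 0L)

  # pure-noise response: path cardinality stays within the sample limit
  yn <- rnorm(n)
  lamn <- select_lambda_cv(X, yn, seed = 4)$lambda
  seln <- tryCatch(select_wavelengths(X, yn, lamn, "L1"),
                   error = function(e) NULL)
  if (!is.null(seln)) expect_lte(seln$n_selected, n)
})

test_that("scan_lambda tabulates the penalty grid faithfully", {
  set.seed(61)
  n <- 50; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, c(3, 17)] %*% c(2, -1.5)) + rnorm(n, sd = 0.4)
  cal <- 1:35; prd <- 36:50
  std <- standardize_for_path(X[cal, ], y[cal])
  lam_max <- max(abs(crossprod(std$Xs, std$ys))) / length(cal)
  tab <- scan_lambda(X[cal, ], y[cal], X[prd, ], y[prd],
                     lam_max * c(0.5, 0.2, 0.2, 0.05), "L1", cv_seed = 2)
  expect_identical(nrow(tab), 3L)                   # duplicate removed
  expect_identical(tab$lambda, lam_max * c(0.5, 0.2, 0.05))
  expect_true(all(!tab$empty))
  expect_true(all(is.finite(tab$Rp)))

  expect_warning(tab2 <- scan_lambda(X[cal, ], y[cal], X[prd, ], y[prd],
                                     lam_max * 1.5, "L1", cv_seed = 2),
                 "empty")
  expect_identical(nrow(tab2), 1L)
  expect_true(tab2$empty)
})

test_that("KKT certification holds along whole seeded paths", {
  for (s in 1:5) {
    inst <- linear_instance(25, 40, noise = 1, seed = 300 + s)
    std <- standardize_for_path(inst$X, inst$y)
    path <- lars_path_l1(std$Xs, std$ys)
    probe <- quantile(path$lambda, c(0.15, 0.4, 0.75), names = FALSE)
    for (lam in probe) {
      expect_lt(check_kkt(std$Xs, std$ys, solution_at_lambda(path, lam), lam),
                1e-8)
    }
  }
})
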