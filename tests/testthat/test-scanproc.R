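grid5 <- wavelength_grid(seq(560, 600, length.out = 5L))

test_that("trim_end_scans removes attenuated end runs only", {
  base <- matrix(100, 5, 5)
  pts <- base
  pts[1, ] <- pts[5, ] <- 10          # ends at 10% of median total
  scan <- multipoint_scan(pts, grid5, "s1")
  tr <- trim_end_scans(scan, rel_threshold = 0.5)
  expect_identical(nrow(tr$points), 3L)
  expect_equal(tr$points, base[2:4, ])

  # uniform scan untouched
  un <- multipoint_scan(base, grid5, "s2")
  expect_equal(trim_end_scans(un)$points, base)

  # interior dips are never removed
  dip <- base
  dip[3, ] <- 1
  expect_identical(nrow(trim_end_scans(multipoint_scan(dip, grid5))$points), 5L)

  # all points below threshold -> degenerate error naming the sample
  alllow <- multipoint_scan(matrix(1, 3, 5), grid5, sample_id = "badscan")
  expect_error(trim_end_scans(alllow, rel_threshold = 2), "badscan")
})

test_that("trim matches the generator's end attenuation exactly", {
  prof <- tiny_profile()
  cfg <- tiny_config(noise_sd = 0, noise_structured_sd = 0,
                     background_noise_sd = 0, saturation_prob = 0,
                     end_attenuation = 0.1)
  scan <- generate_scan(6, "O1", prof, cfg, seed = 3)
  k0 <- nrow(scan$points)
  tr <- trim_end_scans(scan)
  expect_identical(nrow(tr$points), k0 - 2L)
  # verify against the rule by direct totals
  tot <- rowSums(scan$points)
  expect_identical(which(tot >= 0.5 * median(tot)), 2:(k0 - 1L))
})

test_that("flag_saturated uses a strict fraction threshold", {
  pts <- matrix(50, 4, 5)
  scan <- multipoint_scan(pts, grid5, saturation_level = 100)
  expect_true(all(flag_saturated(scan)))

  pts2 <- pts; pts2[2, ] <- 100       # fully clipped point
  scan2 <- multipoint_scan(pts2, grid5, saturation_level = 100)
  expect_identical(flag_saturated(scan2, max_frac = 0.01),
                   c(TRUE, FALSE, TRUE, TRUE))

  # exactly max_frac of channels at the cap -> retained (strict inequality)
  pts3 <- pts; pts3[3, 1] <- 100      # 1 of 5 channels = 0.2
  scan3 <- multipoint_scan(pts3, grid5, saturation_level = 100)
  expect_true(all(flag_saturated(scan3, max_frac = 0.2)))
  expect_false(all(flag_saturated(scan3, max_frac = 0.19)))
})

test_that("estimate_snr implements mean net signal over background noise", {
  bg <- background_spectrum(rep(10, 5), noise_sd = 5, grid5)
  expect_equal(estimate_snr(rep(10, 5), bg), 0)
  expect_equal(estimate_snr(rep(60, 5), bg), 10)   # net 50 / noise 5
  # random fixture vs direct one-line evaluation
  set.seed(7)
  for (i in 1:10) {
    pt <- runif(5, 0, 100)
    expect_equal(estimate_snr(pt, bg),
                 mean(pmax(pt - bg$intensity, 0)) / max(bg$noise_sd, 1e-12))
  }
  # noiseless background guarded by epsilon, still finite ordering
  bg0 <- background_spectrum(rep(0, 5), noise_sd = 0, grid5)
  expect_true(is.finite(estimate_snr(rep(1, 5), bg0)))
  expect_error(estimate_snr(rep(1, 4), bg), "length")
})

test_that("compute_weights is proportional, normalized and monotone", {
  expect_equal(compute_weights(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(compute_weights(c(1, 3)), c(0.25, 0.75))
  expect_equal(compute_weights(c(5, 5, 5), c(TRUE, FALSE, TRUE)),
               c(0.5, 0, 0.5))
  expect_warning(w0 <- compute_weights(c(0, 0), c(TRUE, TRUE)), "uniform")
  expect_equal(w0, c(0.5, 0.5))
  expect_error(compute_weights(c(1, 2), c(FALSE, FALSE)), "retained")
  # monotonicity: raising one SNR never lowers its weight
  set.seed(1)
  for (i in 1:20) {
    s <- runif(6, 0.1, 10)
    j <- sample(6, 1)
    w1 <- compute_weights(s)
    s2 <- s; s2[j] <- s2[j] * 1.5
    expect_gte(compute_weights(s2)[j], w1[j])
  }
})

test_that("weighted_average is an exact convex combination", {
  g2 <- wavelength_grid(c(600, 700))
  sc <- multipoint_scan(rbind(c(1, 3), c(3, 5)), g2)
  expect_equal(weighted_average(sc, c(0.25, 0.75))$intensity, c(2.5, 4.5))
  expect_equal(weighted_average(sc, c(0.5, 0.5))$intensity, c(2, 4))
  expect_equal(weighted_average(sc, c(1, 0))$intensity, c(1, 3))
  expect_error(weighted_average(sc, c(0.5, 0.2)), "sum to 1")
  expect_error(weighted_average(sc, c(1, 0, 0)), "counts differ")
})

test_that("aggregate_scan composes the stages and stays within bounds", {
  set.seed(42)
  P <- 40L
  g <- wavelength_grid(seq(560, 1000, length.out = P))
  truth <- 500 + 400 * sin(seq(0, 3, length.out = P))
  bg <- background_spectrum(rep(5, P), noise_sd = 2, g)

  # identical points: aggregate is any single point
  same <- multipoint_scan(matrix(truth, 4, P, byrow = TRUE), g)
  expect_equal(aggregate_scan(same, bg)$intensity, truth)

  # K = 1 after construction: that point unchanged (trim skipped)
  one <- multipoint_scan(matrix(truth, 1, P, byrow = TRUE), g)
  expect_equal(aggregate_scan(one, bg)$intensity, truth)

  # noisy K = 12 scan: convexity + better than the worst retained point
  K <- 12L
  pts <- matrix(truth, K, P, byrow = TRUE) + matrix(rnorm(K * P, 0, 40), K, P)
  pts <- pmax(pts, 0)
  sc <- multipoint_scan(pts, g)
  agg <- aggregate_scan(sc, bg)
  expect_true(all(agg$intensity >= apply(pts, 2, min) - 1e-9))
  expect_true(all(agg$intensity <= apply(pts, 2, max) + 1e-9))
  w <- attr(agg, "weights")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
  rms <- function(x) sqrt(mean(x^2))
  worst <- max(apply(pts, 1, function(p) rms(p - truth)))
  expect_lt(rms(agg$intensity - truth), worst)

  # order invariance: permuting interior points leaves the result unchanged
  perm <- c(1L, sample(2:(K - 1L)), K)
  sc2 <- multipoint_scan(pts[perm, ], g)
  expect_equal(aggregate_scan(sc2, bg)$intensity, agg$intensity)

  # all points saturated -> degenerate error
  sat <- multipoint_scan(matrix(100, 3, P), g, sample_id = "satscan",
                         saturation_level = 100)
  expect_error(aggregate_scan(sat, bg), "satscan")
})

test_that("aggregation suppresses i.i.d. noise relative to single points", {
  set.seed(11)
  P <- 50L
  g <- wavelength_grid(seq(560, 1072, length.out = P))
  truth <- 800 + 500 * exp(-(seq_len(P) - 25)^2 / 100)
  bg <- background_spectrum(rep(0, P), noise_sd = 3, g)
  for (rep in 1:5) {
    K <- 15L
    pts <- pmax(matrix(truth, K, P, byrow = TRUE) +
                  matrix(rnorm(K * P, 0, 60), K, P), 0)
    sc <- multipoint_scan(pts, g)
    agg <- aggregate_scan(sc, bg)
    mse_agg <- mean((agg$intensity - truth)^2)
    mse_pts <- mean((pts - matrix(truth, K, P, byrow = TRUE))^2)
    expect_lt(mse_agg, mse_pts)
  }
})
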