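test_that("generate_ssc_values matches the cohort moments and truncates", {
  prof <- provence_profile()
  v <- generate_ssc_values(prof, seed = 1)
  expect_length(v, 92L)
  expect_true(all(v >= 3.8 & v <= 8.7))
  expect_lt(abs(mean(v) - 5.8), 0.35)
  expect_lt(abs(sd(v) - 1.1), 0.35)
  expect_identical(v, generate_ssc_values(prof, seed = 1))
  # truncation property across seeds, both varieties
  for (s in 1:20) {
    vj <- generate_ssc_values(jingcai_profile(), seed = s)
    expect_true(all(vj >= 4.5 & vj <= 9.8))
  }
  # vanishing-variance limit
  tight <- variety_profile("t", 3.8, 8.7, 5.8, 0.001, 20L, 3L, 5L)
  expect_true(all(abs(generate_ssc_values(tight, seed = 2) - 5.8) < 0.01))
  expect_error(variety_profile("bad", 3.8, 8.7, 5.8, 0, 10L, 3L, 5L),
               "ssc_sd")
})

test_that("generate_background has the configured level and noise", {
  cfg0 <- tiny_config(background_noise_sd = 0)
  bg0 <- generate_background(cfg0, seed = 1)
  expect_equal(bg0$intensity, rep(cfg0$stray_level, 64L))
  # empirical SD within 20% of nominal for the full-length grid
  cfg <- sim_config()
  bg <- generate_background(cfg, seed = 3)
  emp <- sd(bg$intensity - cfg$stray_level)
  expect_lt(abs(emp - cfg$background_noise_sd), 0.2 * cfg$background_noise_sd)
  expect_identical(bg$intensity, generate_background(cfg, seed = 3)$intensity)
  expect_identical(bg$noise_sd, cfg$background_noise_sd)
})

test_that("generate_scan: deterministic limit gives identical points", {
  prof <- tiny_profile(kmin = 3L, kmax = 3L)
  scan <- generate_scan(6, "O1", prof, exact_config(), seed = 5)
  expect_identical(nrow(scan$points), 3L)
  expect_equal(scan$points[1, ], scan$points[2, ])
  expect_equal(scan$points[2, ], scan$points[3, ])
})

test_that("generate_scan obeys Beer-Lambert monotonicity in SSC", {
  prof <- tiny_profile()
  cfg <- exact_config()
  ctr <- cfg$ssc_bands$center[1]
  ch <- which.min(abs(as.numeric(cfg$grid) - ctr))
  s4 <- generate_scan(4, "O1", prof, cfg, seed = 9)
  s8 <- generate_scan(8, "O1", prof, cfg, seed = 9)
  expect_lt(s8$points[1, ch], s4$points[1, ch])
  # strictly decreasing across a range of SSC values at every band center
  chs <- vapply(cfg$ssc_bands$center,
                function(c0) which.min(abs(as.numeric(cfg$grid) - c0)),
                integer(1))
  vals <- vapply(c(4, 5, 6, 7, 8), function(s) {
    generate_scan(s, "O1", prof, cfg, seed = 9)$points[1, chs]
  }, numeric(3))
  expect_true(all(apply(vals, 1, diff) < 0))
})

test_that("generate_scan: O2 dominates O1 channel-wise under matched seeds", {
  prof <- tiny_profile()
  cfg <- exact_config()
  for (s in 1:5) {
    s1 <- generate_scan(6.2, "O1", prof, cfg, seed = s)
    s2 <- generate_scan(6.2, "O2", prof, cfg, seed = s)
    expect_true(all(s2$points >= s1$points))
  }
})

test_that("generate_scan attenuates the end points as configured", {
  prof <- tiny_profile()
  cfg <- tiny_config(noise_sd = 0, noise_structured_sd = 0,
                     background_noise_sd = 0, saturation_prob = 0,
                     end_attenuation = 0.1)
  for (s in 1:5) {
    scan <- generate_scan(6, "O1", prof, cfg, seed = s)
    tot <- rowSums(scan$points)
    med <- median(tot)
    expect_lt(tot[1], (cfg$end_attenuation + 1e-9) * med)
    expect_lt(tot[length(tot)], (cfg$end_attenuation + 1e-9) * med)
  }
  expect_error(generate_scan(99, "O1", prof, cfg, seed = 1), "outside")
})

test_that("generate_dataset produces the cohort and is reproducible", {
  prof <- provence_profile()
  cfg <- tiny_config()
  set <- generate_dataset(prof, cfg, "O2", seed = 4)
  expect_length(set$scans, 92L)
  ks <- vapply(set$scans, function(s) nrow(s$points), integer(1))
  expect_true(all(ks >= 17L & ks <= 31L))
  expect_equal(set$manifest$ssc_brix, set$truth$ssc)

  jc <- generate_dataset(jingcai_profile(), cfg, "O1", seed = 4)
  expect_length(jc$scans, 96L)
  expect_true(all(jc$manifest$ssc_brix >= 4.5 & jc$manifest$ssc_brix <= 9.8))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(prof, cfg, "O2", seed = 4, dir = d1)
  generate_dataset(prof, cfg, "O2", seed = 4, dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, "scan_001.csv")),
                   readLines(file.path(d2, "scan_001.csv")))
})

test_that("sim_config validates its physical constraints", {
  expect_error(sim_config(path_factor_o1 = 0.5, path_factor_o2 = 0.9),
               "path_factor_o2")
  expect_error(sim_config(end_attenuation = 0), "end_attenuation")
  expect_error(sim_config(scatter_gain_range = c(1.1, 1.4)), "scatter")
  expect_error(sim_config(ssc_bands = data.frame(center = 700, width = 0,
                                                 absorptivity = 1)),
               "width")
})
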