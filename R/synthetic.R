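#' Variety profile
#'
#' Describes one tomato variety as sampled in the emulated study: the SSC
#' distribution (range, mean, SD in degrees Brix), the number of fruit, and the
#' range of acquisition points recorded per fruit on the conveyor.
#'
#' @param name Variety label.
#' @param ssc_min,ssc_max SSC range in degrees Brix.
#' @param ssc_mean,ssc_sd SSC mean and SD in degrees Brix.
#' @param n_samples Number of fruit.
#' @param points_min,points_max Range of acquisition points per scan.
#' @return An object of class `variety_profile`.
#' @export
variety_profile <- function(name, ssc_min, ssc_max, ssc_mean, ssc_sd,
                            n_samples, points_min, points_max) {
  stopifnot(is_number(ssc_min), is_number(ssc_max), is_number(ssc_mean),
            is_number(ssc_sd), is_number(n_samples),
            is_number(points_min), is_number(points_max))
  if (!(ssc_min < ssc_mean && ssc_mean < ssc_max)) {
    stop("need ssc_min < ssc_mean < ssc_max", call. = FALSE)
  }
  if (ssc_sd <= 0) stop("ssc_sd must be positive", call. = FALSE)
  if (!(points_min >= 1 && points_min <= points_max)) {
    stop("need 1 <= points_min <= points_max", call. = FALSE)
  }
  if (n_samples < 1) stop("n_samples must be at least 1", call. = FALSE)
  structure(list(name = name, ssc_min = ssc_min, ssc_max = ssc_max,
                 ssc_mean = ssc_mean, ssc_sd = ssc_sd,
                 n_samples = as.integer(n_samples),
                 points_min = as.integer(points_min),
                 points_max = as.integer(points_max)),
            class = "variety_profile")
}

#' @rdname variety_profile
#' @details `provence_profile()` and `jingcai_profile()` carry the reference
#'   cohorts: Provence, n = 92, SSC 3.8--8.7 Brix (mean 5.8, SD 1.1), 17--31
#'   points per scan; Jingcai No.8, n = 96, SSC 4.5--9.8 Brix (mean 7.4, SD
#'   1.2), 20--29 points per scan.
#' @export
provence_profile <- function() {
  variety_profile("Provence", 3.8, 8.7, 5.8, 1.1, 92L, 17L, 31L)
}

#' @rdname variety_profile
#' @export
jingcai_profile <- function() {
  variety_profile("Jingcai No.8", 4.5, 9.8, 7.4, 1.2, 96L, 20L, 29L)
}

#' Simulation configuration
#'
#' Parameters of the Beer-Lambert forward model used to synthesize multi-point
#' transmission scans.  Each acquisition point of a fruit with soluble solids
#' content `ssc` is generated as
#' `gain * atten_k * source(lambda) * exp(-path * A(lambda)) + noise`,
#' clipped at `saturation_level`, where the absorbance
#' `A = base_absorbance + ssc * eps_ssc(lambda) + sum_j c_j * eps_j(lambda)`
#' combines a bulk flesh/water term, Gaussian SSC absorption bands, and
#' interferent bands with random per-fruit concentrations `c_j ~ U(0, 1)`.
#'
#' @param grid [wavelength_grid]; default the 2047-channel 560--1072 nm grid.
#' @param source_peak Peak source intensity in counts.
#' @param ssc_bands Data frame with columns `center` (nm), `width` (Gaussian
#'   SD, nm) and `absorptivity` (absorbance units per degree Brix at the band
#'   center) describing the SSC-informative bands.
#' @param interferent_bands Same shape; `absorptivity` is the absorbance at
#'   unit concentration.  Concentrations are drawn per fruit.
#' @param base_absorbance Flat bulk absorbance of flesh/water per unit path.
#' @param path_factor_o1,path_factor_o2 Dimensionless optical path multipliers
#'   for the two orientations.  `path_factor_o2 < path_factor_o1`, so the O2
#'   transmitted intensity exceeds O1.
#' @param scatter_gain_range Range `(lo, hi)` bracketing 1 for the per-scan
#'   multiplicative scatter gain (fruit size/skin effects).
#' @param end_attenuation Fraction in (0, 1] applied to the first and last
#'   acquisition points ("incomplete" signals at the scan ends); 1 disables.
#' @param saturation_level Detector cap in counts.
#' @param saturation_prob Probability that one interior point of a scan is
#'   scaled up to clip at the cap.
#' @param noise_sd SD of additive i.i.d. channel noise per point (counts).
#' @param noise_structured_sd SD of smooth, spectrally correlated additive
#'   noise per point (counts); emulates lamp/detector drift.
#' @param noise_corr_channels Correlation length (channels) of the structured
#'   noise.
#' @param stray_level Smooth stray-light level reaching the detector with no
#'   sample present (counts).
#' @param background_noise_sd SD of background channel noise (counts).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid = default_grid(),
                       source_peak = 40000,
                       ssc_bands = data.frame(
                         center = c(730, 840, 960),
                         width = c(3, 4, 3.5),
                         absorptivity = c(0.06, 0.07, 0.06)),
                       interferent_bands = data.frame(
                         center = c(650, 1020),
                         width = c(20, 25),
                         absorptivity = c(0.15, 0.12)),
                       base_absorbance = 1.2,
                       path_factor_o1 = 1.3,
                       path_factor_o2 = 0.8,
                       scatter_gain_range = c(0.7, 1.4),
                       end_attenuation = 0.1,
                       saturation_level = 60000,
                       saturation_prob = 0.05,
                       noise_sd = 2000,
                       noise_structured_sd = 300,
                       noise_corr_channels = 80,
                       stray_level = 100,
                       background_noise_sd = 10) {
  stopifnot(inherits(grid, "wavelength_grid"))
  check_bands <- function(b, what) {
    if (!all(c("center", "width", "absorptivity") %in% names(b))) {
      stop(sprintf("%s needs center/width/absorptivity columns", what),
           call. = FALSE)
    }
    if (nrow(b) > 0 && any(b$width <= 0)) {
      stop(sprintf("%s widths must be positive", what), call. = FALSE)
    }
  }
  check_bands(ssc_bands, "ssc_bands")
  check_bands(interferent_bands, "interferent_bands")
  if (!(path_factor_o2 < path_factor_o1)) {
    stop("need path_factor_o2 < path_factor_o1 (O2 is the shorter path)",
         call. = FALSE)
  }
  if (!(end_attenuation > 0 && end_attenuation <= 1)) {
    stop("end_attenuation must lie in (0, 1]", call. = FALSE)
  }
  if (!(scatter_gain_range[1] <= 1 && scatter_gain_range[2] >= 1 &&
        scatter_gain_range[1] > 0)) {
    stop("scatter_gain_range must bracket 1 and be positive", call. = FALSE)
  }
  stopifnot(saturation_level > 0, saturation_prob >= 0, saturation_prob <= 1,
            noise_sd >= 0, noise_structured_sd >= 0, noise_corr_channels >= 2,
            background_noise_sd >= 0, stray_level >= 0, base_absorbance >= 0,
            source_peak > 0)
  structure(list(grid = grid, source_peak = source_peak,
                 ssc_bands = ssc_bands, interferent_bands = interferent_bands,
                 base_absorbance = base_absorbance,
                 path_factor_o1 = path_factor_o1,
                 path_factor_o2 = path_factor_o2,
                 scatter_gain_range = scatter_gain_range,
                 end_attenuation = end_attenuation,
                 saturation_level = saturation_level,
                 saturation_prob = saturation_prob,
                 noise_sd = noise_sd,
                 noise_structured_sd = noise_structured_sd,
                 noise_corr_channels = noise_corr_channels,
                 stray_level = stray_level,
                 background_noise_sd = background_noise_sd),
            class = "sim_config")
}

#' @rdname sim_config
#' @param config A `sim_config` to strip of all stochastic nuisance terms.
#' @details `noiseless_config()` returns a copy with every nuisance source
#'   disabled: additive and structured noise, background noise, scatter gain
#'   spread, saturation events, end-point attenuation, and interferent bands.
#'   The resulting spectra are a deterministic Beer-Lambert response to SSC
#'   alone, the "perfect signal" limit used by exactness tests.
#' @export
noiseless_config <- function(config = sim_config()) {
  config$noise_sd <- 0
  config$noise_structured_sd <- 0
  config$background_noise_sd <- 0
  config$scatter_gain_range <- c(1, 1)
  config$saturation_prob <- 0
  config$end_attenuation <- 1
  config$interferent_bands <- config$interferent_bands[0, , drop = FALSE]
  config
}

# Smooth positive source envelope: a halogen-like NIR bump plus a visible
# shoulder, scaled so the maximum equals source_peak.
source_curve <- function(config) {
  wl <- as.numeric(config$grid)
  env <- 0.85 * exp(-(wl - 860)^2 / (2 * 160^2)) +
    0.35 * exp(-(wl - 640)^2 / (2 * 90^2))
  config$source_peak * env / max(env)
}

# Sum of Gaussian bands evaluated on the grid; returns a P-vector.
band_profile <- function(grid, bands, scale = bands$absorptivity) {
  wl <- as.numeric(grid)
  out <- numeric(length(wl))
  if (nrow(bands) == 0L) return(out)
  for (j in seq_len(nrow(bands))) {
    out <- out + scale[j] *
      exp(-(wl - bands$center[j])^2 / (2 * bands$width[j]^2))
  }
  out
}

#' Draw reference SSC values for a variety
#'
#' Truncated-normal draw with the profile's mean and SD, rejected outside the
#' profile's `[ssc_min, ssc_max]` range.
#'
#' @param profile [variety_profile].
#' @param seed Integer seed; the draw is a pure function of (profile, seed).
#' @return Numeric vector of length `profile$n_samples`, degrees Brix.
#' @export
generate_ssc_values <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "variety_profile"))
  if (profile$ssc_sd <= 0) stop("degenerate profile: ssc_sd <= 0", call. = FALSE)
  n <- profile$n_samples
  with_seed(seed, {
    vals <- numeric(0)
    while (length(vals) < n) {
      draw <- stats::rnorm(2L * n, profile$ssc_mean, profile$ssc_sd)
      vals <- c(vals, draw[draw >= profile$ssc_min & draw <= profile$ssc_max])
    }
    vals[seq_len(n)]
  })
}

#' Generate a background spectrum
#'
#' The stray-light level plus zero-mean channel noise, as recorded with no
#' sample in the beam.
#'
#' @param config [sim_config].
#' @param seed Integer seed.
#' @return A [background_spectrum] whose `noise_sd` is the configured
#'   background noise SD.
#' @export
generate_background <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  P <- length(config$grid)
  intensity <- with_seed(seed, {
    config$stray_level + stats::rnorm(P, 0, config$background_noise_sd)
  })
  background_spectrum(pmax(intensity, 0), config$background_noise_sd,
                      config$grid)
}

# Smooth spectrally correlated noise: white noise on a coarse knot grid with
# spacing noise_corr_channels, cubic-spline interpolated to all channels.
structured_noise <- function(K, P, sd, corr_channels) {
  if (sd <= 0) return(matrix(0, K, P))
  knots <- unique(c(seq(1L, P, by = as.integer(corr_channels)), P))
  out <- matrix(0, K, P)
  for (k in seq_len(K)) {
    z <- stats::rnorm(length(knots), 0, sd)
    out[k, ] <- stats::spline(knots, z, xout = seq_len(P))$y
  }
  out
}

#' Generate one multi-point transmission scan
#'
#' Simulates the stack of spectra recorded while a fruit with known SSC passes
#' the detector: a per-scan scatter gain, the Beer-Lambert transmitted
#' spectrum, attenuated (incomplete) first/last points, an optional
#' deliberately saturated interior point, additive i.i.d. and spectrally
#' smooth noise, and hard clipping at the detector cap.
#'
#' @param ssc SSC of the fruit (degrees Brix), within the profile range.
#' @param orientation `"O1"` or `"O2"`.
#' @param profile [variety_profile] (supplies the acquisition-point range).
#' @param config [sim_config].
#' @param seed Integer seed.  With the same seed, the stochastic draws (point
#'   count, gain, interferent concentrations, noise) are identical across
#'   orientations, so the O1/O2 pair differs only through the path factor.
#' @param sample_id Sample identifier stored on the scan.
#' @return A [multipoint_scan].
#' @export
generate_scan <- function(ssc, orientation = c("O1", "O2"), profile,
                          config = sim_config(), seed = NULL,
                          sample_id = "sample") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(profile, "variety_profile"), inherits(config, "sim_config"))
  if (!is_number(ssc) || ssc < profile$ssc_min || ssc > profile$ssc_max) {
    stop(sprintf("ssc %.3g outside profile range [%.3g, %.3g]",
                 ssc, profile$ssc_min, profile$ssc_max), call. = FALSE)
  }
  path <- if (orientation == "O1") config$path_factor_o1 else config$path_factor_o2
  P <- length(config$grid)
  src <- source_curve(config)
  eps_ssc <- band_profile(config$grid, config$ssc_bands)
  with_seed(seed, {
    K <- sample_one(seq(profile$points_min, profile$points_max))
    conc <- stats::runif(nrow(config$interferent_bands))
    eps_int <- band_profile(config$grid, config$interferent_bands,
                            scale = conc * config$interferent_bands$absorptivity)
    gain <- stats::runif(1, config$scatter_gain_range[1],
                         config$scatter_gain_range[2])
    absorb <- config$base_absorbance + ssc * eps_ssc + eps_int
    clean <- gain * src * exp(-path * absorb)
    pts <- matrix(clean, K, P, byrow = TRUE)
    if (K >= 2L && config$end_attenuation < 1) {
      pts[1L, ] <- pts[1L, ] * config$end_attenuation
      pts[K, ] <- pts[K, ] * config$end_attenuation
    }
    if (K >= 3L && stats::runif(1) < config$saturation_prob) {
      j <- sample_one(seq(2L, K - 1L))
      pts[j, ] <- pts[j, ] * (1.05 * config$saturation_level / max(pts[j, ]))
    }
    pts <- pts +
      matrix(stats::rnorm(K * P, 0, config$noise_sd), K, P) +
      structured_noise(K, P, config$noise_structured_sd,
                       config$noise_corr_channels)
    pts <- pmin(pmax(pts, 0), config$saturation_level)
    scan <- multipoint_scan(pts, config$grid, sample_id = sample_id,
                            orientation = orientation,
                            saturation_level = config$saturation_level)
    scan$ssc <- ssc
    scan
  })
}

#' Generate a full synthetic acquisition set
#'
#' Draws SSC references for a variety, simulates one multi-point scan per
#' fruit plus a background spectrum, and records the ground truth needed by
#' parameter-recovery tests (SSC values, informative band centers/widths,
#' per-fruit interferent concentrations).
#'
#' @param profile [variety_profile].
#' @param config [sim_config].
#' @param orientation `"O1"` or `"O2"`.
#' @param seed Integer seed; the whole set is a pure function of its inputs.
#' @param dir Optional directory: when given, the CSV fixture set is written
#'   there (`scan_NNN.csv`, `background.csv`, `manifest.csv`,
#'   `ground_truth.json`) and paths are recorded in the manifest.
#' @return A list of class `ssc_scanset` with elements `scans` (list of
#'   [multipoint_scan]), `background`, `truth`, `manifest` (data frame with
#'   columns sample_id, variety, orientation, ssc_brix, scan_path).
#' @export
generate_dataset <- function(profile, config = sim_config(),
                             orientation = c("O1", "O2"), seed = 1L,
                             dir = NULL) {
  orientation <- match.arg(orientation)
  ssc <- generate_ssc_values(profile, seed = derive_seed(seed, 1))
  n <- profile$n_samples
  scan_seeds <- with_seed(derive_seed(seed, 2),
                          sample.int(2147483646L, n))
  ids <- sprintf("%s_%s_%03d", gsub("[^A-Za-z0-9]", "", profile$name),
                 orientation, seq_len(n))
  scans <- vector("list", n)
  conc <- NULL
  for (i in seq_len(n)) {
    scans[[i]] <- generate_scan(ssc[i], orientation, profile, config,
                                seed = scan_seeds[i], sample_id = ids[i])
  }
  background <- generate_background(config, seed = derive_seed(seed, 3))
  truth <- list(ssc = ssc,
                band_centers = config$ssc_bands$center,
                band_widths = config$ssc_bands$width,
                interferent_centers = config$interferent_bands$center)
  manifest <- data.frame(sample_id = ids, variety = profile$name,
                         orientation = orientation, ssc_brix = ssc,
                         scan_path = sprintf("scan_%03d.csv", seq_len(n)),
                         stringsAsFactors = FALSE)
  out <- structure(list(scans = scans, background = background, truth = truth,
                        manifest = manifest, config = config),
                   class = "ssc_scanset")
  if (!is.null(dir)) write_scanset(out, dir)
  out
}

# Fixed-format numeric text so repeated writes are byte-identical.
fmt_num <- function(x) sprintf("%.10g", x)

write_matrix_csv <- function(m, grid, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(fmt_num(as.numeric(grid)), collapse = ","), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(fmt_num(m[i, ]), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname generate_dataset
#' @param scanset An `ssc_scanset`.
#' @export
write_scanset <- function(scanset, dir) {
  stopifnot(inherits(scanset, "ssc_scanset"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  for (i in seq_along(scanset$scans)) {
    write_matrix_csv(scanset$scans[[i]]$points, scanset$scans[[i]]$grid,
                     file.path(dir, scanset$manifest$scan_path[i]))
  }
  write_matrix_csv(matrix(scanset$background$intensity, nrow = 1L),
                   scanset$background$grid, file.path(dir, "background.csv"))
  man <- scanset$manifest
  lines <- c(paste(names(man), collapse = ","),
             vapply(seq_len(nrow(man)), function(i) {
               paste(man$sample_id[i], man$variety[i], man$orientation[i],
                     fmt_num(man$ssc_brix[i]), man$scan_path[i], sep = ",")
             }, character(1)))
  writeLines(lines, file.path(dir, "manifest.csv"))
  jsonlite::write_json(
    list(ssc = scanset$truth$ssc,
         band_centers = scanset$truth$band_centers,
         band_widths = scanset$truth$band_widths,
         background_noise_sd = scanset$background$noise_sd,
         saturation_level = scanset$config$saturation_level),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Simulate an aggregated spectra dataset in one call
#'
#' Convenience wrapper: [generate_dataset()] followed by [aggregate_scan()] on
#' every scan, returning the n x P matrix the modeling stages consume.
#'
#' @inheritParams generate_dataset
#' @param ... Passed to [aggregate_scan()] (e.g. `rel_threshold`).
#' @return An [ssc_dataset] with the scan-level ground truth attached as
#'   attribute `"truth"`.
#' @export
simulate_spectra_dataset <- function(profile, config = sim_config(),
                                     orientation = c("O1", "O2"), seed = 1L,
                                     ...) {
  orientation <- match.arg(orientation)
  set <- generate_dataset(profile, config, orientation, seed)
  X <- t(vapply(set$scans, function(s) {
    aggregate_scan(s, set$background, ...)$intensity
  }, numeric(length(config$grid))))
  ds <- ssc_dataset(X, set$truth$ssc, config$grid,
                    sample_id = set$manifest$sample_id,
                    orientation = orientation, variety = set$manifest$variety[1])
  attr(ds, "truth") <- set$truth
  ds
}
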