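#' 7:3 calibration/prediction split
#'
#' Uniform seeded random permutation; the first `floor(ratio * n)` samples
#' form the calibration set, the remainder the prediction set.
#'
#' @param n Number of samples (at least 4).
#' @param ratio Calibration fraction (default 0.7).
#' @param seed Integer seed; the plan is a pure function of `(n, ratio, seed)`.
#' @return An object of class `split_plan` with `calibration` and
#'   `prediction` index vectors and the `seed`.
#' @export
split_dataset <- function(n, ratio = 0.7, seed = NULL) {
  if (!is_number(n) || n < 4L) {
    stop("need at least 4 samples to populate both sets", call. = FALSE)
  }
  n_cal <- floor(ratio * n)
  if (n_cal < 1L || n_cal >= n) {
    stop("ratio leaves one of the sets empty", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  structure(list(calibration = perm[seq_len(n_cal)],
                 prediction = perm[(n_cal + 1L):n],
                 seed = seed),
            class = "split_plan")
}

# One modeling pass on pre-pretreated matrices.  Everything data-driven
# (wavelength selection, penalty choice, LV count) sees calibration rows only.
run_core <- function(X, y, split, selection = NULL, max_lv = 20L,
                     seed = NULL, wavelengths = NULL, metric_mode = "paper") {
  cal <- split$calibration; prd <- split$prediction
  Xc <- X[cal, , drop = FALSE]; yc <- y[cal]
  sel <- NULL
  cols <- seq_len(ncol(X))
  if (!is.null(selection)) {
    lam <- selection$lambda %||% "cv"
    if (identical(lam, "cv")) {
      if (identical(selection$penalty, "L2")) {
        # CV-stop is built into the L2 rule; lambda sets the ridge weight
        lam <- selection$ridge_lambda %||% 0.1
      } else {
        lam <- select_lambda_cv(Xc, yc, seed = derive_seed(seed, 11))$lambda
      }
    }
    sel <- tryCatch(
      select_wavelengths(Xc, yc, lam, penalty = selection$penalty,
                         cv_seed = derive_seed(seed, 12),
                         wavelengths = wavelengths),
      error = function(e) stop_stage("selection", conditionMessage(e)))
    cols <- sel$channel
  }
  n_cal <- length(cal)
  lv_cap <- min(max_lv, length(cols), n_cal - ceiling(n_cal / 5) - 1L)
  lv <- tryCatch(
    select_lvs_cv(Xc[, cols, drop = FALSE], yc, max_lv = lv_cap,
                  seed = derive_seed(seed, 13)),
    error = function(e) stop_stage("lv_selection", conditionMessage(e)))
  model <- tryCatch(fit_plsr(Xc[, cols, drop = FALSE], yc, lv$n_lv),
                    error = function(e) stop_stage("plsr_fit",
                                                   conditionMessage(e)))
  mc <- compute_metrics(yc, stats::predict(model, Xc[, cols, drop = FALSE]),
                        mode = metric_mode)
  mp <- compute_metrics(y[prd],
                        stats::predict(model, X[prd, cols, drop = FALSE]),
                        mode = metric_mode)
  list(calibration = mc, prediction = mp, n_lv = model$n_lv,
       selection = sel, model = model)
}

#' Run one pretreat-select-fit-evaluate pass
#'
#' Applies the pretreatment (row-wise, so sample-independent), optionally
#' selects wavelengths on the calibration set only, chooses the
#' latent-variable count by 5-fold CV on the calibration set only, fits the
#' PLSR model and evaluates both sets.  No prediction-set information reaches
#' any data-driven choice.
#'
#' @param dataset [ssc_dataset].
#' @param pretreatment [pretreatment_spec].
#' @param selection `NULL` for the full-spectrum model, or a list with
#'   `penalty` (`"L1"`/`"L2"`) and `lambda` (numeric, or `"cv"` for the L1
#'   cross-validated choice; for L2 use `ridge_lambda` with `lambda = "cv"`).
#' @param split [split_plan] over the dataset rows.
#' @param max_lv Cap for the latent-variable search (default 20).
#' @param seed Seed driving the internal cross-validations.
#' @param metric_mode Passed to [compute_metrics()].
#' @return List with `calibration` and `prediction` [compute_metrics()]
#'   results, `n_lv`, and the `selection_result` (if any).
#' @export
run_single <- function(dataset, pretreatment = pretreatment_spec("RAW"),
                       selection = NULL, split, max_lv = 20L, seed = NULL,
                       metric_mode = "paper") {
  stopifnot(inherits(dataset, "ssc_dataset"), inherits(split, "split_plan"))
  X <- tryCatch(apply_pretreatment(dataset$X, pretreatment),
                error = function(e) stop_stage("pretreatment",
                                               conditionMessage(e)))
  run_core(X, dataset$y, split, selection, max_lv, seed,
           wavelengths = as.numeric(dataset$grid), metric_mode = metric_mode)
}

#' Repeated random-split evaluation
#'
#' Repeats the 7:3 split `n_repeats` times (repeat `i` uses seed
#' `base_seed + i`), runs the full modeling pass on each split, and summarizes
#' each metric by its mean and SD across repeats -- the error bars of the
#' stability analysis.
#'
#' @inheritParams run_single
#' @param n_repeats Number of random splits (default 100).
#' @param base_seed Base seed of the split schedule.
#' @param ratio Calibration fraction.
#' @param selection_protocol `"per_repeat"` (default): wavelengths are
#'   re-selected inside every repeat on that repeat's calibration set —
#'   strictly leakage-free.  `"once"`: the wavelength set is selected a
#'   single time on the whole dataset and every repeat refits PLSR on it —
#'   the stability protocol of the emulated study, which carried one optimal
#'   selection into its 100 iterations.  Ignored when `selection` is `NULL`.
#' @return An object of class `repeat_summary`: data frame `metrics` (one row
#'   per repeat: Rc, RMSEC, Rp, RMSEP, n_lv, n_selected), `mean` and `sd`
#'   rows, `n_repeats`, `n_failed`, and `failures` (messages of failed
#'   repeats, if any).
#' @export
run_repeats <- function(dataset, pretreatment = pretreatment_spec("RAW"),
                        selection = NULL, n_repeats = 100L, base_seed = 1L,
                        ratio = 0.7, max_lv = 20L, metric_mode = "paper",
                        selection_protocol = c("per_repeat", "once")) {
  stopifnot(inherits(dataset, "ssc_dataset"))
  selection_protocol <- match.arg(selection_protocol)
  if (n_repeats < 2L) stop("n_repeats must be at least 2", call. = FALSE)
  X <- apply_pretreatment(dataset$X, pretreatment)   # sample-wise: done once
  n <- nrow(X)
  wl <- as.numeric(dataset$grid)
  n_fixed <- NULL
  if (!is.null(selection) && selection_protocol == "once") {
    lam <- selection$lambda %||% "cv"
    if (identical(lam, "cv")) {
      lam <- if (identical(selection$penalty, "L2")) {
        selection$ridge_lambda %||% 0.1
      } else {
        select_lambda_cv(X, dataset$y, seed = derive_seed(base_seed, 11))$lambda
      }
    }
    sel0 <- select_wavelengths(X, dataset$y, lam, penalty = selection$penalty,
                               cv_seed = derive_seed(base_seed, 12),
                               wavelengths = wl)
    X <- X[, sel0$channel, drop = FALSE]              # repeats refit on the set
    wl <- wl[sel0$channel]
    n_fixed <- sel0$n_selected
    selection <- NULL
  }
  rows <- vector("list", n_repeats)
  failures <- character(0)
  for (i in seq_len(n_repeats)) {
    seed_i <- base_seed + i
    res <- tryCatch({
      split <- split_dataset(n, ratio, seed = seed_i)
      r <- run_core(X, dataset$y, split, selection, max_lv, seed = seed_i,
                    wavelengths = wl, metric_mode = metric_mode)
      data.frame(repeat_id = i, Rc = r$calibration$R, RMSEC = r$calibration$RMSE,
                 Rp = r$prediction$R, RMSEP = r$prediction$RMSE,
                 n_lv = r$n_lv,
                 n_selected = if (is.null(r$selection)) ncol(X) else
                   r$selection$n_selected)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("repeat %d: %s", i,
                                      conditionMessage(res)))
    } else {
      rows[[i]] <- res
    }
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(metrics) || nrow(metrics) == 0L) {
    stop("every repeat failed; first failure: ", failures[1], call. = FALSE)
  }
  num <- metrics[, c("Rc", "RMSEC", "Rp", "RMSEP", "n_lv", "n_selected")]
  structure(list(metrics = metrics,
                 mean = colMeans(num), sd = apply(num, 2L, stats::sd),
                 n_repeats = n_repeats, n_failed = length(failures),
                 failures = failures,
                 complete = length(failures) == 0L),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf(
    "<repeat_summary> %d repeats (%d failed)\n  Rp %.3f +/- %.3f, RMSEP %.3f +/- %.3f Brix\n",
    x$n_repeats, x$n_failed, x$mean["Rp"], x$sd["Rp"],
    x$mean["RMSEP"], x$sd["RMSEP"]))
  invisible(x)
}

#' Orientation x pretreatment x model evaluation grid
#'
#' Evaluates every combination of dataset (one per orientation), pretreatment
#' (`RAW`, `SG`, `SNV`) and model variant (full-spectrum PLSR, LARS-L1-PLSR,
#' LARS-L2-PLSR) with [run_repeats()], and reports study-table-shaped rows of
#' mean metrics with their across-repeat SDs.  A failing cell is reported and
#' skipped; the rest of the grid completes.
#'
#' @param datasets List of [ssc_dataset] objects (e.g. one per orientation).
#' @param pretreatments Character vector among `"RAW"`, `"SG"`, `"SNV"`.
#' @param models Character vector among `"full"`, `"LARS-L1"`, `"LARS-L2"`.
#' @param n_repeats,base_seed,ratio,max_lv Passed to [run_repeats()].
#' @param l1_lambda L1 penalty protocol: `"cv_once"` (default) chooses the
#'   penalty once per cell by cross-validation on the whole dataset and holds
#'   it fixed across the split repeats -- the stability protocol of the
#'   emulated study, which ran its 100 iterations under the optimal penalty;
#'   `"cv"` re-chooses it inside every repeat on the calibration set; a
#'   number fixes it directly.
#' @param selection_protocol Passed to [run_repeats()]; the default `"once"`
#'   mirrors the study's stability analysis (one optimal wavelength set
#'   carried through the 100 split repeats).
#' @param l2_ridge_lambda Ridge weight used by the `LARS-L2` variant.
#' @param verbose Log per-cell timing.
#' @return A data frame of class `grid_report`, one row per grid cell, with
#'   columns variety, orientation, pretreatment, model, LVs, n_selected,
#'   Rc, RMSEC, Rp, RMSEP and the matching `*_sd` columns.
#' @export
run_grid <- function(datasets, pretreatments = c("RAW", "SG", "SNV"),
                     models = c("full", "LARS-L1", "LARS-L2"),
                     n_repeats = 100L, base_seed = 1L, ratio = 0.7,
                     max_lv = 20L, l1_lambda = "cv_once",
                     selection_protocol = "once",
                     l2_ridge_lambda = 0.1, verbose = FALSE) {
  if (inherits(datasets, "ssc_dataset")) datasets <- list(datasets)
  if (length(datasets) < 1L) stop("need at least one dataset", call. = FALSE)
  sel_for <- function(model, ds, pt) switch(model,
    "full" = NULL,
    "LARS-L1" = {
      lam <- if (identical(l1_lambda, "cv_once")) {
        X <- apply_pretreatment(ds$X, pretreatment_spec(pt))
        select_lambda_cv(X, ds$y, seed = derive_seed(base_seed, 7))$lambda
      } else l1_lambda
      list(penalty = "L1", lambda = lam)
    },
    "LARS-L2" = list(penalty = "L2", lambda = "cv",
                     ridge_lambda = l2_ridge_lambda),
    stop(sprintf("unknown model variant '%s'", model), call. = FALSE))
  rows <- list()
  for (ds in datasets) {
    for (pt in pretreatments) {
      for (md in models) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(
          run_repeats(ds, pretreatment_spec(pt), sel_for(md, ds, pt),
                      n_repeats = n_repeats, base_seed = base_seed,
                      ratio = ratio, max_lv = max_lv,
                      selection_protocol = selection_protocol),
          error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("grid cell %s/%s/%s failed: %s",
                          ds$orientation, pt, md, conditionMessage(res)))
          next
        }
        if (verbose) {
          message(sprintf("[grid] %s %s %s: Rp = %.3f (%.1fs)",
                          ds$orientation, pt, md, res$mean[["Rp"]],
                          proc.time()[["elapsed"]] - t0))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          variety = ds$variety, orientation = ds$orientation,
          pretreatment = pt, model = md,
          LVs = res$mean[["n_lv"]], n_selected = res$mean[["n_selected"]],
          Rc = res$mean[["Rc"]], RMSEC = res$mean[["RMSEC"]],
          Rp = res$mean[["Rp"]], RMSEP = res$mean[["RMSEP"]],
          Rc_sd = res$sd[["Rc"]], RMSEC_sd = res$sd[["RMSEC"]],
          Rp_sd = res$sd[["Rp"]], RMSEP_sd = res$sd[["RMSEP"]],
          n_failed = res$n_failed, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_report", class(out))
  out
}

#' Read a scan fixture set from disk
#'
#' Loads the manifest CSV (columns sample_id, variety, orientation, ssc_brix,
#' scan_path), every referenced scan CSV (header row of wavelengths, one row
#' per acquisition point) and the background CSV.  Problems are reported with
#' the offending file and row.
#'
#' @param path Path to `manifest.csv`.
#' @param background_path Path to the background CSV (default
#'   `background.csv` beside the manifest).
#' @param background_noise_sd Channel-noise SD to record on the background;
#'   default reads it from `ground_truth.json` beside the manifest if
#'   present, else estimates it from the background's high-frequency
#'   residual.
#' @return An `ssc_scanset` (without ground truth unless the JSON is present).
#' @export
load_manifest <- function(path, background_path = NULL,
                          background_noise_sd = NULL) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path),
                               call. = FALSE)
  dir <- dirname(path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "variety", "orientation", "ssc_brix", "scan_path")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0L) {
    stop(sprintf("manifest %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(man$ssc_brix) || anyNA(man$ssc_brix)) {
    bad <- which(is.na(suppressWarnings(as.numeric(man$ssc_brix))))
    stop(sprintf("non-numeric ssc_brix in %s, row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  read_mat <- function(p) {
    if (!file.exists(p)) stop(sprintf("scan file not found: %s", p),
                              call. = FALSE)
    m <- as.matrix(utils::read.csv(p, header = FALSE, skip = 1L))
    wl <- as.numeric(strsplit(readLines(p, n = 1L), ",", fixed = TRUE)[[1]])
    list(wl = wl, m = unname(m))
  }
  bg_path <- background_path %||% file.path(dir, "background.csv")
  bg <- read_mat(bg_path)
  grid <- wavelength_grid(bg$wl)
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (is.null(background_noise_sd) && file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    background_noise_sd <- as.numeric(gt$background_noise_sd)
    truth <- gt
  }
  if (is.null(background_noise_sd)) {
    background_noise_sd <- stats::sd(diff(drop(bg$m[1L, ]))) / sqrt(2)
  }
  background <- background_spectrum(drop(bg$m[1L, ]), background_noise_sd, grid)
  scans <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sc <- read_mat(file.path(dir, man$scan_path[i]))
    if (length(sc$wl) != length(grid) || any(abs(sc$wl - grid) > 1e-6)) {
      stop(sprintf("wavelength grid mismatch in %s (manifest row %d)",
                   man$scan_path[i], i), call. = FALSE)
    }
    scans[[i]] <- multipoint_scan(sc$m, grid, sample_id = man$sample_id[i],
                                  orientation = man$orientation[i],
                                  saturation_level = truth$saturation_level)
  }
  structure(list(scans = scans, background = background, truth = truth,
                 manifest = man, config = NULL),
            class = "ssc_scanset")
}

#' Aggregate a loaded scan set into a modeling dataset
#'
#' @param scanset An `ssc_scanset` from [generate_dataset()] or
#'   [load_manifest()].
#' @param ... Passed to [aggregate_scan()].
#' @return An [ssc_dataset].
#' @export
aggregate_scanset <- function(scanset, ...) {
  stopifnot(inherits(scanset, "ssc_scanset"))
  grid <- scanset$background$grid
  X <- t(vapply(scanset$scans, function(s) {
    aggregate_scan(s, scanset$background, ...)$intensity
  }, numeric(length(grid))))
  ssc_dataset(X, scanset$manifest$ssc_brix, grid,
              sample_id = scanset$manifest$sample_id,
              orientation = scanset$manifest$orientation[1],
              variety = scanset$manifest$variety[1])
}

#' Write / read a grid report
#'
#' CSV round trip at full double precision (17 significant digits), so
#' write-then-read reproduces the table exactly.
#'
#' @param report A `grid_report` (or any data frame).
#' @param path Output CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_grid_report <- function(report, path) {
  df <- as.data.frame(report)
  cols <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  cols <- matrix(cols, nrow = nrow(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(cols, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grid_report
#' @export
read_grid_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("report not found: %s", path),
                               call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
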