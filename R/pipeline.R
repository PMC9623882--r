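# Configuration, dataset encoding, the end-to-end pipeline driver, the
# input-smoothing robustness sweep, and serialization plumbing.

default_config <- function() {
  list(
    geometry = list(baseline_mm = 60, fixation_distance_mm = 350,
                    focal_length_mm = 350, sensor_mm = 210,
                    image_px = 123, torsion_mode = "none"),
    plane = list(extent_deg = 50),
    grid = list(n_slant = 12, n_tilt = 12, slant_range = c(4, 48),
                tilt_range = c(30, 360)),
    gazes = list(offsets = c(-5, 0, 5), center = c(0, 0)),
    texture = list(density = 0.5),
    bank = list(n_ori = 8, n_phase = 7, base_omega0 = 0.045,
                base_sigma = 7, base_px = 123, normalize = TRUE,
                epsilon = 1e-6, pool_to = 43),
    differentials = list(scale_s = 2),
    network = list(unroll_T = 9, lambda = 0.2, max_iters = 500,
                   target_error = 0.1, loss = "logistic",
                   lr_halving = FALSE),
    split = list(train_frac = 0.7),
    seeds = list(master = 1)
  )
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Experiment configuration
#'
#' Returns the default configuration (the reference simulation: 60 mm
#' baseline, 350 mm fixation distance, 350/210 mm pinhole optics, 123 px
#' images, 12 x 12 orientation grid, 3 x 3 gaze grid at +/- 5 deg, 8 x 7
#' channel bank, recurrent network with unroll depth 9 trained at lambda
#' 0.2 for up to 500 iterations), optionally overridden by a nested list of
#' the same shape.
#'
#' @param overrides nested list (or an already-complete config, returned
#'   merged over the defaults).
#' @return configuration list.
#' @export
stereoslant_config <- function(overrides = list()) {
  merge_config(default_config(), overrides)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return [read_config()] returns a complete config (defaults merged).
#' @export
read_config <- function(path) stereoslant_config(yaml::read_yaml(path))

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

bank_from_config <- function(cfg, px = NULL) {
  disparity_bank(px = px %||% cfg$geometry$image_px,
                 n_ori = cfg$bank$n_ori, n_phase = cfg$bank$n_phase,
                 base_omega0 = cfg$bank$base_omega0,
                 base_sigma = cfg$bank$base_sigma,
                 base_px = cfg$bank$base_px,
                 normalize = cfg$bank$normalize, epsilon = cfg$bank$epsilon)
}

#' Encode a stereo dataset into normalized network inputs
#'
#' Runs every stereo pair through the binocular-energy population and the
#' convolutional front end, then normalizes all features to the training
#' statistics.
#'
#' @param ds a [generate_dataset()] result (images kept).
#' @param progress print a line every 25 orientations.
#' @return An `encoded_features` object: input tensor `Z` of dim
#'   (4 m^2, n_groups, n_gaze, n_orientations), normalization `norm`,
#'   `labels`, the `bank`, and the config.
#' @export
encode_dataset <- function(ds, progress = FALSE) {
  cfg <- ds$config
  px <- cfg$geometry$image_px
  bank <- bank_from_config(cfg)
  filters <- bank_filters(bank, c(px, px))
  n_or <- nrow(ds$labels); n_gz <- nrow(ds$gazes$directions)
  half <- length(bank$theta) / 2; L <- length(bank$dpsi)
  FS <- NULL
  for (i in seq_len(n_or)) {
    for (q in seq_len(n_gz)) {
      pop <- population_response(ds$pairs[[i]][[q]], bank,
                                 pool_to = cfg$bank$pool_to,
                                 filters = filters)
      fz <- preprocess_gaze(pop, scale_s = cfg$differentials$scale_s)
      if (is.null(FS))
        FS <- array(0, dim = c(dim(fz), n_gz, n_or))
      FS[, , , , , q, i] <- fz
    }
    if (progress && i %% 25 == 0) message("encoded ", i, "/", n_or)
  }
  train_idx <- which(ds$labels$split == "train")
  nf <- normalize_features(FS, train_idx = train_idx)
  structure(list(Z = features_to_input(nf$FS), norm = nf$params,
                 labels = ds$labels, bank = bank, config = cfg,
                 m = dim(nf$FS)[1], n_groups = half * L),
            class = "encoded_features")
}

#' Train the orientation classifier on an encoded dataset
#'
#' @param enc an [encode_dataset()] result.
#' @param verbose print the loss every 50 iterations.
#' @return A `stereoslant_model`: trained `params`, loss `trace`, the
#'   normalization, bank and config used.
#' @export
train_pipeline <- function(enc, verbose = FALSE) {
  cfg <- enc$config
  tr <- which(enc$labels$split == "train")
  params <- init_network(n_groups = enc$n_groups,
                         n_gaze = dim(enc$Z)[3], m = enc$m,
                         unroll_T = cfg$network$unroll_T,
                         seed = cfg$seeds$master + 2L)
  fit <- train_bptt(params, enc$Z[, , , tr, drop = FALSE],
                    enc$labels$class[tr],
                    lambda = cfg$network$lambda,
                    max_iters = cfg$network$max_iters,
                    target_error = cfg$network$target_error,
                    loss = cfg$network$loss,
                    lr_halving = cfg$network$lr_halving,
                    verbose = verbose)
  structure(list(params = fit$params, trace = fit$trace,
                 converged = fit$converged, iters = fit$iters,
                 norm = enc$norm, bank = enc$bank, config = cfg),
            class = "stereoslant_model")
}

#' @export
print.stereoslant_model <- function(x, ...) {
  cat("stereoslant_model: trained", x$iters, "iterations, final E =",
      signif(utils::tail(x$trace, 1), 4),
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

#' Evaluate a trained model on a dataset split
#'
#' @param model a [train_pipeline()] model.
#' @param enc the encoded features.
#' @param split `"test"`, `"train"` or `"all"`.
#' @param active_gazes optional gaze subset.
#' @return as [evaluate_network()], plus the example indices used.
#' @export
evaluate_split <- function(model, enc, split = "test", active_gazes = NULL) {
  idx <- if (split == "all") seq_len(nrow(enc$labels)) else
    which(enc$labels$split == split)
  ev <- evaluate_network(model$params, enc$Z[, , , idx, drop = FALSE],
                         enc$labels$class[idx], active_gazes)
  ev$indices <- idx
  ev
}

# Masked (normalized-convolution) separable Gaussian smoothing: each output
# is the Gaussian-weighted average of the valid samples only, so neither NA
# nor the support boundary biases the result where data exist.
masked_smooth <- function(M, valid, S) {
  V <- valid * 1
  Md <- M; Md[!valid] <- 0
  num <- S %*% Md %*% t(S)
  den <- S %*% V %*% t(S)
  out <- num / pmax(den, 1e-12)
  out[den < 1e-6] <- 0
  out
}

#' Input-smoothing robustness sweep
#'
#' De-noises the disparity input with Gaussian filters of increasing
#' standard deviation, then re-encodes and classifies with the trained
#' weights.  The disparity input is the stimulus plane's field, which
#' extends well beyond the sensor crop, so the smoothing is evaluated on an
#' extended field (computed over roughly twice the sensor's field of view,
#' masked-normalized over the plane's support) and the central sensor
#' window is cropped afterwards; the stereo pair is then re-synthesized
#' from the smoothed field with the original texture seed.  SDs are given
#' in arcmin of visual angle and converted to pixels through the pinhole
#' intrinsics, so the sweep is resolution independent.
#'
#' @param model trained model.
#' @param ds the dataset (fields and texture seeds kept).
#' @param sd_values Gaussian SDs (arcmin of visual angle).
#' @param split evaluation split.
#' @param indices optional explicit orientation indices (overrides split).
#' @param progress print one line per SD value.
#' @return list: `accuracy` (n_sd x n_classes matrix of per-class
#'   accuracies), `overall` (n_sd), `sd_values`, `per_class_mean` (averaged
#'   over the sweep), and `min_class_accuracy`.
#' @export
denoise_sweep <- function(model, ds, sd_values, split = "test",
                          indices = NULL, progress = FALSE) {
  cfg <- model$config
  px <- cfg$geometry$image_px
  bank <- model$bank
  filters <- bank_filters(bank, c(px, px))
  idx <- indices %||% which(ds$labels$split == split)
  n_gz <- nrow(ds$gazes$directions)
  n_cl <- model$params$n_classes
  # extended grid: same pixel pitch, ~2x the sensor on each side, centers
  # aligned with the original grid (both odd)
  px_ext <- 2 * px + 1
  off <- (px_ext - px) / 2
  keep <- off + seq_len(px)
  # precompute the extended fields once; they are SD independent
  fields <- lapply(idx, function(i) lapply(seq_len(n_gz), function(q) {
    sp0 <- ds$pairs[[i]][[q]]
    if (is.null(sp0$plane) || is.null(sp0$pose)) return(NULL)
    disparity_field(sp0$plane, sp0$pose, px = px_ext,
                    focal_mm = sp0$field$focal_mm,
                    sensor_mm = sp0$field$sensor_mm * px_ext / px)
  }))
  acc <- matrix(NA_real_, length(sd_values), n_cl,
                dimnames = list(NULL, paste0("class", seq_len(n_cl))))
  overall <- numeric(length(sd_values))
  # arcmin -> pixels at the rendering resolution (small-angle, image center)
  px_per_arcmin <- (pi / 180 / 60) *
    cfg$geometry$focal_length_mm / cfg$geometry$sensor_mm * px
  for (si in seq_along(sd_values)) {
    sd_px <- sd_values[si] * px_per_arcmin
    S <- smooth_mat(px_ext, sd_px)
    FS <- NULL
    for (ii in seq_along(idx)) {
      for (q in seq_len(n_gz)) {
        sp0 <- ds$pairs[[idx[ii]]][[q]]
        f <- sp0$field
        fe <- fields[[ii]][[q]]
        if (is.null(fe)) {          # synthetic field: smooth in place
          f$delta1 <- masked_smooth(f$delta1, f$valid, smooth_mat(px, sd_px))
          f$delta2 <- masked_smooth(f$delta2, f$valid, smooth_mat(px, sd_px))
        } else {
          # extended fields are in their own normalized units; the pixel
          # pitch matches, so rescale to the original sensor fraction
          scl <- px_ext / px
          f$delta1 <- masked_smooth(fe$delta1, fe$valid, S)[keep, keep] * scl
          f$delta2 <- masked_smooth(fe$delta2, fe$valid, S)[keep, keep] * scl
        }
        sp <- render_stereo_pair(texture_seed = sp0$texture_seed,
                                 density = cfg$texture$density, field = f)
        pop <- population_response(sp, bank, pool_to = cfg$bank$pool_to,
                                   filters = filters)
        fz <- preprocess_gaze(pop, scale_s = cfg$differentials$scale_s)
        if (is.null(FS)) FS <- array(0, dim = c(dim(fz), n_gz, length(idx)))
        FS[, , , , , q, ii] <- fz
      }
    }
    nf <- normalize_features(FS, params = model$norm)
    Z <- features_to_input(nf$FS)
    ev <- evaluate_network(model$params, Z, ds$labels$class[idx])
    acc[si, ] <- ev$per_class
    overall[si] <- ev$overall
    if (progress)
      message(sprintf("denoise SD %.1f arcmin: accuracy %.3f",
                      sd_values[si], overall[si]))
  }
  per_class_mean <- colMeans(acc)
  list(accuracy = acc, overall = overall, sd_values = sd_values,
       per_class_mean = per_class_mean,
       min_class_accuracy = min(per_class_mean, na.rm = TRUE))
}

#' Run the full pipeline: generate, encode, train, evaluate
#'
#' @param config a [stereoslant_config()] (or overrides).
#' @param denoise_sds optional SD sweep for the robustness evaluation.
#' @param gaze_orderings orderings for the accuracy-vs-gaze-count curve
#'   (0 skips it).
#' @param scanpath_rate classification-rate criterion for the active-gaze
#'   summary (NULL skips it).
#' @param out_dir optional output directory: writes `report.json`,
#'   `manifest.csv` and `loss.csv`.
#' @param progress verbose progress.
#' @return A report list: per-class and overall train/test accuracies,
#'   loss trace summary, gaze-count curve, optional robustness sweep and
#'   scanpath summary, and the config (with all seeds).
#' @export
run_pipeline <- function(config = stereoslant_config(), denoise_sds = NULL,
                         gaze_orderings = 10, scanpath_rate = 0.75,
                         out_dir = NULL, progress = FALSE) {
  cfg <- stereoslant_config(config)
  ds <- generate_dataset(cfg, progress = progress)
  enc <- encode_dataset(ds, progress = progress)
  model <- train_pipeline(enc, verbose = progress)
  ev_tr <- evaluate_split(model, enc, "train")
  has_test <- any(enc$labels$split == "test")
  ev_te <- if (has_test) evaluate_split(model, enc, "test") else ev_tr
  te_idx <- ev_te$indices
  report <- list(
    config = cfg,
    n_orientations = nrow(enc$labels),
    n_pairs = nrow(enc$labels) * dim(enc$Z)[3],
    train = list(overall = ev_tr$overall, per_class = ev_tr$per_class),
    test = list(overall = ev_te$overall, per_class = ev_te$per_class),
    final_error = utils::tail(model$trace, 1),
    iters = model$iters, converged = model$converged
  )
  if (gaze_orderings > 0) {
    report$gaze_curve <- gaze_count_accuracy(
      model$params, enc$Z[, , , te_idx, drop = FALSE],
      enc$labels$class[te_idx], n_orderings = gaze_orderings,
      seed = cfg$seeds$master + 3L)
  }
  if (!is.null(scanpath_rate)) {
    sp <- scanpath_to_rate(model$params, enc$Z[, , , te_idx, drop = FALSE],
                           enc$labels$class[te_idx], rate = scanpath_rate)
    report$scanpath <- list(rate = scanpath_rate, lengths = sp$lengths,
                            median = sp$median)
  }
  if (!is.null(denoise_sds)) {
    report$denoise <- denoise_sweep(model, ds, denoise_sds,
                                    progress = progress)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report), "config")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(cfg, file.path(out_dir, "config.yaml"))
    utils::write.csv(dataset_manifest(ds),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(data.frame(iter = seq_along(model$trace),
                                loss = model$trace),
                     file.path(out_dir, "loss.csv"), row.names = FALSE)
  }
  attr(report, "model") <- model
  attr(report, "dataset") <- ds
  attr(report, "encoded") <- enc
  report
}

#' Save / load pipeline artifacts
#'
#' Thin wrappers around R-native serialization for datasets, encoded
#' features and trained models.
#'
#' @param x object to save.
#' @param path file path (.rds).
#' @export
save_artifact <- function(x, path) { saveRDS(x, path); invisible(path) }

#' @rdname save_artifact
#' @export
load_artifact <- function(path) readRDS(path)
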