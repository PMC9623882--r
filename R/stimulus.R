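# Stimulus dataset: the slant/tilt orientation grid, the 3x3 gaze grid,
# random-dot stereo pairs with ground-truth disparity fields, nine-way
# orientation class labels, and the packaged train/test dataset.

#' Orientation sampling grid
#'
#' Evenly spaced slant and tilt values spanning closed ranges; the default
#' reproduces the 12 x 12 grid (slants 4..48 deg step 4, tilts 30..360 deg
#' step 30) whose 144 pairs form the simulation dataset.
#'
#' @param n_slant,n_tilt number of samples per axis.
#' @param slant_range,tilt_range closed ranges (deg).
#' @return An `orientation_grid`: `slants`, `tilts`, and a data.frame
#'   `pairs` with columns `sigma`, `tau`.
#' @export
build_orientation_grid <- function(n_slant = 12, n_tilt = 12,
                                   slant_range = c(4, 48),
                                   tilt_range = c(30, 360)) {
  stopifnot(n_slant >= 1, n_tilt >= 1)
  if ((n_slant > 1 && diff(slant_range) <= 0) ||
      (n_tilt > 1 && diff(tilt_range) <= 0))
    stop("degenerate range with more than one sample")
  slants <- if (n_slant == 1) slant_range[1] else
    seq(slant_range[1], slant_range[2], length.out = n_slant)
  tilts <- if (n_tilt == 1) tilt_range[1] else
    seq(tilt_range[1], tilt_range[2], length.out = n_tilt)
  pairs <- expand.grid(sigma = slants, tau = tilts, KEEP.OUT.ATTRS = FALSE)
  structure(list(slants = slants, tilts = tilts,
                 slant_range = slant_range, tilt_range = tilt_range,
                 pairs = pairs),
            class = "orientation_grid")
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat("orientation_grid:", length(x$slants), "slants x", length(x$tilts),
      "tilts =", nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' 3x3 grid of gaze directions
#'
#' @param offsets azimuth/elevation offsets (deg) applied on both axes.
#' @param center central gaze direction (alpha0, epsilon0) in deg.
#' @return A `gaze_grid` with a data.frame `directions` (alpha, epsilon).
#' @export
gaze_grid <- function(offsets = c(-5, 0, 5), center = c(0, 0)) {
  d <- expand.grid(d_alpha = offsets, d_epsilon = offsets,
                   KEEP.OUT.ATTRS = FALSE)
  structure(list(offsets = offsets, center = center,
                 directions = data.frame(alpha = center[1] + d$d_alpha,
                                         epsilon = center[2] + d$d_epsilon)),
            class = "gaze_grid")
}

#' Nine-way orientation class of a slant/tilt pair
#'
#' Splits the slant range and the tilt range into three equal-width bins and
#' assigns `class_id = 3 * (tilt_bin - 1) + slant_bin`, so classes {1, 4, 7}
#' form the low-slant "inner ring" and {3, 6, 9} the high-slant "outer ring".
#'
#' @param sigma,tau slant and tilt (deg); vectorized.
#' @param grid the [build_orientation_grid()] whose ranges define the bins.
#' @return integer class ids in 1..9, with attributes `slant_bin`
#'   (inner/middle/outer) and `tilt_bin`.
#' @export
assign_class <- function(sigma, tau, grid) {
  se <- seq(grid$slant_range[1], grid$slant_range[2], length.out = 4)
  te <- seq(grid$tilt_range[1], grid$tilt_range[2], length.out = 4)
  if (any(sigma < se[1] - 1e-9 | sigma > se[4] + 1e-9 |
          tau < te[1] - 1e-9 | tau > te[4] + 1e-9))
    stop("orientation outside the grid ranges")
  sb <- pmin(findInterval(sigma, se, rightmost.closed = TRUE), 3L)
  tb <- pmin(findInterval(tau, te, rightmost.closed = TRUE), 3L)
  out <- 3L * (tb - 1L) + sb
  attr(out, "slant_bin") <- c("inner", "middle", "outer")[sb]
  attr(out, "tilt_bin") <- tb
  out
}

# Fixation point for a cyclopean gaze direction: the intersection of the
# cyclopean ray with the plane.
fixation_on_plane <- function(plane, alpha, epsilon) {
  dir <- gaze_direction(alpha, epsilon)
  denom <- sum(plane$normal * dir)
  if (abs(denom) < 1e-9) stop("gaze direction parallel to the plane")
  tt <- sum(plane$normal * plane$center) / denom
  if (tt <= 0) stop("plane behind the observer for this gaze direction")
  tt * dir
}

#' Render a random-dot stereo pair of an oriented plane
#'
#' The plane carries a dense random-dot texture: dots are anchored at random
#' continuous positions of the cyclopean image, carried to the 3D plane by
#' the cyclopean ray, and their exact left/right pinhole projections are
#' splatted with anti-aliased bilinear footprints into the two images.  The
#' per-dot projections are read from the ground-truth disparity and
#' mean-offset fields by bilinear interpolation, which makes re-rendering
#' from a (possibly filtered) disparity field exactly consistent with the
#' original rendering.
#'
#' @param plane a [plane_stimulus()]; ignored if `field` is supplied.
#' @param pose a [fixate()] pose; ignored if `field` is supplied.
#' @param texture_seed integer seed; same seed, same parameters give
#'   bit-identical images.
#' @param px image resolution (pixels per side).
#' @param focal_mm,sensor_mm camera intrinsics (mm).
#' @param density dot density (dots per pixel of image area).
#' @param field optional precomputed `disparity_field` (e.g. a smoothed one)
#'   used in place of the geometric one.
#' @return A `stereo_pair`: `left`, `right` (px x px matrices, first index =
#'   x1), the field used, and the generating parameters.
#' @export
render_stereo_pair <- function(plane = NULL, pose = NULL, texture_seed = 1,
                               px = 123, focal_mm = 350, sensor_mm = 210,
                               density = 0.5, field = NULL) {
  if (is.null(field)) {
    stopifnot(!is.null(plane), !is.null(pose))
    field <- disparity_field(plane, pose, px = px, focal_mm = focal_mm,
                             sensor_mm = sensor_mm)
  }
  px <- field$px
  if (!any(field$valid)) stop("plane fully outside the viewing frustum")
  n_dots <- max(1L, round(density * px * px))
  dots <- with_seed(texture_seed, {
    cbind(stats::runif(n_dots, 0.5, px + 0.5),
          stats::runif(n_dots, 0.5, px + 0.5))
  })
  d1 <- bilinear_interp(field$delta1, dots[, 1], dots[, 2], field$valid)
  d2 <- bilinear_interp(field$delta2, dots[, 1], dots[, 2], field$valid)
  m1 <- bilinear_interp(field$mu1, dots[, 1], dots[, 2], field$valid)
  m2 <- bilinear_interp(field$mu2, dots[, 1], dots[, 2], field$valid)
  ok <- !is.na(d1)
  if (!any(ok)) stop("no texture dots fall on the visible plane")
  # positions in pixel units; fields are stored in normalized units
  scl <- if (field$units == "norm") px else 1
  xc1 <- dots[ok, 1]; xc2 <- dots[ok, 2]
  l1 <- xc1 + (m1[ok] - d1[ok] / 2) * scl
  l2 <- xc2 + (m2[ok] - d2[ok] / 2) * scl
  r1 <- xc1 + (m1[ok] + d1[ok] / 2) * scl
  r2 <- xc2 + (m2[ok] + d2[ok] / 2) * scl
  structure(list(left = bilinear_splat(l1, l2, px, px),
                 right = bilinear_splat(r1, r2, px, px),
                 field = field, texture_seed = texture_seed, px = px,
                 focal_mm = field$focal_mm, sensor_mm = field$sensor_mm,
                 plane = field$plane, pose = field$pose),
            class = "stereo_pair")
}

#' Uniform- or synthetic-disparity random-dot stereogram
#'
#' Convenience wrapper: builds a `stereo_pair` from an explicit disparity
#' field given in pixels (e.g. a constant field for tuning probes or a
#' linear field for differential-component probes).
#'
#' @param delta1,delta2 disparity component matrices in pixels, or scalars
#'   (expanded to uniform fields).
#' @param px image size, required when scalars are given.
#' @param texture_seed,density as in [render_stereo_pair()].
#' @return A `stereo_pair`.
#' @export
synthetic_rds <- function(delta1, delta2, px = NULL, texture_seed = 1,
                          density = 0.5) {
  if (is.null(dim(delta1))) {
    stopifnot(!is.null(px))
    delta1 <- matrix(delta1, px, px)
    delta2 <- matrix(delta2, px, px)
  }
  f <- make_disparity_field(delta1, delta2)
  render_stereo_pair(texture_seed = texture_seed, density = density,
                     field = f)
}

derive_texture_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 104729 + index * 7919) %% 2147483647)
}

#' Generate the packaged slant/tilt stereo dataset
#'
#' For every (orientation, gaze) combination: fixates the intersection of
#' the cyclopean gaze ray with the plane, computes the ground-truth
#' disparity field, and renders the random-dot stereo pair.  Orientation
#' pairs are split 70/30 into train/test, stratified by class, with all nine
#' gazes of a pair kept together.
#'
#' @param config a [stereoslant_config()] list (or overrides for one).
#' @param keep_images,keep_fields drop the heavy arrays when FALSE (labels,
#'   seeds and counts are always kept).
#' @param progress print a line every 25 orientations.
#' @return A `stereo_dataset`: `config`, `grid`, `gazes`, a `labels`
#'   data.frame (index, sigma, tau, class, split), and `pairs`, a list (one
#'   element per orientation) of lists (one per gaze) of `stereo_pair`s.
#' @export
generate_dataset <- function(config = stereoslant_config(),
                             keep_images = TRUE, keep_fields = TRUE,
                             progress = FALSE) {
  cfg <- stereoslant_config(config)
  grid <- build_orientation_grid(cfg$grid$n_slant, cfg$grid$n_tilt,
                                 cfg$grid$slant_range, cfg$grid$tilt_range)
  gz <- gaze_grid(cfg$gazes$offsets, cfg$gazes$center)
  n_or <- nrow(grid$pairs); n_gz <- nrow(gz$directions)
  cls <- assign_class(grid$pairs$sigma, grid$pairs$tau, grid)
  split <- rep("train", n_or)
  test_idx <- with_seed(cfg$seeds$master + 1L, {
    unlist(lapply(sort(unique(as.integer(cls))), function(cl) {
      members <- which(as.integer(cls) == cl)
      n_test <- round((1 - cfg$split$train_frac) * length(members))
      if (n_test >= 1) sample(members, n_test) else integer(0)
    }))
  })
  split[test_idx] <- "test"
  labels <- data.frame(index = seq_len(n_or), sigma = grid$pairs$sigma,
                       tau = grid$pairs$tau, class = as.integer(cls),
                       split = split)
  pairs <- vector("list", n_or)
  for (i in seq_len(n_or)) {
    pl <- plane_stimulus(grid$pairs$sigma[i], grid$pairs$tau[i],
                         center = c(0, 0, cfg$geometry$fixation_distance_mm),
                         extent_deg = cfg$plane$extent_deg)
    per_gaze <- vector("list", n_gz)
    for (q in seq_len(n_gz)) {
      al <- gz$directions$alpha[q]; ep <- gz$directions$epsilon[q]
      target <- fixation_on_plane(pl, al, ep)
      pose <- fixate(target, baseline = cfg$geometry$baseline_mm,
                     torsion_mode = cfg$geometry$torsion_mode)
      seed_iq <- derive_texture_seed(cfg$seeds$master, (i - 1L) * n_gz + q)
      sp <- render_stereo_pair(pl, pose, texture_seed = seed_iq,
                               px = cfg$geometry$image_px,
                               focal_mm = cfg$geometry$focal_length_mm,
                               sensor_mm = cfg$geometry$sensor_mm,
                               density = cfg$texture$density)
      sp$gaze <- c(alpha = al, epsilon = ep)
      if (!keep_images) sp$left <- sp$right <- NULL
      if (!keep_fields) sp$field <- NULL
      per_gaze[[q]] <- sp
    }
    pairs[[i]] <- per_gaze
    if (progress && i %% 25 == 0)
      message("generated ", i, "/", n_or, " orientations")
  }
  structure(list(config = cfg, grid = grid, gazes = gz, labels = labels,
                 pairs = pairs),
            class = "stereo_dataset")
}

#' @export
print.stereo_dataset <- function(x, ...) {
  cat("stereo_dataset:", nrow(x$labels), "orientations x",
      nrow(x$gazes$directions), "gazes =",
      nrow(x$labels) * nrow(x$gazes$directions), "stereo pairs\n")
  cat("  train/test:", sum(x$labels$split == "train"), "/",
      sum(x$labels$split == "test"), "orientation pairs\n")
  invisible(x)
}

#' Manifest table of a dataset
#'
#' @param ds a `stereo_dataset`.
#' @return data.frame with one row per (orientation, gaze) pair.
#' @export
dataset_manifest <- function(ds) {
  n_gz <- nrow(ds$gazes$directions)
  do.call(rbind, lapply(seq_len(nrow(ds$labels)), function(i) {
    data.frame(index = i, gaze = seq_len(n_gz),
               sigma = ds$labels$sigma[i], tau = ds$labels$tau[i],
               alpha = ds$gazes$directions$alpha,
               epsilon = ds$gazes$directions$epsilon,
               class = ds$labels$class[i], split = ds$labels$split[i],
               texture_seed = vapply(seq_len(n_gz), function(q)
                 ds$pairs[[i]][[q]]$texture_seed, numeric(1)))
  }))
}
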