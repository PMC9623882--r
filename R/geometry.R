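# Vergent binocular viewing geometry: eye kinematics, toe-in pinhole
# projection, oriented planes, and ground-truth vector disparity fields.
#
# Conventions (head-centric, right-handed):
#   +X rightward (along the baseline), +Y upward, +Z straight ahead into the
#   scene.  At primary position an eye's optical axis is +Z; image coordinate
#   x1 increases rightward (+X) and x2 upward (+Y).  Helmholtz angles: the
#   full eye rotation is R = R_eps %*% R_alpha (elevation composed outside
#   azimuth), positive alpha turning the gaze toward +X and positive epsilon
#   toward +Y.  Image coordinates are "normalized" units: sensor fractions
#   (mm on the sensor divided by the sensor size).

#' Gaze direction for Helmholtz azimuth/elevation angles
#'
#' @param alpha azimuth (deg), positive toward +X.
#' @param epsilon elevation (deg), positive toward +Y.
#' @return unit 3-vector in head coordinates.
#' @export
gaze_direction <- function(alpha, epsilon) {
  a <- deg2rad(alpha); e <- deg2rad(epsilon)
  c(sin(a), sin(e) * cos(a), cos(e) * cos(a))
}

helmholtz_rotation <- function(alpha_rad, epsilon_rad) {
  rot_x(-epsilon_rad) %*% rot_y(alpha_rad)
}

# Helmholtz angles aiming the optical axis (+Z of the rotated frame) from
# `origin` at `target`.
aim_angles <- function(target, origin) {
  d <- target - origin
  if (sqrt(d[2]^2 + d[3]^2) < 1e-9)
    stop("degenerate fixation target: on (or collinear with) the baseline; ",
         "vergence geometry is undefined")
  alpha <- atan2(d[1], sqrt(d[2]^2 + d[3]^2))
  epsilon <- atan2(d[2], d[3])
  c(alpha = alpha, epsilon = epsilon)
}

# Binocular Listing (L2) torsion: each eye's orientation is the single-axis
# rotation from a primary direction that is itself rotated temporally by half
# the vergence angle (the half-angle extension of Listing's law to a verging
# eye pair).  Returns the torsion angle gamma (about the gaze line) that
# carries the Helmholtz orientation into the L2 orientation.
l2_torsion <- function(R_helm, origin, target, side) {
  gaze <- unitv(target - origin)
  b2 <- abs(origin[1])
  # vergence angle between the two lines of sight
  gL <- unitv(target - c(-b2, origin[2], origin[3]))
  gR <- unitv(target - c(b2, origin[2], origin[3]))
  mu <- acos(pmin(1, pmax(-1, sum(gL * gR))))
  sgn <- if (side == "L") -1 else 1          # temporal: -X for L, +X for R
  prim <- as.vector(rot_y(sgn * mu / 2) %*% c(0, 0, 1))
  ax <- pracma_cross(prim, gaze)
  R_l2 <- if (vnorm(ax) < 1e-12) diag(3) else
    rot_axis(ax, acos(pmin(1, pmax(-1, sum(prim * gaze)))))
  R_l2 <- R_l2 %*% rot_y(sgn * mu / 2)
  # R_l2 and R_helm share the gaze direction, so their difference is a pure
  # rotation about it; extract its signed angle.
  D <- R_l2 %*% t(R_helm)
  up <- unitv(pracma_cross(gaze, c(1, 0, 0)))
  v <- as.vector(D %*% up)
  gamma <- atan2(sum(pracma_cross(up, v) * gaze), sum(up * v))
  list(gamma = gamma, R = D %*% R_helm)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fixate a target with a vergent binocular head
#'
#' Builds the binocular pose of a toe-in camera pair separated by `baseline`
#' mm, each eye rotated through Helmholtz azimuth/elevation so that its
#' optical axis passes through `target`; optionally adds binocular Listing
#' (L2) torsion about the gaze lines.
#'
#' @param target fixation point, 3-vector (mm, head-centric); must lie off
#'   the interocular axis with positive Z.
#' @param baseline interocular distance b (mm); eyes sit at (+/- b/2, 0, 0).
#' @param torsion_mode `"none"` (Helmholtz orientation only, the default) or
#'   `"L2"` (pre-multiply by the half-angle Listing torsion).
#' @return An object of class `binocular_pose`: per-eye rotation matrices,
#'   origins, Helmholtz angles (deg), torsion angles (deg), plus the
#'   cyclopean eye (head origin, aimed at the target).
#' @export
fixate <- function(target, baseline = 60, torsion_mode = c("none", "L2")) {
  torsion_mode <- match.arg(torsion_mode)
  target <- as.numeric(target)
  stopifnot(length(target) == 3)
  if (target[3] <= 0)
    stop("fixation target must have positive Z (in front of the head)")
  b2 <- baseline / 2
  origins <- list(L = c(-b2, 0, 0), R = c(b2, 0, 0), C = c(0, 0, 0))
  eyes <- lapply(c(L = "L", R = "R", C = "C"), function(side) {
    o <- origins[[side]]
    ang <- aim_angles(target, o)
    R <- helmholtz_rotation(ang["alpha"], ang["epsilon"])
    gamma <- 0
    if (torsion_mode == "L2" && side != "C") {
      tw <- l2_torsion(R, o, target, side)
      gamma <- tw$gamma
      R <- tw$R
    }
    list(origin = o, R = R, alpha = rad2deg(ang[["alpha"]]),
         epsilon = rad2deg(ang[["epsilon"]]), gamma = rad2deg(gamma))
  })
  structure(list(fixation_point = target, baseline = baseline,
                 torsion_mode = torsion_mode, L = eyes$L, R = eyes$R,
                 C = eyes$C),
            class = "binocular_pose")
}

#' @export
print.binocular_pose <- function(x, ...) {
  cat("binocular_pose: b =", x$baseline, "mm, torsion =", x$torsion_mode, "\n")
  cat(sprintf("  fixation (%.1f, %.1f, %.1f) mm\n", x$fixation_point[1],
              x$fixation_point[2], x$fixation_point[3]))
  cat(sprintf("  alpha L/R = %+.3f/%+.3f deg, epsilon L/R = %+.3f/%+.3f deg\n",
              x$L$alpha, x$R$alpha, x$L$epsilon, x$R$epsilon))
  invisible(x)
}

#' Pinhole projection into one eye of a binocular pose
#'
#' Projects head-centric points into the image plane of the left, right, or
#' cyclopean eye.  Image coordinates are in normalized units (fractions of
#' the sensor size); x1 is rightward, x2 upward, (0, 0) at the image center.
#'
#' @param points 3-vector or n x 3 matrix of points (mm).
#' @param pose a [fixate()] pose.
#' @param eye `"L"`, `"R"` or `"cyclopean"`.
#' @param focal_mm,sensor_mm pinhole focal length and sensor size (mm).
#' @return 2-vector or n x 2 matrix of image coordinates.
#' @export
project <- function(points, pose, eye = c("L", "R", "cyclopean"),
                    focal_mm = 350, sensor_mm = 210) {
  eye <- match.arg(eye)
  key <- if (eye == "cyclopean") "C" else eye
  P <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  cam <- pose[[key]]
  E <- sweep(P, 2, cam$origin) %*% cam$R   # rows: t(R) %*% (p - o)
  if (any(E[, 3] <= 1e-9))
    stop("point at or behind the ", eye, " eye's image plane")
  out <- (focal_mm / sensor_mm) * E[, 1:2, drop = FALSE] / E[, 3]
  colnames(out) <- c("x1", "x2")
  if (is.null(dim(points))) out[1, ] else out
}

#' Oriented planar stimulus
#'
#' A planar disk parameterized by slant/tilt: the surface rotation is
#' `R = R_tau %*% R_sigma` with slant sigma a rotation about Y and tilt tau a
#' rotation about the line of sight Z, so the unit normal is
#' (sin s cos t, sin s sin t, cos s).  Slant-zero planes are therefore
#' frontoparallel for every tilt.
#'
#' @param slant,tilt orientation angles (deg).
#' @param center plane center P0 (mm), default (0, 0, 350).
#' @param extent_deg angular diameter of the disk as seen from the head
#'   origin (deg of visual angle).
#' @return An object of class `plane_stimulus`.
#' @export
plane_stimulus <- function(slant, tilt, center = c(0, 0, 350),
                           extent_deg = 50) {
  Rm <- rot_z(deg2rad(tilt)) %*% rot_y(deg2rad(slant))
  structure(list(slant = slant, tilt = tilt, center = as.numeric(center),
                 extent_deg = extent_deg,
                 radius = vnorm(center) * tan(deg2rad(extent_deg) / 2),
                 rotation = Rm, normal = as.vector(Rm %*% c(0, 0, 1))),
            class = "plane_stimulus")
}

#' @export
print.plane_stimulus <- function(x, ...) {
  cat(sprintf("plane_stimulus: slant %.1f deg, tilt %.1f deg, center (%g, %g, %g) mm, extent %g deg\n",
              x$slant, x$tilt, x$center[1], x$center[2], x$center[3],
              x$extent_deg))
  invisible(x)
}

# Intersect rays from `origin` (single point) along rows of `dirs` with the
# plane; returns n x 3 points with NA rows for misses.
ray_plane <- function(origin, dirs, plane) {
  n <- plane$normal
  denom <- dirs %*% n
  num <- sum(n * (plane$center - origin))
  tt <- ifelse(abs(denom) < 1e-12, NA_real_, num / denom)
  tt[!is.na(tt) & tt <= 0] <- NA_real_
  P <- dirs * as.vector(tt)
  P <- sweep(P, 2, -origin)       # origin + t * dir
  d2 <- rowSums(sweep(P, 2, plane$center)^2)
  P[which(!is.na(d2) & d2 > plane$radius^2), ] <- NA_real_
  P
}

# Centered pixel coordinates (in normalized image units) of an n-pixel axis.
pixel_axis <- function(px) (seq_len(px) - (px + 1) / 2) / px

#' Ground-truth vector disparity field of a plane under a binocular pose
#'
#' For every cyclopean pixel, casts the cyclopean ray, intersects it with the
#' plane, projects the intersection into both eyes and records the
#' left/right image coordinate differences `delta = (x1R - x1L, x2R - x2L)`
#' in normalized image units.  Also records the mean-offset fields
#' `mu = (xL + xR)/2 - x_cyc` used by the renderer.  Pixels whose ray misses
#' the plane (or falls behind an eye) are masked invalid.
#'
#' @param plane a [plane_stimulus()].
#' @param pose a [fixate()] pose.
#' @param px image resolution (pixels per side).
#' @param focal_mm,sensor_mm camera intrinsics (mm).
#' @return An object of class `disparity_field` with matrices `delta1`,
#'   `delta2`, `mu1`, `mu2` (px x px, first index = x1), logical `valid`,
#'   and the generating pose/plane.  `spacing` is the pixel pitch in
#'   normalized units (1/px).
#' @export
disparity_field <- function(plane, pose, px = 123, focal_mm = 350,
                            sensor_mm = 210) {
  ax <- pixel_axis(px)
  x1 <- matrix(ax, px, px)
  x2 <- matrix(ax, px, px, byrow = TRUE)
  sf <- sensor_mm / focal_mm
  dirs_cam <- cbind(as.vector(x1) * sf, as.vector(x2) * sf, 1)
  dirs <- dirs_cam %*% t(pose$C$R)
  P <- ray_plane(pose$C$origin, dirs, plane)
  ok <- !is.na(P[, 1])
  if (!any(ok)) stop("plane does not intersect the cyclopean viewing frustum")
  proj_eye <- function(key) {
    cam <- pose[[key]]
    E <- sweep(P[ok, , drop = FALSE], 2, cam$origin) %*% cam$R
    bad <- E[, 3] <= 1e-9
    out <- (focal_mm / sensor_mm) * E[, 1:2, drop = FALSE] / E[, 3]
    out[bad, ] <- NA_real_
    out
  }
  xl <- proj_eye("L"); xr <- proj_eye("R")
  full <- function(v) {
    m <- rep(NA_real_, px * px); m[ok] <- v; matrix(m, px, px)
  }
  d1 <- full(xr[, 1] - xl[, 1]); d2 <- full(xr[, 2] - xl[, 2])
  m1 <- full((xr[, 1] + xl[, 1]) / 2 - as.vector(x1)[ok])
  m2 <- full((xr[, 2] + xl[, 2]) / 2 - as.vector(x2)[ok])
  valid <- !is.na(d1) & !is.na(d2)
  structure(list(delta1 = d1, delta2 = d2, mu1 = m1, mu2 = m2,
                 valid = valid, px = px, spacing = 1 / px,
                 units = "norm", focal_mm = focal_mm, sensor_mm = sensor_mm,
                 pose = pose, plane = plane),
            class = "disparity_field")
}

#' Construct a disparity field from explicit component matrices
#'
#' Mainly for synthetic test fields; `spacing` is the grid step used by
#' [analytic_jacobian()] (1 means "per pixel").
#'
#' @param delta1,delta2 component matrices (first index = x1).
#' @param spacing grid step.
#' @param valid optional logical mask.
#' @return A `disparity_field`.
#' @export
make_disparity_field <- function(delta1, delta2, spacing = 1, valid = NULL) {
  stopifnot(all(dim(delta1) == dim(delta2)))
  if (is.null(valid)) valid <- is.finite(delta1) & is.finite(delta2)
  z <- matrix(0, nrow(delta1), ncol(delta1))
  structure(list(delta1 = delta1, delta2 = delta2, mu1 = z, mu2 = z,
                 valid = valid, px = nrow(delta1), spacing = spacing,
                 units = "px", focal_mm = NA, sensor_mm = NA,
                 pose = NULL, plane = NULL),
            class = "disparity_field")
}

#' First-order differential components of a disparity field
#'
#' Central finite differences of (delta1, delta2), combined into the four
#' elementary components of the field's Jacobian:
#' div = d1/dx1 + d2/dx2, rot = d2/dx1 - d1/dx2,
#' def1 = d2/dx1 + d1/dx2, def2 = d1/dx1 - d2/dx2.
#' Serves as the ground-truth oracle for the population-based differentials.
#'
#' @param field a `disparity_field`.
#' @param spacing grid step; defaults to the field's own.
#' @return list of matrices `div`, `rot`, `def1`, `def2` (NA on the one-pixel
#'   frame and wherever a 3x3 neighbourhood is not valid).
#' @export
analytic_jacobian <- function(field, spacing = NULL) {
  stopifnot(inherits(field, "disparity_field"))
  h <- spacing %||% field$spacing
  v <- field$valid
  if (sum(v) < 9) stop("need at least a 3x3 block of valid pixels")
  n1 <- nrow(v); n2 <- ncol(v)
  cd <- function(M, along) {
    out <- matrix(NA_real_, n1, n2)
    if (along == 1) {
      out[2:(n1 - 1), ] <- (M[3:n1, ] - M[1:(n1 - 2), ]) / (2 * h)
    } else {
      out[, 2:(n2 - 1)] <- (M[, 3:n2] - M[, 1:(n2 - 2)]) / (2 * h)
    }
    out
  }
  okn <- v
  okn[2:(n1 - 1), ] <- okn[2:(n1 - 1), ] & v[1:(n1 - 2), ] & v[3:n1, ]
  okn[, 2:(n2 - 1)] <- okn[, 2:(n2 - 1)] & v[, 1:(n2 - 2)] & v[, 3:n2]
  okn[c(1, n1), ] <- FALSE; okn[, c(1, n2)] <- FALSE
  d11 <- cd(field$delta1, 1); d12 <- cd(field$delta1, 2)
  d21 <- cd(field$delta2, 1); d22 <- cd(field$delta2, 2)
  mask <- function(M) { M[!okn] <- NA_real_; M }
  list(div = mask(d11 + d22), rot = mask(d21 - d12),
       def1 = mask(d21 + d12), def2 = mask(d11 - d22))
}

#' Convert normalized-unit disparities to degrees of visual angle
#'
#' @param delta disparity in normalized image units (sensor fractions).
#' @param focal_mm,sensor_mm camera intrinsics (mm).
#' @return disparity in degrees (small-angle exact at the image center).
#' @export
disparity_to_deg <- function(delta, focal_mm = 350, sensor_mm = 210) {
  rad2deg(atan(delta * sensor_mm / focal_mm))
}
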