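# Distributed representation of first-order disparity-field differentials:
# scale-space directional derivatives of the population activity, combined
# per direction-pair channel into div / rot / def1 / def2 maps.
#
# Each direction pair k couples the channels tuned along theta_k and
# theta_k + pi/2 (with M = 8 orientations: k at 0, pi/8, pi/4, 3pi/8).  The
# derivatives entering the combinations are taken along the pair's own axes
# (directional derivatives along m1(k), m2(k)); div and rot are invariant to
# that frame choice while the deformation pair is counter-rotated by -2
# theta_k back to the head-centric axes, so every (k, l) channel yields a
# consistent estimate of the same four elementary components.

#' Express a disparity field in a rotated component basis
#'
#' Projects the field onto the orthogonal generators
#' m1 = (cos theta, sin theta), m2 = (-sin theta, cos theta).
#'
#' @param field a `disparity_field`.
#' @param theta_k basis rotation (rad).
#' @return A `disparity_field` whose `delta1`/`delta2` hold the rotated
#'   components.
#' @export
rebase_disparity <- function(field, theta_k) {
  stopifnot(inherits(field, "disparity_field"))
  c1 <- cos(theta_k); s1 <- sin(theta_k)
  out <- field
  out$delta1 <- c1 * field$delta1 + s1 * field$delta2
  out$delta2 <- -s1 * field$delta1 + c1 * field$delta2
  out
}

#' Scale-space image gradient
#'
#' Derivative-of-Gaussian filtering at scale `s` px (same-size output,
#' reflected boundaries); exact on linear inputs.
#'
#' @param map input matrix (first index = x1).
#' @param scale_s Gaussian scale (px), > 0.
#' @return list with matrices `d1` (d/dx1) and `d2` (d/dx2).
#' @export
scale_space_gradient <- function(map, scale_s) {
  if (scale_s <= 0) stop("scale must be positive")
  size <- 2 * ceiling(3 * scale_s) + 1
  g <- gauss_taps(size, scale_s)
  d <- gauss_deriv_taps(size, scale_s)
  D1 <- conv_mat_reflect(nrow(map), d)
  G1 <- conv_mat_reflect(nrow(map), g)
  D2 <- conv_mat_reflect(ncol(map), d)
  G2 <- conv_mat_reflect(ncol(map), g)
  list(d1 = D1 %*% map %*% t(G2), d2 = G1 %*% map %*% t(D2))
}

# Shared combination step: given gradients of the pair (r1, r2) for
# direction theta, return the four head-centric component maps.
combine_pair_gradients <- function(g1d1, g1d2, g2d1, g2d2, theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  # directional derivatives along m1(k) and m2(k)
  r1u1 <- c1 * g1d1 + s1 * g1d2
  r1u2 <- -s1 * g1d1 + c1 * g1d2
  r2u1 <- c1 * g2d1 + s1 * g2d2
  r2u2 <- -s1 * g2d1 + c1 * g2d2
  dv <- r1u1 + r2u2
  rt <- r2u1 - r1u2
  f1 <- r2u1 + r1u2
  f2 <- r1u1 - r2u2
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  list(div = dv, rot = rt,
       def1 = c2 * f1 + s2 * f2,       # counter-rotate by -2 theta
       def2 = -s2 * f1 + c2 * f2)
}

#' Distributed first-order differential maps of the population activity
#'
#' For every direction pair k (channels theta_k and theta_k + pi/2) and
#' phase channel l, computes scale-space directional derivatives of the two
#' paired response maps and combines them into divergence, rotation and the
#' two deformation components.
#'
#' @param pop a [population_response()] (even orientation count).
#' @param scale_s Gaussian derivative scale (px of the response maps).
#' @return A `differential_maps` object: array `comp` of dim
#'   (n, n, 4, M/2, L) with component order div, rot, def1, def2; `border`
#'   gives the boundary width to exclude from quantitative use.
#' @export
population_differentials <- function(pop, scale_s = 2) {
  M <- length(pop$bank$theta); L <- length(pop$bank$dpsi)
  if (M %% 2 != 0) stop("orientation channels cannot be paired")
  half <- M / 2
  n <- pop$n
  comp <- array(0, dim = c(n, n, 4, half, L))
  for (k in seq_len(half)) {
    th <- pop$bank$theta[k]
    for (l in seq_len(L)) {
      gr1 <- scale_space_gradient(pop$resp[, , k, l], scale_s)
      gr2 <- scale_space_gradient(pop$resp[, , k + half, l], scale_s)
      cc <- combine_pair_gradients(gr1$d1, gr1$d2, gr2$d1, gr2$d2, th)
      comp[, , 1, k, l] <- cc$div
      comp[, , 2, k, l] <- cc$rot
      comp[, , 3, k, l] <- cc$def1
      comp[, , 4, k, l] <- cc$def2
    }
  }
  structure(list(comp = comp, scale_s = scale_s,
                 theta_pairs = pop$bank$theta[seq_len(half)],
                 border = ceiling(scale_s), bank = pop$bank),
            class = "differential_maps")
}

#' @export
print.differential_maps <- function(x, ...) {
  d <- dim(x$comp)
  cat("differential_maps:", d[3], "components x", d[4], "direction pairs x",
      d[5], "phase channels, maps", d[1], "x", d[2], "\n")
  invisible(x)
}

#' Channel-aggregated differential component maps
#'
#' Combines the per-(k, l) maps into one map per elementary component using
#' sin(dpsi_l) weights across phase channels (averaged over direction
#' pairs).  The first-order differential signal in the response maps is odd
#' in the channel phase shift while the leading cross-component
#' contamination (tuning-curve curvature) is even, so this weighting adds
#' the signal coherently and cancels the contamination.
#'
#' @param dm a [population_differentials()] result.
#' @return list of four matrices: `div`, `rot`, `def1`, `def2`.
#' @export
aggregate_components <- function(dm) {
  w <- sin(dm$bank$dpsi)
  wn <- sum(abs(w))
  if (wn < 1e-12) stop("phase-shift grid has no odd channels to weight")
  n <- dim(dm$comp)[1]; half <- dim(dm$comp)[4]; L <- dim(dm$comp)[5]
  out <- lapply(1:4, function(ci) {
    A <- matrix(0, n, n)
    for (k in seq_len(half)) for (l in seq_len(L))
      A <- A + w[l] * dm$comp[, , ci, k, l]
    A / (wn * half)
  })
  names(out) <- c("div", "rot", "def1", "def2")
  out
}

#' Mean absolute magnitude of each differential component
#'
#' Computed on the channel-aggregated maps (see [aggregate_components()])
#' over an interior window (a border of `margin` pixels is excluded).
#' `aggregate = FALSE` instead averages |.| over the raw per-channel maps.
#'
#' @param dm a [population_differentials()] result.
#' @param margin border width to exclude; default uses the map's own.
#' @param aggregate use the sin-weighted channel aggregation (default).
#' @return named numeric vector (div, rot, def1, def2).
#' @export
component_energy <- function(dm, margin = NULL, aggregate = TRUE) {
  m <- margin %||% max(dm$border, 1)
  n <- dim(dm$comp)[1]
  keep <- (m + 1):(n - m)
  if (aggregate) {
    agg <- aggregate_components(dm)
    out <- vapply(agg, function(A) mean(abs(A[keep, keep])), numeric(1))
  } else {
    sub <- dm$comp[keep, keep, , , , drop = FALSE]
    out <- vapply(1:4, function(ci) mean(abs(sub[, , ci, , ])), numeric(1))
  }
  names(out) <- c("div", "rot", "def1", "def2")
  out
}
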