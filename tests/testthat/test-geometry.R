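# Distance from point P to the line through O with unit direction v.
point_line_dist <- function(P, O, v) {
  w <- P - O
  vnorm <- function(x) sqrt(sum(x^2))
  v <- v / vnorm(v)
  vnorm(w - sum(w * v) * v)
}

test_that("fixation aims both optical axes through the target", {
  p <- fixate(c(0, 0, 350), baseline = 60)
  expect_equal(p$L$alpha, atan(30 / 350) * 180 / pi, tolerance = 1e-10)
  expect_equal(p$R$alpha, -atan(30 / 350) * 180 / pi, tolerance = 1e-10)
  expect_equal(p$L$epsilon, 0)
  for (eye in c("L", "R", "C")) {
    axis <- as.vector(p[[eye]]$R %*% c(0, 0, 1))
    expect_lt(point_line_dist(c(0, 0, 350), p[[eye]]$origin, axis), 1e-6)
  }
  # brute-force over random targets: axes intersect the target, rotations
  # stay orthonormal with determinant +1
  set.seed(42)
  for (i in 1:25) {
    tgt <- c(runif(1, -150, 150), runif(1, -150, 150), runif(1, 150, 900))
    p <- fixate(tgt, baseline = 60)
    for (eye in c("L", "R")) {
      R <- p[[eye]]$R
      expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
      expect_equal(det(R), 1, tolerance = 1e-10)
      axis <- as.vector(R %*% c(0, 0, 1))
      expect_lt(point_line_dist(tgt, p[[eye]]$origin, axis), 1e-6)
    }
  }
})

test_that("straight-ahead fixation at great distance is the primary position", {
  p <- fixate(c(0, 0, 1e9), baseline = 60)
  expect_lt(abs(p$L$alpha), 1e-5)
  expect_lt(abs(p$L$epsilon), 1e-5)
  expect_lt(max(abs(p$L$R - diag(3))), 1e-6)
  expect_lt(max(abs(p$R$R - diag(3))), 1e-6)
})

test_that("elevation-only targets give a common Helmholtz elevation", {
  p <- fixate(c(0, 100, 350), baseline = 60)
  expect_gt(abs(p$L$epsilon), 1)
  expect_equal(p$L$epsilon, p$R$epsilon, tolerance = 1e-12)
})

test_that("degenerate fixation targets are rejected", {
  expect_error(fixate(c(40, 0, 0)), "positive Z")
  expect_error(fixate(c(0, 0, -350)), "positive Z")
})

test_that("L2 torsion keeps orthonormal rotations aimed at the target", {
  tgt <- c(80, 60, 300)
  p <- fixate(tgt, baseline = 60, torsion_mode = "L2")
  expect_identical(p$torsion_mode, "L2")
  for (eye in c("L", "R")) {
    R <- p[[eye]]$R
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    axis <- as.vector(R %*% c(0, 0, 1))
    expect_lt(point_line_dist(tgt, p[[eye]]$origin, axis), 1e-6)
  }
  # oblique eccentric gaze carries nonzero torsion
  expect_gt(abs(p$L$gamma) + abs(p$R$gamma), 1e-4)
})

test_that("projection sends the fixation point to the image center", {
  tgt <- c(30, -40, 400)
  p <- fixate(tgt, baseline = 60)
  for (eye in c("L", "R", "cyclopean"))
    expect_lt(max(abs(project(tgt, p, eye))), 1e-12)
  # any point on the left optical axis projects to (0, 0) in the left image
  axis <- as.vector(p$L$R %*% c(0, 0, 1))
  pt <- p$L$origin + 500 * axis
  expect_lt(max(abs(project(pt, p, "L"))), 1e-12)
})

test_that("projection matches a homogeneous-matrix pipeline oracle", {
  p <- fixate(c(0, 0, 1e9), baseline = 60)   # straight-ahead gaze
  f <- 350; s <- 210
  pts <- rbind(c(20, 35, 500), c(-80, 10, 300), c(5, -60, 700))
  for (eye in c("L", "R")) {
    # independent 4x4 pipeline: translate, then perspective divide
    Tm <- diag(4); Tm[1:3, 4] <- -fixate(c(0, 0, 1e9), 60)[[eye]]$origin
    K <- rbind(c(f / s, 0, 0, 0), c(0, f / s, 0, 0), c(0, 0, 1, 0))
    for (i in 1:3) {
      h <- K %*% Tm %*% c(pts[i, ], 1)
      expect_equal(as.vector(project(pts[i, ], p, eye)),
                   as.vector(h[1:2] / h[3]), tolerance = 1e-6)
    }
  }
  expect_error(project(c(0, 0, -5), p, "L"), "behind")
})

test_that("plane stimulus geometry follows the slant/tilt convention", {
  pl <- plane_stimulus(28, 60)
  s <- sin(28 * pi / 180); cs <- cos(28 * pi / 180)
  expect_equal(pl$normal,
               c(s * cos(60 * pi / 180), s * sin(60 * pi / 180), cs),
               tolerance = 1e-12)
  # generated surface points satisfy the plane equation
  set.seed(3)
  for (i in 1:10) {
    v <- pl$rotation %*% c(runif(1, -100, 100), runif(1, -100, 100), 0)
    P <- pl$center + as.vector(v)
    expect_lt(abs(sum(pl$normal * (P - pl$center))), 1e-9)
  }
})

test_that("disparity vanishes at fixation and on the symmetry midline", {
  pl <- plane_stimulus(0, 0)
  pose <- fixate(c(0, 0, 350))
  f <- disparity_field(pl, pose, px = 31)
  mid <- 16
  expect_lt(abs(f$delta1[mid, mid]), 1e-12)
  expect_lt(abs(f$delta2[mid, mid]), 1e-12)
  # vertical disparity is zero along the horizontal image midline
  expect_lt(max(abs(f$delta2[, mid]), na.rm = TRUE), 1e-9)
  # random planes and gazes: fixating the plane nulls central disparity
  set.seed(7)
  for (i in 1:20) {
    pl <- plane_stimulus(runif(1, 4, 48), runif(1, 30, 360))
    tgt <- fixation_on_plane(pl, runif(1, -5, 5), runif(1, -5, 5))
    f <- disparity_field(pl, fixate(tgt), px = 31)
    expect_lt(abs(f$delta1[mid, mid]) + abs(f$delta2[mid, mid]), 1e-3)
  }
})

test_that("mirror-symmetric gazes mirror the disparity field", {
  # mirroring about the median plane swaps the two eyes, so the horizontal
  # disparity mirrors unnegated and the vertical disparity flips sign
  for (tau in c(90, 270)) {
    pl <- plane_stimulus(25, tau)       # tilt axis in the median plane
    t1 <- fixation_on_plane(pl, 5, 3)
    t2 <- fixation_on_plane(pl, -5, 3)
    f1 <- disparity_field(pl, fixate(t1), px = 31)
    f2 <- disparity_field(pl, fixate(t2), px = 31)
    flip <- function(M) M[31:1, ]
    expect_lt(max(abs(f1$delta1 - flip(f2$delta1)), na.rm = TRUE), 1e-6)
    expect_lt(max(abs(f1$delta2 + flip(f2$delta2)), na.rm = TRUE), 1e-6)
  }
})

test_that("slant-zero planes give tilt-independent fields", {
  pose <- fixate(c(0, 0, 350))
  f0 <- disparity_field(plane_stimulus(0, 30), pose, px = 21)
  for (tau in c(120, 275)) {
    f <- disparity_field(plane_stimulus(0, tau), pose, px = 21)
    expect_lt(max(abs(f$delta1 - f0$delta1), na.rm = TRUE), 1e-9)
    expect_lt(max(abs(f$delta2 - f0$delta2), na.rm = TRUE), 1e-9)
  }
})

test_that("slanted planes under eccentric gaze show rotational structure", {
  pl <- plane_stimulus(28, 60)
  tgt <- fixation_on_plane(pl, 5, 5)
  f <- disparity_field(pl, fixate(tgt), px = 43)
  J <- analytic_jacobian(f)
  expect_gt(max(abs(J$rot), na.rm = TRUE), 1e-4)
})

test_that("the finite-difference Jacobian is exact on linear fields", {
  n <- 21
  cases <- list(expansion = c(2, 0, 0, 0), rotation = c(0, 2, 0, 0),
                shear = c(0, 0, 2, 0), stretch = c(0, 0, 0, 2))
  for (nm in names(cases)) {
    fl <- linear_field(nm, n)
    J <- analytic_jacobian(make_disparity_field(fl$d1, fl$d2))
    got <- c(J$div[11, 11], J$rot[11, 11], J$def1[11, 11], J$def2[11, 11])
    expect_equal(got, cases[[nm]], tolerance = 1e-12)
    # constant across the interior
    expect_lt(stats::sd(J$div[3:19, 3:19]), 1e-12)
  }
  expect_error(analytic_jacobian(
    make_disparity_field(matrix(1, 2, 2), matrix(1, 2, 2))), "3x3")
})
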