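test_that("rebasing rotates disparity components and preserves norms", {
  fl <- linear_field("shear", 15, 0.3)
  f <- make_disparity_field(fl$d1, fl$d2)
  r0 <- rebase_disparity(f, 0)
  expect_identical(r0$delta1, f$delta1)
  expect_identical(r0$delta2, f$delta2)
  r90 <- rebase_disparity(f, pi / 2)
  expect_equal(r90$delta1, f$delta2, tolerance = 1e-12)
  expect_equal(r90$delta2, -f$delta1, tolerance = 1e-12)
  r <- rebase_disparity(f, 0.7)
  expect_equal(r$delta1^2 + r$delta2^2, f$delta1^2 + f$delta2^2,
               tolerance = 1e-12)
})

test_that("scale-space gradients are exact on polynomials up to degree 2", {
  n <- 41; ax <- seq_len(n) - 21
  X1 <- matrix(ax, n, n); X2 <- matrix(ax, n, n, byrow = TRUE)
  interior <- 11:31
  g <- scale_space_gradient(matrix(5, n, n), 2)
  expect_lt(max(abs(g$d1[interior, interior])), 1e-10)
  expect_lt(max(abs(g$d2[interior, interior])), 1e-10)
  g <- scale_space_gradient(0.3 * X1, 2)
  expect_equal(g$d1[interior, interior],
               matrix(0.3, 21, 21), tolerance = 1e-10)
  expect_lt(max(abs(g$d2[interior, interior])), 1e-10)
  # quadratic map: compare with the compose-smoothing-then-central-diff
  # oracle (both are exact on quadratics in the interior)
  Q <- 0.05 * X1^2 + 0.02 * X1 * X2
  g <- scale_space_gradient(Q, 2)
  size <- 2 * ceiling(3 * 2) + 1
  Gm <- conv_mat_reflect(n, gauss_taps(size, 2))
  Sm <- Gm %*% Q %*% t(Gm)
  cd1 <- (Sm[3:n, ] - Sm[1:(n - 2), ]) / 2
  expect_lt(max(abs(g$d1[interior, interior] -
                      cd1[interior - 1, interior])), 1e-8)
  expect_error(scale_space_gradient(Q, -1), "positive")
})

test_that("population differentials are linear and vanish for uniform input", {
  pop <- fx_pop63()
  dm <- population_differentials(pop, scale_s = 2)
  expect_equal(dim(dm$comp), c(43, 43, 4, 4, 7))
  pop2 <- pop; pop2$resp <- 3 * pop$resp
  dm2 <- population_differentials(pop2, scale_s = 2)
  expect_equal(dm2$comp, 3 * dm$comp, tolerance = 1e-10)
  # spatially uniform activity has no differential structure
  popu <- pop
  popu$resp[] <- rep(colMeans(matrix(pop$resp, 43 * 43)),
                     each = 43 * 43)
  dmu <- population_differentials(popu, scale_s = 2)
  inner <- 5:39
  expect_lt(max(abs(dmu$comp[inner, inner, , , ])), 1e-10)
  # odd orientation counts cannot be paired
  pop3 <- pop; pop3$bank$theta <- pop$bank$theta[1:3]
  expect_error(population_differentials(pop3), "paired")
})

test_that("encoded elementary fields are dominated by the right component", {
  # pure expansion, encoded on a random-dot stereogram
  fl <- linear_field("expansion", 99, 0.02)
  sp <- synthetic_rds(fl$d1, fl$d2, texture_seed = 7)
  pop <- population_response(sp, disparity_bank(px = 99), pool_to = 43)
  ce <- component_energy(population_differentials(pop, scale_s = 3),
                         margin = 10)
  expect_equal(names(which.max(ce)), "div")
  expect_gt(ce["div"] / max(ce[c("rot", "def1", "def2")]), 5)
})

test_that("population components track the analytic Jacobian across stimuli", {
  # probe grid: 3 slants x 3 tilts x 3 gazes; compare the sign/magnitude
  # pattern of population-derived components with the ground-truth field
  # Jacobian (rank correlation; exact agreement is not expected)
  bank <- disparity_bank(px = 63)
  filters <- stereoslant:::bank_filters(bank, c(63, 63))
  P <- pool_area_mat(63, 43)
  popv <- c(); gtv <- c()
  set.seed(5)
  for (sg in c(10, 28, 45)) for (tu in c(60, 180, 300)) {
    pl <- plane_stimulus(sg, tu)
    for (g in list(c(0, 0), c(-5, 5), c(5, 0))) {
      pose <- fixate(fixation_on_plane(pl, g[1], g[2]))
      f <- disparity_field(pl, pose, px = 63)
      sp <- render_stereo_pair(pl, pose,
                               texture_seed = sample.int(1e6, 1), px = 63)
      pop <- population_response(sp, bank, pool_to = 43, filters = filters)
      agg <- aggregate_components(population_differentials(pop, scale_s = 3))
      J <- analytic_jacobian(f)
      ctr <- 15:29
      for (cn in c("div", "rot", "def1", "def2")) {
        popv <- c(popv, mean(agg[[cn]][ctr, ctr]))
        Jc <- J[[cn]]; Jc[is.na(Jc)] <- 0
        Jp <- P %*% Jc %*% t(P)
        gtv <- c(gtv, mean(Jp[ctr, ctr]))
      }
    }
  }
  expect_gt(stats::cor(popv, gtv, method = "spearman"), 0.8)
})

test_that("first-order components vary less across gaze than raw disparity", {
  # gaze-robustness surrogate: across the nine gaze directions, the
  # coefficient of variation of the population first-order component
  # magnitude (L2 norm of div/rot/def1/def2, which is tilt-equivariant)
  # stays below that of the zero-order disparity magnitude |delta|; the
  # texture seed is held fixed so only the viewing geometry varies
  bank <- disparity_bank(px = 63)
  filters <- stereoslant:::bank_filters(bank, c(63, 63))
  gz <- gaze_grid()
  ok <- 0; tot <- 0
  for (sg in c(20, 40)) for (tu in c(90, 210, 330)) {
    pl <- plane_stimulus(sg, tu)
    e1 <- c(); e0 <- c()
    for (q in seq_len(nrow(gz$directions))) {
      pose <- fixate(fixation_on_plane(pl, gz$directions$alpha[q],
                                       gz$directions$epsilon[q]))
      f <- disparity_field(pl, pose, px = 63)
      sp <- render_stereo_pair(pl, pose, texture_seed = 77, px = 63)
      pop <- population_response(sp, bank, pool_to = 43, filters = filters)
      agg <- aggregate_components(population_differentials(pop, scale_s = 3))
      ctr <- 15:29
      e1 <- c(e1, mean(sqrt(agg$div[ctr, ctr]^2 + agg$rot[ctr, ctr]^2 +
                              agg$def1[ctr, ctr]^2 + agg$def2[ctr, ctr]^2)))
      ctr2 <- 22:42
      e0 <- c(e0, mean(sqrt(f$delta1[ctr2, ctr2]^2 +
                              f$delta2[ctr2, ctr2]^2), na.rm = TRUE))
    }
    cv <- function(x) stats::sd(x) / mean(x)
    tot <- tot + 1
    if (cv(e1) < cv(e0)) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.8)
})
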