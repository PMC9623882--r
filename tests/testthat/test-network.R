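test_that("the convolutional front end has the 43 -> 32 -> 5 shape chain", {
  pop <- fx_pop63()
  expect_equal(pop$n, 43)
  fz <- preprocess_gaze(pop)
  expect_equal(dim(fz), c(5, 5, 4, 4, 7))
  # intermediate valid-convolution size: 43 - 12 + 1 = 32, then
  # (32 - 8)/6 + 1 = 5 pooled samples per axis
  expect_equal(nrow(stereoslant:::pool_gauss_mat(32, 8, 6, 2)), 5)
  # constant channels are annihilated by the derivative kernels
  popc <- pop
  popc$resp[] <- 1.3
  expect_lt(max(abs(preprocess_gaze(popc))), 1e-10)
  # linearity before normalization
  pop2 <- pop; pop2$resp <- 2.5 * pop$resp
  expect_equal(preprocess_gaze(pop2), 2.5 * fz, tolerance = 1e-10)
})

test_that("feature normalization gives zero-mean [-1, 1] training features", {
  set.seed(8)
  FS <- array(rnorm(5 * 5 * 4 * 2 * 3 * 2 * 6, 2, 3),
              dim = c(5, 5, 4, 2, 3, 2, 6))
  nf <- normalize_features(FS, train_idx = 1:4)
  tr <- nf$FS[, , , , , , 1:4, drop = FALSE]
  expect_lt(max(abs(apply(tr, c(3, 4, 5), mean))), 1e-12)
  expect_lte(max(abs(tr)), 1 + 1e-12)
  # reusing stored parameters reproduces the same transform
  nf2 <- normalize_features(FS, params = nf$params)
  expect_equal(nf2$FS, nf$FS, tolerance = 1e-14)
  Z <- features_to_input(nf$FS)
  expect_equal(dim(Z), c(100, 6, 2, 6))
})

test_that("forward pass fixed points: zero weights and tie-breaking", {
  G <- 2; m <- 3; Q <- 4
  p <- random_network(G, n_gaze = Q, m = m, n_classes = 5, unroll_T = 3,
                      sd = 0.4, seed = 2)
  p$win[] <- 0; p$wrec[] <- 0; p$wout[] <- 0; p$bias[] <- 0
  Z <- array(1, dim = c(4 * m^2, G, Q, 2))
  fw <- forward_network(p, Z, keep_hidden = TRUE)
  expect_true(all(abs(fw$hidden - 0.5) < 1e-12))   # S(0) = 0.5
  expect_true(all(fw$scores == 0))
  expect_equal(fw$pred, c(1L, 1L))                 # ties -> lowest class
  expect_error(forward_network(p, Z, active_gazes = integer(0)), "nonempty")
})

test_that("zero recurrence with one step reduces to a feed-forward net", {
  set.seed(3)
  G <- 2; m <- 3; Q <- 3; B <- 5
  Z <- array(rnorm(4 * m^2 * G * Q * B), dim = c(4 * m^2, G, Q, B))
  p <- random_network(G, n_gaze = Q, m = m, n_classes = 4, unroll_T = 1,
                      sd = 0.3, seed = 6)
  p$wrec[] <- 0
  fw <- forward_network(p, Z)
  # independent single-pass oracle, computed with plain loops
  for (b in 1:B) {
    h <- c()
    for (q in 1:Q) {
      hq <- numeric(0)
      for (g in 1:G)
        hq <- c(hq, p$win[, , g, q] %*% Z[, g, q, b])
      h <- cbind(h, 1 / (1 + exp(-(hq + p$bias[, q]))))
    }
    sc <- p$wout %*% as.vector(h)
    expect_equal(fw$scores[, b], as.vector(sc), tolerance = 1e-12)
  }
})

test_that("BPTT gradients match central-difference numerical gradients", {
  set.seed(2)
  G <- 2; m <- 3; Q <- 3; B <- 4; n_in <- 4 * m^2
  Z <- array(rnorm(n_in * G * Q * B, 0, 0.5), dim = c(n_in, G, Q, B))
  labels <- c(1, 2, 3, 2)
  for (lossname in c("logistic", "sse")) {
    p <- random_network(G, n_gaze = Q, m = m, n_classes = 3, unroll_T = 3,
                        sd = 0.3, seed = 4)
    gr <- network_gradients(p, Z, labels, loss = lossname)
    set.seed(9)
    for (field in c("win", "wrec", "wout", "bias")) {
      for (r in 1:10) {
        idx <- sample(length(p[[field]]), 1)
        eps <- 1e-6
        p1 <- p; p1[[field]][idx] <- p1[[field]][idx] + eps
        p2 <- p; p2[[field]][idx] <- p2[[field]][idx] - eps
        ng <- (network_loss(p1, Z, labels, loss = lossname) -
                 network_loss(p2, Z, labels, loss = lossname)) / (2 * eps)
        ag <- gr[[field]][idx]
        expect_lt(abs(ng - ag) / max(1e-6, abs(ng) + abs(ag)), 1e-5)
      }
    }
  }
})

test_that("training is deterministic and solves a separable toy problem", {
  # two well-separated feature patterns, two classes
  set.seed(10)
  G <- 2; m <- 3; Q <- 3; n_in <- 4 * m^2
  proto <- array(rnorm(n_in * G * Q, 0, 0.5), dim = c(n_in, G, Q))
  B <- 10
  Z <- array(0, dim = c(n_in, G, Q, B))
  labels <- rep(1:2, each = 5)
  for (b in 1:B)
    Z[, , , b] <- (if (labels[b] == 1) proto else -proto) +
      array(rnorm(n_in * G * Q, 0, 0.05), dim = dim(proto))
  p0 <- init_network(G, n_gaze = Q, m = m, n_classes = 2, unroll_T = 3,
                     seed = 5)
  fit <- train_bptt(p0, Z, labels, lambda = 0.2, max_iters = 200,
                    target_error = 1e-4)
  acc <- evaluate_network(fit$params, Z, labels)$overall
  expect_equal(acc, 1)
  # same seed, same data -> bit-identical parameters
  fit2 <- train_bptt(p0, Z, labels, lambda = 0.2, max_iters = 200,
                     target_error = 1e-4)
  expect_identical(fit$params$win, fit2$params$win)
  expect_identical(fit$params$wout, fit2$params$wout)
  # training loss is non-increasing almost everywhere once stable
  dtr <- diff(fit$trace)
  expect_lt(mean(dtr > 1e-8), 0.1)
})

test_that("untrained random networks classify at chance", {
  set.seed(12)
  G <- 3; m <- 3; Q <- 9; n_in <- 4 * m^2; B <- 90
  Z <- array(rnorm(n_in * G * Q * B), dim = c(n_in, G, Q, B))
  labels <- rep(1:9, each = 10)
  accs <- vapply(1:15, function(r) {
    p <- random_network(G, n_gaze = Q, m = m, unroll_T = 3, seed = 100 + r)
    evaluate_network(p, Z, labels)$overall
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 9), 0.06)
})

test_that("active gaze selection honours its stopping contracts", {
  G <- 2; m <- 3; Q <- 5
  p <- random_network(G, n_gaze = Q, m = m, n_classes = 3, unroll_T = 2,
                      sd = 0.3, seed = 7)
  z <- array(rnorm(4 * m^2 * G * Q), dim = c(4 * m^2, G, Q))
  # threshold 0: stop after the first fixation
  r0 <- active_gaze_selection(p, z, threshold = 0, start_gaze = 2)
  expect_equal(r0$gazes, 2)
  expect_true(r0$converged)
  # unreachable threshold: exhaust all gazes, flagged not converged
  r1 <- active_gaze_selection(p, z, threshold = 2, start_gaze = 1)
  expect_equal(sort(r1$gazes), 1:Q)
  expect_false(r1$converged)
  expect_length(r1$pred, Q)
  # deterministic given the start gaze
  r2 <- active_gaze_selection(p, z, threshold = 2, start_gaze = 1)
  expect_identical(r1$gazes, r2$gazes)
})
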