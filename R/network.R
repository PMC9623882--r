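# The hierarchical classifier: a hard-wired convolutional front end that
# turns 43x43 population maps into normalized 5x5 elementary-component
# feature maps (div/rot/def1/def2 per direction-pair x phase channel), and a
# trainable recurrent stage of nine gaze blocks whose hidden units exchange
# activity across gazes and project linearly to nine orientation classes.
#
# Layout conventions used throughout:
#   feature vector per (gaze, channel group): 4 components x m^2 pixels,
#     index = (comp - 1) * m^2 + pixel            (n_in = 4 m^2, default 100)
#   hidden vector per gaze: G groups x m^2,
#     index = (group - 1) * m^2 + pixel           (n_h = G m^2)
#   full hidden vector: index = (gaze - 1) * n_h + j

#' Convolutional preprocessing of one gaze's population maps
#'
#' (1) filters every (orientation, phase) response map with 12x12
#' first-order Gaussian-derivative kernels (valid convolution, 43 -> 32);
#' (2) combines the derivative maps of each direction pair into the four
#' elementary components (div, rot, def1, def2); (3) pools each component
#' with an 8x8 sliding Gaussian at stride 6 (32 -> 5).  Normalization to the
#' training statistics is applied separately (see [normalize_features()]).
#'
#' @param pop a [population_response()] with maps at 43 x 43 (any size >= 20
#'   is accepted; the 43 -> 32 -> 5 chain is the reference configuration).
#' @param scale_s Gaussian scale of the derivative kernels (px).
#' @param deriv_size,pool_size,pool_stride front-end kernel geometry.
#' @return raw feature array of dim (m, m, 4, M/2, L).
#' @export
preprocess_gaze <- function(pop, scale_s = 2, deriv_size = 12,
                            pool_size = 8, pool_stride = 6) {
  n <- pop$n
  if (n < deriv_size + pool_size) stop("population maps too small: ", n)
  M <- length(pop$bank$theta); L <- length(pop$bank$dpsi)
  if (M %% 2 != 0) stop("orientation channels cannot be paired")
  half <- M / 2
  g <- gauss_taps(deriv_size, scale_s)
  d <- gauss_deriv_taps(deriv_size, scale_s)
  Dv <- conv_mat_valid(n, d); Gv <- conv_mat_valid(n, g)
  n2 <- n - deriv_size + 1
  P <- pool_gauss_mat(n2, pool_size, pool_stride, sigma = pool_size / 4)
  m <- nrow(P)
  out <- array(0, dim = c(m, m, 4, half, L))
  for (k in seq_len(half)) {
    th <- pop$bank$theta[k]
    for (l in seq_len(L)) {
      r1 <- pop$resp[, , k, l]; r2 <- pop$resp[, , k + half, l]
      cc <- combine_pair_gradients(Dv %*% r1 %*% t(Gv), Gv %*% r1 %*% t(Dv),
                                   Dv %*% r2 %*% t(Gv), Gv %*% r2 %*% t(Dv),
                                   th)
      out[, , 1, k, l] <- P %*% cc$div %*% t(P)
      out[, , 2, k, l] <- P %*% cc$rot %*% t(P)
      out[, , 3, k, l] <- P %*% cc$def1 %*% t(P)
      out[, , 4, k, l] <- P %*% cc$def2 %*% t(P)
    }
  }
  out
}

#' Normalize a feature set to the training statistics
#'
#' Per feature channel (component x direction pair x phase): remove the mean
#' and scale by the maximum absolute deviation, both estimated over the
#' training examples (all pixels and gazes), so training features have zero
#' mean and a [-1, 1] magnitude range.
#'
#' @param FS feature array of dim (m, m, 4, half, L, n_gaze, B).
#' @param train_idx indices (along the last dim) of the training examples.
#' @param params optional precomputed normalization (reused for new data).
#' @return list `FS` (normalized), `params` (`mean`, `scale`, arrays of dim
#'   (4, half, L)).
#' @export
normalize_features <- function(FS, train_idx = NULL, params = NULL) {
  dm <- dim(FS)
  stopifnot(length(dm) == 7)
  if (is.null(params)) {
    stopifnot(!is.null(train_idx))
    tr <- FS[, , , , , , train_idx, drop = FALSE]
    mu <- apply(tr, c(3, 4, 5), mean)
    sc <- apply(abs(sweep(tr, c(3, 4, 5), mu)), c(3, 4, 5), max)
    sc[sc < 1e-12] <- 1
    params <- list(mean = mu, scale = sc)
  }
  FS <- sweep(FS, c(3, 4, 5), params$mean)
  FS <- sweep(FS, c(3, 4, 5), params$scale, "/")
  list(FS = FS, params = params)
}

#' Flatten normalized features into the network input tensor
#'
#' @param FS normalized feature array (m, m, 4, half, L, n_gaze, B).
#' @return array `Z` of dim (4 m^2, n_groups = half x L, n_gaze, B).
#' @export
features_to_input <- function(FS) {
  dm <- dim(FS)
  m <- dm[1]; half <- dm[4]; L <- dm[5]; Q <- dm[6]; B <- dm[7]
  # (m, m, comp, k, l, q, b) -> (m, m, comp) x (k, l) x q x b
  Z <- aperm(FS, c(1, 2, 3, 4, 5, 6, 7))
  dim(Z) <- c(m * m * 4, half * L, Q, B)
  Z
}

# ---- parameters ------------------------------------------------------------

gauss_profile_mat <- function(m, sigma) {
  px <- expand.grid(u = seq_len(m), v = seq_len(m))
  D2 <- outer(seq_len(m^2), seq_len(m^2), function(i, j)
    (px$u[i] - px$u[j])^2 + (px$v[i] - px$v[j])^2)
  exp(-D2 / (2 * sigma^2))
}

#' Initialize the recurrent gaze-block network
#'
#' Input weights start as radially symmetric Gaussian profiles between input
#' and hidden pixels; recurrent weights as a Gaussian in gaze-grid distance
#' (one scalar per ordered gaze pair, applied between corresponding hidden
#' units); output weights as centered 3x3 Gaussian crops (sd 1.5 px) of each
#' hidden map.  A small seeded jitter breaks exact ties.
#'
#' @param n_groups number of (direction pair x phase) channel groups.
#' @param n_gaze number of gaze blocks.
#' @param m hidden/input map side (px).
#' @param n_classes output classes.
#' @param gaze_pos n_gaze x 2 gaze-grid coordinates (defaults to the 3x3
#'   grid in row-major alpha-fastest order).
#' @param unroll_T recurrence steps used by the forward pass and BPTT.
#' @param seed jitter seed.
#' @param gains named list of initialization gains.
#' @return A `network_params` object: `win` (m^2 x 4m^2 x n_groups x
#'   n_gaze), `wrec` (n_gaze x n_gaze), `wout` (n_classes x n_gaze*n_h),
#'   `bias` (n_h x n_gaze).
#' @export
init_network <- function(n_groups, n_gaze = 9, m = 5, n_classes = 9,
                         gaze_pos = NULL, unroll_T = 9, seed = 1,
                         gains = list(win = 0.1, rec = 0.05, out = 0.5)) {
  n_px <- m^2; n_in <- 4 * n_px; n_h <- n_px * n_groups
  if (is.null(gaze_pos)) {
    side <- sqrt(n_gaze)
    gaze_pos <- if (side == round(side)) {
      ax <- seq_len(side) - (side + 1) / 2
      as.matrix(expand.grid(a = ax, e = ax))
    } else cbind(seq_len(n_gaze), 0)
  }
  G0 <- gains$win * gauss_profile_mat(m, sigma = 4 / 3)   # n_px x n_px
  win0 <- cbind(G0, G0, G0, G0)                           # tile over comps
  D2 <- as.matrix(stats::dist(gaze_pos))^2
  wrec0 <- gains$rec * exp(-D2 / 2)
  cm <- (m + 1) / 2
  prof <- outer(seq_len(m), seq_len(m), function(u, v)
    exp(-((u - cm)^2 + (v - cm)^2) / (2 * 1.5^2)) *
      (abs(u - cm) <= 1) * (abs(v - cm) <= 1))
  # scale the readout so initial class scores are O(1): each hidden unit
  # sits near 0.5 and every (group, gaze) map contributes one profile
  out_scale <- gains$out / (n_groups * n_gaze * sum(prof) / 2)
  wout_map <- out_scale * as.vector(prof)                 # one hidden map
  wout0 <- matrix(rep(wout_map, n_groups * n_gaze), n_classes,
                  n_h * n_gaze, byrow = TRUE)
  jit <- function(x, amp) x + amp *
    (array(stats::runif(length(x)), dim = dim(x) %||% length(x)) - 0.5)
  params <- with_seed(seed, {
    list(win = jit(array(win0, dim = c(n_px, n_in, n_groups, n_gaze)), 0.02),
         wrec = jit(wrec0, 0.01),
         wout = jit(wout0, 2 * out_scale),
         bias = matrix(0, n_h, n_gaze))
  })
  structure(c(params, list(m = m, n_groups = n_groups, n_gaze = n_gaze,
                           n_classes = n_classes, unroll_T = unroll_T)),
            class = "network_params")
}

#' Random (untrained) network parameters
#'
#' Gaussian weights everywhere; used for chance-level checks.
#'
#' @inheritParams init_network
#' @param sd weight standard deviation.
#' @return A `network_params`.
#' @export
random_network <- function(n_groups, n_gaze = 9, m = 5, n_classes = 9,
                           unroll_T = 9, sd = 0.5, seed = 1) {
  n_px <- m^2; n_in <- 4 * n_px; n_h <- n_px * n_groups
  with_seed(seed, {
    structure(list(
      win = array(stats::rnorm(n_px * n_in * n_groups * n_gaze, 0, sd),
                  dim = c(n_px, n_in, n_groups, n_gaze)),
      wrec = matrix(stats::rnorm(n_gaze^2, 0, sd / n_gaze), n_gaze, n_gaze),
      wout = matrix(stats::rnorm(n_classes * n_h * n_gaze, 0, sd),
                    n_classes, n_h * n_gaze),
      bias = matrix(stats::rnorm(n_h * n_gaze, 0, sd), n_h, n_gaze),
      m = m, n_groups = n_groups, n_gaze = n_gaze, n_classes = n_classes,
      unroll_T = unroll_T), class = "network_params")
  })
}

#' @export
print.network_params <- function(x, ...) {
  cat("network_params:", x$n_gaze, "gaze blocks,", x$n_groups,
      "channel groups, hidden", x$m, "x", x$m, "maps, unroll_T =",
      x$unroll_T, "\n")
  invisible(x)
}

# ---- forward / loss / gradients -------------------------------------------

as_input_tensor <- function(Z) {
  if (length(dim(Z)) == 3) dim(Z) <- c(dim(Z), 1)
  Z
}

# Feed-forward drive FFh (n_h, B, Q) from the input tensor.
ff_drive <- function(params, Z, active) {
  dz <- dim(Z)
  n_in <- dz[1]; G <- dz[2]; Q <- dz[3]; B <- dz[4]
  n_px <- params$m^2
  FF <- array(0, dim = c(n_px, G, B, Q))
  for (q in if (is.null(active)) seq_len(Q) else active)
    for (g in seq_len(G))
      FF[, g, , q] <- params$win[, , g, q] %*% matrix(Z[, g, q, ], n_in, B)
  dim(FF) <- c(n_px * G, B, Q)
  FF
}

#' Forward pass of the recurrent gaze-block network
#'
#' Hidden activations start at zero and are iterated `unroll_T` steps of
#' a_j(q) = S(FF_j(q) + sum_p wrec[q, p] a_j(p) + b_j(q)); gaze blocks
#' outside `active_gazes` receive null feed-forward input (their hidden
#' units still participate in the recurrence).  Class scores are the linear
#' readout of all hidden units; ties in the argmax go to the lowest class.
#'
#' @param params a `network_params`.
#' @param Z input tensor (4m^2, n_groups, n_gaze, B) or a single example
#'   (4m^2, n_groups, n_gaze).
#' @param active_gazes nonempty subset of gaze indices (default all).
#' @param keep_hidden return the hidden state trajectory.
#' @return list: `scores` (n_classes x B), `y` (sigmoid scores),
#'   `pred` (B), optionally `hidden` (n_h, B, n_gaze) and `trajectory`.
#' @export
forward_network <- function(params, Z, active_gazes = NULL,
                            keep_hidden = FALSE) {
  Z <- as_input_tensor(Z)
  Q <- params$n_gaze; B <- dim(Z)[4]
  if (!is.null(active_gazes) && length(active_gazes) == 0)
    stop("active_gazes must be a nonempty subset of gaze blocks")
  FFh <- ff_drive(params, Z, active_gazes)
  n_h <- dim(FFh)[1]
  H <- array(0, dim = c(n_h, B, Q))
  traj <- if (keep_hidden) vector("list", params$unroll_T) else NULL
  for (t in seq_len(params$unroll_T)) {
    R <- matrix(H, n_h * B, Q) %*% t(params$wrec)
    pre <- FFh + array(R, dim = c(n_h, B, Q))
    for (q in seq_len(Q)) pre[, , q] <- pre[, , q] + params$bias[, q]
    H <- sigmoid(pre)
    if (keep_hidden) traj[[t]] <- H
  }
  Hv <- aperm(H, c(1, 3, 2))
  dim(Hv) <- c(n_h * Q, B)
  scores <- params$wout %*% Hv
  y <- sigmoid(scores)
  pred <- apply(scores, 2, which.max)     # ties resolve to lowest class id
  out <- list(scores = scores, y = y, pred = pred)
  if (keep_hidden) { out$hidden <- H; out$trajectory <- traj }
  out
}

one_hot <- function(labels, n_classes) {
  T9 <- matrix(0, n_classes, length(labels))
  T9[cbind(labels, seq_along(labels))] <- 1
  T9
}

#' Training loss of the network on labelled inputs
#'
#' The logistic error is the cross-entropy between the sigmoid outputs and
#' the 1-out-of-N targets (summed over classes, averaged over examples);
#' `"sse"` is the corresponding half sum of squares.
#'
#' @inheritParams forward_network
#' @param labels integer class labels (1-based).
#' @param loss `"logistic"` or `"sse"`.
#' @return scalar loss.
#' @export
network_loss <- function(params, Z, labels, loss = c("logistic", "sse"),
                         active_gazes = NULL) {
  loss <- match.arg(loss)
  fw <- forward_network(params, Z, active_gazes)
  B <- length(labels)
  T9 <- one_hot(labels, params$n_classes)
  if (loss == "logistic") {
    yc <- pmin(pmax(fw$y, 1e-12), 1 - 1e-12)
    -sum(T9 * log(yc) + (1 - T9) * log(1 - yc)) / B
  } else {
    0.5 * sum((fw$y - T9)^2) / B
  }
}

#' Analytic BPTT gradients of the training loss
#'
#' Backpropagation through the unrolled recurrence; returns gradients for
#' all four parameter groups plus the loss value.
#'
#' @inheritParams network_loss
#' @return list `loss`, `win`, `wrec`, `wout`, `bias` (shapes match params).
#' @export
network_gradients <- function(params, Z, labels, loss = c("logistic", "sse"),
                              active_gazes = NULL) {
  loss <- match.arg(loss)
  Z <- as_input_tensor(Z)
  Q <- params$n_gaze; B <- dim(Z)[4]
  G <- params$n_groups; n_px <- params$m^2; n_in <- 4 * n_px
  FFh <- ff_drive(params, Z, active_gazes)
  n_h <- dim(FFh)[1]
  Tn <- params$unroll_T
  A <- vector("list", Tn)
  H <- array(0, dim = c(n_h, B, Q))
  for (t in seq_len(Tn)) {
    R <- matrix(H, n_h * B, Q) %*% t(params$wrec)
    pre <- FFh + array(R, dim = c(n_h, B, Q))
    for (q in seq_len(Q)) pre[, , q] <- pre[, , q] + params$bias[, q]
    H <- sigmoid(pre)
    A[[t]] <- H
  }
  Hv <- aperm(H, c(1, 3, 2)); dim(Hv) <- c(n_h * Q, B)
  scores <- params$wout %*% Hv
  y <- sigmoid(scores)
  T9 <- one_hot(labels, params$n_classes)
  if (loss == "logistic") {
    yc <- pmin(pmax(y, 1e-12), 1 - 1e-12)
    E <- -sum(T9 * log(yc) + (1 - T9) * log(1 - yc)) / B
    dscores <- (y - T9) / B
  } else {
    E <- 0.5 * sum((y - T9)^2) / B
    dscores <- (y - T9) * y * (1 - y) / B
  }
  dwout <- dscores %*% t(Hv)
  dHv <- crossprod(params$wout, dscores)
  dim(dHv) <- c(n_h, Q, B)
  dH <- aperm(dHv, c(1, 3, 2))
  dwrec <- matrix(0, Q, Q)
  dbias <- matrix(0, n_h, Q)
  dFF <- array(0, dim = c(n_h, B, Q))
  for (t in rev(seq_len(Tn))) {
    At <- A[[t]]
    dPre <- dH * At * (1 - At)
    dbias <- dbias + apply(dPre, c(1, 3), sum)
    dFF <- dFF + dPre
    if (t > 1)
      dwrec <- dwrec + crossprod(matrix(dPre, n_h * B, Q),
                                 matrix(A[[t - 1]], n_h * B, Q))
    dH <- array(matrix(dPre, n_h * B, Q) %*% params$wrec,
                dim = c(n_h, B, Q))
  }
  if (!is.null(active_gazes)) {
    inactive <- setdiff(seq_len(Q), active_gazes)
    dFF[, , inactive] <- 0
  }
  dim(dFF) <- c(n_px, G, B, Q)
  dwin <- array(0, dim = dim(params$win))
  for (q in seq_len(Q))
    for (g in seq_len(G))
      dwin[, , g, q] <- matrix(dFF[, g, , q], n_px, B) %*%
        t(matrix(Z[, g, q, ], n_in, B))
  list(loss = E, win = dwin, wrec = dwrec, wout = dwout, bias = dbias)
}

#' Train the network with batch backpropagation through time
#'
#' Plain batch gradient descent on the logistic error against 1-out-of-N
#' targets, unrolling the recurrence `unroll_T` steps; stops at `max_iters`
#' or when the error drops below `target_error`.  Deterministic given the
#' initial parameters.
#'
#' @param params initial `network_params` (see [init_network()]).
#' @param Z input tensor (training examples).
#' @param labels integer class labels.
#' @param lambda learning rate.
#' @param max_iters iteration cap.
#' @param target_error stop when the batch error falls below this.
#' @param loss `"logistic"` (default) or `"sse"`.
#' @param lr_halving halve lambda whenever the batch loss increases.
#' @param verbose print the loss every 50 iterations.
#' @return list: trained `params`, numeric `trace` of per-iteration loss,
#'   `converged`, `iters`.
#' @export
train_bptt <- function(params, Z, labels, lambda = 0.2, max_iters = 500,
                       target_error = 0.1, loss = c("logistic", "sse"),
                       lr_halving = FALSE, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(length(unique(labels)) >= 1)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iters)) {
    gr <- network_gradients(params, Z, labels, loss)
    if (!is.finite(gr$loss))
      stop("non-finite training loss at iteration ", it,
           " (lambda = ", lambda, "); inspect the feature normalization")
    trace <- c(trace, gr$loss)
    if (gr$loss < target_error) {
      return(list(params = params, trace = trace, converged = TRUE,
                  iters = it, lambda = lambda))
    }
    if (lr_halving && gr$loss > prev) lambda <- lambda / 2
    prev <- gr$loss
    params$win <- params$win - lambda * gr$win
    params$wrec <- params$wrec - lambda * gr$wrec
    params$wout <- params$wout - lambda * gr$wout
    params$bias <- params$bias - lambda * gr$bias
    if (verbose && it %% 50 == 0)
      message(sprintf("iter %4d  E = %.5f", it, gr$loss))
  }
  list(params = params, trace = trace, converged = FALSE,
       iters = max_iters, lambda = lambda)
}

#' Classification accuracy of the network
#'
#' @inheritParams network_loss
#' @return list: `overall` accuracy, `per_class` (named, NA for classes
#'   absent from `labels`), `pred`, `confusion` table.
#' @export
evaluate_network <- function(params, Z, labels, active_gazes = NULL) {
  fw <- forward_network(params, Z, active_gazes)
  per <- vapply(seq_len(params$n_classes), function(cl) {
    sel <- labels == cl
    if (!any(sel)) NA_real_ else mean(fw$pred[sel] == cl)
  }, numeric(1))
  names(per) <- paste0("class", seq_len(params$n_classes))
  list(overall = mean(fw$pred == labels), per_class = per, pred = fw$pred,
       confusion = table(factor(labels, levels = seq_len(params$n_classes)),
                         factor(fw$pred, levels = seq_len(params$n_classes))))
}

#' Mean accuracy as a function of the number of active gaze blocks
#'
#' Accumulates gaze blocks along random orderings and evaluates the network
#' with only the leading subset active.
#'
#' @inheritParams evaluate_network
#' @param n_orderings number of random gaze orderings to average.
#' @param seed RNG seed for the orderings.
#' @return numeric vector of length n_gaze: mean accuracy with 1..n_gaze
#'   active blocks.
#' @export
gaze_count_accuracy <- function(params, Z, labels, n_orderings = 20,
                                seed = 1) {
  Q <- params$n_gaze
  acc <- matrix(0, n_orderings, Q)
  perms <- with_seed(seed, replicate(n_orderings, sample(Q), simplify = FALSE))
  for (r in seq_len(n_orderings)) {
    for (k in seq_len(Q)) {
      acc[r, k] <- evaluate_network(params, Z, labels,
                                    active_gazes = perms[[r]][seq_len(k)])$overall
    }
  }
  colMeans(acc)
}

# ---- active gaze selection -------------------------------------------------

#' Active next-gaze selection for a single stimulus
#'
#' Starting from one gaze block, repeatedly adds the unused gaze whose
#' hidden-map total activation is highest under the current input, stopping
#' when the prediction confidence (top normalized sigmoid score) reaches
#' `threshold` or all blocks are used.
#'
#' @param params trained `network_params`.
#' @param z single-example input (4m^2, n_groups, n_gaze).
#' @param threshold confidence criterion in [0, 1]; 0 stops after the first
#'   gaze, an unreachable value uses all gazes (flagged not converged).
#' @param start_gaze initial gaze block (default: seeded random).
#' @param seed seed for the random initial gaze.
#' @return list: `gazes` (scanpath, in order), `pred` (per step),
#'   `confidence` (per step), `converged`.
#' @export
active_gaze_selection <- function(params, z, threshold, start_gaze = NULL,
                                  seed = 1) {
  Q <- params$n_gaze
  if (is.null(start_gaze))
    start_gaze <- with_seed(seed, sample.int(Q, 1))
  active <- start_gaze
  preds <- integer(0); confs <- numeric(0)
  converged <- FALSE
  repeat {
    fw <- forward_network(params, z, active_gazes = active,
                          keep_hidden = TRUE)
    preds <- c(preds, fw$pred)
    conf <- max(fw$y[, 1]) / sum(fw$y[, 1])
    confs <- c(confs, conf)
    if (conf >= threshold) { converged <- TRUE; break }
    if (length(active) == Q) break
    tot <- colSums(matrix(fw$hidden, dim(fw$hidden)[1], Q))  # per gaze map
    tot[active] <- -Inf
    active <- c(active, which.max(tot))
  }
  list(gazes = active, pred = preds, confidence = confs,
       converged = converged)
}

#' Scanpath length to a target classification rate
#'
#' For each labelled example, runs the active-selection scanpath from every
#' possible initial gaze and finds the first step at which the fraction of
#' runs predicting the correct class reaches `rate`; reports per-example
#' lengths and their median.
#'
#' @inheritParams evaluate_network
#' @param rate required classification rate (default 0.75).
#' @return list: `lengths` (per example; n_gaze when never reached, flagged
#'   in `reached`), `median`, `reached`.
#' @export
scanpath_to_rate <- function(params, Z, labels, rate = 0.75) {
  Z <- as_input_tensor(Z)
  Q <- params$n_gaze; B <- dim(Z)[4]
  lengths <- integer(B); reached <- logical(B)
  for (b in seq_len(B)) {
    z <- Z[, , , b, drop = FALSE]
    dim(z) <- dim(Z)[1:3]
    correct <- matrix(FALSE, Q, Q)        # start gaze x step
    for (s in seq_len(Q)) {
      res <- active_gaze_selection(params, z, threshold = 2,
                                   start_gaze = s)
      correct[s, seq_along(res$pred)] <- res$pred == labels[b]
    }
    rate_t <- colMeans(correct)
    hit <- which(rate_t >= rate)
    lengths[b] <- if (length(hit)) hit[1] else Q
    reached[b] <- length(hit) > 0
  }
  list(lengths = lengths, median = stats::median(lengths), reached = reached)
}
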