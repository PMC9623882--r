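# ---- small numeric helpers -------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never perturbs the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) stats::plogis(x)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Elementary rotation matrices (right-handed, fixed frame, angles in radians).
rot_x <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}
rot_y <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}
rot_z <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

# Rotation about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# ---- 1D kernels ------------------------------------------------------------

# Sampled Gaussian on a centered grid of `size` taps (even sizes sit on
# half-integer offsets), normalized to unit sum.
gauss_taps <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Gaussian first-derivative taps, normalized so that correlation with a unit
# ramp returns exactly 1 (the derivative is then exact on linear inputs).
gauss_deriv_taps <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  d <- x * g
  d <- d - mean(d) * 0      # antisymmetric by construction, zero sum
  d / sum(d * x)
}

# ---- separable filtering as banded matrices --------------------------------

# Matrix implementing 1D 'valid' correlation with `taps` on a signal of
# length n_in; output length n_in - k + 1.
conv_mat_valid <- function(n_in, taps) {
  k <- length(taps)
  n_out <- n_in - k + 1
  stopifnot(n_out >= 1)
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) M[i, i:(i + k - 1)] <- taps
  M
}

# Same-size 1D correlation with reflected (symmetric) boundary handling.
conv_mat_reflect <- function(n, taps) {
  k <- length(taps)
  h <- (k - 1) / 2
  stopifnot(k %% 2 == 1)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (t in seq_len(k)) {
      j <- i + t - 1 - h
      # reflect about the edges (symmetric padding, no repeated edge sample)
      while (j < 1 || j > n) {
        if (j < 1) j <- 2 - j
        if (j > n) j <- 2 * n - j
      }
      M[i, j] <- M[i, j] + taps[t]
    }
  }
  M
}

# Area-averaging resize matrix (n_out x n_in): each output pixel averages the
# input interval it covers, with fractional overlap at the edges.
pool_area_mat <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  w <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * w
    hi <- i * w
    for (j in ceiling(lo + 1e-12):ceiling(hi - 1e-12)) {
      ov <- min(hi, j) - max(lo, j - 1)
      M[i, j] <- ov / w
    }
  }
  M
}

# Strided Gaussian pooling matrix: windows of `size` taps, step `stride`.
pool_gauss_mat <- function(n_in, size, stride, sigma) {
  n_out <- (n_in - size) %/% stride + 1
  g <- gauss_taps(size, sigma)
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    j0 <- (i - 1) * stride
    M[i, j0 + seq_len(size)] <- g
  }
  M
}

# Dense same-size Gaussian smoothing matrix with truncation-renormalized rows
# (each output is a proper weighted average whatever the boundary distance).
smooth_mat <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  x <- seq_len(n)
  M <- outer(x, x, function(i, j) exp(-(i - j)^2 / (2 * sd^2)))
  M / rowSums(M)
}

# ---- 2D FFT correlation ----------------------------------------------------

# Cross-correlation of `img` with a centered kernel, same-size output,
# zero-padded boundaries.  Kernel FFTs can be precomputed with corr2_plan().
corr2_plan <- function(kern, dim_img) {
  k1 <- nrow(kern); k2 <- ncol(kern)
  n1 <- nextn(dim_img[1] + k1 - 1, c(2, 3, 5))
  n2 <- nextn(dim_img[2] + k2 - 1, c(2, 3, 5))
  kp <- matrix(0, n1, n2)
  # place the flipped kernel so that its center lands on index (1, 1)
  kf <- kern[k1:1, k2:1, drop = FALSE]
  h1 <- (k1 - 1) %/% 2; h2 <- (k2 - 1) %/% 2
  i1 <- ((seq_len(k1) - 1 - (k1 - 1 - h1)) %% n1) + 1
  i2 <- ((seq_len(k2) - 1 - (k2 - 1 - h2)) %% n2) + 1
  kp[i1, i2] <- kf
  list(K = stats::fft(kp), n1 = n1, n2 = n2, d1 = dim_img[1], d2 = dim_img[2])
}

img_fft <- function(img, plan) {
  ip <- matrix(0, plan$n1, plan$n2)
  ip[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  stats::fft(ip)
}

# Apply a planned (possibly complex-valued) kernel FFT to a precomputed image
# FFT; returns the same-size complex correlation map.
corr2_apply <- function(IF, plan) {
  out <- stats::fft(IF * plan$K, inverse = TRUE) / (plan$n1 * plan$n2)
  out[seq_len(plan$d1), seq_len(plan$d2)]
}

corr2 <- function(img, kern) {
  plan <- corr2_plan(kern, dim(img))
  Re(corr2_apply(img_fft(img, plan), plan))
}

# ---- bilinear sampling / splatting ----------------------------------------

# Sample matrix M (pixel centers at integer coordinates 1..n) at continuous
# positions; returns NA outside the grid or where `valid` is FALSE for any
# of the four neighbours.
bilinear_interp <- function(M, x, y, valid = NULL) {
  n1 <- nrow(M); n2 <- ncol(M)
  i0 <- floor(x); j0 <- floor(y)
  fx <- x - i0; fy <- y - j0
  ok <- i0 >= 1 & i0 <= n1 - 1 & j0 >= 1 & j0 <= n2 - 1
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  i0k <- i0[ok]; j0k <- j0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  id <- function(i, j) (j - 1L) * n1 + i
  v00 <- M[id(i0k, j0k)];     v10 <- M[id(i0k + 1, j0k)]
  v01 <- M[id(i0k, j0k + 1)]; v11 <- M[id(i0k + 1, j0k + 1)]
  out[ok] <- v00 * (1 - fxk) * (1 - fyk) + v10 * fxk * (1 - fyk) +
    v01 * (1 - fxk) * fyk + v11 * fxk * fyk
  if (!is.null(valid)) {
    bad <- rep(FALSE, length(x))
    bad[ok] <- !(valid[id(i0k, j0k)] & valid[id(i0k + 1, j0k)] &
                   valid[id(i0k, j0k + 1)] & valid[id(i0k + 1, j0k + 1)])
    out[bad] <- NA_real_
  }
  out
}

# Accumulate unit-mass dots at continuous positions into an n1 x n2 image.
# Each dot has a small Gaussian footprint (sd `dot_sigma` px, truncated at
# `radius` px): an anti-aliased ~1 px dot whose sampled spectrum carries
# negligible energy near Nyquist, which suppresses pixel-locking bias in
# sub-pixel disparity estimation.
bilinear_splat <- function(x, y, n1, n2, w = NULL, dot_sigma = 0.6,
                           radius = 2L) {
  if (is.null(w)) w <- rep(1, length(x))
  v <- numeric(n1 * n2)
  i0 <- round(x); j0 <- round(y)
  offs <- -radius:radius
  for (du in offs) for (dv in offs) {
    ci <- i0 + du; cj <- j0 + dv
    cw <- w * exp(-((ci - x)^2 + (cj - y)^2) / (2 * dot_sigma^2))
    ok <- ci >= 1 & ci <= n1 & cj >= 1 & cj <= n2 & cw > 1e-8
    if (!any(ok)) next
    idx <- (cj[ok] - 1L) * n1 + ci[ok]
    s <- rowsum(cw[ok], idx)
    at <- as.integer(rownames(s))
    v[at] <- v[at] + s[, 1]
  }
  matrix(v, n1, n2)
}
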