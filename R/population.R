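# Distributed encoding of vector disparity by a population of binocular
# energy complex cells: oriented Gabor quadrature pairs with an interocular
# phase shift delta-psi, which confers a preferred disparity of
# delta_psi / (2*pi*omega0) pixels along the channel direction.

#' Tuning bank of binocular disparity channels
#'
#' M orientations uniformly spaced over [0, pi) times L interocular phase
#' shifts (symmetric about zero in steps of pi/4 by default, 7 values).
#' The peak frequency and envelope scale with the rendering resolution so
#' that the preferred-disparity range spans the disparity gamut of the
#' simulated geometry in visual-angle terms: at the reference 123 px the
#' defaults are omega0 = 0.045 cycles/px and sigma = 7 px, giving preferred
#' disparities up to (3*pi/4)/(2*pi*0.045) ~ 8.3 px.
#'
#' @param px image resolution the bank will filter (pixels per side).
#' @param n_ori number of orientation channels M.
#' @param n_phase number of phase-shift values L (odd; symmetric grid).
#' @param base_omega0,base_sigma,base_px reference tuning at `base_px`.
#' @param normalize divide complex-cell energy by the local monocular energy
#'   (plus `epsilon`) so responses are contrast-bounded.
#' @param epsilon normalization floor.
#' @return A `disparity_bank` with fields `theta` (rad), `dpsi` (rad),
#'   `omega0` (cycles/px), `sigma` (px), `ksize` (odd kernel size).
#' @export
disparity_bank <- function(px = 123, n_ori = 8, n_phase = 7,
                           base_omega0 = 0.045, base_sigma = 7,
                           base_px = 123, normalize = TRUE,
                           epsilon = 1e-6) {
  stopifnot(n_ori >= 2, n_ori %% 2 == 0, n_phase >= 1, n_phase %% 2 == 1)
  omega0 <- base_omega0 * base_px / px
  sigma <- base_sigma * px / base_px
  ksize <- 2 * ceiling(2 * sigma) + 1
  half <- (n_phase - 1) / 2
  structure(list(theta = (seq_len(n_ori) - 1) * pi / n_ori,
                 dpsi = seq(-half, half) * pi / 4,
                 omega0 = omega0, sigma = sigma, ksize = ksize, px = px,
                 normalize = normalize, epsilon = epsilon),
            class = "disparity_bank")
}

#' Number of disparity channels in a bank
#' @param bank a [disparity_bank()].
#' @return integer, L x M.
#' @export
n_channels <- function(bank) length(bank$theta) * length(bank$dpsi)

#' Preferred disparities of a bank (px, along each channel direction)
#' @param bank a [disparity_bank()].
#' @return numeric vector, one per phase-shift value.
#' @export
preferred_disparities <- function(bank) bank$dpsi / (2 * pi * bank$omega0)

#' @export
print.disparity_bank <- function(x, ...) {
  cat("disparity_bank:", length(x$theta), "orientations x", length(x$dpsi),
      "phase shifts =", n_channels(x), "channels\n")
  cat(sprintf("  omega0 %.4f c/px, sigma %.2f px, kernel %d px, preferred disparities %s px\n",
              x$omega0, x$sigma, x$ksize,
              paste(sprintf("%+.2f", preferred_disparities(x)), collapse = " ")))
  invisible(x)
}

#' Oriented Gabor receptive field
#'
#' Isotropic Gaussian envelope with a cosine carrier along direction
#' `theta` (the direction orthogonal to the receptive-field stripes, i.e.
#' the direction of disparity sensitivity).  Even-phase kernels have their
#' envelope-weighted mean removed so that uniform luminance evokes no
#' response.
#'
#' @param theta carrier direction (rad).
#' @param psi carrier phase (rad): 0 gives an even-symmetric kernel, pi/2 an
#'   odd-symmetric one.
#' @param omega0 peak spatial frequency (cycles/px), > 0.
#' @param sigma envelope standard deviation (px), > 0.
#' @param size odd kernel size (px), >= 3.
#' @return size x size matrix (first index = x1).
#' @export
gabor_rf <- function(theta, psi, omega0, sigma, size) {
  if (omega0 <= 0 || sigma <= 0) stop("frequency and envelope must be positive")
  if (size < 3 || size %% 2 != 1) stop("kernel size must be odd and >= 3")
  x <- seq_len(size) - (size + 1) / 2
  X1 <- matrix(x, size, size); X2 <- matrix(x, size, size, byrow = TRUE)
  u <- X1 * cos(theta) + X2 * sin(theta)
  env <- exp(-(X1^2 + X2^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * omega0 * u + psi)
  k - (sum(k) / sum(env)) * env       # zero-DC, envelope-localized
}

# Per-orientation even/odd kernel FFT plans for a given image size.
bank_filters <- function(bank, dim_img) {
  lapply(bank$theta, function(th) {
    ke <- gabor_rf(th, 0, bank$omega0, bank$sigma, bank$ksize)
    ko <- gabor_rf(th, pi / 2, bank$omega0, bank$sigma, bank$ksize)
    corr2_plan(ke + 1i * ko, dim_img)   # complex kernel: Re=even, Im=odd
  })
}

# Complex-valued monocular response C = (even * I) + i (odd * I) for each
# orientation; list over orientations.
monocular_responses <- function(img, bank, filters = NULL) {
  if (is.null(filters)) filters <- bank_filters(bank, dim(img))
  IF <- img_fft(img, filters[[1]])
  lapply(filters, function(pl) corr2_apply(IF, pl))
}

#' Binocular simple-cell response map
#'
#' Linear binocular stage: the sum of left and right monocular Gabor
#' responses sharing orientation, frequency and envelope, with the
#' interocular phase shift split symmetrically (psi_L = +dpsi/2,
#' psi_R = -dpsi/2); `psi_offset` shifts both monocular phases and selects
#' the quadrature-pair member.
#'
#' @param pair a `stereo_pair` (left/right images of equal size).
#' @param theta,dpsi channel direction (rad) and interocular phase shift.
#' @param bank a [disparity_bank()] providing omega0/sigma/kernel size.
#' @param psi_offset common phase offset (rad).
#' @return response matrix, same size as the images.
#' @export
simple_cell_response <- function(pair, theta, dpsi, bank,
                                 psi_offset = 0) {
  if (!all(dim(pair$left) == dim(pair$right)))
    stop("left/right image shape mismatch")
  ke <- gabor_rf(theta, 0, bank$omega0, bank$sigma, bank$ksize)
  ko <- gabor_rf(theta, pi / 2, bank$omega0, bank$sigma, bank$ksize)
  pl <- corr2_plan(ke + 1i * ko, dim(pair$left))
  CL <- corr2_apply(img_fft(pair$left, pl), pl)
  CR <- corr2_apply(img_fft(pair$right, pl), pl)
  # monocular response at phase psi: Re(C e^{-i psi}) = even cos + odd sin
  Re(CL * exp(-1i * (psi_offset + dpsi / 2))) +
    Re(CR * exp(-1i * (psi_offset - dpsi / 2)))
}

#' Binocular energy complex-cell response map
#'
#' Sum of squared quadrature-pair simple-cell responses; with
#' `bank$normalize` the energy is divided by the local monocular energy
#' plus `bank$epsilon`, bounding it to [0, 2].
#'
#' @inheritParams simple_cell_response
#' @return nonnegative response matrix.
#' @export
complex_cell_response <- function(pair, theta, dpsi, bank) {
  r0 <- simple_cell_response(pair, theta, dpsi, bank, 0)
  r1 <- simple_cell_response(pair, theta, dpsi, bank, pi / 2)
  r <- r0^2 + r1^2
  if (isTRUE(bank$normalize)) {
    ke <- gabor_rf(theta, 0, bank$omega0, bank$sigma, bank$ksize)
    ko <- gabor_rf(theta, pi / 2, bank$omega0, bank$sigma, bank$ksize)
    pl <- corr2_plan(ke + 1i * ko, dim(pair$left))
    CL <- corr2_apply(img_fft(pair$left, pl), pl)
    CR <- corr2_apply(img_fft(pair$right, pl), pl)
    r <- r / (Mod(CL)^2 + Mod(CR)^2 + bank$epsilon)
  }
  r
}

#' Population response of the full disparity channel bank
#'
#' Stacks the complex-cell energy of every (orientation k, phase l) channel.
#' Internally each orientation is filtered once per eye with a complex
#' (even + i odd) Gabor kernel; all L phase channels then follow from the
#' closed form |C_L e^{+i dpsi/2} + C_R e^{-i dpsi/2}|^2.  Maps are
#' average-pooled from the rendering resolution to `pool_to` pixels.
#'
#' @param pair a `stereo_pair`.
#' @param bank a [disparity_bank()] (nonempty).
#' @param pool_to output map resolution (default 43); NULL keeps full size.
#' @param filters optional precomputed [bank_filters()] plans.
#' @return A `population_response`: array `resp` of dim (n, n, M, L), the
#'   bank, and bookkeeping fields.
#' @export
population_response <- function(pair, bank, pool_to = 43, filters = NULL) {
  if (!inherits(bank, "disparity_bank") || n_channels(bank) == 0)
    stop("empty or invalid tuning bank")
  if (!all(dim(pair$left) == dim(pair$right)))
    stop("left/right image shape mismatch")
  M <- length(bank$theta); L <- length(bank$dpsi)
  px <- nrow(pair$left)
  if (is.null(filters)) filters <- bank_filters(bank, dim(pair$left))
  IFL <- img_fft(pair$left, filters[[1]])
  IFR <- img_fft(pair$right, filters[[1]])
  n_out <- if (is.null(pool_to)) px else pool_to
  P <- if (is.null(pool_to) || pool_to == px) NULL else
    pool_area_mat(px, pool_to)
  resp <- array(0, dim = c(n_out, n_out, M, L))
  for (k in seq_len(M)) {
    CL <- corr2_apply(IFL, filters[[k]])
    CR <- corr2_apply(IFR, filters[[k]])
    mono <- Mod(CL)^2 + Mod(CR)^2
    Xr <- Re(CL * Conj(CR)); Xi <- Im(CL * Conj(CR))
    for (l in seq_len(L)) {
      dp <- bank$dpsi[l]
      r <- mono + 2 * (Xr * cos(dp) + Xi * sin(dp))   # 2 Re(X e^{-i dpsi})
      if (isTRUE(bank$normalize)) r <- r / (mono + bank$epsilon)
      r[r < 0] <- 0                       # clip tiny negative fft residue
      resp[, , k, l] <- if (is.null(P)) r else P %*% r %*% t(P)
    }
  }
  structure(list(resp = resp, bank = bank, px_in = px, n = n_out,
                 pose = pair$pose, gaze = pair$gaze),
            class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  d <- dim(x$resp)
  cat("population_response:", d[3], "orientations x", d[4],
      "phase channels, maps", d[1], "x", d[2], "\n")
  invisible(x)
}

#' Population decoding of the disparity field
#'
#' For each direction pair (theta_k, theta_k + pi/2) the two disparity
#' components are read out of the L phase channels, then rotated back to
#' the head-centric axes and averaged over direction pairs.  The default
#' `"phase"` decoder exploits the energy-model tuning r_l = a + b cos(w d -
#' dpsi_l): a least-squares fit of (a, b cos, b sin) over the phase channels
#' gives d = atan2 of the quadrature pair, which is exact for ideal
#' responses.  `"com"` is the rectified center-of-mass over preferred
#' disparities (baseline-subtracted channel-weighted average).
#'
#' @param pop a [population_response()].
#' @param method `"phase"` (default) or `"com"`.
#' @return list of matrices `delta1`, `delta2` in pixels of the encoding
#'   resolution (`pop$px_in` scale).
#' @export
decode_disparity <- function(pop, method = c("phase", "com")) {
  method <- match.arg(method)
  bank <- pop$bank
  M <- length(bank$theta); L <- length(bank$dpsi)
  prefs <- preferred_disparities(bank)      # px at the encoding resolution
  half <- M / 2
  n <- pop$n
  omega <- 2 * pi * bank$omega0
  X <- cbind(1, cos(bank$dpsi), sin(bank$dpsi))
  Xp <- solve(crossprod(X), t(X))           # 3 x L least-squares operator
  decode_channel <- function(kk) {
    R <- pop$resp[, , kk, ]
    if (method == "phase") {
      Rm <- matrix(R, n * n, L)
      cf <- Rm %*% t(Xp)                    # columns: a, b_cos, b_sin
      matrix(atan2(cf[, 3], cf[, 2]) / omega, n, n)
    } else {
      base <- apply(R, c(1, 2), mean)
      W <- pmax(R - as.vector(base), 0)
      num <- matrix(0, n, n); den <- matrix(0, n, n)
      for (l in seq_len(L)) {
        num <- num + prefs[l] * W[, , l]
        den <- den + W[, , l]
      }
      num / (den + 1e-12)
    }
  }
  d1 <- matrix(0, n, n); d2 <- matrix(0, n, n)
  for (k in seq_len(half)) {
    th <- bank$theta[k]
    c1 <- decode_channel(k); c2 <- decode_channel(k + half)
    d1 <- d1 + cos(th) * c1 - sin(th) * c2
    d2 <- d2 + sin(th) * c1 + cos(th) * c2
  }
  list(delta1 = d1 / half, delta2 = d2 / half)
}
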