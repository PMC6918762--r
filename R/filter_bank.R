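# Multi-scale texture filter bank: per scale sigma, n_orientations
# odd-symmetric + n_orientations even-symmetric elongated Gaussian-derivative
# kernels (orientations evenly spaced in [0, 180)), plus four
# rotation-invariant members (Gaussian at sigma/2 and sigma, LoG at sigma/2
# and sigma). With the four field scales and five orientations the bank has
# 56 members per image channel.

#' Build the texture filter bank
#'
#' Even-symmetric members are second derivatives of an elongated Gaussian
#' (3:1 aspect by default, derivative taken across the short axis);
#' odd-symmetric members are their Hilbert-transform pairs along the same
#' axis. Rotation-invariant members are two plain Gaussians and two
#' Laplacian-of-Gaussian kernels at sigma/2 and sigma. Kernels are sampled on
#' a `2*ceiling(2*sigma)+1` square window and L1-normalised: zero-mean
#' families by their absolute sum, plain Gaussians to unit sum.
#'
#' @param scales Gaussian scales sigma in pixels; default the field protocol's
#'   `c(16, 24, 32, 48)`.
#' @param n_orientations oriented kernels per symmetry class, default 5.
#' @param aspect elongation of the oriented Gaussians (long/short axis).
#' @return an object of class `filter_bank`: list with `kernels` (list of
#'   matrices, scale-major order: odd by orientation, even by orientation,
#'   gaussian, log) and a `meta` data frame (scale, family, orientation).
#' @export
build_bank <- function(scales = c(16, 24, 32, 48), n_orientations = 5,
                       aspect = 3) {
  if (!length(scales)) stop("scales must be non-empty")
  if (any(scales <= 0)) stop("scales must be positive")
  if (n_orientations < 1) stop("n_orientations must be >= 1")
  thetas <- seq(0, 180, length.out = n_orientations + 1)[seq_len(n_orientations)]
  kernels <- list(); meta <- NULL
  for (s in scales) {
    half <- ceiling(2 * s)
    for (th in thetas) {
      kernels <- c(kernels, list(oriented_kernel(s, th, aspect, half, odd = TRUE)))
      meta <- rbind(meta, data.frame(scale = s, family = "odd-deriv", orientation = th))
    }
    for (th in thetas) {
      kernels <- c(kernels, list(oriented_kernel(s, th, aspect, half, odd = FALSE)))
      meta <- rbind(meta, data.frame(scale = s, family = "even-deriv", orientation = th))
    }
    for (gs in c(s / 2, s)) {
      kernels <- c(kernels, list(gaussian_kernel(gs, half)))
      meta <- rbind(meta, data.frame(scale = s, family = "gaussian", orientation = NA))
    }
    for (gs in c(s / 2, s)) {
      kernels <- c(kernels, list(log_kernel(gs, half)))
      meta <- rbind(meta, data.frame(scale = s, family = "log", orientation = NA))
    }
  }
  structure(list(kernels = kernels, meta = meta,
                 scales = scales, n_orientations = n_orientations),
            class = "filter_bank")
}

#' @export
length.filter_bank <- function(x) length(x$kernels)

kernel_grid <- function(half) {
  g <- seq(-half, half)
  list(x = matrix(rep(g, each = 2 * half + 1), 2 * half + 1),   # column coord
       y = matrix(rep(g, times = 2 * half + 1), 2 * half + 1))  # row coord
}

# Oriented kernel at angle theta (degrees, 0 = horizontal edge axis):
# G''(u; sigma/aspect) * G(v; sigma) evaluated in rotated coordinates, u
# across the filter axis, v along it. Odd member replaces the second
# derivative profile with its Hilbert transform.
oriented_kernel <- function(sigma, theta, aspect, half, odd = FALSE) {
  g <- kernel_grid(half)
  th <- theta * pi / 180
  u <- g$x * sin(th) + g$y * cos(th)
  v <- g$x * cos(th) - g$y * sin(th)
  su <- sigma / aspect
  prof <- if (odd) hilbert_gauss2(u, su) else gauss2_profile(u, su)
  k <- prof * exp(-v^2 / (2 * sigma^2))
  normalize_zero_mean(k)
}

gauss2_profile <- function(u, s) (u^2 / s^4 - 1 / s^2) * exp(-u^2 / (2 * s^2))

# Hilbert transform of the second-derivative-of-Gaussian profile, computed
# once per scale on a dense 1-D grid by FFT (transfer function -i*sign(f))
# and interpolated at the rotated coordinates.
hilbert_gauss2 <- function(u, s) {
  extent <- max(abs(u)) + 6 * s
  n <- 2^ceiling(log2(max(1024, 16 * extent)))
  step <- 2 * extent / n
  grid <- (seq_len(n) - n / 2 - 1) * step
  f <- gauss2_profile(grid, s)
  freq <- c(seq(0, n / 2 - 1), seq(-n / 2, -1))
  # fftshift before the transform so the profile is centered at index 1
  f0 <- c(f[(n / 2 + 1):n], f[1:(n / 2)])
  h0 <- Re(stats::fft(stats::fft(f0) * (-1i) * sign(freq), inverse = TRUE)) / n
  h <- c(h0[(n / 2 + 1):n], h0[1:(n / 2)])
  stats::approx(grid, h, xout = as.vector(u), rule = 2)$y |>
    matrix(nrow(u), ncol(u))
}

gaussian_kernel <- function(s, half) {
  g <- kernel_grid(half)
  k <- exp(-(g$x^2 + g$y^2) / (2 * s^2))
  k / sum(k)
}

log_kernel <- function(s, half) {
  g <- kernel_grid(half)
  r2 <- g$x^2 + g$y^2
  k <- (r2 / s^4 - 2 / s^2) * exp(-r2 / (2 * s^2))
  normalize_zero_mean(k)
}

normalize_zero_mean <- function(k) {
  k <- k - mean(k)
  k / sum(abs(k))
}

#' Per-pixel texture features of a Lab scene
#'
#' Convolves each of the L, a, b channels with every kernel of the bank
#' (sliding inner product with reflect padding — the image-filtering
#' convention, under which an impulse responds with the flipped kernel).
#' With the default 56-member bank this yields 168 feature maps per pixel.
#'
#' @param lab a `lab_scene`.
#' @param bank a `filter_bank`.
#' @return an object of class `feature_stack`: `features` is an
#'   H x W x (3*length(bank)) array, `channel_order` records the (channel,
#'   kernel) layout (channel-major: all L responses, then a, then b).
#' @export
apply_bank <- function(lab, bank) {
  stopifnot(inherits(lab, "lab_scene"), inherits(bank, "filter_bank"))
  channels <- list(L = lab$L, a = lab$a, b = lab$b)
  ks <- vapply(bank$kernels, function(k) nrow(k), integer(1))
  half <- max((ks - 1L) %/% 2L)
  d <- dim(lab$L)
  if (any(d < max(ks)))
    stop("image (", paste(d, collapse = "x"),
         ") smaller than largest kernel support (", max(ks), ")")
  nk <- length(bank$kernels)
  feats <- array(NA_real_, c(d[1], d[2], 3L * nk))
  i <- 0L
  for (ch in channels) {
    pad <- reflect_pad(ch, half)
    fpad <- stats::fft(pad)
    for (k in bank$kernels) {
      i <- i + 1L
      feats[, , i] <- fft_convolve_padded(fpad, dim(pad), k, half, d)
    }
  }
  structure(list(features = feats,
                 channel_order = paste(rep(names(channels), each = nk),
                                       rep(seq_len(nk), 3L), sep = ".")),
            class = "feature_stack")
}

reflect_pad <- function(m, p) {
  if (p == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  ridx <- c(rev(seq_len(p) + 1L), seq_len(h), h - seq_len(p))
  cidx <- c(rev(seq_len(p) + 1L), seq_len(w), w - seq_len(p))
  m[ridx, cidx]
}

# Circular FFT filtering on the padded plane; with padding >= kernel
# half-width the crop of the central block equals the linear result. The
# kernel is flipped so the product of transforms realises the sliding inner
# product rather than algebraic convolution.
fft_convolve_padded <- function(fpad, pdim, kernel, p, out_dim) {
  kernel <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel)))]
  kh <- (nrow(kernel) - 1L) %/% 2L
  kp <- matrix(0, pdim[1], pdim[2])
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  # shift so the kernel center sits at (1,1)
  kp <- kp[c((kh + 1):pdim[1], seq_len(kh)), c((kh + 1):pdim[2], seq_len(kh))]
  full <- Re(stats::fft(fpad * stats::fft(kp), inverse = TRUE)) / prod(pdim)
  full[p + seq_len(out_dim[1]), p + seq_len(out_dim[2])]
}

#' Direct spatial filtering (reference path)
#'
#' Plain O(H W k^2) sliding-inner-product summation with reflect padding;
#' the production path in [apply_bank()] is FFT-based and agrees with this
#' to numerical precision. Exposed for validation on small inputs.
#'
#' @param m numeric matrix.
#' @param kernel odd-sized square kernel.
#' @return matrix of the same size as `m`.
#' @export
convolve2_direct <- function(m, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  pad <- reflect_pad(m, kh)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    block <- pad[i + kh + seq(-kh, kh), j + kh + seq(-kh, kh)]
    out[i, j] <- sum(block * kernel)
  }
  out
}
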