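# Low-level vectorized image utilities shared across the pipeline.
# All matrices are indexed [row = y, col = x], 1-based; frame stacks are
# 3-D arrays dim = c(ny, nx, nt).

# Pad a matrix by `r` pixels on every side with edge replication.
pad_replicate <- function(m, r) {
  ny <- nrow(m)
  nx <- ncol(m)
  ri <- c(rep(1L, r), seq_len(ny), rep(ny, r))
  ci <- c(rep(1L, r), seq_len(nx), rep(nx, r))
  m[ri, ci, drop = FALSE]
}

# Median of 9 values, vectorized over pixels: full compare-exchange sort of
# the 9 parallel planes, then take the middle plane. 36 pmin/pmax pairs on
# full matrices beats apply() by orders of magnitude.
median9 <- function(planes) {
  stopifnot(length(planes) == 9L)
  for (i in 1:8) {
    for (j in 1:(9 - i)) {
      lo <- pmin(planes[[j]], planes[[j + 1L]])
      hi <- pmax(planes[[j]], planes[[j + 1L]])
      planes[[j]] <- lo
      planes[[j + 1L]] <- hi
    }
  }
  planes[[5L]]
}

# 3x3 median filter of a single frame, edge-replicated border.
median3x3 <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  p <- pad_replicate(m, 1L)
  planes <- vector("list", 9L)
  k <- 0L
  for (dy in 0:2) {
    for (dx in 0:2) {
      k <- k + 1L
      planes[[k]] <- p[dy + seq_len(ny), dx + seq_len(nx), drop = FALSE]
    }
  }
  median9(planes)
}

# Separable Gaussian blur, edge-replicated border. Kernel truncated at
# 3*sigma (radius >= 1) and renormalized, matching common implementations.
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  ny <- nrow(m)
  nx <- ncol(m)
  # rows direction (blur along y)
  p <- m[c(rep(1L, r), seq_len(ny), rep(ny, r)), , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (j in seq_along(k)) {
    out <- out + k[j] * p[(j - 1L) + seq_len(ny), , drop = FALSE]
  }
  # columns direction (blur along x)
  p <- out[, c(rep(1L, r), seq_len(nx), rep(nx, r)), drop = FALSE]
  out <- matrix(0, ny, nx)
  for (j in seq_along(k)) {
    out <- out + k[j] * p[, (j - 1L) + seq_len(nx), drop = FALSE]
  }
  out
}

# Translate a frame by (dx, dy) pixels (x rightwards, y downwards) with
# bilinear interpolation; pixels sampled from outside the frame are 0.
# out(y, x) = in(y - dy, x - dx).
translate_bilinear <- function(m, dx, dy) {
  ny <- nrow(m)
  nx <- ncol(m)
  sr <- seq_len(ny) - dy
  sc <- seq_len(nx) - dx
  r0 <- floor(sr)
  c0 <- floor(sc)
  fr <- sr - r0
  fc <- sc - c0
  # zero-padded copy: source index i maps to i + 1; anything outside
  # [0, n + 1] clamps into the zero border and contributes nothing.
  p <- matrix(0, ny + 2L, nx + 2L)
  p[seq_len(ny) + 1L, seq_len(nx) + 1L] <- m
  cl <- function(i, n) pmin(pmax(i, 1L), n + 2L)
  ri0 <- cl(r0 + 1L, ny); ri1 <- cl(r0 + 2L, ny)
  ci0 <- cl(c0 + 1L, nx); ci1 <- cl(c0 + 2L, nx)
  outer(1 - fr, 1 - fc) * p[ri0, ci0, drop = FALSE] +
    outer(1 - fr, fc)   * p[ri0, ci1, drop = FALSE] +
    outer(fr, 1 - fc)   * p[ri1, ci0, drop = FALSE] +
    outer(fr, fc)       * p[ri1, ci1, drop = FALSE]
}

# Integer-pixel translate (nearest lattice shift), zero fill.
translate_integer <- function(m, dx, dy) {
  dx <- as.integer(round(dx))
  dy <- as.integer(round(dy))
  ny <- nrow(m)
  nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  oky <- ys >= 1L & ys <= ny
  okx <- xs >= 1L & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx], drop = FALSE]
  out
}

# Signed DFT sample frequencies (fftfreq * n), length n.
fft_freq_signed <- function(n) {
  f <- seq_len(n) - 1
  wrap <- f > floor((n - 1) / 2)
  f[wrap] <- f[wrap] - n
  f
}

# Estimate the translation (dx, dy) mapping `ref` onto `mov`
# (mov(y, x) ~= ref(y - dy, x - dx)) by cross-correlation with local
# upsampled-DFT refinement (matrix-multiply evaluation of the
# cross-correlation on a 1.5 px window at 1/upsample resolution).
# The cross-power spectrum is weighted by a spectral Gaussian (equivalent to
# circularly pre-smoothing both images with sd = presmooth px): this
# suppresses the high-frequency band where noise dominates and where
# bilinear-resampled images deviate from an ideal phase shift, which
# otherwise biases the subpixel peak, while keeping integer circular shifts
# exactly recoverable. Plain (unnormalized) cross-correlation is used rather
# than pure phase correlation: at the low SNR of luminescence imaging the
# signal-weighted spectrum localizes the peak better than a whitened one.
estimate_translation <- function(ref, mov, upsample = 100L, presmooth = 1) {
  if (all(ref == 0) || all(mov == 0)) {
    warning("degenerate (all-zero) frame: assuming zero shift")
    return(c(dx = 0, dy = 0))
  }
  ny <- nrow(ref)
  nx <- ncol(ref)
  cp <- stats::fft(mov) * Conj(stats::fft(ref))
  if (presmooth > 0) {
    gy <- exp(-2 * pi^2 * presmooth^2 * (fft_freq_signed(ny) / ny)^2)
    gx <- exp(-2 * pi^2 * presmooth^2 * (fft_freq_signed(nx) / nx)^2)
    cp <- cp * outer(gy, gx)^2
  }
  cc <- Re(stats::fft(cp, inverse = TRUE))
  pk <- which.max(cc)
  py <- ((pk - 1L) %% ny)
  px <- ((pk - 1L) %/% ny)
  if (py > ny / 2) py <- py - ny
  if (px > nx / 2) px <- px - nx
  # refine around the integer peak
  fy <- fft_freq_signed(ny)
  fx <- fft_freq_signed(nx)
  step <- 1 / upsample
  ys <- py + seq(-0.75, 0.75, by = step)
  xs <- px + seq(-0.75, 0.75, by = step)
  ey <- exp(2i * pi * outer(ys, fy) / ny)
  ex <- exp(2i * pi * outer(fx, xs) / nx)
  ccu <- Re(ey %*% cp %*% ex)
  u <- which(ccu == max(ccu), arr.ind = TRUE)[1L, ]
  c(dx = xs[u[2L]], dy = ys[u[1L]])
}

# Nearest-rank k-permille quantile: value at 1-based sorted index
# ceil(k * n / 1000), clamped to [1, n].
permille_nearest_rank <- function(x, k) {
  stopifnot(k >= 0, k <= 1000, length(x) >= 1L)
  s <- sort(x)
  n <- length(s)
  s[min(max(ceiling(k * n / 1000), 1L), n)]
}
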