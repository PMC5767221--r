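# Independent brute-force oracles and small fixtures, deliberately written
# with naive loops so they share no code path with the package internals.

# median of the 3x3 neighborhood of one interior pixel, by explicit sort
oracle_median3x3_at <- function(m, i, j) {
  v <- as.vector(m[(i - 1):(i + 1), (j - 1):(j + 1)])
  sort(v)[5]
}

# exhaustive within-class-variance Otsu over a 256-bin histogram
oracle_otsu <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  w <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / w) + 1L, nbins)
  cnt <- tabulate(idx, nbins)
  mids <- lo + (seq_len(nbins) - 0.5) * w
  best <- Inf; bt <- NA_integer_
  for (t in seq_len(nbins - 1L)) {
    n0 <- sum(cnt[1:t]); n1 <- sum(cnt[(t + 1):nbins])
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum(cnt[1:t] * mids[1:t]) / n0
    mu1 <- sum(cnt[(t + 1):nbins] * mids[(t + 1):nbins]) / n1
    wcv <- (sum(cnt[1:t] * (mids[1:t] - mu0)^2) +
              sum(cnt[(t + 1):nbins] * (mids[(t + 1):nbins] - mu1)^2)) / (n0 + n1)
    if (wcv < best) { best <- wcv; bt <- t }
  }
  lo + bt * w
}

# exhaustive minimum-cross-entropy (Li) scan over a 256-bin histogram
oracle_li <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  w <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / w) + 1L, nbins)
  cnt <- tabulate(idx, nbins)
  mids <- lo + (seq_len(nbins) - 0.5) * w
  best <- Inf; bt <- NA_integer_
  for (t in seq_len(nbins - 1L)) {
    n0 <- sum(cnt[1:t]); n1 <- sum(cnt[(t + 1):nbins])
    if (n0 == 0L || n1 == 0L) next
    s0 <- sum(cnt[1:t] * mids[1:t])
    s1 <- sum(cnt[(t + 1):nbins] * mids[(t + 1):nbins])
    ce <- -(s0 * log(s0 / n0) + s1 * log(s1 / n1))
    if (ce < best) { best <- ce; bt <- t }
  }
  lo + bt * w
}

# literal windowed Phansalkar mask by explicit per-pixel loops
oracle_phansalkar <- function(frame, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  mx <- max(frame)
  v <- if (mx > 0) frame / mx else frame
  ny <- nrow(v); nx <- ncol(v)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      vals <- c()
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          if (di * di + dj * dj > radius * radius) next
          ii <- min(max(i + di, 1L), ny)  # edge replication
          jj <- min(max(j + dj, 1L), nx)
          vals <- c(vals, v[ii, jj])
        }
      }
      mu <- mean(vals)
      sg <- sqrt(mean((vals - mu)^2))
      thr <- mu * (1 + p * exp(-q * mu) + k * (sg / r - 1))
      out[i, j] <- as.numeric(v[i, j] > thr)
    }
  }
  out
}

# circular (periodic) integer roll, for exact-shift registration fixtures
roll2 <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1L - dy) %% ny) + 1L, ((seq_len(nx) - 1L - dx) %% nx) + 1L]
}

# small fast phantom for unit tests (128 x 128, 5 frames)
small_phantom <- function(seed = 1L, n_frames = 5L, drift = c(0.3, -0.2),
                          noise_sd = 5) {
  spec <- phantom_spec(
    frame_shape = c(128L, 128L), n_frames = n_frames,
    soma = list(center = c(45, 45), radius = 12, amplitude = 1000, ratio = 0.50),
    neurites = list(
      list(from = c(56, 45), to = c(120, 40), width = 2, amplitude = 60, ratio = 0.55),
      list(from = c(48, 55), to = c(70, 115), width = 2, amplitude = 60, ratio = 0.55)
    ),
    spines = list(
      list(center = c(85, 37.5), radius = 2, amplitude = 40, ratio = 0.65),
      list(center = c(62, 82), radius = 2, amplitude = 40, ratio = 0.65)
    ),
    drift_per_frame = drift, noise_sd = noise_sd, seed = seed
  )
  generate_phantom(spec)
}

# textured scene with a smooth vignette to zero at the borders, the regime
# the registration contract targets (luminescent specimens on a dark field);
# SNR refers to the central signal amplitude over the noise SD
texture_scene <- function(seed, n = 128L, amplitude = 100) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- bretr:::gaussian_blur(m, 3)
  m <- m / stats::sd(m) * amplitude
  r2 <- outer((seq_len(n) - (n + 1) / 2)^2, (seq_len(n) - (n + 1) / 2)^2, "+")
  m * exp(-r2 / (2 * (n / 4)^2))
}
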