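# Donor masking. Five methods are provided: a constant global threshold, a
# per-frame median of a reference region, per-frame Otsu, per-frame
# Phansalkar local thresholding, and the composite method that combines
# Li thresholds of two blur-difference images with a global Otsu mask.
#
# One convention everywhere: a pixel is KEPT iff its value is strictly
# greater than the threshold. Masks are numeric arrays with values in {0, 1};
# multiplying a stack by its mask zeroes discarded pixels and leaves the rest
# bit-identical.

# 256-bin histogram over [min, max] of the values.
hist256 <- function(v, nbins = 256L) {
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) return(NULL)  # constant frame
  w <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / w) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  list(counts = counts, lo = lo, hi = hi, width = w,
       mids = lo + (seq_len(nbins) - 0.5) * w,
       edges = lo + seq_len(nbins - 1L) * w)  # candidate thresholds
}

#' Global Otsu threshold of one frame
#'
#' Picks, over a 256-bin histogram spanning the frame's value range, the
#' split that maximizes the between-class variance (equivalently minimizes
#' the within-class variance). The returned threshold is the bin edge of the
#' optimal split; the mask keeps pixels strictly above it.
#'
#' @param frame 2-D numeric matrix.
#' @param nbins Number of histogram bins (default 256).
#' @return A list: \code{threshold} (numeric) and \code{mask} (0/1 matrix).
#'   A constant frame yields an all-zero mask with a warning.
#' @export
threshold_otsu <- function(frame, nbins = 256L) {
  h <- hist256(frame, nbins)
  if (is.null(h)) {
    warning("constant frame: Otsu threshold undefined, returning empty mask")
    return(list(threshold = NA_real_, mask = frame * 0))
  }
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)                 # class-0 weight up to bin t
  mu <- cumsum(p * h$mids)           # class-0 first moment
  mu_t <- mu[length(mu)]
  t_range <- seq_len(nbins - 1L)
  sb <- (mu_t * omega[t_range] - mu[t_range])^2 /
    pmax(omega[t_range] * (1 - omega[t_range]), .Machine$double.eps)
  sb[omega[t_range] == 0 | omega[t_range] == 1] <- -Inf
  tbest <- which.max(sb)
  thr <- h$edges[tbest]
  list(threshold = thr, mask = (frame > thr) * 1)
}

# Li & Tam minimum-cross-entropy iteration on a 256-bin histogram.
# The fixed point is then snapped to the neighboring candidate bin edge that
# minimizes the cross-entropy criterion, so the result is exactly the
# criterion minimizer at bin resolution.
li_criterion <- function(h) {
  # criterion at each candidate split t (bins 1..t vs t+1..n):
  # -(S1 log m1 + S2 log m2), lower is better
  wts <- h$counts
  gw <- h$mids * wts
  W1 <- cumsum(wts)
  S1 <- cumsum(gw)
  Wt <- W1[length(W1)]
  St <- S1[length(S1)]
  t_range <- seq_len(length(wts) - 1L)
  w1 <- W1[t_range]; s1 <- S1[t_range]
  w2 <- Wt - w1; s2 <- St - s1
  crit <- rep(Inf, length(t_range))
  ok <- w1 > 0 & w2 > 0
  m1 <- s1[ok] / w1[ok]
  m2 <- s2[ok] / w2[ok]
  crit[ok] <- -(s1[ok] * log(m1) + s2[ok] * log(m2))
  crit
}

#' Li minimum-cross-entropy threshold of one frame
#'
#' Runs the Li & Tam fixed-point iteration
#' \code{t <- (m1 - m2) / (log(m1) - log(m2))} (with \code{m1}, \code{m2} the
#' means of the values below/above \code{t}) on a 256-bin histogram, then
#' snaps to the nearest candidate bin edge minimizing the cross-entropy
#' criterion. Requires nonnegative intensities.
#'
#' @inheritParams threshold_otsu
#' @param max_iter Iteration cap (the fixed point converges in far fewer).
#' @return A list: \code{threshold}, \code{mask} (0/1) and \code{iterations}.
#' @export
threshold_li <- function(frame, nbins = 256L, max_iter = 100L) {
  if (min(frame) < 0) stop("Li threshold requires nonnegative intensities")
  h <- hist256(frame, nbins)
  if (is.null(h)) {
    warning("constant frame: Li threshold undefined, returning empty mask")
    return(list(threshold = NA_real_, mask = frame * 0, iterations = 0L))
  }
  wts <- h$counts
  mids <- h$mids  # strictly positive when min(frame) >= 0
  t_cur <- sum(wts * mids) / sum(wts)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    below <- mids <= t_cur
    w1 <- sum(wts[below]); w2 <- sum(wts[!below])
    if (w1 == 0 || w2 == 0) break
    m1 <- sum(wts[below] * mids[below]) / w1
    m2 <- sum(wts[!below] * mids[!below]) / w2
    t_new <- (m1 - m2) / (log(m1) - log(m2))
    done <- abs(t_new - t_cur) < h$width / 1000
    t_cur <- t_new
    if (done || iter >= max_iter) break
  }
  # snap to the best candidate edge in the fixed point's neighborhood: the
  # criterion is nearly flat around its minimum, so the converged fixed
  # point can sit a bin or two off the discrete argmin
  crit <- li_criterion(h)
  t0 <- min(max(floor((t_cur - h$lo) / h$width), 1L), length(crit))
  cand <- intersect((t0 - 2L):(t0 + 2L), seq_along(crit))
  tbest <- cand[which.min(crit[cand])]
  thr <- h$edges[tbest]
  list(threshold = thr, mask = (frame > thr) * 1, iterations = iter)
}

#' Phansalkar local adaptive threshold of one frame
#'
#' The frame is normalized to [0, 1] by its maximum; for each pixel, with
#' \code{mu} and \code{sigma} the mean and (population) standard deviation of
#' the circular window of the given radius (edge-replicated border), the
#' local threshold is
#' \code{t = mu * (1 + p * exp(-q * mu) + k * (sigma / r - 1))}
#' and the pixel is kept iff its normalized value is strictly above \code{t}.
#' Defaults are the published reference parameters.
#'
#' @param frame 2-D numeric matrix.
#' @param radius Window radius in pixels.
#' @param k,r,p,q Method parameters.
#' @return A list: \code{threshold} (matrix of local thresholds on the
#'   normalized scale) and \code{mask} (0/1 matrix).
#' @export
threshold_phansalkar <- function(frame, radius = 15L, k = 0.25, r = 0.5,
                                 p = 2, q = 10) {
  stopifnot(radius >= 1L)
  mx <- max(frame)
  v <- if (mx > 0) frame / mx else frame
  ny <- nrow(v); nx <- ncol(v)
  pad <- pad_replicate(v, radius)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  s <- matrix(0, ny, nx)
  s2 <- matrix(0, ny, nx)
  for (i in seq_len(nrow(offs))) {
    sub <- pad[offs$dy[i] + radius + seq_len(ny),
               offs$dx[i] + radius + seq_len(nx), drop = FALSE]
    s <- s + sub
    s2 <- s2 + sub * sub
  }
  n <- nrow(offs)
  mu <- s / n
  sigma <- sqrt(pmax(s2 / n - mu^2, 0))
  thr <- mu * (1 + p * exp(-q * mu) + k * (sigma / r - 1))
  list(threshold = thr, mask = (v > thr) * 1)
}

#' Composite adaptive donor threshold of one frame
#'
#' The composite mask combines local and global evidence:
#' \enumerate{
#'   \item subtract a weakly blurred copy of the frame from itself
#'     (\code{sigma_low}), clamp at 0, threshold with Li's method;
#'   \item same with a strongly blurred copy (\code{sigma_high});
#'   \item AND the two Li masks (the low blur keeps structures at their true
#'     width but admits noise, the high blur suppresses noise but thickens
#'     structures; their intersection keeps only pixels present in both);
#'   \item OR with the global Otsu mask of the raw frame, which restores the
#'     interiors of globally bright structures (the soma) that the
#'     difference images hollow out.
#' }
#' By construction the result is a superset of the Otsu mask.
#'
#' @param frame 2-D numeric matrix, values >= 0.
#' @param sigma_low,sigma_high Gaussian blur sigmas in pixels,
#'   \code{sigma_low < sigma_high}. The defaults were calibrated once on the
#'   bundled neuron phantom (maximum mean specimen recall over the time
#'   series under a background false-positive constraint); see the vignette.
#' @return A 0/1 mask matrix.
#' @export
threshold_composite <- function(frame, sigma_low = 1.5, sigma_high = 2.5) {
  stopifnot(sigma_low < sigma_high)
  if (min(frame) < 0) stop("composite threshold requires nonnegative intensities")
  d_low <- pmax(frame - gaussian_blur(frame, sigma_low), 0)
  d_high <- pmax(frame - gaussian_blur(frame, sigma_high), 0)
  m_low <- threshold_li(d_low)$mask
  m_high <- threshold_li(d_high)$mask
  m_otsu <- threshold_otsu(frame)$mask
  pmax(m_low * m_high, m_otsu)  # (AND) OR
}

#' Constant global threshold over a whole stack
#'
#' @param stack An \code{ImageStack}.
#' @param value Threshold applied to every frame; pixels strictly above it
#'   are kept.
#' @return A mask stack: list with 0/1 \code{$frames} (class
#'   \code{MaskStack}).
#' @export
threshold_constant <- function(stack, value) {
  stopifnot(value >= 0)
  mask_stack((stack$frames > value) * 1, thresholds = rep(value, n_frames(stack)))
}

#' Per-frame median threshold of a reference region
#'
#' For each time point, the threshold is the median of the reference region's
#' pixels in that frame (the region should contain roughly half pixels to
#' keep and half to remove), so the threshold tracks the donor decay.
#'
#' @param stack An \code{ImageStack}.
#' @param reference A \code{Region} straddling the specimen boundary.
#' @return A \code{MaskStack}; the per-frame thresholds are in
#'   \code{$thresholds}.
#' @export
threshold_median_roi <- function(stack, reference) {
  idx <- region_index(reference, frame_dim(stack))
  nt <- n_frames(stack)
  out <- stack$frames * 0
  thr <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- stack$frames[, , t]
    thr[t] <- stats::median(fr[idx])
    out[, , t] <- (fr > thr[t]) * 1
  }
  mask_stack(out, thresholds = thr)
}

# MaskStack constructor: binary per-frame specimen masks.
mask_stack <- function(frames, thresholds = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  storage.mode(frames) <- "double"
  stopifnot(all(frames %in% c(0, 1)))
  structure(list(frames = frames, thresholds = thresholds), class = "MaskStack")
}

#' @export
print.MaskStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("MaskStack: %d frame(s) of %d x %d, %.1f%% pixels kept\n",
              d[3L], d[1L], d[2L], 100 * mean(x$frames)))
  invisible(x)
}

#' Threshold configuration
#'
#' Bundles the method choice and its parameters for
#' \code{\link{make_mask_stack}} and the pipeline runner.
#'
#' @param method One of \code{"composite"}, \code{"otsu"},
#'   \code{"phansalkar"}, \code{"median_roi"}, \code{"constant"}.
#' @param constant_value Threshold for \code{method = "constant"}.
#' @param reference_region \code{Region} for \code{method = "median_roi"}.
#' @param sigma_low,sigma_high Blur sigmas (px) for the composite method.
#' @param radius,k,r,p,q Phansalkar parameters.
#' @return A list of class \code{ThresholdConfig}.
#' @export
threshold_config <- function(method = c("composite", "otsu", "phansalkar",
                                        "median_roi", "constant"),
                             constant_value = NULL, reference_region = NULL,
                             sigma_low = 1.5, sigma_high = 2.5,
                             radius = 15L, k = 0.25, r = 0.5, p = 2, q = 10) {
  method <- match.arg(method)
  if (method == "constant" &&
      (is.null(constant_value) || constant_value < 0)) {
    stop("constant method needs constant_value >= 0")
  }
  if (method == "median_roi" && is.null(reference_region)) {
    stop("median_roi method needs a reference_region")
  }
  stopifnot(sigma_low < sigma_high, radius >= 1L)
  structure(list(method = method, constant_value = constant_value,
                 reference_region = reference_region,
                 sigma_low = sigma_low, sigma_high = sigma_high,
                 radius = radius, k = k, r = r, p = p, q = q),
            class = "ThresholdConfig")
}

#' Build the donor mask stack with a chosen method
#'
#' Dispatches on the configured method. All per-frame methods (median_roi,
#' otsu, phansalkar, composite) recompute their thresholds independently for
#' every time point, so the mask tracks the specimen through donor decay.
#'
#' @param stack The (cleaned) donor \code{ImageStack}.
#' @param config A \code{\link{threshold_config}}.
#' @return A \code{MaskStack} of the same shape.
#' @export
make_mask_stack <- function(stack, config = threshold_config()) {
  stopifnot(inherits(config, "ThresholdConfig"))
  switch(config$method,
    constant = threshold_constant(stack, config$constant_value),
    median_roi = threshold_median_roi(stack, config$reference_region),
    otsu = {
      out <- stack$frames * 0
      thr <- numeric(n_frames(stack))
      for (t in seq_len(n_frames(stack))) {
        r <- threshold_otsu(stack$frames[, , t])
        out[, , t] <- r$mask
        thr[t] <- r$threshold
      }
      mask_stack(out, thresholds = thr)
    },
    phansalkar = {
      out <- stack$frames * 0
      for (t in seq_len(n_frames(stack))) {
        out[, , t] <- threshold_phansalkar(stack$frames[, , t], config$radius,
                                           config$k, config$r, config$p,
                                           config$q)$mask
      }
      mask_stack(out)
    },
    composite = {
      out <- stack$frames * 0
      for (t in seq_len(n_frames(stack))) {
        out[, , t] <- threshold_composite(stack$frames[, , t],
                                          config$sigma_low, config$sigma_high)
      }
      mask_stack(out)
    }
  )
}

#' Apply a mask to a stack
#'
#' Pixel-wise product: discarded pixels become 0, surviving pixel values are
#' unchanged.
#'
#' @param stack An \code{ImageStack}.
#' @param masks A \code{MaskStack} of the same shape.
#' @return The masked \code{ImageStack}.
#' @export
apply_mask <- function(stack, masks) {
  if (!identical(dim(stack$frames), dim(masks$frames))) {
    stop("mask shape does not match the stack")
  }
  stack$frames <- stack$frames * masks$frames
  stack
}

#' Write a mask stack as an 8-bit TIFF (0/255 on disk)
#' @param masks A \code{MaskStack}.
#' @param path Output path.
#' @export
write_mask <- function(masks, path) {
  write_tiff(masks$frames * 255, path, depth = "uint8")
  invisible(path)
}

#' Read a mask stack written by \code{\link{write_mask}}
#'
#' Values on disk are 0/255; dividing by 255 restores the in-memory 0/1
#' convention.
#'
#' @param path Path to the 8-bit mask TIFF.
#' @export
read_mask <- function(path) {
  r <- read_tiff(path)
  mask_stack(r$frames / 255)
}
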