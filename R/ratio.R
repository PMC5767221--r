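# Step 2, "divide": masked pixel-by-pixel A/D division, display-range
# selection from the pooled stack histogram, pseudocolor and donor-weighted
# renderings. The value 0 is reserved as the background sentinel in ratio
# images: it marks pixels removed by the donor mask and is rendered black.

#' Pixel-wise acceptor/donor ratio
#'
#' Divides the acceptor by the (already masked) donor wherever the donor is
#' strictly positive; everywhere else the ratio is exactly 0. The result
#' contains no infinities or NaNs: near-zero donor pixels, whose raw ratio
#' would explode, must be removed by the mask beforehand.
#'
#' @param acceptor Cleaned acceptor \code{ImageStack}.
#' @param donor_thresholded Cleaned, masked donor \code{ImageStack}.
#' @return A \code{RatioStack} (same shape, \code{$frames} holding A/D).
#' @export
ratio_divide <- function(acceptor, donor_thresholded) {
  if (!identical(dim(acceptor$frames), dim(donor_thresholded$frames))) {
    stop("acceptor and donor shapes differ")
  }
  d <- donor_thresholded$frames
  a <- acceptor$frames
  out <- array(0, dim = dim(d))
  pos <- d > 0
  out[pos] <- a[pos] / d[pos]
  structure(list(frames = out), class = "RatioStack")
}

#' @export
print.RatioStack <- function(x, ...) {
  d <- dim(x$frames)
  nz <- x$frames[x$frames > 0]
  cat(sprintf("RatioStack: %d frame(s) of %d x %d, %d nonzero pixels\n",
              d[3L], d[1L], d[2L], length(nz)))
  if (length(nz)) cat(sprintf("  nonzero ratio range [%.4g, %.4g]\n", min(nz), max(nz)))
  invisible(x)
}

#' Suggest a display range from the pooled ratio histogram
#'
#' Pools the nonzero pixels of all frames and returns the nearest-rank
#' permille quantiles (sorted index \code{ceil(k * n / 1000)}, 1-based).
#' Defaults are the 5th and 995th permilles. Zero (background) pixels are
#' never counted. The chosen range should then be kept fixed across the whole
#' series so frames remain visually comparable.
#'
#' @param ratio A \code{RatioStack}.
#' @param low_permille,high_permille Integers in [0, 1000],
#'   \code{low_permille < high_permille}.
#' @return A list of class \code{DisplayRange}: \code{low}, \code{high},
#'   and the permilles used.
#' @export
display_range <- function(ratio, low_permille = 5L, high_permille = 995L) {
  stopifnot(low_permille >= 0, high_permille <= 1000,
            low_permille < high_permille)
  nz <- ratio$frames[ratio$frames > 0]
  if (length(nz) == 0L) stop("ratio stack has no nonzero pixels")
  structure(list(low = permille_nearest_rank(nz, low_permille),
                 high = permille_nearest_rank(nz, high_permille),
                 low_permille = low_permille, high_permille = high_permille),
            class = "DisplayRange")
}

#' Manually specified display range
#' @param low,high Ratio bounds, \code{low <= high}.
#' @export
manual_range <- function(low, high) {
  stopifnot(low <= high)
  structure(list(low = low, high = high,
                 low_permille = NA_integer_, high_permille = NA_integer_),
            class = "DisplayRange")
}

#' The default 16-color cold-to-hot lookup table
#'
#' 16 RGB triples running blue, cyan, green, yellow to red (HSV hue ramp from
#' 240 degrees down to 0 at full saturation and value).
#'
#' @return A 16 x 3 integer matrix (columns R, G, B in 0..255), coldest color
#'   first.
#' @export
lut_cold_hot <- function() {
  cols <- grDevices::hsv(seq(240, 0, length.out = 16) / 360, 1, 1)
  t(grDevices::col2rgb(cols))
}

# Map ratio values to LUT bins 0..15; zero pixels get bin -1 (background).
ratio_bins <- function(frame, range) {
  stopifnot(range$low < range$high)
  b <- floor(16 * (frame - range$low) / (range$high - range$low))
  b <- pmin(pmax(b, 0), 15)
  b[frame == 0] <- -1
  b
}

#' Render a ratio frame in pseudocolor
#'
#' Nonzero pixels are binned as
#' \code{floor(16 * (v - low) / (high - low))}, clamped to bins 0..15, and
#' painted with the LUT; zero pixels are black, so masked background is
#' always distinguishable from a genuinely low ratio.
#'
#' @param ratio_frame 2-D ratio matrix (one frame of a \code{RatioStack}).
#' @param range A \code{DisplayRange}.
#' @param lut A 16 x 3 RGB matrix, see \code{\link{lut_cold_hot}}.
#' @return An (ny, nx, 3) integer array, values 0..255.
#' @export
render_pseudocolor <- function(ratio_frame, range, lut = lut_cold_hot()) {
  stopifnot(nrow(lut) == 16L, ncol(lut) == 3L)
  b <- ratio_bins(ratio_frame, range)
  out <- array(0L, dim = c(dim(ratio_frame), 3L))
  fg <- b >= 0
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[fg] <- lut[b[fg] + 1L, ch]
    out[, , ch] <- plane
  }
  out
}

#' Render a donor-weighted ratio frame
#'
#' Same pseudocolor hue as \code{\link{render_pseudocolor}}, but each pixel's
#' brightness is scaled by the donor intensity relative to
#' \code{donor_max} (default: the 995th permille of the nonzero donor
#' pixels), clamped to [0, 1]. This hides background noise but also fades the
#' signal of dim, low-expression structures, so it is an option rather than
#' the default representation.
#'
#' @param ratio_frame 2-D ratio matrix.
#' @param donor_frame Matching 2-D donor matrix.
#' @param range A \code{DisplayRange}.
#' @param lut A 16 x 3 RGB matrix.
#' @param donor_max Brightness normalization; computed from the donor frame
#'   when \code{NULL}.
#' @return An (ny, nx, 3) integer array, values 0..255.
#' @export
render_weighted <- function(ratio_frame, donor_frame, range,
                            lut = lut_cold_hot(), donor_max = NULL) {
  stopifnot(identical(dim(ratio_frame), dim(donor_frame)))
  if (is.null(donor_max)) {
    nz <- donor_frame[donor_frame > 0]
    if (length(nz) == 0L) return(array(0L, dim = c(dim(ratio_frame), 3L)))
    donor_max <- permille_nearest_rank(nz, 995L)
  }
  scale <- pmin(pmax(donor_frame / donor_max, 0), 1)
  rgb <- render_pseudocolor(ratio_frame, range, lut)
  for (ch in 1:3) rgb[, , ch] <- as.integer(round(rgb[, , ch] * scale))
  rgb
}

#' Pooled histogram of nonzero ratio values
#'
#' Bins the nonzero pixels of all frames between the permille display bounds.
#' Bin edges are half-open \code{[edge_i, edge_{i+1})} with the top bin
#' closed; zeros and values outside the bounds are not counted.
#'
#' @param ratio A \code{RatioStack}.
#' @param bins Number of bins.
#' @param range Optional \code{DisplayRange}; defaults to the 5th/995th
#'   permille bounds of the stack.
#' @return A data frame with \code{bin_low}, \code{bin_high}, \code{count}.
#' @export
stack_histogram <- function(ratio, bins = 64L, range = NULL) {
  nz <- ratio$frames[ratio$frames > 0]
  if (length(nz) == 0L) stop("ratio stack has no nonzero pixels")
  if (is.null(range)) range <- display_range(ratio)
  lo <- range$low
  hi <- range$high
  if (hi <= lo) stop("degenerate display range")
  v <- nz[nz >= lo & nz <= hi]
  idx <- pmin(floor(bins * (v - lo) / (hi - lo)) + 1L, bins)
  counts <- tabulate(idx, bins)
  edges <- lo + (hi - lo) * (0:bins) / bins
  data.frame(bin_low = edges[-(bins + 1L)], bin_high = edges[-1L],
             count = counts)
}
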