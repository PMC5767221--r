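# Step 1, "clean": outlier removal, background subtraction, alignment.
# The stage order is fixed: 3x3 median filter, then per-frame median
# background subtraction, then translation-only registration.

#' Remove outlier pixels with a 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighborhood, independently
#' per frame. The border is handled by edge replication, so constant frames
#' pass through unchanged and borders are not darkened.
#'
#' @param stack An \code{ImageStack}.
#' @return The filtered \code{ImageStack}.
#' @export
median_filter_3x3 <- function(stack) {
  map_frames(stack, median3x3)
}

#' Subtract the per-frame median of a background region
#'
#' For each frame independently, the median intensity inside the background
#' region is subtracted from every pixel (camera offset plus global light
#' background, assumed spatially homogeneous). Negative results are clamped
#' to 0, mirroring unsigned-integer camera semantics.
#'
#' @param stack An \code{ImageStack}.
#' @param background A \code{Region} covering background only.
#' @return A list: \code{stack} (corrected \code{ImageStack}) and
#'   \code{medians} (numeric, the per-frame offsets that were removed).
#' @export
subtract_background <- function(stack, background) {
  idx <- region_index(background, frame_dim(stack))
  if (length(idx) < 1L) stop("empty background region")
  nt <- n_frames(stack)
  meds <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- stack$frames[, , t]
    meds[t] <- stats::median(fr[idx])
    stack$frames[, , t] <- pmax(fr - meds[t], 0)
  }
  list(stack = stack, medians = meds)
}

#' Subtract a background reference image
#'
#' Pixel-wise subtraction of a background image (1 frame, broadcast to all
#' time points, or one page per frame), clamped at 0.
#'
#' @param stack An \code{ImageStack}.
#' @param background_image An \code{ImageStack} with 1 or \code{n_frames}
#'   frames of the same (y, x) shape.
#' @return The corrected \code{ImageStack}.
#' @export
subtract_background_image <- function(stack, background_image) {
  if (!identical(frame_dim(stack), frame_dim(background_image))) {
    stop("background image shape does not match the stack")
  }
  nb <- n_frames(background_image)
  nt <- n_frames(stack)
  if (!(nb == 1L || nb == nt)) {
    stop("background image must have 1 frame or as many frames as the stack")
  }
  for (t in seq_len(nt)) {
    b <- background_image$frames[, , if (nb == 1L) 1L else t]
    stack$frames[, , t] <- pmax(stack$frames[, , t] - b, 0)
  }
  stack
}

#' Register a donor/acceptor pair over time (translation only)
#'
#' Estimates a subpixel (dx, dy) translation per frame on the donor channel
#' against a reference frame (phase correlation with upsampled refinement) and
#' applies the same transform to donor and acceptor with bilinear
#' interpolation, so the spatial correspondence of the two channels is
#' preserved and measurement areas track the same part of the specimen.
#' Pixels shifted in from outside the frame are set to 0.
#'
#' @param donor,acceptor \code{ImageStack}s of equal shape.
#' @param reference_frame Frame (1-based) the others are aligned to.
#' @return A list: \code{donor}, \code{acceptor} (registered stacks) and
#'   \code{alignment} with \code{shifts} (n x 2 matrix of applied dx, dy,
#'   i.e. the estimated drift) and \code{reference_frame}.
#' @export
align_stack <- function(donor, acceptor, reference_frame = 1L) {
  if (!identical(dim(donor$frames), dim(acceptor$frames))) {
    stop("donor and acceptor shapes differ")
  }
  nt <- n_frames(donor)
  if (reference_frame < 1L || reference_frame > nt) stop("invalid reference frame")
  ref <- donor$frames[, , reference_frame]
  shifts <- matrix(0, nt, 2L, dimnames = list(NULL, c("dx", "dy")))
  for (t in seq_len(nt)) {
    if (t == reference_frame) next
    s <- estimate_translation(ref, donor$frames[, , t])
    shifts[t, ] <- s
    if (any(s != 0)) {
      donor$frames[, , t] <- translate_bilinear(donor$frames[, , t], -s[1L], -s[2L])
      acceptor$frames[, , t] <- translate_bilinear(acceptor$frames[, , t], -s[1L], -s[2L])
    }
  }
  list(donor = donor, acceptor = acceptor,
       alignment = list(shifts = shifts, reference_frame = reference_frame))
}

#' Crop a stack to a rectangular region
#'
#' @param stack An \code{ImageStack}.
#' @param reg A rectangle \code{Region} (half-open pixel range).
#' @return The cropped \code{ImageStack} (all frames).
#' @export
crop <- function(stack, reg) {
  if (reg$kind != "rectangle") stop("crop requires a rectangle region")
  rc <- rasterize_region(reg, frame_dim(stack))
  rows <- sort(unique(rc[, "row"]))
  cols <- sort(unique(rc[, "col"]))
  image_stack(stack$frames[rows, cols, , drop = FALSE], dtype_in = stack$dtype_in)
}

#' Run the full cleaning stage on a donor/acceptor pair
#'
#' Convenience wrapper applying, in order: 3x3 median filter, per-frame
#' median background subtraction (or a background image), and optional
#' translation registration estimated on the donor.
#'
#' @param donor,acceptor \code{ImageStack}s of equal shape.
#' @param background Background \code{Region} (ignored when
#'   \code{background_image} is given).
#' @param background_image Optional background \code{ImageStack}.
#' @param median Apply the median filter first (default \code{TRUE}).
#' @param align Register frames over time (default \code{TRUE}).
#' @param reference_frame Reference frame for registration.
#' @return A list with \code{donor}, \code{acceptor}, \code{log} (per-frame
#'   background medians for both channels and the alignment result).
#' @export
clean_stacks <- function(donor, acceptor, background = NULL,
                         background_image = NULL, median = TRUE,
                         align = TRUE, reference_frame = 1L) {
  log <- list()
  if (median) {
    donor <- median_filter_3x3(donor)
    acceptor <- median_filter_3x3(acceptor)
  }
  if (!is.null(background_image)) {
    donor <- subtract_background_image(donor, background_image)
    acceptor <- subtract_background_image(acceptor, background_image)
  } else if (!is.null(background)) {
    d <- subtract_background(donor, background)
    a <- subtract_background(acceptor, background)
    donor <- d$stack
    acceptor <- a$stack
    log$background_median_donor <- d$medians
    log$background_median_acceptor <- a$medians
  }
  if (align) {
    r <- align_stack(donor, acceptor, reference_frame)
    donor <- r$donor
    acceptor <- r$acceptor
    log$alignment <- r$alignment
  }
  list(donor = donor, acceptor = acceptor, log = log)
}
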