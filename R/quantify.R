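# Final "measure" step: per-ROI, per-frame mean and SD of the ratio.
# Zero-valued pixels (the background sentinel left by the donor mask) are
# excluded from every statistic, so ROIs need not trace the specimen outline
# precisely. Frames where the mask annihilates an ROI yield missing values,
# never silent zeros.

#' Quantify ratio statistics in regions of interest
#'
#' For every ROI and every frame, computes over the pixels with strictly
#' positive ratio inside the ROI: the mean, the sample standard deviation
#' (n - 1 denominator) and the pixel count. The mean is \code{NA} when no
#' pixel survives, the SD is \code{NA} when fewer than two do.
#'
#' @param ratio A \code{RatioStack}.
#' @param rois A list of \code{Region} objects (or a single \code{Region}).
#' @return A data frame with columns \code{roi_name}, \code{frame_index}
#'   (1-based), \code{mean_ratio}, \code{sd_ratio}, \code{n_pixels}.
#' @export
measure_rois <- function(ratio, rois) {
  if (inherits(rois, "Region")) rois <- list(rois)
  if (length(rois) == 0L) stop("empty ROI list")
  dims <- dim(ratio$frames)[1:2]
  nt <- dim(ratio$frames)[3L]
  rows <- vector("list", length(rois) * nt)
  i <- 0L
  for (reg in rois) {
    idx <- region_index(reg, dims)
    for (t in seq_len(nt)) {
      fr <- ratio$frames[, , t]
      vals <- fr[idx]
      vals <- vals[vals > 0]
      n <- length(vals)
      i <- i + 1L
      rows[[i]] <- data.frame(
        roi_name = reg$name,
        frame_index = t,
        mean_ratio = if (n >= 1L) mean(vals) else NA_real_,
        sd_ratio = if (n >= 2L) stats::sd(vals) else NA_real_,
        n_pixels = n,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Pool measurement tables from several sources
#'
#' Concatenates per-recording measurement tables, adding a \code{source}
#' label column so ROIs pooled from multiple images stay distinguishable.
#' Duplicate ROI names within one source are an error.
#'
#' @param tables A non-empty list of measurement tables
#'   (\code{\link{measure_rois}} output).
#' @param labels Character vector of source labels, one per table.
#' @return The concatenated data frame with a leading \code{source} column.
#' @export
pool_measurements <- function(tables, labels) {
  if (length(tables) == 0L) stop("empty list of measurement tables")
  stopifnot(length(tables) == length(labels))
  out <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    per_frame <- table(tb$roi_name, tb$frame_index)
    if (any(per_frame > 1L)) {
      stop("duplicate roi_name within source '", labels[i], "'")
    }
    out[[i]] <- cbind(source = labels[i], tb, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Across-ROI summary per frame
#'
#' Summarizes a (pooled) measurement table into a per-frame mean of the ROI
#' means with its standard error (SEM = SD / sqrt(n_rois)), the way a
#' multi-area time course is reported.
#'
#' @param table A measurement table, pooled or not.
#' @return A data frame with \code{frame_index}, \code{mean}, \code{sem},
#'   \code{n_rois} (ROIs with a defined mean in that frame).
#' @export
roi_series_summary <- function(table) {
  frames <- sort(unique(table$frame_index))
  res <- lapply(frames, function(t) {
    m <- table$mean_ratio[table$frame_index == t]
    m <- m[!is.na(m)]
    k <- length(m)
    data.frame(frame_index = t,
               mean = if (k >= 1L) mean(m) else NA_real_,
               sem = if (k >= 2L) stats::sd(m) / sqrt(k) else NA_real_,
               n_rois = k)
  })
  do.call(rbind, res)
}
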