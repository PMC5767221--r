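# Pipeline orchestration: clean -> align -> threshold -> divide -> measure,
# as one reproducible run with a manifest recording everything needed to
# re-run bit-identically.

#' Pipeline configuration
#'
#' Collects every knob of a run. Inputs may be given as file paths (TIFF /
#' JSON sidecar) or as in-memory objects; paths win over in-memory values
#' when both are set.
#'
#' @param donor,acceptor \code{ImageStack} or TIFF path.
#' @param regions Named list of \code{Region} or path to a JSON sidecar.
#'   Roles select how each region is used: \code{background} regions feed the
#'   background subtraction, \code{threshold-reference} feeds the
#'   \code{median_roi} method, \code{measurement} regions are quantified.
#' @param out_dir Output directory; \code{NULL} disables writing.
#' @param median,align,reference_frame Cleaning options (see
#'   \code{\link{clean_stacks}}).
#' @param background_image Optional background \code{ImageStack} or path.
#' @param threshold A \code{\link{threshold_config}}.
#' @param low_permille,high_permille Display-range permilles.
#' @param manual_display Optional \code{c(low, high)} overriding the permille
#'   range.
#' @param weighted Also render donor-weighted images.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the config is used to generate a
#'   phantom).
#' @return A list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(donor, acceptor, regions, out_dir = NULL,
                            median = TRUE, align = TRUE, reference_frame = 1L,
                            background_image = NULL,
                            threshold = threshold_config(),
                            low_permille = 5L, high_permille = 995L,
                            manual_display = NULL, weighted = FALSE,
                            seed = 1L) {
  structure(list(donor = donor, acceptor = acceptor, regions = regions,
                 out_dir = out_dir, median = median, align = align,
                 reference_frame = reference_frame,
                 background_image = background_image, threshold = threshold,
                 low_permille = low_permille, high_permille = high_permille,
                 manual_display = manual_display, weighted = weighted,
                 seed = seed),
            class = "PipelineConfig")
}

.load_stack <- function(x) {
  if (is.character(x)) read_stack(x) else x
}

.load_regions <- function(x) {
  if (is.character(x)) read_regions(x) else x
}

.regions_by_role <- function(regions, role) {
  Filter(function(r) r$role == role, regions)
}

#' Run the full pipeline
#'
#' Executes, in order: clean (median filter, per-frame median background
#' subtraction or background image, translation registration), donor
#' thresholding, masked A/D division, display-range selection and rendering,
#' and ROI quantification. When \code{out_dir} is set, all intermediates are
#' written: cleaned stacks, the mask (8-bit 0/255), the ratio (32-bit float
#' TIFF), pseudocolor renders (8-bit RGB TIFF) and the measurement CSV, plus
#' a JSON manifest with the configuration, package version and per-stage log
#' (background medians, shifts, thresholds).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A list: \code{ratio} (\code{RatioStack}), \code{measurements}
#'   (data frame), \code{mask} (\code{MaskStack}), \code{donor},
#'   \code{acceptor} (cleaned stacks), \code{range} (\code{DisplayRange}) and
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  donor <- .load_stack(config$donor)
  acceptor <- .load_stack(config$acceptor)
  regions <- .load_regions(config$regions)
  bg_img <- if (!is.null(config$background_image)) {
    .load_stack(config$background_image)
  }
  bg <- .regions_by_role(regions, "background")
  if (length(bg) == 0L && is.null(bg_img)) {
    stop("pipeline stage 'clean': no background region or image configured")
  }
  thr_cfg <- config$threshold
  if (thr_cfg$method == "median_roi" && is.null(thr_cfg$reference_region)) {
    ref <- .regions_by_role(regions, "threshold-reference")
    if (length(ref) == 0L) {
      stop("pipeline stage 'threshold': median_roi needs a threshold-reference region")
    }
    thr_cfg$reference_region <- ref[[1L]]
  }

  cl <- clean_stacks(donor, acceptor,
                     background = if (length(bg)) bg[[1L]],
                     background_image = bg_img, median = config$median,
                     align = config$align,
                     reference_frame = config$reference_frame)
  mask <- make_mask_stack(cl$donor, thr_cfg)
  donor_masked <- apply_mask(cl$donor, mask)
  ratio <- ratio_divide(cl$acceptor, donor_masked)
  rng <- if (!is.null(config$manual_display)) {
    manual_range(config$manual_display[1L], config$manual_display[2L])
  } else {
    display_range(ratio, config$low_permille, config$high_permille)
  }
  rois <- .regions_by_role(regions, "measurement")
  measurements <- if (length(rois)) measure_rois(ratio, rois)

  manifest <- list(
    package = "bretr",
    version = as.character(utils::packageVersion("bretr")),
    seed = config$seed,
    stages = c("clean", "threshold", "divide", "measure"),
    options = list(median = config$median, align = config$align,
                   reference_frame = config$reference_frame,
                   threshold = thr_cfg[!vapply(thr_cfg, is.null, TRUE) &
                                         names(thr_cfg) != "reference_region"],
                   low_permille = config$low_permille,
                   high_permille = config$high_permille,
                   manual_display = config$manual_display,
                   weighted = config$weighted),
    log = c(cl$log, list(
      mask_thresholds = mask$thresholds,
      mask_pixels_per_frame = apply(mask$frames, 3L, sum),
      display_range = c(rng$low, rng$high)
    ))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    write_stack(cl$donor, out("donor_clean.tif"))
    write_stack(cl$acceptor, out("acceptor_clean.tif"))
    write_mask(mask, out("mask.tif"))
    write_stack(ratio, out("ratio.tif"))
    lut <- lut_cold_hot()
    renders <- lapply(seq_len(n_frames(ratio)), function(t) {
      render_pseudocolor(ratio$frames[, , t], rng, lut)
    })
    write_tiff(renders, out("render_pseudocolor.tif"))
    if (isTRUE(config$weighted)) {
      wrenders <- lapply(seq_len(n_frames(ratio)), function(t) {
        render_weighted(ratio$frames[, , t], cl$donor$frames[, , t], rng, lut)
      })
      write_tiff(wrenders, out("render_weighted.tif"))
    }
    if (!is.null(measurements)) write_measurements(measurements, out("measures.csv"))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(ratio = ratio, measurements = measurements, mask = mask,
       donor = cl$donor, acceptor = cl$acceptor, range = rng,
       manifest = manifest)
}

#' Compare threshold methods against ground truth
#'
#' Runs several masking methods on the same (cleaned) donor stack and
#' reports, per method and frame, the specimen recall (fraction of true
#' specimen pixels kept) and the background false-positive rate (fraction of
#' true background pixels kept) when a truth mask is available, plus the raw
#' mask pixel count. \code{"constant"} uses a global threshold fixed from the
#' first frame's Otsu value unless \code{constant_value} is given — the
#' static-threshold baseline whose late-frame failure motivates the per-frame
#' adaptive methods.
#'
#' @param donor A cleaned donor \code{ImageStack}.
#' @param methods Character vector of method names (see
#'   \code{\link{threshold_config}}).
#' @param truth Optional binary (y, x, t) array of true specimen pixels.
#' @param config Base \code{\link{threshold_config}} supplying method
#'   parameters.
#' @param constant_value Optional fixed threshold for \code{"constant"}.
#' @return A data frame: \code{method}, \code{frame}, \code{n_mask},
#'   \code{recall}, \code{fpr} (the last two \code{NA} without truth).
#' @export
compare_thresholds <- function(donor, methods = c("composite", "otsu",
                                                  "phansalkar", "constant"),
                               truth = NULL, config = threshold_config(),
                               constant_value = NULL) {
  stopifnot(length(methods) >= 2L)
  nt <- n_frames(donor)
  rows <- list()
  for (m in methods) {
    cfg <- config
    cfg$method <- m
    if (m == "constant") {
      cfg$constant_value <- if (!is.null(constant_value)) constant_value else
        threshold_otsu(donor$frames[, , 1L])$threshold
    }
    mask <- make_mask_stack(donor, cfg)
    for (t in seq_len(nt)) {
      mk <- mask$frames[, , t]
      if (!is.null(truth)) {
        tr <- truth[, , t]
        recall <- sum(mk * tr) / max(sum(tr), 1)
        fpr <- sum(mk * (1 - tr)) / max(sum(1 - tr), 1)
      } else {
        recall <- NA_real_
        fpr <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, frame = t, n_mask = sum(mk),
        recall = recall, fpr = fpr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
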