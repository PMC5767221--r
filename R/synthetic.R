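# Deterministic neuron-like two-channel phantom generator.
#
# The phantom states the acquisition model the pipeline assumes: a static
# luminescent structure (bright soma, thin neurites, small spines) whose
# donor brightness decays exponentially as substrate is consumed, a
# homogeneous additive camera offset, additive Gaussian read noise (optional
# Poisson shot noise), and a rigid subpixel xy drift applied identically to
# both channels. The acceptor is the donor structure scaled by a
# per-compartment true ratio map, so every stage of the pipeline can be
# checked against known ground truth without any real recording.

# distance from pixel centers to a segment, vectorized over a coordinate grid
.dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1
  vy <- y2 - y1
  len2 <- vx * vx + vy * vy
  tt <- ((px - x1) * vx + (py - y1) * vy) / len2
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2)
}

#' Phantom specification
#'
#' Defaults are the standard neuron phantom used by the validation suite:
#' 256 x 256 pixels, 10 frames, a soma disk of 1000 counts, three 2 px wide
#' neurites of 60 counts, five spine disks (radius 2 px) of 40 counts sitting
#' 4.5 px off the neurite axes, true ratio 0.50 in the soma, 0.55 in
#' neurites, 0.65 in spines, donor decay time constant 8 frames, camera
#' offset 100 counts, Gaussian noise SD 5 counts, and a cumulative drift of
#' (0.3, -0.2) px per frame.
#'
#' @param frame_shape Frame dimensions \code{c(ny, nx)}.
#' @param n_frames Number of time points.
#' @param soma List: \code{center} (x, y), \code{radius} px,
#'   \code{amplitude} counts, \code{ratio}.
#' @param neurites List of lists: \code{from}, \code{to} (x, y),
#'   \code{width} px, \code{amplitude}, \code{ratio}.
#' @param spines List of lists: \code{center} (x, y), \code{radius} px,
#'   \code{amplitude}, \code{ratio}.
#' @param donor_decay_tau Donor decay time constant in frames
#'   (\code{Inf} disables decay).
#' @param drift_per_frame Drift (dx, dy) in px added every frame.
#' @param camera_offset Additive offset in counts.
#' @param noise_sd Gaussian noise SD in counts.
#' @param poisson Add Poisson shot noise on the signal (default off).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @return A list of class \code{PhantomSpec}.
#' @export
phantom_spec <- function(frame_shape = c(256L, 256L), n_frames = 10L,
                         soma = list(center = c(90, 90), radius = 16,
                                     amplitude = 1000, ratio = 0.50),
                         neurites = NULL, spines = NULL,
                         donor_decay_tau = 8, drift_per_frame = c(0.3, -0.2),
                         camera_offset = 100, noise_sd = 5, poisson = FALSE,
                         seed = 1L) {
  if (is.null(neurites)) {
    neurites <- list(
      list(from = c(104, 90), to = c(235, 80), width = 2, amplitude = 60, ratio = 0.55),
      list(from = c(95, 103), to = c(140, 230), width = 2, amplitude = 60, ratio = 0.55),
      list(from = c(78, 102), to = c(30, 225), width = 2, amplitude = 60, ratio = 0.55)
    )
  }
  if (is.null(spines)) {
    # spine disks 4.5 px off the neurite axis: off the shaft, clearly
    # separated, in the 0.5 um-scale size regime of real spine heads
    spine_on <- function(seg, f, side) {
      p <- seg$from + f * (seg$to - seg$from)
      v <- seg$to - seg$from
      n <- c(-v[2], v[1]) / sqrt(sum(v^2))
      p + side * 4.5 * n
    }
    spines <- list(
      list(center = spine_on(neurites[[1]], 0.35, +1), radius = 2, amplitude = 40, ratio = 0.65),
      list(center = spine_on(neurites[[1]], 0.70, -1), radius = 2, amplitude = 40, ratio = 0.65),
      list(center = spine_on(neurites[[2]], 0.50, +1), radius = 2, amplitude = 40, ratio = 0.65),
      list(center = spine_on(neurites[[2]], 0.80, -1), radius = 2, amplitude = 40, ratio = 0.65),
      list(center = spine_on(neurites[[3]], 0.60, +1), radius = 2, amplitude = 40, ratio = 0.65)
    )
  }
  stopifnot(soma$amplitude > 0, camera_offset >= 0, noise_sd >= 0,
            n_frames >= 1L, donor_decay_tau > 0)
  structure(list(frame_shape = as.integer(frame_shape),
                 n_frames = as.integer(n_frames), soma = soma,
                 neurites = neurites, spines = spines,
                 donor_decay_tau = donor_decay_tau,
                 drift_per_frame = drift_per_frame,
                 camera_offset = camera_offset, noise_sd = noise_sd,
                 poisson = poisson, seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Rasterize the noiseless structure (donor amplitudes) and the per-pixel
# true ratio map. Draw order: neurites, soma, spines (later wins).
.phantom_structure <- function(spec) {
  ny <- spec$frame_shape[1L]
  nx <- spec$frame_shape[2L]
  px <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)   # x coordinate
  py <- matrix(rep(0:(ny - 1L), times = nx), ny, nx)  # y coordinate
  s <- matrix(0, ny, nx)
  r <- matrix(0, ny, nx)
  for (ne in spec$neurites) {
    d <- .dist_to_segment(px, py, ne$from[1], ne$from[2], ne$to[1], ne$to[2])
    hit <- d <= ne$width / 2
    s[hit] <- ne$amplitude
    r[hit] <- ne$ratio
  }
  d <- sqrt((px - spec$soma$center[1])^2 + (py - spec$soma$center[2])^2)
  hit <- d <= spec$soma$radius
  s[hit] <- spec$soma$amplitude
  r[hit] <- spec$soma$ratio
  for (sp in spec$spines) {
    d <- sqrt((px - sp$center[1])^2 + (py - sp$center[2])^2)
    hit <- d <= sp$radius
    if (!any(hit)) stop("spine falls outside the frame")
    s[hit] <- sp$amplitude
    r[hit] <- sp$ratio
  }
  if (max(s) <= 0) stop("phantom structure is empty")
  list(structure = s, ratio_map = r)
}

#' Generate a two-channel phantom time lapse with ground truth
#'
#' Builds, per frame t (1-based),
#' \code{donor_t = offset + exp(-(t-1)/tau) * shift(S) + noise} and
#' \code{acceptor_t = offset + exp(-(t-1)/tau) * shift(S * R) + noise},
#' where S is the noiseless donor structure, R the true ratio map and the
#' cumulative drift is applied to both channels identically with bilinear
#' interpolation (so subpixel registration is genuinely exercised). Pixels
#' are rounded to whole camera counts and clamped at 0.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list: \code{donor}, \code{acceptor} (\code{ImageStack}s) and
#'   \code{truth} with \code{specimen_mask} (binary (y, x, t) array, the
#'   nearest-pixel footprint under drift), \code{ratio_map} (frame-0
#'   geometry), \code{ratio_maps} (per-frame, drifted), \code{drift}
#'   (n x 2 applied cumulative shifts), \code{decay} (per-frame donor scale)
#'   and \code{structure}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(spec$seed)
  st <- .phantom_structure(spec)
  ny <- spec$frame_shape[1L]
  nx <- spec$frame_shape[2L]
  nt <- spec$n_frames
  base_mask <- (st$structure > 0) * 1
  donor <- array(0, dim = c(ny, nx, nt))
  acceptor <- array(0, dim = c(ny, nx, nt))
  mask <- array(0, dim = c(ny, nx, nt))
  rmaps <- array(0, dim = c(ny, nx, nt))
  drift <- matrix(0, nt, 2L, dimnames = list(NULL, c("dx", "dy")))
  decay <- exp(-(seq_len(nt) - 1) / spec$donor_decay_tau)
  sr <- st$structure * st$ratio_map
  for (t in seq_len(nt)) {
    drift[t, ] <- (t - 1) * spec$drift_per_frame
    s_t <- if (t == 1L) st$structure else
      translate_bilinear(st$structure, drift[t, 1L], drift[t, 2L])
    sr_t <- if (t == 1L) sr else
      translate_bilinear(sr, drift[t, 1L], drift[t, 2L])
    d_sig <- spec$camera_offset + decay[t] * s_t
    a_sig <- spec$camera_offset + decay[t] * sr_t
    if (spec$poisson) {
      d_sig <- stats::rpois(length(d_sig), lambda = d_sig)
      a_sig <- stats::rpois(length(a_sig), lambda = a_sig)
    }
    d_fr <- d_sig + stats::rnorm(ny * nx, sd = spec$noise_sd)
    a_fr <- a_sig + stats::rnorm(ny * nx, sd = spec$noise_sd)
    donor[, , t] <- pmax(round(d_fr), 0)
    acceptor[, , t] <- pmax(round(a_fr), 0)
    # truth footprint: nearest-lattice shift, so the pixel count is constant
    mask[, , t] <- translate_integer(base_mask, drift[t, 1L], drift[t, 2L])
    rmaps[, , t] <- translate_integer(st$ratio_map, drift[t, 1L], drift[t, 2L])
  }
  list(donor = image_stack(donor, "uint16"),
       acceptor = image_stack(acceptor, "uint16"),
       truth = list(specimen_mask = mask, ratio_map = st$ratio_map,
                    ratio_maps = rmaps, drift = drift, decay = decay,
                    structure = st$structure, spec = spec))
}

#' The standard neuron phantom with its regions
#'
#' Generates the default phantom of \code{\link{phantom_spec}} together with
#' the region set the validation suite uses: a background rectangle, a
#' threshold-reference box straddling the soma edge (about half specimen,
#' half background), a soma ROI fully inside the soma, one neurite ROI, and
#' one 6 x 6 ROI per spine. The true ratio of each measurement ROI is in
#' \code{truth$roi_truth}.
#'
#' @param seed Integer seed.
#' @return As \code{\link{generate_phantom}}, plus \code{regions} (named
#'   list of \code{Region}) and \code{truth$roi_truth}.
#' @export
default_neuron_phantom <- function(seed = 1L) {
  spec <- phantom_spec(seed = seed)
  ph <- generate_phantom(spec)
  regs <- list(
    region("background", "rectangle", rbind(c(4, 4), c(44, 44)),
           role = "background"),
    region("soma_edge_ref", "rectangle", rbind(c(70, 70), c(110, 110)),
           role = "threshold-reference"),
    region("soma", "rectangle", rbind(c(80, 80), c(100, 100)),
           role = "measurement"),
    region("neurite_1", "rectangle", rbind(c(160, 79), c(176, 91)),
           role = "measurement")
  )
  truth_ratio <- c(soma = spec$soma$ratio, neurite_1 = spec$neurites[[1]]$ratio)
  for (i in seq_along(spec$spines)) {
    cc <- round(spec$spines[[i]]$center)
    nm <- paste0("spine_", i)
    regs[[length(regs) + 1L]] <- region(nm, "rectangle",
                                        rbind(cc - 3, cc + 3),
                                        role = "measurement")
    truth_ratio[nm] <- spec$spines[[i]]$ratio
  }
  names(regs) <- vapply(regs, `[[`, "", "name")
  ph$regions <- regs
  ph$truth$roi_truth <- truth_ratio
  ph
}

#' Write a phantom to disk
#'
#' Writes \code{D.tif}, \code{A.tif} (16-bit), \code{truth_mask.tif} (8-bit
#' 0/255), \code{regions.json} and \code{truth.json} (parameters, drift,
#' decay, per-ROI true ratios) into a directory.
#'
#' @param ph Output of \code{\link{default_neuron_phantom}} or
#'   \code{\link{generate_phantom}}.
#' @param dir Output directory (created if needed).
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(ph$donor, file.path(dir, "D.tif"), depth = "uint16")
  write_stack(ph$acceptor, file.path(dir, "A.tif"), depth = "uint16")
  write_tiff(ph$truth$specimen_mask * 255, file.path(dir, "truth_mask.tif"),
             depth = "uint8")
  if (!is.null(ph$regions)) write_regions(ph$regions, file.path(dir, "regions.json"))
  spec <- ph$truth$spec
  truth <- list(
    seed = spec$seed, n_frames = spec$n_frames,
    frame_shape = spec$frame_shape,
    camera_offset = spec$camera_offset, noise_sd = spec$noise_sd,
    donor_decay_tau = spec$donor_decay_tau,
    drift_per_frame = spec$drift_per_frame,
    decay = ph$truth$decay,
    drift = apply(ph$truth$drift, 1, function(x) as.numeric(x), simplify = FALSE),
    roi_truth = as.list(ph$truth$roi_truth)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
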