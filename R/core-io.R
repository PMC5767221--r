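#' Image stacks
#'
#' An \code{ImageStack} is an ordered sequence of 2-D intensity frames for a
#' single channel, stored as a numeric 3-D array \code{(y, x, t)} in arbitrary
#' units (camera counts). Pixel values are held as doubles throughout the
#' pipeline; the original on-disk pixel depth is kept in \code{dtype_in}.
#'
#' @param frames Numeric matrix (single frame) or 3-D array \code{(y, x, t)}.
#' @param dtype_in Original pixel depth, one of \code{"uint8"},
#'   \code{"uint16"}, \code{"float32"}.
#' @return An object of class \code{ImageStack}.
#' @export
image_stack <- function(frames, dtype_in = "float32") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[3L] >= 1L)
  storage.mode(frames) <- "double"
  if (anyNA(frames)) stop("ImageStack frames contain NA")
  structure(list(frames = frames, dtype_in = dtype_in), class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ImageStack: %d frame(s) of %d x %d (y, x), dtype_in = %s\n",
              d[3L], d[1L], d[2L], x$dtype_in))
  cat(sprintf("  value range [%g, %g]\n", min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An \code{ImageStack}, mask stack, or ratio stack.
#' @export
n_frames <- function(stack) dim(stack$frames)[3L]

#' Frame dimensions (ny, nx) of a stack
#' @inheritParams n_frames
#' @export
frame_dim <- function(stack) dim(stack$frames)[1:2]

#' Extract one frame as a matrix
#' @inheritParams n_frames
#' @param t Frame number (1-based).
#' @export
get_frame <- function(stack, t) stack$frames[, , t]

# Apply a matrix -> matrix function to every frame.
map_frames <- function(stack, f, ...) {
  out <- stack$frames
  for (t in seq_len(dim(out)[3L])) out[, , t] <- f(stack$frames[, , t], ...)
  stack$frames <- out
  stack
}

#' Read an image stack from a multi-page TIFF
#'
#' @param path Path to a single- or multi-page grayscale TIFF (8/16-bit
#'   unsigned or 32-bit float, uncompressed).
#' @return An \code{ImageStack} with one frame per TIFF page.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  r <- read_tiff(path)
  image_stack(r$frames, dtype_in = r$dtype)
}

#' Write an image stack to a multi-page TIFF
#'
#' Integer depths refuse out-of-range values with an error rather than
#' wrapping silently.
#'
#' @param stack An \code{ImageStack} (or any object with 3-D \code{$frames}).
#' @param path Output path.
#' @param depth Pixel depth on disk: \code{"float32"} (default),
#'   \code{"uint16"} or \code{"uint8"}.
#' @export
write_stack <- function(stack, path, depth = c("float32", "uint16", "uint8")) {
  depth <- match.arg(depth)
  write_tiff(stack$frames, path, depth = depth)
  invisible(path)
}

#' Regions of interest
#'
#' A \code{Region} is a named rectangle or polygon in 0-based pixel
#' coordinates, (x, y) with the origin at the top-left corner. Rectangles are
#' half-open: \code{[x0, x1) x [y0, y1)}. Polygons are rasterized by an
#' even-odd pixel-center-inside test, pixel centers sitting at integer
#' coordinates.
#'
#' @param name Region name (unique within a sidecar file).
#' @param kind \code{"rectangle"} (two opposite corners) or \code{"polygon"}
#'   (at least 3 vertices).
#' @param vertices Two-column matrix or list of \code{(x, y)} pairs.
#' @param role What the region is for: \code{"background"},
#'   \code{"measurement"}, \code{"threshold-reference"} or \code{"crop"}.
#' @return An object of class \code{Region}.
#' @export
region <- function(name, kind = c("rectangle", "polygon"), vertices,
                   role = c("measurement", "background", "threshold-reference", "crop")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- matrix(as.numeric(vertices), ncol = 2L)
  if (kind == "rectangle" && nrow(vertices) != 2L) {
    stop("rectangle region '", name, "' needs exactly 2 corner vertices")
  }
  if (kind == "polygon" && nrow(vertices) < 3L) {
    stop("polygon region '", name, "' needs at least 3 vertices")
  }
  structure(list(name = as.character(name), kind = kind,
                 vertices = vertices, role = role), class = "Region")
}

#' @export
print.Region <- function(x, ...) {
  cat(sprintf("Region '%s': %s (%d vertices), role = %s\n",
              x$name, x$kind, nrow(x$vertices), x$role))
  invisible(x)
}

#' Rasterize a region to pixel indices
#'
#' Returns the set of pixel centers covered by the region, as 1-based
#' \code{(row, col)} indices into a frame of dimensions \code{dim}. Pixel
#' centers sit at integer (x, y); a rectangle \code{[x0, x1) x [y0, y1)}
#' covers centers \code{x0 .. x1-1}. Out-of-bounds parts are clipped with a
#' warning.
#'
#' @param reg A \code{Region}.
#' @param dim Frame dimensions \code{c(ny, nx)}.
#' @return Integer matrix with columns \code{row}, \code{col}.
#' @export
rasterize_region <- function(reg, dim) {
  ny <- dim[1L]; nx <- dim[2L]
  v <- reg$vertices
  if (reg$kind == "rectangle") {
    x0 <- min(v[, 1L]); x1 <- max(v[, 1L])
    y0 <- min(v[, 2L]); y1 <- max(v[, 2L])
    xs <- seq.int(ceiling(x0), ceiling(x1) - 1L)
    ys <- seq.int(ceiling(y0), ceiling(y1) - 1L)
    if (length(xs) == 0L || length(ys) == 0L) {
      stop("region '", reg$name, "' rasterizes to an empty pixel set")
    }
    px <- rep(xs, each = length(ys))
    py <- rep(ys, times = length(xs))
  } else {
    xr <- range(v[, 1L]); yr <- range(v[, 2L])
    xs <- seq.int(floor(xr[1L]), ceiling(xr[2L]))
    ys <- seq.int(floor(yr[1L]), ceiling(yr[2L]))
    px <- rep(xs, each = length(ys))
    py <- rep(ys, times = length(xs))
    inside <- point_in_polygon(px, py, v)
    px <- px[inside]; py <- py[inside]
    if (length(px) == 0L) stop("region '", reg$name, "' rasterizes to an empty pixel set")
  }
  ok <- px >= 0 & px <= nx - 1L & py >= 0 & py <= ny - 1L
  if (!all(ok)) {
    warning("region '", reg$name, "' extends outside the frame; clipped ",
            sum(!ok), " pixel(s)")
    px <- px[ok]; py <- py[ok]
  }
  if (length(px) == 0L) stop("region '", reg$name, "' lies entirely outside the frame")
  cbind(row = as.integer(py) + 1L, col = as.integer(px) + 1L)
}

# Even-odd ray-crossing test, vectorized over query points.
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Linear (column-major) indices of a region's pixels within an (ny, nx) frame.
region_index <- function(reg, dim) {
  rc <- rasterize_region(reg, dim)
  (rc[, "col"] - 1L) * dim[1L] + rc[, "row"]
}

#' Read regions from a JSON sidecar
#'
#' The sidecar format is
#' \code{{"regions": [{"name": ..., "kind": "rectangle"|"polygon",
#' "vertices": [[x, y], ...], "role": ...}, ...]}} with 0-based (x, y)
#' pixel coordinates.
#'
#' @param path Path to the JSON file.
#' @return A named list of \code{Region} objects.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path)
  if (is.null(j$regions)) stop("malformed region file (no 'regions' key): ", path)
  regs <- lapply(j$regions, function(r) {
    if (is.null(r$name) || is.null(r$kind) || is.null(r$vertices)) {
      stop("malformed region entry in ", path)
    }
    region(r$name, r$kind, lapply(r$vertices, unlist),
           role = if (is.null(r$role)) "measurement" else r$role)
  })
  names(regs) <- vapply(regs, `[[`, "", "name")
  regs
}

#' Write regions to a JSON sidecar
#' @param regions A list of \code{Region} objects.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  out <- list(regions = lapply(regions, function(r) {
    list(name = r$name, kind = r$kind,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])),
         role = r$role)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a measurement table to CSV
#'
#' Columns are \code{roi_name, frame_index, mean_ratio, sd_ratio, n_pixels}
#' (plus \code{source} after pooling); missing values are written as empty
#' fields.
#'
#' @param table A data frame as returned by \code{\link{measure_rois}}.
#' @param path Output path.
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a measurement table from CSV
#' @param path Path to a CSV written by \code{\link{write_measurements}}.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
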