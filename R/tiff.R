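# Minimal baseline TIFF codec.
#
# No TIFF package ships with the target environment, so the pipeline carries
# its own reader/writer for the subset it needs: uncompressed baseline TIFF,
# little- or big-endian on read (little-endian on write), grayscale 1 sample
# per pixel at 8/16-bit unsigned or 32-bit IEEE float, plus 8-bit RGB
# (3 samples, chunky) for pseudocolor renders. Multi-page stacks, one or more
# strips per page. Tiled, compressed or palette TIFFs are rejected with an
# error rather than misread.

.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.tiff_read_entry_values <- function(con, type, count, endian) {
  size <- .tiff_type_size[type]
  total <- size * count
  here <- seek(con, NA)
  if (total > 4) {
    off <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    seek(con, off)
  }
  vals <- switch(as.character(type),
    "1" = readBin(con, "integer", count, size = 1L, signed = FALSE, endian = endian),
    "3" = readBin(con, "integer", count, size = 2L, signed = FALSE, endian = endian),
    "4" = readBin(con, "integer", count, size = 4L, endian = endian),
    {
      # types we never need (ASCII, RATIONAL, ...): skip
      readBin(con, "raw", total)
      NULL
    }
  )
  seek(con, here + 4)
  vals
}

.tiff_read_ifd <- function(con, offset, endian) {
  seek(con, offset)
  n <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n)) {
    tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    vals <- .tiff_read_entry_values(con, type, count, endian)
    tags[[as.character(tag)]] <- vals
  }
  nxt <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  list(tags = tags, next_ifd = nxt)
}

#' Read a single- or multi-page grayscale TIFF
#'
#' Reads an uncompressed baseline TIFF into a numeric 3-D array
#' \code{(y, x, t)}. Supports 8/16-bit unsigned integer and 32-bit float
#' pixels, little- or big-endian files, multiple strips per page.
#'
#' @param path Path to the TIFF file.
#' @return A list with \code{frames} (3-D numeric array) and \code{dtype}
#'   (one of \code{"uint8"}, \code{"uint16"}, \code{"float32"}).
#' @keywords internal
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  endian <- if (identical(magic, as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic, as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  fortytwo <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  if (fortytwo != 42L) stop("not a TIFF file (bad magic): ", path)
  offset <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (offset == 0L) stop("TIFF has zero pages: ", path)
  pages <- list()
  dtype <- NULL
  while (offset != 0L) {
    ifd <- .tiff_read_ifd(con, offset, endian)
    tg <- ifd$tags
    need <- function(code, default = NULL) {
      v <- tg[[as.character(code)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF missing required tag ", code)
        default
      } else v
    }
    w <- need(256)
    h <- need(257)
    bits <- need(258, 1L)
    compression <- need(259, 1L)
    spp <- need(277, 1L)
    sfmt <- need(339, 1L)
    if (compression != 1L) stop("unsupported TIFF compression: ", compression)
    if (!is.null(tg[["322"]]) || !is.null(tg[["324"]])) stop("tiled TIFF unsupported")
    if (any(spp != 1L)) stop("read_tiff() handles grayscale (1 sample/pixel) only")
    bps <- bits[1L]
    this_dtype <- if (sfmt[1L] == 3L && bps == 32L) "float32"
                  else if (sfmt[1L] %in% c(1L, 4L) && bps == 8L) "uint8"
                  else if (sfmt[1L] %in% c(1L, 4L) && bps == 16L) "uint16"
                  else stop("unsupported pixel format: ", bps, "-bit, sample format ", sfmt[1L])
    offs <- need(273)
    cnts <- need(279)
    raw <- raw(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      raw <- c(raw, readBin(con, "raw", cnts[s]))
    }
    npx <- as.numeric(w) * as.numeric(h)
    vals <- switch(this_dtype,
      uint8   = as.numeric(readBin(raw, "integer", npx, size = 1L, signed = FALSE, endian = endian)),
      uint16  = as.numeric(readBin(raw, "integer", npx, size = 2L, signed = FALSE, endian = endian)),
      float32 = readBin(raw, "double", npx, size = 4L, endian = endian)
    )
    if (length(vals) != npx) stop("truncated TIFF strip data in ", path)
    # TIFF is row-major (rows of y), R arrays are column-major
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    if (is.null(dtype)) dtype <- this_dtype
    offset <- ifd$next_ifd
  }
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("TIFF pages differ in size: ", path)
  }
  frames <- array(unlist(pages), dim = c(dims[1L, 1L], dims[2L, 1L], length(pages)))
  list(frames = frames, dtype = dtype)
}

.tiff_entry <- function(tag, type, count, value_raw4) {
  c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    value_raw4)
}

.tiff_short_val <- function(v) {
  c(writeBin(as.integer(v), raw(), size = 2L, endian = "little"), as.raw(c(0, 0)))
}

.tiff_long_val <- function(v) {
  writeBin(as.integer(v), raw(), size = 4L, endian = "little")
}

#' Write a grayscale or RGB multi-page TIFF
#'
#' Writes an uncompressed little-endian baseline TIFF, one strip per page.
#'
#' @param frames 3-D array \code{(y, x, t)} for grayscale, or a list of
#'   \code{(y, x, 3)} arrays for 8-bit RGB pages.
#' @param path Output path.
#' @param depth \code{"uint8"}, \code{"uint16"} or \code{"float32"}
#'   (grayscale only; RGB pages are always 8-bit).
#' @keywords internal
write_tiff <- function(frames, path, depth = c("float32", "uint16", "uint8")) {
  depth <- match.arg(depth)
  rgb <- is.list(frames)
  if (!rgb && length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  npages <- if (rgb) length(frames) else dim(frames)[3L]
  stopifnot(npages >= 1L)
  if (rgb) depth <- "uint8"
  if (depth %in% c("uint8", "uint16")) {
    vmax <- if (depth == "uint8") 255 else 65535
    vals <- if (rgb) unlist(frames) else frames
    if (any(vals < 0) || any(vals > vmax)) {
      stop("values out of range for ", depth, " TIFF (no silent wrap)")
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)  # II, 42
  get_page <- function(i) if (rgb) frames[[i]] else frames[, , i, drop = FALSE]
  d1 <- dim(get_page(1L))
  h <- d1[1L]; w <- d1[2L]
  spp <- if (rgb) 3L else 1L
  bps <- switch(depth, uint8 = 8L, uint16 = 16L, float32 = 32L)
  strip_bytes <- as.integer(h * w * (bps / 8L) * spp)
  # grayscale IFD: 10 entries incl. SampleFormat; RGB IFD: 9 entries plus an
  # out-of-line BitsPerSample triple (6 bytes) after the next-IFD pointer
  n_entries <- if (rgb) 9L else 10L
  extra_bps <- if (rgb) 6L else 0L
  ifd_bytes <- 2L + n_entries * 12L + 4L + extra_bps
  # layout: header(8) then per page [strip data][IFD]
  offset <- 8L
  ifd_offsets <- integer(npages)
  strip_offsets <- integer(npages)
  for (i in seq_len(npages)) {
    strip_offsets[i] <- offset
    ifd_offsets[i] <- offset + strip_bytes
    offset <- offset + strip_bytes + ifd_bytes
  }
  writeBin(as.integer(ifd_offsets[1L]), con, size = 4L, endian = "little")
  for (i in seq_len(npages)) {
    pg <- get_page(i)
    if (rgb) {
      # interleave channels within row-major pixel order: RGBRGB...
      a <- aperm(array(pg, dim = c(h, w, 3L)), c(3L, 2L, 1L))
      writeBin(as.integer(round(a)), con, size = 1L, endian = "little")
    } else {
      v <- as.vector(t(matrix(pg, h, w)))  # row-major
      if (depth == "float32") {
        writeBin(as.double(v), con, size = 4L, endian = "little")
      } else {
        writeBin(as.integer(round(v)), con, size = bps / 8L, endian = "little")
      }
    }
    bps_val <- if (rgb) .tiff_long_val(ifd_offsets[i] + 2L + n_entries * 12L + 4L)
               else .tiff_short_val(bps)
    entries <- list(
      .tiff_entry(256, 4, 1, .tiff_long_val(w)),
      .tiff_entry(257, 4, 1, .tiff_long_val(h)),
      .tiff_entry(258, 3, spp, bps_val),
      .tiff_entry(259, 3, 1, .tiff_short_val(1L)),  # uncompressed
      .tiff_entry(262, 3, 1, .tiff_short_val(if (rgb) 2L else 1L)),
      .tiff_entry(273, 4, 1, .tiff_long_val(strip_offsets[i])),
      .tiff_entry(277, 3, 1, .tiff_short_val(spp)),
      .tiff_entry(278, 4, 1, .tiff_long_val(h)),
      .tiff_entry(279, 4, 1, .tiff_long_val(strip_bytes))
    )
    if (!rgb) {
      # SampleFormat: 1 = unsigned int, 3 = IEEE float
      entries <- c(entries, list(
        .tiff_entry(339, 3, 1, .tiff_short_val(if (depth == "float32") 3L else 1L))
      ))
    }
    writeBin(as.integer(length(entries)), con, size = 2L, endian = "little")
    for (e in entries) writeBin(e, con)
    nxt <- if (i < npages) ifd_offsets[i + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4L, endian = "little")
    if (rgb) writeBin(as.integer(c(8L, 8L, 8L)), con, size = 2L, endian = "little")
  }
  invisible(path)
}
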