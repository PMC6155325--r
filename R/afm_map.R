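#' AFM height map
#'
#' A rectangular grid of surface heights in nanometres with a known square
#' pixel size. Row index is the slow (y, downward) axis and column index the
#' fast (x, rightward) axis, so element `(row, col)` sits at physical
#' position `((col - 0.5) * pixel_size, (row - 0.5) * pixel_size)` nm
#' (pixel-centre convention).
#'
#' @param grid numeric matrix of heights in nm; must be finite.
#' @param pixel_size edge length of one (square) pixel in nm.
#' @return an object of class `afm_map` with elements `grid` and
#'   `pixel_size`.
#' @export
#' @examples
#' m <- afm_map(matrix(0, 4, 4), pixel_size = 2)
#' dim(m$grid)
afm_map <- function(grid, pixel_size) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix")
  if (!all(is.finite(grid)))
    stop("`grid` contains non-finite heights")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (nm)")
  structure(list(grid = grid, pixel_size = as.numeric(pixel_size)),
            class = "afm_map")
}

#' @export
print.afm_map <- function(x, ...) {
  cat(sprintf("AFM height map: %d x %d px, %.4g nm/px (%.3g x %.3g nm)\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              ncol(x$grid) * x$pixel_size, nrow(x$grid) * x$pixel_size))
  cat(sprintf("  height range: [%.4g, %.4g] nm\n",
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Read an AFM height map from TIFF or ASCII
#'
#' Accepts single-channel TIFF rasters (32-bit float preferred; integer
#' rasters are multiplied by `scale` to convert counts to nm) or a
#' whitespace-delimited ASCII matrix. The pixel size is never inferred from
#' file metadata: it must be supplied explicitly, because instrument TIFF
#' tags are unreliable.
#'
#' @param path file to read; format chosen by extension (`.tif`/`.tiff`
#'   versus anything else, treated as ASCII).
#' @param pixel_size nm per pixel.
#' @param scale multiplicative factor applied to raw pixel values
#'   (default 1); use it to convert integer instrument counts to nm.
#' @return an [afm_map()].
#' @export
read_height_map <- function(path, pixel_size, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # as.is = TRUE returns raw integer counts for integer rasters but is
    # unsupported for float images, where plain reading is already lossless
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path))
    if (length(dim(raw)) != 2L)
      stop("multi-channel TIFF not supported (", paste(dim(raw), collapse = "x"),
           "): supply a single-channel height raster")
    grid <- matrix(as.numeric(raw) * scale, nrow(raw), ncol(raw))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty ASCII matrix: ", path)
    rows <- lapply(strsplit(trimws(lines), "[ \t]+"), function(tok) {
      suppressWarnings(as.numeric(tok))
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L)
      stop("ragged ASCII matrix (row widths ", paste(unique(widths), collapse = ", "),
           "): ", path)
    vals <- unlist(rows)
    if (anyNA(vals))
      stop("non-numeric entries in ASCII matrix: ", path)
    grid <- matrix(vals * scale, nrow = length(rows), byrow = TRUE)
  }
  afm_map(grid, pixel_size)
}

#' Write an AFM height map to TIFF (32-bit float) or ASCII
#'
#' The TIFF output is a single-strip, single-channel, little-endian 32-bit
#' floating-point raster (sample format IEEE float), readable by
#' `tiff::readTIFF` and standard imaging tools; heights are stored at single
#' precision. The ASCII output is a whitespace-delimited matrix with full
#' double precision (`%.17g`).
#'
#' @param map an [afm_map()].
#' @param path output file.
#' @param format `"tiff"` or `"ascii"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(map, path, format = NULL) {
  stopifnot(inherits(map, "afm_map"))
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) %in% c("tif", "tiff"))
      "tiff" else "ascii"
  }
  format <- match.arg(format, c("tiff", "ascii"))
  if (format == "tiff") {
    write_float_tiff(map$grid, path)
  } else {
    rows <- apply(map$grid, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    writeLines(rows, path)
  }
  invisible(path)
}

# Minimal single-strip little-endian TIFF with 32-bit IEEE float samples.
# (The tiff package reads this format but can only write unsigned-integer
# sample formats, hence this writer.)
write_float_tiff <- function(grid, path) {
  width <- ncol(grid)
  height <- nrow(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # tag id, type (3 = short, 4 = long), count, value
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  n_entries <- 10L
  data_offset <- 8L + 2L + n_entries * 12L + 4L
  writeBin(charToRaw("II"), con)      # little-endian byte order
  wr2(42L)                            # TIFF magic
  wr4(8L)                             # offset of first (only) IFD
  wr2(n_entries)
  entry(256L, 3L, 1L, width)          # ImageWidth
  entry(257L, 3L, 1L, height)         # ImageLength
  entry(258L, 3L, 1L, 32L)            # BitsPerSample
  entry(259L, 3L, 1L, 1L)             # Compression: none
  entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)    # StripOffsets
  entry(277L, 3L, 1L, 1L)             # SamplesPerPixel
  entry(278L, 3L, 1L, height)         # RowsPerStrip
  entry(279L, 4L, 1L, width * height * 4L)  # StripByteCounts
  entry(339L, 3L, 1L, 3L)             # SampleFormat: IEEE float
  wr4(0L)                             # no further IFD
  # pixel data, row-major
  writeBin(as.numeric(t(grid)), con, size = 4, endian = "little")
  invisible(path)
}
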