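#' Validate a radiograph matrix
#'
#' Checks the invariants every downstream module relies on: a numeric
#' matrix with at least 3 rows and 3 columns, all values finite and in
#' `[0, 1]`. Returns the matrix unchanged (invisibly gains no class;
#' radiographs are plain matrices throughout the package).
#'
#' @param x numeric matrix.
#' @param what label used in error messages.
#' @return the validated matrix.
#' @export
as_radiograph <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    btd_stop("btd_error_bad_input", "%s must be a numeric matrix", what)
  if (nrow(x) < 3L || ncol(x) < 3L)
    btd_stop("btd_error_bad_input", "%s must be at least 3x3 pixels", what)
  if (any(!is.finite(x)))
    btd_stop("btd_error_bad_input", "%s contains non-finite values", what)
  if (min(x) < 0 || max(x) > 1)
    btd_stop("btd_error_bad_input",
             "%s has values outside [0, 1] (range %.4g..%.4g)",
             what, min(x), max(x))
  x
}

#' Load a grayscale radiograph from PNG or TIFF
#'
#' Integer samples are normalized by the full-scale maximum of their bit
#' depth (255 or 65535), never by the per-image maximum, so that the
#' linear relationship between intensity and X-ray dose is preserved;
#' floating-point TIFF samples are clipped to `[0, 1]`. Multi-channel
#' files are accepted only when all channels are identical (a common way
#' grayscale images are stored) and are reduced to one channel.
#'
#' The pipeline operates in the bones-bright convention (the subtracted
#' display in which bone is bright). For sensor-native bones-dark images
#' set `invert = TRUE`, which maps `v` to `1 - v` after normalization;
#' there is no auto-detection.
#'
#' @param path path to a single-channel PNG or TIFF file.
#' @param invert flip intensities (`v -> 1 - v`) after normalization.
#' @param rescale if `TRUE`, linearly stretch the image to span `[0, 1]`
#'   using its own min/max. Off by default because it destroys the
#'   dose-intensity relationship; offered for display-normalized inputs.
#' @return numeric matrix with values in `[0, 1]`, rows = image rows.
#' @export
load_radiograph <- function(path, invert = FALSE, rescale = FALSE) {
  x <- read_raster(path)
  if (isTRUE(rescale)) {
    rng <- range(x)
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
  }
  x <- pmin(pmax(x, 0), 1)
  if (isTRUE(invert)) x <- 1 - x
  if (max(x) == min(x))
    btd_warn("image '%s' is constant (value %.4g)", path, x[1])
  as_radiograph(x, sprintf("image '%s'", path))
}

# Shared PNG/TIFF reader; returns a matrix of doubles in [0,1] for integer
# files (the readers divide by the dtype maximum) or raw floats for float
# TIFF. Channel reduction happens here.
read_raster <- function(path) {
  if (!file.exists(path))
    btd_stop("btd_error_bad_input", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    btd_stop("btd_error_bad_input",
             "unsupported image format '.%s' (use PNG or TIFF)", ext)
  )
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    # drop a fully opaque alpha channel, then require equal gray channels
    if (nc %in% c(2L, 4L) && all(x[, , nc] == 1)) {
      x <- x[, , -nc, drop = FALSE]
      nc <- dim(x)[3]
    }
    if (nc > 1L) {
      for (k in seq_len(nc - 1L))
        if (any(x[, , k] != x[, , k + 1L]))
          btd_stop("btd_error_bad_input",
                   "multi-channel image with unequal channels: %s", path)
    }
    x <- x[, , 1L]
  }
  if (!is.matrix(x))
    btd_stop("btd_error_bad_input", "could not read a 2-D raster from %s", path)
  x
}

#' Save an image as PNG or TIFF
#'
#' Integer output uses round-half-up quantization (`floor(v * m + 0.5)`
#' with `m` the full-scale maximum), so a save/load round trip differs by
#' at most half a quantization step per pixel. Float output (32-bit IEEE
#' TIFF) is lossless. Values outside `[0, 1]` are rejected, not clipped.
#'
#' PNG supports 8-bit output only; use TIFF for 16-bit and float.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param path destination; extension selects the container (.png/.tif).
#' @param bit_depth one of `"8"`, `"16"`, `"float"`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bit_depth = c("8", "16", "float")) {
  bit_depth <- match.arg(as.character(bit_depth), c("8", "16", "float"))
  if (!is.matrix(img) || !is.numeric(img))
    btd_stop("btd_error_bad_input", "img must be a numeric matrix")
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 1)
    btd_stop("btd_error_bad_input",
             "refusing to save values outside [0, 1]; clip explicitly first")
  ext <- tolower(tools::file_ext(path))
  if (bit_depth == "float") {
    if (!ext %in% c("tif", "tiff"))
      btd_stop("btd_error_bad_input", "float output requires a .tif path")
    write_tiff_float32(img, path)
    return(invisible(path))
  }
  m <- if (bit_depth == "8") 255 else 65535
  q <- floor(img * m + 0.5)
  if (bit_depth == "8" && ext == "png") {
    png::writePNG(q / m, path)  # writePNG rounds to nearest: stores q
  } else if (ext %in% c("tif", "tiff")) {
    # writeTIFF truncates; mid-bin values make it store exactly q
    tiff::writeTIFF(pmin((q + 0.5) / m, 1), path,
                    bits.per.sample = as.integer(bit_depth))
  } else {
    btd_stop("btd_error_bad_input",
             "cannot write %s-bit output to '.%s' (PNG is 8-bit only)",
             bit_depth, ext)
  }
  invisible(path)
}

# Minimal single-strip grayscale 32-bit float TIFF writer (little-endian).
# The tiff package reads IEEE-float TIFFs but only writes unsigned
# integers, so lossless float output is produced here directly.
write_tiff_float32 <- function(img, path) {
  h <- nrow(img); w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                       # little-endian
  writeBin(42L, con, size = 2, endian = "little")      # TIFF magic
  writeBin(8L, con, size = 4, endian = "little")       # first IFD offset
  tags <- list(  # tag, type (3=SHORT, 4=LONG), value
    c(256L, 4L, w),          # ImageWidth
    c(257L, 4L, h),          # ImageLength
    c(258L, 3L, 32L),        # BitsPerSample
    c(259L, 3L, 1L),         # Compression: none
    c(262L, 3L, 1L),         # Photometric: BlackIsZero
    c(273L, 4L, 0L),         # StripOffsets (patched below)
    c(277L, 3L, 1L),         # SamplesPerPixel
    c(278L, 4L, h),          # RowsPerStrip: one strip
    c(279L, 4L, 4L * h * w), # StripByteCounts
    c(339L, 3L, 3L)          # SampleFormat: IEEE float
  )
  n <- length(tags)
  writeBin(as.integer(n), con, size = 2, endian = "little")
  data_offset <- 8L + 2L + n * 12L + 4L
  for (tg in tags) {
    if (tg[1] == 273L) tg[3] <- data_offset
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (tg[2] == 3L) {  # SHORT payload is left-justified in the 4 bytes
      writeBin(as.integer(tg[3]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")       # no next IFD
  # pixel data, row-major (TIFF scanline order)
  writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
  invisible(path)
}

#' Load a binary mask image
#'
#' Reads a PNG/TIFF raster and binarizes it: nonzero pixels are inside the
#' mask.
#'
#' @param path path to the mask image.
#' @return logical matrix.
#' @export
load_mask <- function(path) {
  read_raster(path) > 0
}

#' Save a binary mask image
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param path destination PNG or TIFF path; written 8-bit, inside = 255.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  save_image(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)),
             path, bit_depth = "8")
}
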