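#' Raster image container
#'
#' A thin wrapper around an integer intensity grid: a matrix (single channel)
#' or an `H x W x 3` array (3-channel), carrying its bit depth and the role
#' the channel plays in the pipeline (`"nuclei"` for DAPI, `"damage"` for
#' gamma-H2A.X foci, `"composite"` for overlays, `"generic"` otherwise).
#' All pipeline operations accept plain matrices too and coerce with
#' 8-bit defaults.
#'
#' @param pixels Numeric matrix or `H x W x 3` array of intensities in
#'   `[0, 2^bitdepth - 1]`.
#' @param bitdepth Integer, 8 or 16.
#' @param channel_role One of `"nuclei"`, `"damage"`, `"composite"`,
#'   `"generic"`.
#' @return A `raster_image` object.
#' @export
raster_image <- function(pixels, bitdepth = 8L,
                         channel_role = c("generic", "nuclei", "damage", "composite")) {
  channel_role <- match.arg(channel_role)
  if (!bitdepth %in% c(8L, 16L)) {
    stop("bitdepth must be 8 or 16", call. = FALSE)
  }
  if (is.matrix(pixels)) {
    if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
      stop("image must have both dimensions >= 1", call. = FALSE)
    }
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] != 3L) {
      stop("multi-channel images must have exactly 3 channels", call. = FALSE)
    }
  } else {
    stop("pixels must be a matrix or an H x W x 3 array", call. = FALSE)
  }
  maxval <- bit_maxval(bitdepth)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > maxval) {
    stop("intensities outside [0, ", maxval, "]", call. = FALSE)
  }
  structure(pixels, bitdepth = as.integer(bitdepth), channel_role = channel_role,
            class = c("raster_image", class(pixels)))
}

bit_maxval <- function(bitdepth) as.integer(2L^as.integer(bitdepth) - 1L)

#' @rdname raster_image
#' @param x Object to coerce or test.
#' @export
as_raster_image <- function(x, bitdepth = 8L, channel_role = "generic") {
  if (is_raster_image(x)) return(x)
  raster_image(x, bitdepth = bitdepth, channel_role = channel_role)
}

#' @rdname raster_image
#' @export
is_raster_image <- function(x) inherits(x, "raster_image")

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image> %d x %d%s, %d-bit, role = %s\n",
              d[1], d[2], if (length(d) == 3L) " x 3" else "",
              attr(x, "bitdepth"), attr(x, "channel_role")))
  invisible(x)
}

img_bitdepth <- function(img) {
  bd <- attr(img, "bitdepth")
  if (is.null(bd)) 8L else bd
}

## strip raster attributes, returning the bare matrix/array
img_pixels <- function(img) {
  attributes(img) <- attributes(img)["dim"]
  img
}

#' Convert a multi-channel image to grayscale
#'
#' Single-channel inputs are returned unchanged. Three-channel inputs are
#' reduced with ITU-R BT.601 luminance weights (0.299 R + 0.587 G + 0.114 B),
#' rounded to the nearest integer.
#'
#' @param image A `raster_image` (matrix or `H x W x 3` array).
#' @return A single-channel `raster_image` with the same bit depth.
#' @export
to_grayscale <- function(image) {
  bd <- img_bitdepth(image)
  role <- attr(image, "channel_role") %||% "generic"
  if (is.matrix(image)) {
    return(as_raster_image(img_pixels(image), bitdepth = bd, channel_role = role))
  }
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("unsupported channel count: expected 1 or 3 channels", call. = FALSE)
  }
  px <- img_pixels(image)
  g <- round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  g <- pmin(pmax(g, 0), bit_maxval(bd))
  raster_image(g, bitdepth = bd, channel_role = role)
}

#' Lossless quarter-turn rotation
#'
#' Rotates an image by `k` quarter turns clockwise as a pure pixel
#' permutation (no interpolation). Non-square images swap dimensions for
#' odd `k`.
#'
#' @param image Matrix or `H x W x 3` array.
#' @param k Integer number of clockwise quarter turns (any integer; taken
#'   modulo 4).
#' @return The rotated image, attributes preserved.
#' @export
rotate_quarter <- function(image, k) {
  k <- as.integer(k) %% 4L
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rot <- function(m) {
    for (i in seq_len(k)) m <- rot1(m)
    m
  }
  bd <- img_bitdepth(image)
  role <- attr(image, "channel_role") %||% "generic"
  if (k == 0L) return(image)
  if (is.matrix(image)) {
    out <- rot(img_pixels(image))
  } else {
    px <- img_pixels(image)
    ch <- lapply(1:3, function(i) rot(px[, , i]))
    out <- array(c(ch[[1]], ch[[2]], ch[[3]]), dim = c(dim(ch[[1]]), 3L))
  }
  if (is_raster_image(image)) raster_image(out, bitdepth = bd, channel_role = role) else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write slide images
#'
#' Reads 8- or 16-bit PNG/TIFF images into integer rasters (single- or
#' 3-channel); writes rasters back out, inferring the format from the file
#' extension. TIFF and PNG store intensities scaled to `[0, 1]`; these
#' helpers convert to and from the integer range of the declared bit depth.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param channel_role Role tag attached to the result.
#' @return `read_slide_image()`: a `raster_image`. `write_slide_image()`:
#'   the path, invisibly.
#' @export
read_slide_image <- function(path, channel_role = "generic") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  bits <- attr(arr, "bits.per.sample") %||% 8L
  bd <- if (bits > 8L) 16L else 8L
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 2L) arr <- arr[, , 1]          # gray + alpha
    else if (dim(arr)[3] == 4L) arr <- arr[, , 1:3]   # drop alpha
  }
  px <- round(arr * bit_maxval(bd))
  raster_image(px, bitdepth = bd, channel_role = channel_role)
}

#' @rdname read_slide_image
#' @param image A `raster_image` or plain matrix/array.
#' @export
write_slide_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  bd <- img_bitdepth(image)
  arr <- img_pixels(image) / bit_maxval(bd)
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = as.integer(bd))
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}
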