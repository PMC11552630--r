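#' Bicubic resampling
#'
#' Separable bicubic interpolation with the Keys kernel (a = -0.5, the
#' common library default). Output sample positions are mapped to source
#' coordinates by `s = i * (n_in - 1) / (n_out - 1)` (corner-aligned, so
#' image corners are preserved exactly), border samples are replicated, and
#' results are rounded and clipped to the valid intensity range. `bicubic_upscale()` is the integer-factor
#' enlargement used by nucleus segmentation: a per-axis factor of 4 gives
#' the 16-fold area enlargement.
#'
#' @param image Single-channel `raster_image` or matrix.
#' @param out_h,out_w Output dimensions (positive integers).
#' @return A `raster_image` with the requested dimensions.
#' @export
resize_bicubic <- function(image, out_h, out_w) {
  if (out_h < 1 || out_w < 1) stop("output dimensions must be >= 1", call. = FALSE)
  bd <- img_bitdepth(image)
  role <- attr(image, "channel_role") %||% "generic"
  px <- img_pixels(image)
  if (!is.matrix(px)) stop("resize_bicubic expects a single-channel image", call. = FALSE)
  A <- interp_matrix(nrow(px), out_h)
  B <- interp_matrix(ncol(px), out_w)
  out <- as.matrix(A %*% px %*% Matrix::t(B))
  out <- pmin(pmax(round(out), 0), bit_maxval(bd))
  raster_image(out, bitdepth = bd, channel_role = role)
}

#' @rdname resize_bicubic
#' @param factor Integer per-axis enlargement factor, >= 1.
#' @export
bicubic_upscale <- function(image, factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != round(factor)) {
    stop("factor must be a single integer >= 1", call. = FALSE)
  }
  if (factor == 1L) return(image)
  resize_bicubic(image, nrow(image) * factor, ncol(image) * factor)
}

#' Keys cubic convolution kernel (a = -0.5)
#' @param x Distance from the sample point.
#' @return Kernel weight.
#' @keywords internal
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1,
         (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

## sparse (n_out x n_in) row-interpolation operator; edge replication
interp_matrix <- function(n_in, n_out) {
  i_out <- seq_len(n_out) - 1
  s <- if (n_out == 1L) rep((n_in - 1) / 2, 1L) else i_out * (n_in - 1) / (n_out - 1)
  base <- floor(s)
  offs <- -1:2
  rows <- rep(seq_len(n_out), times = 4L)
  src <- as.vector(outer(base, offs, `+`))
  w <- cubic_kernel(rep(s, times = 4L) - src)
  src <- pmin(pmax(src, 0), n_in - 1) + 1  # replicate borders
  M <- Matrix::sparseMatrix(i = rows, j = src, x = w, dims = c(n_out, n_in))
  # renormalize rows (guards degenerate cases; interior rows already sum to 1)
  rs <- Matrix::rowSums(M)
  Matrix::Diagonal(x = 1 / rs) %*% M
}

#' Model-input preprocessing
#'
#' Aspect-preserving resize of the longer side to `input_size`, zero-padded
#' (top-left anchored) to a square, intensities scaled to `[0, 1]`, and
#' single-channel inputs replicated to 3 channels. This is the canonical
#' geometry normalization applied to both nucleus crops (arbitrary bounding
#' boxes) and fixed-size patches before classification.
#'
#' @param item `raster_image`, matrix, or `H x W x 3` array.
#' @param input_size Side length of the square model input.
#' @return An `input_size x input_size x 3` numeric array in `[0, 1]`.
#' @export
preprocess_for_model <- function(item, input_size) {
  if (input_size < 16) stop("input_size must be >= 16", call. = FALSE)
  bd <- img_bitdepth(item)
  px <- img_pixels(item)
  chans <- if (is.matrix(px)) list(px, px, px) else lapply(1:3, function(i) px[, , i])
  h <- nrow(chans[[1]]); w <- ncol(chans[[1]])
  sc <- input_size / max(h, w)
  nh <- max(1L, as.integer(round(h * sc)))
  nw <- max(1L, as.integer(round(w * sc)))
  out <- array(0, dim = c(input_size, input_size, 3L))
  for (i in 1:3) {
    ch <- chans[[i]]
    if (nh != h || nw != w) {
      ch <- img_pixels(resize_bicubic(raster_image(ch, bitdepth = bd), nh, nw))
    }
    out[seq_len(nh), seq_len(nw), i] <- ch / bit_maxval(bd)
  }
  out
}
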