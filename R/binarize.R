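#' Otsu threshold selection
#'
#' Picks the integer threshold maximizing between-class variance of the
#' intensity histogram, the standard criterion for separating bright nuclei
#' from dark background. Foreground is defined as intensities strictly
#' greater than the returned threshold (see [binarize()]). Ties are broken
#' toward the smallest maximizing threshold.
#'
#' @param image Single-channel `raster_image` or matrix of integer
#'   intensities.
#' @return Integer threshold `t`; pixels with intensity `> t` are
#'   foreground.
#' @export
otsu_threshold <- function(image) {
  bd <- img_bitdepth(image)
  px <- as.vector(img_pixels(image))
  maxval <- bit_maxval(bd)
  counts <- as.numeric(tabulate(px + 1L, nbins = maxval + 1L))
  if (sum(counts > 0) < 2L) {
    stop("degenerate input: constant image has no Otsu threshold", call. = FALSE)
  }
  n <- sum(counts)
  levels <- 0:maxval
  w0 <- cumsum(counts)                 # background size for threshold t = level
  m0 <- cumsum(counts * levels)        # background intensity mass
  mt <- m0[length(m0)]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / w0
  mu1 <- (mt - m0) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  as.integer(levels[which.max(bcv)])
}

#' Binarize an image at a threshold
#'
#' @param image Single-channel `raster_image` or matrix.
#' @param threshold Integer within the image's intensity range; pixels
#'   strictly greater than it map to 1.
#' @return A 0/1 integer matrix of class `binary_mask`.
#' @export
binarize <- function(image, threshold) {
  bd <- img_bitdepth(image)
  if (threshold < 0 || threshold > bit_maxval(bd)) {
    stop("threshold outside the intensity range", call. = FALSE)
  }
  m <- (img_pixels(image) > threshold) + 0L
  structure(m, class = c("binary_mask", class(m)))
}

#' Structuring element for binary morphology
#'
#' @param size Odd side length (default 3).
#' @param shape `"box"` (all-true square) or `"cross"`.
#' @return Logical matrix with odd sides and a true origin.
#' @export
structuring_element <- function(size = 3L, shape = c("box", "cross")) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("size must be a positive odd integer", call. = FALSE)
  if (shape == "box") {
    se <- matrix(TRUE, size, size)
  } else {
    se <- matrix(FALSE, size, size)
    mid <- (size + 1L) %/% 2L
    se[mid, ] <- TRUE
    se[, mid] <- TRUE
  }
  se
}

## reflect-pad a matrix by (pr, pc) on each side (edge-inclusive mirror)
reflect_pad <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(rev(seq_len(min(pr, nr))), seq_len(nr), nr + 1 - rev(seq_len(min(pr, nr))))
  if (pr > nr) stop("structuring element larger than image", call. = FALSE)
  cidx <- c(rev(seq_len(min(pc, nc))), seq_len(nc), nc + 1 - rev(seq_len(min(pc, nc))))
  m[ridx, cidx, drop = FALSE]
}

morph_extreme <- function(mask, se, op) {
  se <- as.matrix(se)
  if (nrow(se) %% 2L == 0L || ncol(se) %% 2L == 0L) {
    stop("structuring element must have odd side lengths", call. = FALSE)
  }
  cr <- (nrow(se) + 1L) %/% 2L; cc <- (ncol(se) + 1L) %/% 2L
  if (!isTRUE(se[cr, cc] != 0)) stop("structuring element origin must be true", call. = FALSE)
  m <- img_pixels(mask) + 0L
  nr <- nrow(m); nc <- ncol(m)
  p <- reflect_pad(m, cr - 1L, cc - 1L)
  out <- NULL
  for (i in seq_len(nrow(se))) {
    for (j in seq_len(ncol(se))) {
      if (!se[i, j]) next
      v <- p[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
      out <- if (is.null(out)) v else op(out, v)
    }
  }
  structure(out, class = c("binary_mask", class(out)))
}

#' Binary dilation, erosion and morphological gradient
#'
#' The morphological gradient (dilation minus erosion) of the Otsu mask
#' outlines nucleus contours. Borders are handled by reflect padding, so a
#' constant mask has an all-zero gradient.
#'
#' @param mask 0/1 matrix (`binary_mask`).
#' @param se Structuring element from [structuring_element()].
#' @return A `binary_mask` of the same shape.
#' @export
dilate_mask <- function(mask, se = structuring_element()) morph_extreme(mask, se, pmax)

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, se = structuring_element()) morph_extreme(mask, se, pmin)

#' @rdname dilate_mask
#' @export
morphological_gradient <- function(mask, se = structuring_element()) {
  g <- dilate_mask(mask, se) - erode_mask(mask, se)
  structure(g, class = c("binary_mask", class(g)))
}

#' Connected-component labeling
#'
#' Labels maximal connected foreground regions (8-connected by default, the
#' standard choice for convex nucleus blobs) and measures each object's
#' pixel-count area and tight bounding rectangle.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return A data frame with one row per object: `object_id`, `area_px`,
#'   and a 0-based half-open bounding box (`row_min`, `col_min`, `height`,
#'   `width`). The label matrix is attached as attribute `"labels"`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  m <- img_pixels(mask) + 0L
  storage.mode(m) <- "integer"
  lab <- .label_cc(m, as.integer(connectivity))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    out <- data.frame(object_id = integer(), area_px = integer(),
                      row_min = integer(), col_min = integer(),
                      height = integer(), width = integer())
    attr(out, "labels") <- lab
    return(out)
  }
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(m)        # 0-based row
  cc <- (idx - 1L) %/% nrow(m)      # 0-based col
  area <- tabulate(l)
  rmin <- tapply(r, l, min); rmax <- tapply(r, l, max)
  cmin <- tapply(cc, l, min); cmax <- tapply(cc, l, max)
  out <- data.frame(
    object_id = seq_along(area),
    area_px = area,
    row_min = as.integer(rmin),
    col_min = as.integer(cmin),
    height = as.integer(rmax - rmin + 1L),
    width = as.integer(cmax - cmin + 1L)
  )
  attr(out, "labels") <- lab
  out
}
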