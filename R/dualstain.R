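#' Automatic brightness/contrast adjustment
#'
#' Histogram-based linear rescale in the style of the familiar "Auto"
#' brightness/contrast tool: intensities at the `saturation_fraction` tails
#' of the histogram are saturated and the remaining range is mapped linearly
#' onto the full output range. With `saturation_fraction = 0` the image
#' minimum maps to 0 and the maximum to the top of the range. A constant
#' channel is returned unchanged (its histogram carries no contrast).
#'
#' @param channel Single-channel `raster_image` or matrix.
#' @param saturation_fraction Fraction in `[0, 0.5)` of pixels saturated at
#'   each end (default 0.0035, i.e. 0.35%).
#' @return Rescaled `raster_image` of the same bit depth.
#' @export
auto_contrast <- function(channel, saturation_fraction = 0.0035) {
  if (saturation_fraction < 0 || saturation_fraction >= 0.5) {
    stop("saturation_fraction must be in [0, 0.5)", call. = FALSE)
  }
  bd <- img_bitdepth(channel)
  role <- attr(channel, "channel_role") %||% "generic"
  maxval <- bit_maxval(bd)
  px <- img_pixels(channel)
  counts <- tabulate(as.vector(px) + 1L, nbins = maxval + 1L)
  n <- sum(counts)
  cum <- cumsum(counts)
  ncut <- saturation_fraction * n
  lo <- min(which(cum > ncut)) - 1L          # intensity level, 0-based
  hi <- max(which(n - cum + counts > ncut)) - 1L
  if (hi <= lo) return(as_raster_image(px, bitdepth = bd, channel_role = role))
  out <- round((px - lo) / (hi - lo) * maxval)
  out <- pmin(pmax(out, 0), maxval)
  raster_image(out, bitdepth = bd, channel_role = role)
}

#' Overlay nuclei and DNA-damage channels into a dual-stain composite
#'
#' Builds the 3-channel composite used for prognosis prediction: each
#' channel is auto-contrasted, then the DAPI nuclei channel is placed in
#' blue and the gamma-H2A.X damage channel in red (the conventional
#' fluorophore display), green left empty. The mapping is configurable;
#' downstream classifiers only require consistency.
#'
#' @param nuclei,damage Same-shape single-channel images.
#' @param channel_map Named character vector assigning `"red"`, `"green"` or
#'   `"blue"` to `nuclei` and `damage`.
#' @param saturation_fraction Passed to [auto_contrast()].
#' @return A 3-channel `raster_image` with role `"composite"`.
#' @export
overlay_channels <- function(nuclei, damage,
                             channel_map = c(nuclei = "blue", damage = "red"),
                             saturation_fraction = 0.0035) {
  if (!identical(dim(img_pixels(nuclei)), dim(img_pixels(damage)))) {
    stop("channel dimensions differ: nuclei and damage images are not aligned",
         call. = FALSE)
  }
  slots <- c(red = 1L, green = 2L, blue = 3L)
  if (channel_map[["nuclei"]] == channel_map[["damage"]]) {
    stop("nuclei and damage must map to different display channels", call. = FALSE)
  }
  bd <- img_bitdepth(nuclei)
  nc <- img_pixels(auto_contrast(nuclei, saturation_fraction))
  dc <- img_pixels(auto_contrast(damage, saturation_fraction))
  out <- array(0, dim = c(dim(nc), 3L))
  out[, , slots[[channel_map[["nuclei"]]]]] <- nc
  out[, , slots[[channel_map[["damage"]]]]] <- dc
  raster_image(out, bitdepth = bd, channel_role = "composite")
}

#' Tile an image into fixed-size patches
#'
#' Non-overlapping grid tiling with stride equal to the patch size, row-major
#' order, partial edge tiles dropped: the patch count is
#' `floor(H / s) * floor(W / s)`. An 8064 x 10240 slide at `patch_size = 128`
#' yields 5040 patches.
#'
#' @param image `raster_image` (single- or 3-channel) or matrix.
#' @param patch_size Side length `s >= 1`.
#' @param patient_id,label Optional metadata inherited by every patch
#'   (weak labeling: patches carry their patient's outcome label).
#' @param pixels If `FALSE`, return grid metadata only (no pixel copies);
#'   useful when only counts or manifests are needed.
#' @return List of `patch` objects with fields `image`, `patient_id`,
#'   `grid_pos` (0-based `(tile_row, tile_col)`), `label`.
#' @export
tile_patches <- function(image, patch_size = 128L, patient_id = NA_character_,
                         label = NA_integer_, pixels = TRUE) {
  s <- as.integer(patch_size)
  if (s < 1L) stop("patch_size must be >= 1", call. = FALSE)
  bd <- img_bitdepth(image)
  px <- img_pixels(image)
  multi <- !is.matrix(px)
  h <- dim(px)[1]; w <- dim(px)[2]
  nr <- h %/% s; nc <- w %/% s
  if (nr == 0L || nc == 0L) return(list())
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    rows <- ((i - 1L) * s + 1L):(i * s)
    for (j in seq_len(nc)) {
      k <- k + 1L
      im <- NULL
      if (pixels) {
        cols <- ((j - 1L) * s + 1L):(j * s)
        sub <- if (multi) px[rows, cols, , drop = FALSE] else px[rows, cols, drop = FALSE]
        im <- raster_image(sub, bitdepth = bd,
                           channel_role = attr(image, "channel_role") %||% "generic")
      }
      out[[k]] <- structure(list(image = im, patient_id = patient_id,
                                 grid_pos = c(tile_row = i - 1L, tile_col = j - 1L),
                                 label = label),
                            class = "patch")
    }
  }
  out
}

#' Number of patches a tiling produces
#'
#' @param h,w Image dimensions.
#' @param patch_size Side length.
#' @return `floor(h / s) * floor(w / s)`.
#' @export
patch_count <- function(h, w, patch_size = 128L) {
  (h %/% patch_size) * (w %/% patch_size)
}

#' Write patches to disk with a manifest
#'
#' @param patches List from [tile_patches()] (with pixels).
#' @param dir Output directory.
#' @param prefix Filename prefix (default the patient id).
#' @param manifest_path Optional CSV path.
#' @return Data frame manifest, invisibly.
#' @export
write_patches <- function(patches, dir, prefix = NULL,
                          manifest_path = file.path(dir, "patches.csv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    pre <- prefix %||% if (is.na(p$patient_id)) "patch" else p$patient_id
    path <- file.path(dir, sprintf("%s_r%03d_c%03d.png", pre,
                                   p$grid_pos[["tile_row"]], p$grid_pos[["tile_col"]]))
    write_slide_image(p$image, path)
    data.frame(item_path = path, patient_id = p$patient_id,
               tile_row = p$grid_pos[["tile_row"]],
               tile_col = p$grid_pos[["tile_col"]], label = p$label)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) manifest <- data.frame()
  if (!is.null(manifest_path)) write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}
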