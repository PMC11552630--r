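#' Nucleus segmentation configuration
#'
#' Parameters of the five-step nucleus isolation procedure. The slide is
#' converted to grayscale, enlarged bicubically (`upscale_factor` per axis;
#' the default 4 gives a 16-fold area enlargement, needed because cardiac
#' nuclei are only a few pixels across at acquisition resolution), Otsu
#' binarized, contoured with a morphological gradient, and labeled; objects
#' with area at most `max_area_px` (measured in upscaled pixels, where areas
#' were computed) are kept and cropped at their tight bounding rectangles.
#'
#' @param upscale_factor Integer per-axis enlargement factor (default 4).
#' @param max_area_px Largest object area retained, in upscaled pixels
#'   (default 512; pass `Inf` to disable).
#' @param min_area_px Smallest object area retained (default 1, i.e. none
#'   excluded).
#' @param se_size Side of the square structuring element for the gradient.
#' @param connectivity 4 or 8 (default 8).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(upscale_factor = 4L, max_area_px = 512,
                                min_area_px = 1L, se_size = 3L,
                                connectivity = 8L) {
  if (upscale_factor < 1L) stop("upscale_factor must be >= 1", call. = FALSE)
  if (max_area_px < 1) stop("max_area_px must be >= 1", call. = FALSE)
  structure(list(upscale_factor = as.integer(upscale_factor),
                 max_area_px = max_area_px,
                 min_area_px = min_area_px,
                 se_size = as.integer(se_size),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

#' Filter detected objects by area
#'
#' Keeps exactly the objects with `min_area_px <= area_px <= max_area_px`
#' ("512 pixels or less" style inclusive cap), preserving input order.
#'
#' @param objects Data frame from [label_components()].
#' @param max_area_px Inclusive upper area bound (`Inf` keeps everything).
#' @param min_area_px Inclusive lower bound (default 1).
#' @return The filtered data frame.
#' @export
filter_by_area <- function(objects, max_area_px, min_area_px = 1L) {
  objects[objects$area_px <= max_area_px & objects$area_px >= min_area_px, ,
          drop = FALSE]
}

#' Segment nuclei from a whole-slide DAPI image
#'
#' Runs the full isolation procedure (grayscale, bicubic enlargement, Otsu
#' binarization, morphological-gradient contouring, component labeling,
#' area filtering, bounding-box cropping) and returns one crop per
#' surviving nucleus. Crops are taken from the upscaled grayscale image,
#' the frame in which coordinates and areas are measured. Component areas
#' are pixel counts of the filled Otsu components; the gradient contour
#' mask is used for visualization and can be retained with
#' `keep_contour = TRUE`.
#'
#' A constant slide admits no Otsu threshold; it yields an empty result
#' with a warning rather than an error.
#'
#' @param slide Single- or 3-channel `raster_image` (or matrix).
#' @param config A [segmentation_config()].
#' @param slide_id,patient_id Identifiers carried into each crop.
#' @param keep_contour If `TRUE`, attach the gradient contour mask as
#'   attribute `"contour"`.
#' @return A list of `nucleus_crop` objects (fields `image`, `bbox`,
#'   `area_px`, `object_id`, `source_slide_id`, `patient_id`), with the
#'   detected-object table attached as attribute `"objects"`.
#' @export
segment_nuclei <- function(slide, config = segmentation_config(),
                           slide_id = "slide", patient_id = NA_character_,
                           keep_contour = FALSE) {
  gray <- to_grayscale(as_raster_image(slide))
  if (length(unique(as.vector(img_pixels(gray)))) < 2L) {
    warning("constant slide: no Otsu threshold exists; returning no nuclei",
            call. = FALSE)
    out <- list()
    attr(out, "objects") <- filter_by_area(label_components(matrix(0L, 1, 1)), Inf)
    return(out)
  }
  up <- bicubic_upscale(gray, config$upscale_factor)
  thr <- otsu_threshold(up)
  mask <- binarize(up, thr)
  objects <- label_components(mask, config$connectivity)
  kept <- filter_by_area(objects, config$max_area_px, config$min_area_px)
  crops <- lapply(seq_len(nrow(kept)), function(i) {
    b <- kept[i, ]
    rows <- (b$row_min + 1L):(b$row_min + b$height)
    cols <- (b$col_min + 1L):(b$col_min + b$width)
    structure(list(
      image = raster_image(img_pixels(up)[rows, cols, drop = FALSE],
                           bitdepth = img_bitdepth(up), channel_role = "nuclei"),
      bbox = c(row_min = b$row_min, col_min = b$col_min,
               height = b$height, width = b$width),
      area_px = b$area_px,
      object_id = b$object_id,
      source_slide_id = slide_id,
      patient_id = patient_id
    ), class = "nucleus_crop")
  })
  attr(crops, "objects") <- kept
  attr(crops, "threshold") <- thr
  if (keep_contour) {
    attr(crops, "contour") <- morphological_gradient(
      mask, structuring_element(config$se_size))
  }
  crops
}

#' Write nucleus crops to disk with a manifest
#'
#' @param crops Result of [segment_nuclei()].
#' @param dir Output directory (created if needed).
#' @param manifest_path Optional CSV path for the crop manifest.
#' @return Data frame manifest (crop path, slide id, patient id, bbox,
#'   area), invisibly.
#' @export
write_crops <- function(crops, dir, manifest_path = file.path(dir, "crops.csv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(crops), function(i) {
    cr <- crops[[i]]
    path <- file.path(dir, sprintf("%s_nucleus_%04d.png", cr$source_slide_id, i))
    write_slide_image(cr$image, path)
    data.frame(item_path = path, slide_id = cr$source_slide_id,
               patient_id = cr$patient_id, area_px = cr$area_px,
               row_min = cr$bbox[["row_min"]], col_min = cr$bbox[["col_min"]],
               height = cr$bbox[["height"]], width = cr$bbox[["width"]])
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) manifest <- data.frame()
  if (!is.null(manifest_path)) write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}
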