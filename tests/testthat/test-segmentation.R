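# fixture: dark slide with bright disks at given centers/radii
disk_slide <- function(h, w, centers, radii, bg = 10, fg = 200) {
  m <- matrix(bg, h, w)
  for (k in seq_len(nrow(centers))) {
    rr <- pmax(1, floor(centers[k, 1] - radii[k])):pmin(h, ceiling(centers[k, 1] + radii[k]))
    cc <- pmax(1, floor(centers[k, 2] - radii[k])):pmin(w, ceiling(centers[k, 2] + radii[k]))
    for (r in rr) for (c in cc) {
      if ((r - centers[k, 1])^2 + (c - centers[k, 2])^2 <= radii[k]^2) m[r, c] <- fg
    }
  }
  raster_image(m, channel_role = "nuclei")
}

test_that("area filter keeps the inclusive 'or less' boundary", {
  obj <- data.frame(object_id = 1:4, area_px = c(100L, 512L, 513L, 1000L),
                    row_min = 0L, col_min = 0L, height = 40L, width = 40L)
  kept <- filter_by_area(obj, 512)
  expect_equal(kept$area_px, c(100L, 512L))
  expect_equal(nrow(filter_by_area(obj[0, ], 512)), 0L)
  expect_equal(filter_by_area(obj, Inf), obj)
})

test_that("a single bright disk yields one crop equal to the upscaled sub-image", {
  slide <- disk_slide(40, 50, cbind(20, 25), 3)
  crops <- segment_nuclei(slide, segmentation_config(), "s", "P1")
  expect_length(crops, 1L)
  cr <- crops[[1]]
  up <- bicubic_upscale(to_grayscale(slide), 4)
  b <- cr$bbox
  sub <- unclass(up)[(b[["row_min"]] + 1):(b[["row_min"]] + b[["height"]]),
                     (b[["col_min"]] + 1):(b[["col_min"]] + b[["width"]])]
  expect_equal(unclass(cr$image)[, ], sub, ignore_attr = TRUE)
  expect_true(cr$area_px <= b[["height"]] * b[["width"]])
})

test_that("oversized objects are excluded and each crop holds one centroid", {
  centers <- rbind(c(10, 10), c(10, 35), c(30, 12), c(32, 38), c(20, 24))
  radii <- c(2.5, 2.5, 2.5, 2.5, 8)   # last disk exceeds the cap after 4x upscale
  slide <- disk_slide(44, 48, centers, radii)
  crops <- segment_nuclei(slide, segmentation_config(), "s", "P1")
  expect_length(crops, 4L)
  hits <- vapply(crops, function(cr) {
    b <- cr$bbox
    sum(centers[, 1] * 4 >= b[["row_min"]] & centers[, 1] * 4 < b[["row_min"]] + b[["height"]] &
        centers[, 2] * 4 >= b[["col_min"]] & centers[, 2] * 4 < b[["col_min"]] + b[["width"]])
  }, 0)
  expect_true(all(hits == 1))
})

test_that("constant slide warns and returns no nuclei", {
  expect_warning(crops <- segment_nuclei(matrix(0, 30, 30)), "constant")
  expect_length(crops, 0L)
})

test_that("raising the area cap never loses crops; bboxes stay in bounds", {
  set.seed(21)
  p <- phenotype_params(n_nuclei = 25, nucleus_radius_mean = 2.5,
                        nucleus_radius_sd = 0.4, slide_height = 200,
                        slide_width = 260)
  slide <- generate_slide(p, seed = 3)$nuclei
  caps <- c(128, 256, 512, 1024, Inf)
  counts <- vapply(caps, function(cap) {
    length(segment_nuclei(slide, segmentation_config(max_area_px = cap)))
  }, 0)
  expect_true(all(diff(counts) >= 0))
  crops <- segment_nuclei(slide, segmentation_config(max_area_px = Inf))
  H <- nrow(slide) * 4L; W <- ncol(slide) * 4L
  for (cr in crops) {
    b <- cr$bbox
    expect_true(b[["row_min"]] >= 0 && b[["row_min"]] + b[["height"]] <= H)
    expect_true(b[["col_min"]] >= 0 && b[["col_min"]] + b[["width"]] <= W)
  }
})

test_that("segmentation is deterministic for identical slide and config", {
  set.seed(4)
  p <- phenotype_params(n_nuclei = 15, nucleus_radius_mean = 2.5,
                        slide_height = 150, slide_width = 150)
  slide <- generate_slide(p, seed = 8)$nuclei
  c1 <- segment_nuclei(slide, segmentation_config(), "s", "P1")
  c2 <- segment_nuclei(slide, segmentation_config(), "s", "P1")
  expect_identical(lapply(c1, `[[`, "image"), lapply(c2, `[[`, "image"))
  expect_identical(attr(c1, "objects"), attr(c2, "objects"))
})

test_that("crops written to disk round-trip through the manifest", {
  slide <- disk_slide(40, 40, rbind(c(12, 12), c(28, 28)), c(2.5, 2.5))
  crops <- segment_nuclei(slide, segmentation_config(), "sl1", "P9")
  dir <- tempfile()
  man <- write_crops(crops, dir)
  expect_equal(nrow(man), length(crops))
  expect_true(all(file.exists(man$item_path)))
  back <- read_slide_image(man$item_path[1])
  expect_equal(unclass(back)[, ], unclass(crops[[1]]$image)[, ],
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
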