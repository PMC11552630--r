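test_that("grayscale conversion is identity on 1 channel and BT.601 on 3", {
  m <- matrix(0:99, 10, 10)
  expect_equal(unclass(to_grayscale(raster_image(m)))[, ], m, ignore_attr = TRUE)

  const <- array(77, dim = c(4, 5, 3))
  g <- to_grayscale(raster_image(const))
  expect_true(all(g == 77))

  red <- array(0, dim = c(3, 3, 3)); red[, , 1] <- 255
  g <- to_grayscale(raster_image(red))
  expect_true(all(g == round(0.299 * 255)))

  bad <- array(0, dim = c(3, 3, 3))
  expect_error(raster_image(bad[, , 1:2]), "3 channels")
})

test_that("bicubic resize matches direct Keys-kernel evaluation", {
  # identity and constants
  m <- matrix(sample(0:255, 30), 5, 6)
  expect_equal(unclass(bicubic_upscale(raster_image(m), 1))[, ], m,
               ignore_attr = TRUE)
  cu <- bicubic_upscale(raster_image(matrix(80, 3, 3)), 4)
  expect_true(all(cu == 80))
  expect_equal(dim(cu), c(12L, 12L))

  # independent scalar evaluation of the separable kernel (corner-aligned,
  # replicated borders), on a 2x2 ramp and on random images
  keys <- function(x, a = -0.5) {
    x <- abs(x)
    if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
    else if (x < 2) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
    else 0
  }
  direct_resize <- function(m, oh, ow) {
    interp1 <- function(vals, n_out) {
      n_in <- length(vals)
      sapply(seq_len(n_out) - 1, function(i) {
        s <- if (n_out == 1) (n_in - 1) / 2 else i * (n_in - 1) / (n_out - 1)
        j <- floor(s) + (-1:2)
        w <- vapply(s - j, keys, 0)
        jc <- pmin(pmax(j, 0), n_in - 1) + 1
        sum(w * vals[jc]) / sum(w)
      })
    }
    rowint <- apply(m, 2, interp1, n_out = oh)         # oh x ncol
    t(apply(rowint, 1, interp1, n_out = ow))           # oh x ow
  }
  ramp <- matrix(c(0, 50, 100, 150), 2, 2)
  got <- unclass(bicubic_upscale(raster_image(ramp), 2))[, ]
  want <- pmin(pmax(round(direct_resize(ramp, 4, 4)), 0), 255)
  expect_equal(got, want, ignore_attr = TRUE)
  # corners preserved exactly
  expect_equal(got[c(1, 4), c(1, 4)], ramp, ignore_attr = TRUE)

  set.seed(42)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 35, replace = TRUE), 5, 7)
    f <- sample(2:3, 1)
    got <- unclass(bicubic_upscale(raster_image(m), f))[, ]
    want <- pmin(pmax(round(direct_resize(m, 5 * f, 7 * f)), 0), 255)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  expect_error(bicubic_upscale(raster_image(ramp), 0), "factor")
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  expect_equal(otsu_threshold(img), brute_otsu(img))

  bi <- matrix(c(rep(0, 30), rep(255, 34)), 8, 8)
  t <- otsu_threshold(bi)
  m <- binarize(bi, t)
  expect_equal(sum(m), 34)
  expect_true(all(m[bi == 0] == 0))

  expect_error(otsu_threshold(matrix(7, 4, 4)), "constant")

  set.seed(101)
  for (i in 1:40) {
    img <- random_test_image()
    expect_equal(otsu_threshold(img), brute_otsu(img))
  }
})

test_that("binarize uses the strict greater-than convention", {
  expect_true(all(binarize(matrix(0, 3, 3), 0) == 0))
  img <- matrix(c(5, 5, 9, 9), 2, 2)
  expect_true(all(binarize(img, 4) == 1))
  expect_equal(unclass(binarize(img, 5))[, ], matrix(c(0L, 0L, 1L, 1L), 2, 2),
               ignore_attr = TRUE)
  expect_error(binarize(raster_image(img), 300), "range")
})

test_that("morphological gradient equals brute-force dilation minus erosion", {
  se <- structuring_element(3)
  z <- matrix(0L, 6, 6)
  expect_true(all(morphological_gradient(z, se) == 0))
  o <- matrix(1L, 6, 6)
  expect_true(all(morphological_gradient(o, se) == 0))  # reflect border

  sq <- matrix(0L, 7, 7); sq[3:5, 3:5] <- 1L
  g <- morphological_gradient(sq, se)
  expect_equal(unclass(g)[, ], brute_dilate(sq, se) - brute_erode(sq, se),
               ignore_attr = TRUE)

  set.seed(7)
  for (i in 1:40) {
    m <- matrix(rbinom(80, 1, runif(1, 0.2, 0.8)), 8, 10)
    se_i <- structuring_element(sample(c(3, 5), 1),
                                sample(c("box", "cross"), 1))
    d <- dilate_mask(m, se_i); e <- erode_mask(m, se_i)
    expect_equal(unclass(d)[, ], brute_dilate(m, se_i), ignore_attr = TRUE)
    expect_equal(unclass(e)[, ], brute_erode(m, se_i), ignore_attr = TRUE)
    g <- morphological_gradient(m, se_i)
    # gradient is a subset of the dilation and disjoint from the erosion
    expect_true(all(g <= d))
    expect_true(all(g[e == 1] == 0))
  }
})

test_that("component labeling matches an independent flood-fill labeler", {
  empty <- label_components(matrix(0L, 5, 5))
  expect_equal(nrow(empty), 0L)

  two <- matrix(0L, 8, 8); two[1:2, 1:2] <- 1L; two[5:6, 6:7] <- 1L
  obj <- label_components(two)
  expect_equal(obj$area_px, c(4L, 4L))
  expect_equal(obj$height, c(2L, 2L))
  expect_equal(obj$width, c(2L, 2L))

  set.seed(13)
  for (i in 1:40) {
    m <- matrix(rbinom(256, 1, runif(1, 0.2, 0.7)), 16, 16)
    for (conn in c(4L, 8L)) {
      got <- label_components(m, conn)
      want <- flood_fill_objects(m, conn)
      expect_equal(object_multiset(got), object_multiset(want))
      # component areas partition the foreground
      expect_equal(sum(got$area_px), sum(m))
    }
  }
})

test_that("quarter-turn rotations are lossless permutations", {
  set.seed(5)
  m <- matrix(sample(0:255, 12 * 12, replace = TRUE), 12, 12)
  r4 <- rotate_quarter(rotate_quarter(rotate_quarter(rotate_quarter(m, 1), 1), 1), 1)
  expect_identical(r4, m)
  expect_identical(rotate_quarter(m, 4), m)
  # non-square dimensions swap for odd turns
  ns <- matrix(1:6, 2, 3)
  expect_equal(dim(rotate_quarter(ns, 1)), c(3L, 2L))
  expect_identical(rotate_quarter(rotate_quarter(ns, 1), 3), ns)
  expect_identical(sort(as.vector(rotate_quarter(ns, 1))), sort(as.vector(ns)))
})

test_that("image io round-trips 8-bit rasters through PNG and TIFF", {
  set.seed(9)
  img <- raster_image(matrix(sample(0:255, 48, replace = TRUE), 6, 8),
                      channel_role = "nuclei")
  for (ext in c("png", "tif")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_slide_image(img, p)
    back <- read_slide_image(p, channel_role = "nuclei")
    expect_equal(unclass(back)[, ], unclass(img)[, ], ignore_attr = TRUE)
    unlink(p)
  }
})
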