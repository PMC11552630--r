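#' Phenotype parameters for synthetic slide generation
#'
#' Describes the statistical structure of one class's slides: bright
#' elliptical nuclei (DAPI channel) on a noisy dark background, and a
#' damage channel with per-nucleus Poisson-distributed punctate foci.
#' Disease classes are separated through these parameters — diagnosis-track
#' classes differ in nuclear size/eccentricity (altered nuclear
#' morphology), prognosis-track classes in the foci rate (DNA-damage
#' activation).
#'
#' The nominal nucleus radius `r` controls area (`pi r^2` regardless of
#' eccentricity): semi-axes are `a = r / (1 - e^2)^(1/4)` and
#' `b = r * (1 - e^2)^(1/4)`. Nuclei are rendered small (a few pixels) so
#' the 16-fold bicubic enlargement step of segmentation is exercised
#' meaningfully.
#'
#' @param n_nuclei Number of nuclei per slide.
#' @param nucleus_radius_mean,nucleus_radius_sd Nominal radius distribution
#'   (pixels, truncated normal).
#' @param eccentricity_mean,eccentricity_sd Eccentricity distribution
#'   (truncated to `[0, 0.95]`).
#' @param foci_rate Mean damage foci per nucleus (Poisson).
#' @param focus_radius Focus disk radius (pixels).
#' @param nucleus_intensity,background_level,background_noise_sd DAPI
#'   channel intensities (8-bit scale by default).
#' @param foci_intensity,damage_background_level,damage_noise_sd Damage
#'   channel intensities.
#' @param slide_height,slide_width Slide dimensions; the defaults
#'   8064 x 10240 tile into exactly 5040 patches of 128 x 128.
#' @param bitdepth 8 or 16.
#' @param non_overlapping If `TRUE` (default), nuclei are placed on a
#'   jittered occupancy grid that guarantees no overlap.
#' @return A `phenotype_params` list.
#' @export
phenotype_params <- function(n_nuclei = 20000L,
                             nucleus_radius_mean = 2.6, nucleus_radius_sd = 0.3,
                             eccentricity_mean = 0.4, eccentricity_sd = 0.1,
                             foci_rate = 1, focus_radius = 1.2,
                             nucleus_intensity = 200, background_level = 12,
                             background_noise_sd = 8,
                             foci_intensity = 200, damage_background_level = 8,
                             damage_noise_sd = 5,
                             slide_height = 8064L, slide_width = 10240L,
                             bitdepth = 8L, non_overlapping = TRUE) {
  stopifnot(n_nuclei >= 0, nucleus_radius_mean > 0, foci_rate >= 0,
            focus_radius > 0, slide_height >= 1, slide_width >= 1)
  structure(as.list(environment()), class = "phenotype_params")
}

#' Class-parameter pairs for the two cohorts
#'
#' `hf_phenotypes()` returns control/heart-failure parameters differing in
#' nuclear morphology; `lvrr_phenotypes()` returns LVRR-positive/negative
#' parameters differing in DNA-damage foci rate (non-responders carry more
#' damage). Slide sizes default small for the diagnosis track (segmentation
#' runs on the 4x-upscaled frame) and full-size for the prognosis track.
#' Nucleus density for the prognosis track defaults to 4 per 128 x 128
#' patch so that every patch carries class signal.
#'
#' @param slide_height,slide_width Slide dimensions.
#' @param n_nuclei Nuclei per slide (default for `lvrr_phenotypes` scales
#'   with the patch count).
#' @param foci_rate_pos,foci_rate_neg Foci rates of the responder /
#'   non-responder classes.
#' @param ... Passed through to [phenotype_params()].
#' @return Named list of two `phenotype_params` (positive class first:
#'   `hf` / `lvrr_pos`).
#' @export
hf_phenotypes <- function(slide_height = 512L, slide_width = 640L,
                          n_nuclei = 120L, ...) {
  list(
    hf = phenotype_params(n_nuclei = n_nuclei, nucleus_radius_mean = 2.9,
                          eccentricity_mean = 0.7, eccentricity_sd = 0.08,
                          slide_height = slide_height, slide_width = slide_width,
                          ...),
    ctrl = phenotype_params(n_nuclei = n_nuclei, nucleus_radius_mean = 2.4,
                            eccentricity_mean = 0.3, eccentricity_sd = 0.08,
                            slide_height = slide_height, slide_width = slide_width,
                            ...)
  )
}

#' @rdname hf_phenotypes
#' @export
lvrr_phenotypes <- function(slide_height = 8064L, slide_width = 10240L,
                            foci_rate_pos = 0.5, foci_rate_neg = 5,
                            n_nuclei = NULL, ...) {
  if (is.null(n_nuclei)) {
    n_nuclei <- 4L * patch_count(slide_height, slide_width, 128L)
  }
  list(
    lvrr_pos = phenotype_params(n_nuclei = n_nuclei, foci_rate = foci_rate_pos,
                                slide_height = slide_height,
                                slide_width = slide_width, ...),
    lvrr_neg = phenotype_params(n_nuclei = n_nuclei, foci_rate = foci_rate_neg,
                                slide_height = slide_height,
                                slide_width = slide_width, ...)
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

## exact distribution of round(N(base, sd)) clipped to [0, maxval]
noise_levels <- function(base, maxval) 0:maxval

noise_probs <- function(base, sd, maxval) {
  vals <- noise_levels(base, maxval)
  p <- pnorm(vals + 0.5, base, sd) - pnorm(vals - 0.5, base, sd)
  p[1] <- pnorm(0.5, base, sd)                     # mass clipped at 0
  p[length(p)] <- 1 - pnorm(maxval - 0.5, base, sd)  # mass clipped at maxval
  p / sum(p)
}

#' Generate one synthetic dual-channel slide
#'
#' Renders the DAPI nuclei channel (filled ellipses plus Gaussian
#' background noise) and the paired damage channel (per-nucleus Poisson
#' foci as small bright disks inside the nucleus), with per-nucleus ground
#' truth. Fully reproducible from `(params, seed)`.
#'
#' @param params A [phenotype_params()].
#' @param seed Integer seed.
#' @return List with `nuclei` and `damage` (`raster_image`s of identical
#'   dimensions) and `truth`, a data frame of per-nucleus records
#'   (`nucleus_id`, centroid `cy`/`cx`, semi-axes `a`/`b`, `theta`,
#'   rasterized `area_px`, `n_foci`) carrying the seed as an attribute.
#' @export
generate_slide <- function(params, seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  h <- params$slide_height; w <- params$slide_width
  maxval <- bit_maxval(params$bitdepth)
  nuc <- .noise_matrix(h, w,
                       noise_levels(params$background_level, maxval),
                       noise_probs(params$background_level,
                                   params$background_noise_sd, maxval))
  dmg <- .noise_matrix(h, w,
                       noise_levels(params$damage_background_level, maxval),
                       noise_probs(params$damage_background_level,
                                   params$damage_noise_sd, maxval))
  n <- params$n_nuclei
  if (n == 0L) {
    truth <- data.frame(nucleus_id = integer(), cy = numeric(), cx = numeric(),
                        a = numeric(), b = numeric(), theta = numeric(),
                        area_px = integer(), n_foci = integer())
    attr(truth, "seed") <- seed
    return(list(nuclei = raster_image(nuc, params$bitdepth, "nuclei"),
                damage = raster_image(dmg, params$bitdepth, "damage"),
                truth = truth))
  }
  rmax <- params$nucleus_radius_mean + 4 * params$nucleus_radius_sd
  emax <- min(params$eccentricity_mean + 4 * params$eccentricity_sd, 0.95)
  amax <- rmax / (1 - emax^2)^(1 / 4)
  margin <- ceiling(amax) + 1L
  if (params$non_overlapping) {
    cell <- 2L * margin + 4L
    gh <- h %/% cell; gw <- w %/% cell
    if (n > gh * gw) {
      stop("infeasible non-overlap packing: ", n, " nuclei will not fit ",
           gh * gw, " grid cells", call. = FALSE)
    }
    cells <- sample.int(gh * gw, n)
    ci <- (cells - 1L) %% gh       # 0-based grid row
    cj <- (cells - 1L) %/% gh
    jitter_max <- cell - 2L * margin
    cy <- ci * cell + margin + runif(n) * jitter_max
    cx <- cj * cell + margin + runif(n) * jitter_max
  } else {
    cy <- runif(n, margin, h - margin)
    cx <- runif(n, margin, w - margin)
  }
  r <- rtrunc_norm(n, params$nucleus_radius_mean, params$nucleus_radius_sd, 0.8, rmax)
  e <- rtrunc_norm(n, params$eccentricity_mean, params$eccentricity_sd, 0, emax)
  theta <- runif(n, 0, pi)
  a <- r / (1 - e^2)^(1 / 4)
  b <- r * (1 - e^2)^(1 / 4)
  inten <- rtrunc_norm(n, params$nucleus_intensity, 10, 0, maxval)
  n_foci <- rpois(n, params$foci_rate)
  area_px <- .render_ellipses(nuc, cy - 1, cx - 1, a, b, theta,
                              as.integer(round(inten)))
  nf <- sum(n_foci)
  if (nf > 0L) {
    ## uniform points inside each parent ellipse (polar sampling, no
    ## rejection), mapped to slide coordinates through the ellipse frame
    k <- rep.int(seq_len(n), n_foci)
    rad <- sqrt(runif(nf))
    phi <- runif(nf, 0, 2 * pi)
    pu <- rad * cos(phi)
    pv <- rad * sin(phi)
    ct <- cos(theta[k]); st <- sin(theta[k])
    fy <- cy[k] + pu * a[k] * ct - pv * b[k] * st
    fx <- cx[k] + pu * a[k] * st + pv * b[k] * ct
    .render_disks(dmg, fy - 1, fx - 1, params$focus_radius,
                  as.integer(round(params$foci_intensity)))
  }
  truth <- data.frame(nucleus_id = seq_len(n), cy = cy, cx = cx, a = a, b = b,
                      theta = theta, area_px = area_px, n_foci = n_foci)
  attr(truth, "seed") <- seed
  list(nuclei = raster_image(nuc, params$bitdepth, "nuclei"),
       damage = raster_image(dmg, params$bitdepth, "damage"),
       truth = truth)
}

#' Generate a synthetic patient cohort
#'
#' One dual-channel slide per synthetic patient, labels assigned by class
#' (the first element of `class_params` is the positive class), per-patient
#' seeds derived deterministically from the master seed. Slides can be
#' kept in an in-memory [image_store()], written to TIFF files, or handed
#' one at a time to `per_patient_fn` (memory-bounded streaming over
#' full-size slides; only the function's return values are kept).
#'
#' @param n_per_class Patients per class (scalar or length-2 vector
#'   `(positive, negative)`).
#' @param class_params Named list of two [phenotype_params()] (positive
#'   first), e.g. from [lvrr_phenotypes()].
#' @param seed Master seed.
#' @param cohort `"LVRR_cohort"` or `"HF_cohort"`.
#' @param keep `"store"` (default), `"files"` (requires `dir`), or
#'   `"none"`.
#' @param dir Output directory for `keep = "files"`.
#' @param per_patient_fn Optional `function(patient_id, label, slide)`
#'   called with each generated slide.
#' @return List with `records` (list of [patient_record()]s), `truth`
#'   (combined ground-truth table with `patient_id`), `store` (when
#'   `keep = "store"`), and `results` (per-patient values of
#'   `per_patient_fn`).
#' @export
generate_cohort <- function(n_per_class, class_params, seed = 1L,
                            cohort = c("LVRR_cohort", "HF_cohort"),
                            keep = c("store", "files", "none"),
                            dir = NULL, per_patient_fn = NULL) {
  cohort <- match.arg(cohort)
  keep <- match.arg(keep)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  if (keep == "files") {
    if (is.null(dir)) stop("dir is required for keep = \"files\"", call. = FALSE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  n_total <- sum(n_per_class)
  seeds <- sample.int(.Machine$integer.max, n_total)
  labels <- rep(c(1L, 0L), times = n_per_class)
  classes <- rep(names(class_params), times = n_per_class)
  ids <- sprintf("P%03d", seq_len(n_total))
  store <- if (keep == "store") image_store() else NULL
  records <- vector("list", n_total)
  truths <- vector("list", n_total)
  results <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sl <- generate_slide(class_params[[classes[i]]], seed = seeds[i])
    paths <- c(paste0(ids[i], "/nuclei"), paste0(ids[i], "/damage"))
    if (keep == "store") {
      store_put(store, paths[1], sl$nuclei)
      store_put(store, paths[2], sl$damage)
    } else if (keep == "files") {
      paths <- file.path(dir, c(paste0(ids[i], "_nuclei.tif"),
                                paste0(ids[i], "_damage.tif")))
      write_slide_image(sl$nuclei, paths[1])
      write_slide_image(sl$damage, paths[2])
    }
    if (!is.null(per_patient_fn)) {
      results[[i]] <- per_patient_fn(ids[i], labels[i], sl)
    }
    tr <- sl$truth
    if (nrow(tr) > 0L) tr$patient_id <- ids[i]
    truths[[i]] <- tr
    records[[i]] <- patient_record(ids[i], cohort, labels[i], paths,
                                   label_provenance = classes[i])
    rm(sl)
  }
  truth <- do.call(rbind, truths)
  names(results) <- ids
  out <- list(records = records, truth = truth, results = results,
              seed = seed, patient_seeds = seeds)
  if (keep == "store") out$store <- store
  out
}
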