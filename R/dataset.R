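#' Patient record
#'
#' Metadata row for one patient: cohort membership, binary outcome label
#' (HF vs control, or LVRR-positive vs LVRR-negative), the image items
#' belonging to the patient, and free-text label provenance (e.g. the
#' clinical rule under which the outcome was adjudicated — stored verbatim,
#' never computed here).
#'
#' @param patient_id Identifier.
#' @param cohort `"HF_cohort"` or `"LVRR_cohort"`.
#' @param label 0 or 1.
#' @param item_paths Character vector of at least one image path (or
#'   in-memory store key).
#' @param label_provenance Free text.
#' @return A `patient_record` list.
#' @export
patient_record <- function(patient_id, cohort = c("LVRR_cohort", "HF_cohort"),
                           label, item_paths, label_provenance = "") {
  cohort <- match.arg(cohort)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  if (length(item_paths) < 1L) stop("patient must have at least one item", call. = FALSE)
  structure(list(patient_id = as.character(patient_id), cohort = cohort,
                 label = as.integer(label), item_paths = as.character(item_paths),
                 label_provenance = label_provenance),
            class = "patient_record")
}

#' Split specification
#'
#' Per-class patient counts for the train and test sets, plus the sampling
#' seed. The canonical prognosis-cohort shape is 16 + 16 training and 7 + 7
#' test patients drawn from 23 + 23.
#'
#' @param train_pos,train_neg,test_pos,test_neg Non-negative patient counts.
#' @param seed Integer RNG seed for the stratified assignment.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_pos, train_neg, test_pos = 0L, test_neg = 0L,
                       seed = 1L) {
  counts <- c(train_pos, train_neg, test_pos, test_neg)
  if (any(counts < 0)) stop("patient counts must be non-negative", call. = FALSE)
  structure(list(train_pos = as.integer(train_pos), train_neg = as.integer(train_neg),
                 test_pos = as.integer(test_pos), test_neg = as.integer(test_neg),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Patient-exclusive train/test split
#'
#' Assigns whole patients to splits by seeded sampling stratified on the
#' class label; every item of a patient inherits that patient's split, so no
#' patient's images can appear on both sides (the leakage guard all
#' training and evaluation rely on). Exclusivity is asserted on the result.
#'
#' @param records List of [patient_record()]s.
#' @param spec A [split_spec()].
#' @return Manifest data frame with columns `item_path`, `patient_id`,
#'   `label`, `split`, `augmentation_tag` (`"rot000"`), carrying the seed as
#'   attribute `"seed"`.
#' @export
patient_split <- function(records, spec) {
  ids <- vapply(records, `[[`, "", "patient_id")
  labels <- vapply(records, `[[`, 0L, "label")
  if (anyDuplicated(ids)) stop("duplicate patient ids", call. = FALSE)
  pos <- ids[labels == 1L]; neg <- ids[labels == 0L]
  if (length(pos) < spec$train_pos + spec$test_pos ||
      length(neg) < spec$train_neg + spec$test_neg) {
    stop("insufficient patients per class for the requested split", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  pick <- function(pool, n) if (n == 0L) character() else sample(pool, n)
  train_p <- pick(pos, spec$train_pos)
  test_p <- pick(setdiff(pos, train_p), spec$test_pos)
  train_n <- pick(neg, spec$train_neg)
  test_n <- pick(setdiff(neg, train_n), spec$test_neg)
  assign_split <- function(id) {
    if (id %in% c(train_p, train_n)) "train"
    else if (id %in% c(test_p, test_n)) "test"
    else NA_character_
  }
  rows <- lapply(records, function(rec) {
    spl <- assign_split(rec$patient_id)
    if (is.na(spl)) return(NULL)
    data.frame(item_path = rec$item_paths, patient_id = rec$patient_id,
               label = rec$label, split = spl, augmentation_tag = "rot000",
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) {
    manifest <- data.frame(item_path = character(), patient_id = character(),
                           label = integer(), split = character(),
                           augmentation_tag = character())
  }
  rownames(manifest) <- NULL
  assert_patient_exclusive(manifest)
  attr(manifest, "seed") <- spec$seed
  manifest
}

## save/restore the global RNG state so seeded helpers are side-effect free
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Assert that a manifest is patient-exclusive
#'
#' @param manifest Manifest data frame.
#' @return `TRUE` invisibly; errors if any patient appears in both splits.
#' @export
assert_patient_exclusive <- function(manifest) {
  both <- intersect(manifest$patient_id[manifest$split == "train"],
                    manifest$patient_id[manifest$split == "test"])
  if (length(both) > 0L) {
    stop("patient-exclusivity violated: ", paste(both, collapse = ", "),
         " present in both splits", call. = FALSE)
  }
  invisible(TRUE)
}

#' Join items with patient labels into a manifest
#'
#' @param items Data frame with columns `item_path` and `patient_id`
#'   (optionally `split`).
#' @param records List of [patient_record()]s supplying labels.
#' @return Manifest data frame (`split` defaults to `NA` if absent).
#' @export
build_manifest <- function(items, records) {
  ids <- vapply(records, `[[`, "", "patient_id")
  labels <- vapply(records, `[[`, 0L, "label")
  orphan <- setdiff(unique(items$patient_id), ids)
  if (length(orphan) > 0L) {
    stop("items reference unknown patient ids: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(items$item_path)) {
    stop("duplicate item paths in manifest", call. = FALSE)
  }
  data.frame(item_path = items$item_path, patient_id = items$patient_id,
             label = labels[match(items$patient_id, ids)],
             split = if ("split" %in% names(items)) items$split else NA_character_,
             augmentation_tag = "rot000", stringsAsFactors = FALSE)
}

#' Four-rotation augmentation of the training split
#'
#' Replaces every training item with four items tagged `rot000`, `rot090`,
#' `rot180`, `rot270` (quarter turns applied losslessly at image-load time),
#' exactly quadrupling the training set; the test split is never augmented.
#'
#' @param manifest Manifest data frame.
#' @param split Must be `"train"`; requesting any other split is a policy
#'   error (augmenting evaluation data would inflate performance).
#' @return The augmented manifest.
#' @export
rotate_augment <- function(manifest, split = "train") {
  if (!identical(split, "train")) {
    stop("augmentation is restricted to the training split", call. = FALSE)
  }
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  rest <- manifest[manifest$split != "train" | is.na(manifest$split), , drop = FALSE]
  if (nrow(tr) == 0L) return(manifest)
  tags <- c("rot000", "rot090", "rot180", "rot270")
  aug <- tr[rep(seq_len(nrow(tr)), each = 4L), , drop = FALSE]
  aug$augmentation_tag <- rep(tags, times = nrow(tr))
  out <- rbind(aug, rest)
  rownames(out) <- NULL
  if (anyDuplicated(out[, c("item_path", "augmentation_tag")])) {
    stop("duplicate (item_path, augmentation_tag) rows after augmentation",
         call. = FALSE)
  }
  attr(out, "seed") <- attr(manifest, "seed")
  out
}

#' Manifest I/O
#'
#' Manifests are written as plain CSV with a JSON sidecar
#' (`<path>.meta.json`) recording the split seed and any extra provenance,
#' keeping both diff-able and language-neutral.
#'
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @param extra Named list merged into the sidecar.
#' @return `write_manifest()`: the path invisibly; `read_manifest()`: the
#'   manifest with sidecar fields restored as attributes.
#' @export
write_manifest <- function(manifest, path, extra = list()) {
  write.csv(manifest, path, row.names = FALSE)
  meta <- c(list(seed = attr(manifest, "seed")), extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$seed)) attr(manifest, "seed") <- as.integer(meta$seed)
  }
  manifest
}

#' In-memory image store
#'
#' Training and evaluation resolve manifest item paths either against the
#' filesystem or against this store (an environment mapping path keys to
#' images), which desk-scale runs and tests use to avoid disk round-trips.
#'
#' @return An empty `image_store` environment.
#' @export
image_store <- function() structure(new.env(parent = emptyenv()), class = "image_store")

#' @rdname image_store
#' @param store An `image_store`.
#' @param path Item key.
#' @param image Image to store.
#' @export
store_put <- function(store, path, image) {
  assign(path, image, envir = store)
  invisible(store)
}

#' Load a manifest item, applying its rotation tag
#'
#' @param path Item path (file or store key).
#' @param store Optional [image_store()] checked before the filesystem.
#' @param rotation Augmentation tag `"rot000"` ... `"rot270"`.
#' @return The (possibly rotated) image.
#' @export
load_item <- function(path, store = NULL, rotation = "rot000") {
  img <- if (!is.null(store) && exists(path, envir = store, inherits = FALSE)) {
    get(path, envir = store, inherits = FALSE)
  } else if (file.exists(path)) {
    read_slide_image(path)
  } else {
    stop("cannot load item: file not found: ", path, call. = FALSE)
  }
  k <- match(rotation, c("rot000", "rot090", "rot180", "rot270")) - 1L
  if (is.na(k)) stop("unknown rotation tag: ", rotation, call. = FALSE)
  rotate_quarter(img, k)
}
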