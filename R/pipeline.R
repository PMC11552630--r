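#' Pipeline configuration
#'
#' Bundles the stage configurations of the two published workflows: the
#' diagnosis track (`"hf"`: segment nuclei -> split -> augment -> train ->
#' predict -> evaluate) and the prognosis track (`"lvrr"`: overlay ->
#' patch -> split -> augment -> train -> predict -> aggregate -> evaluate).
#'
#' @param track `"lvrr"` or `"hf"`.
#' @param class_params Named pair of [phenotype_params()] (positive class
#'   first) used when the pipeline simulates its cohort; ignored when a
#'   pre-built cohort is supplied to [run_pipeline()].
#' @param n_train_per_class,n_test_per_class Patients per class and split.
#' @param seed Master seed for cohort generation and splitting.
#' @param classifier A [classifier_config()].
#' @param seg_config A [segmentation_config()] (hf track).
#' @param patch_size Patch side length (lvrr track).
#' @param decision_threshold Patch decision threshold.
#' @param augment Whether to apply four-rotation augmentation to training
#'   data.
#' @param out_root Optional directory for manifests and the report JSON.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(track = c("lvrr", "hf"), class_params = NULL,
                            n_train_per_class = 4L, n_test_per_class = 2L,
                            seed = 1L, classifier = classifier_config(),
                            seg_config = segmentation_config(),
                            patch_size = 128L, decision_threshold = 0.5,
                            augment = TRUE, out_root = NULL) {
  track <- match.arg(track)
  if (is.null(class_params)) {
    class_params <- if (track == "lvrr") {
      lvrr_phenotypes(slide_height = 512L, slide_width = 640L)
    } else {
      hf_phenotypes()
    }
  }
  structure(list(track = track, class_params = class_params,
                 n_train_per_class = as.integer(n_train_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 seed = as.integer(seed), classifier = classifier,
                 seg_config = seg_config, patch_size = as.integer(patch_size),
                 decision_threshold = decision_threshold, augment = augment,
                 out_root = out_root),
            class = "pipeline_config")
}

## per-patient item extraction: lvrr = overlay + tile, hf = segment nuclei
extract_items <- function(config, patient_id, slide, store) {
  if (config$track == "lvrr") {
    comp <- overlay_channels(slide$nuclei, slide$damage)
    patches <- tile_patches(comp, config$patch_size, patient_id = patient_id)
    keys <- vapply(patches, function(p) {
      sprintf("%s/patch_r%03d_c%03d", patient_id,
              p$grid_pos[["tile_row"]], p$grid_pos[["tile_col"]])
    }, "")
    for (i in seq_along(patches)) store_put(store, keys[i], patches[[i]]$image)
  } else {
    crops <- segment_nuclei(slide$nuclei, config$seg_config,
                            slide_id = patient_id, patient_id = patient_id)
    keys <- vapply(seq_along(crops), function(i) {
      sprintf("%s/nucleus_%04d", patient_id, i)
    }, "")
    for (i in seq_along(crops)) store_put(store, keys[i], crops[[i]]$image)
  }
  keys
}

#' Run a full prediction pipeline
#'
#' Executes the configured track end to end on a synthetic cohort
#' (generated from `config$class_params` unless a prebuilt `cohort` from
#' [generate_cohort()] is supplied), producing patch/image-level and
#' patient-level evaluation. Identical config and seeds reproduce an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional result of [generate_cohort()] with an image
#'   store; must match the track's channel requirements.
#' @return The evaluation report list (with provenance block); also written
#'   as `report.json` under `config$out_root` when set.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(
      config$n_train_per_class + config$n_test_per_class,
      config$class_params, seed = config$seed,
      cohort = if (config$track == "lvrr") "LVRR_cohort" else "HF_cohort")
  }
  if (is.null(cohort$store)) {
    stop("cohort must carry an image store (generate_cohort(keep = \"store\"))",
         call. = FALSE)
  }
  item_store <- image_store()
  item_records <- lapply(cohort$records, function(rec) {
    slide <- list(
      nuclei = load_item(rec$item_paths[1], store = cohort$store),
      damage = if (length(rec$item_paths) > 1L)
        load_item(rec$item_paths[2], store = cohort$store) else NULL)
    keys <- extract_items(config, rec$patient_id, slide, item_store)
    if (length(keys) == 0L) return(NULL)
    patient_record(rec$patient_id, rec$cohort, rec$label, keys,
                   label_provenance = rec$label_provenance)
  })
  item_records <- Filter(Negate(is.null), item_records)
  if (length(item_records) == 0L) {
    stop("pipeline stage '", if (config$track == "hf") "segment" else "patch",
         "': no items extracted from any slide", call. = FALSE)
  }
  spec <- split_spec(config$n_train_per_class, config$n_train_per_class,
                     config$n_test_per_class, config$n_test_per_class,
                     seed = config$seed)
  manifest <- patient_split(item_records, spec)
  if (config$augment) manifest <- rotate_augment(manifest)
  train <- manifest[manifest$split == "train", , drop = FALSE]
  test <- manifest[manifest$split == "test", , drop = FALSE]
  state <- fit_classifier(config$classifier, train, store = item_store)
  scores <- predict_proba(state, test, store = item_store)
  report <- evaluation_report(scores, config$decision_threshold,
                              per_patient = TRUE)
  report$track <- config$track
  report$n_train_items <- nrow(train)
  report$n_test_items <- nrow(test)
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("cardiopatch")),
    seed = config$seed,
    classifier_seed = config$classifier$seed,
    config_hash = config_hash(config))
  if (!is.null(config$out_root)) {
    dir.create(config$out_root, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(config$out_root, "manifest.csv"))
    write.csv(scores, file.path(config$out_root, "scores.csv"), row.names = FALSE)
    rep_json <- report
    rep_json$patients <- NULL
    jsonlite::write_json(rep_json, file.path(config$out_root, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(report$patients, file.path(config$out_root, "patients.csv"),
              row.names = FALSE)
  }
  report
}

## stable md5 of the serialized configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_root <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
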