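#' Classifier configuration
#'
#' Uniform configuration for the pluggable patch-classification backends.
#' Two backends ship with the package: `"transformer_small"`, a compact
#' vision transformer trained from scratch on CPU (patch-token embedding,
#' pre-LayerNorm multi-head self-attention blocks, mean pooling, 2-logit
#' softmax head), and `"intensity_baseline"`, a logistic model on
#' per-channel mean/standard-deviation features that serves as a fast
#' sanity backend. Both honour the same fit/score contract, so the
#' aggregation and evaluation stages run unchanged over either — the
#' multi-model comparison is a configuration sweep.
#'
#' @param backend `"transformer_small"` or `"intensity_baseline"`.
#' @param input_size Square model-input side length after
#'   [preprocess_for_model()] (default 32; must be a multiple of `patch`).
#' @param patch Token patch size of the transformer (default 8).
#' @param d_model,n_layers,n_heads,mlp_hidden Transformer geometry
#'   (defaults 32 / 2 / 2 / 64, a desk-scale model trainable in seconds).
#' @param epochs,batch_size,learning_rate Training hyperparameters
#'   (Adam, cross-entropy loss).
#' @param pretrained Reserved switch for loading externally published
#'   weights; the shipped backends always train from scratch.
#' @param seed RNG seed governing initialization and batch order; fixed
#'   seed + fixed manifest gives bit-identical scores.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(backend = c("transformer_small", "intensity_baseline"),
                              input_size = 32L, patch = 8L, d_model = 32L,
                              n_layers = 2L, n_heads = 2L, mlp_hidden = 64L,
                              epochs = 12L, batch_size = 32L,
                              learning_rate = 1e-3, pretrained = FALSE,
                              seed = 1L) {
  backend <- match.arg(backend)
  if (input_size < 16L) stop("input_size must be >= 16", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (input_size %% patch != 0L) stop("input_size must be a multiple of patch", call. = FALSE)
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads", call. = FALSE)
  structure(list(backend = backend, input_size = as.integer(input_size),
                 patch = as.integer(patch), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 mlp_hidden = as.integer(mlp_hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, pretrained = pretrained,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

## resolve manifest rows to preprocessed arrays
load_model_inputs <- function(manifest, cfg, store = NULL) {
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_item(manifest$item_path[i], store = store,
                     rotation = manifest$augmentation_tag[i] %||% "rot000")
    preprocess_for_model(img, cfg$input_size)
  })
}

intensity_features <- function(arrs) {
  t(vapply(arrs, function(a) {
    c(mean(a[, , 1]), mean(a[, , 2]), mean(a[, , 3]),
      sd(a[, , 1]), sd(a[, , 2]), sd(a[, , 3]))
  }, numeric(6)))
}

manifest_digest <- function(manifest) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(manifest[order(manifest$item_path, manifest$augmentation_tag), ],
            tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Train a patch classifier
#'
#' Fits the configured backend on the training rows of a manifest (rows
#' with `split == "train"` when a split column is populated, all rows
#' otherwise), resolving items through the filesystem or an
#' [image_store()] and applying rotation-augmentation tags at load time.
#'
#' @param config A [classifier_config()].
#' @param train_manifest Manifest data frame with at least two classes.
#' @param store Optional [image_store()].
#' @return A `model_state` list (backend, fitted parameters, the config,
#'   and a digest of the training manifest for provenance).
#' @export
fit_classifier <- function(config, train_manifest, store = NULL) {
  m <- train_manifest
  if ("split" %in% names(m) && any(!is.na(m$split))) {
    m <- m[m$split == "train", , drop = FALSE]
  }
  if (length(unique(m$label)) < 2L) {
    stop("training manifest must contain both classes", call. = FALSE)
  }
  arrs <- load_model_inputs(m, config, store)
  y <- as.integer(m$label)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  if (config$backend == "intensity_baseline") {
    X <- intensity_features(arrs)
    mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg < 1e-9] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, `/`)
    df <- as.data.frame(Xs); df$y <- y
    model <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    params <- list(coef = coef(model), mu = mu, sg = sg)
  } else {
    toks_list <- lapply(arrs, vit_tokenize, patch = config$patch)
    tok_mat <- do.call(rbind, toks_list)
    fmu <- colMeans(tok_mat); fsd <- apply(tok_mat, 2, sd); fsd[fsd < 1e-6] <- 1
    toks_list <- lapply(toks_list, function(t) sweep(sweep(t, 2, fmu), 2, fsd, `/`))
    params <- list(weights = vit_fit(toks_list, y, config),
                   feat_mean = fmu, feat_sd = fsd)
  }
  structure(list(backend = config$backend, params = params, config = config,
                 train_digest = manifest_digest(m)),
            class = "model_state")
}

#' Score manifest items with a trained classifier
#'
#' @param state A `model_state` from [fit_classifier()].
#' @param items Manifest data frame to score (any split).
#' @param store Optional [image_store()].
#' @return A score table: one row per item with `item_path`, `patient_id`,
#'   `true_label` and `score` in `[0, 1]` (higher = positive class).
#' @export
predict_proba <- function(state, items, store = NULL) {
  if (nrow(items) == 0L) {
    return(data.frame(item_path = character(), patient_id = character(),
                      true_label = integer(), score = numeric()))
  }
  cfg <- state$config
  arrs <- load_model_inputs(items, cfg, store)
  if (state$backend == "intensity_baseline") {
    X <- intensity_features(arrs)
    Xs <- sweep(sweep(X, 2, state$params$mu), 2, state$params$sg, `/`)
    beta <- state$params$coef
    beta[is.na(beta)] <- 0
    eta <- beta[1] + Xs %*% beta[-1]
    scores <- as.vector(plogis(eta))
  } else {
    toks_list <- lapply(arrs, vit_tokenize, patch = cfg$patch)
    toks_list <- lapply(toks_list, function(t)
      sweep(sweep(t, 2, state$params$feat_mean), 2, state$params$feat_sd, `/`))
    scores <- vit_predict(state$params$weights, toks_list, cfg)
  }
  data.frame(item_path = items$item_path, patient_id = items$patient_id,
             true_label = as.integer(items$label), score = scores,
             stringsAsFactors = FALSE)
}

#' Save and load trained model state
#'
#' Serialization round-trips bit-identically (the determinism contracts
#' in the test suite rely on this).
#'
#' @param state A `model_state`.
#' @param path File path.
#' @return `save_model_state()`: the path invisibly; `load_model_state()`:
#'   the restored `model_state`.
#' @export
save_model_state <- function(state, path) {
  saveRDS(state, path, version = 2)
  invisible(path)
}

#' @rdname save_model_state
#' @export
load_model_state <- function(path) readRDS(path)
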