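# build an in-memory labeled image set: 3-channel items whose red-channel
# mean determines the class (a closed-form Bayes rule for feature models)
make_color_items <- function(n, seed, noise = 8, cut = 100, size = 16L) {
  set.seed(seed)
  store <- image_store()
  rows <- lapply(seq_len(n), function(i) {
    level <- sample(c(60, 140), 1)
    arr <- array(0, dim = c(size, size, 3))
    arr[, , 1] <- pmin(pmax(round(level + rnorm(size * size, 0, noise)), 0), 255)
    arr[, , 3] <- pmin(pmax(round(100 + rnorm(size * size, 0, noise)), 0), 255)
    key <- sprintf("item%03d", i)
    store_put(store, key, raster_image(arr))
    data.frame(item_path = key, patient_id = sprintf("P%02d", (i %% 4) + 1),
               label = as.integer(level > cut), split = "train",
               augmentation_tag = "rot000")
  })
  list(manifest = do.call(rbind, rows), store = store)
}

test_that("model-input preprocessing preserves aspect and pads with zeros", {
  patch <- raster_image(matrix(100, 128, 128))
  a <- preprocess_for_model(patch, 128)
  expect_equal(dim(a), c(128L, 128L, 3L))
  expect_true(all(abs(a - 100 / 255) < 1e-9))

  crop <- raster_image(matrix(200, 30, 10))
  b <- preprocess_for_model(crop, 64)
  expect_equal(dim(b), c(64L, 64L, 3L))
  # 30x10 scaled by 64/30 -> 64 x 21 occupied region, remainder zero
  expect_true(all(b[, 1:21, ] > 0))
  expect_true(all(b[, 22:64, ] == 0))

  const <- preprocess_for_model(raster_image(matrix(50, 20, 20)), 32)
  occupied <- const[1:32, 1:32, 1]
  expect_true(all(abs(occupied - 50 / 255) < 1e-9))
})

test_that("transformer gradients match finite differences", {
  cfg <- classifier_config(input_size = 16, patch = 8, d_model = 8,
                           n_layers = 2, n_heads = 2, mlp_hidden = 12, seed = 3)
  set.seed(3)
  params <- cardiopatch:::vit_init(cfg)
  N <- (16 %/% 8)^2
  toks <- matrix(rnorm(3 * N * 192), 3 * N, 192)
  y <- c(0L, 1L, 1L)
  lg <- cardiopatch:::vit_loss_grad(params, toks, y, cfg)
  eps <- 1e-5
  for (nm in c("We", "pos", "Wq1", "Wv2", "Wo1", "W12", "ln1_g1", "ln2_b2",
               "lnf_g", "Wh", "be")) {
    p <- params[[nm]]
    for (rep in 1:2) {
      i <- sample(length(p), 1)
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (cardiopatch:::vit_loss_grad(pp, toks, y, cfg)$loss -
                cardiopatch:::vit_loss_grad(pm, toks, y, cfg)$loss) / (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
    }
  }
})

test_that("intensity baseline recovers a channel-threshold labeling rule", {
  train <- make_color_items(60, seed = 51)
  test <- make_color_items(40, seed = 52)
  cfg <- classifier_config("intensity_baseline", input_size = 16)
  state <- fit_classifier(cfg, train$manifest, train$store)
  sc <- predict_proba(state, test$manifest, test$store)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  acc <- mean((sc$score > 0.5) == (sc$true_label == 1))
  expect_gte(acc, 0.95)
})

test_that("the small transformer learns a separable patch task", {
  train <- make_color_items(60, seed = 61)
  test <- make_color_items(30, seed = 62)
  cfg <- classifier_config("transformer_small", input_size = 16, patch = 8,
                           d_model = 16, n_layers = 1, n_heads = 2,
                           mlp_hidden = 32, epochs = 10, seed = 9)
  state <- fit_classifier(cfg, train$manifest, train$store)
  sc <- predict_proba(state, test$manifest, test$store)
  acc <- mean((sc$score > 0.5) == (sc$true_label == 1))
  expect_gte(acc, 0.9)
})

test_that("fixed seed and manifest give bit-identical scores", {
  train <- make_color_items(24, seed = 71)
  test <- make_color_items(10, seed = 72)
  cfg <- classifier_config("transformer_small", input_size = 16, patch = 8,
                           d_model = 8, n_layers = 1, n_heads = 2,
                           mlp_hidden = 12, epochs = 2, seed = 4)
  s1 <- predict_proba(fit_classifier(cfg, train$manifest, train$store),
                      test$manifest, test$store)
  s2 <- predict_proba(fit_classifier(cfg, train$manifest, train$store),
                      test$manifest, test$store)
  expect_identical(s1, s2)
})

test_that("inverted class encoding mirrors the AUC", {
  train <- make_color_items(40, seed = 81, noise = 25)
  test <- make_color_items(30, seed = 82, noise = 25)
  cfg <- classifier_config("intensity_baseline", input_size = 16)
  s <- predict_proba(fit_classifier(cfg, train$manifest, train$store),
                     test$manifest, test$store)
  flipped <- train$manifest
  flipped$label <- 1L - flipped$label
  s2 <- predict_proba(fit_classifier(cfg, flipped, train$store),
                      test$manifest, test$store)
  auc <- roc_auc(s)$auc
  s2$true_label <- s$true_label  # same evaluation labels, inverted training
  auc2 <- roc_auc(s2)$auc
  expect_equal(auc2, 1 - auc, tolerance = 1e-6)
})

test_that("training requires two classes and predicts empty manifests", {
  train <- make_color_items(10, seed = 91)
  mono <- train$manifest
  mono$label <- 1L
  cfg <- classifier_config("intensity_baseline", input_size = 16)
  expect_error(fit_classifier(cfg, mono, train$store), "both classes")

  state <- fit_classifier(cfg, train$manifest, train$store)
  empty <- train$manifest[0, ]
  expect_equal(nrow(predict_proba(state, empty, train$store)), 0L)
  expect_error(predict_proba(state, data.frame(
    item_path = "missing.png", patient_id = "P", label = 1L,
    augmentation_tag = "rot000"), NULL), "not found")
})

test_that("model state round-trips through save and load", {
  train <- make_color_items(16, seed = 99)
  cfg <- classifier_config("intensity_baseline", input_size = 16)
  state <- fit_classifier(cfg, train$manifest, train$store)
  p <- tempfile(fileext = ".rds")
  save_model_state(state, p)
  back <- load_model_state(p)
  expect_equal(back, state)
  s1 <- predict_proba(state, train$manifest, train$store)
  s2 <- predict_proba(back, train$manifest, train$store)
  expect_identical(s1, s2)
  unlink(p)
})
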