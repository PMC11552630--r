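test_that("majority vote follows the declared tie rule and invariances", {
  sc <- data.frame(patient_id = "P1", true_label = 1L,
                   score = c(0.9, 0.8, 0.7, 0.2, 0.1))
  v <- vote_patient(sc)
  expect_equal(v$predicted_label, 1L)
  expect_equal(v$n_positive_votes, 3L)
  expect_false(v$tie_broken)

  tie <- data.frame(patient_id = "P2", true_label = 0L,
                    score = c(0.9, 0.9, 0.3, 0.3))
  v <- vote_patient(tie)
  expect_equal(v$predicted_label, 1L)  # mean 0.6 > 0.5
  expect_true(v$tie_broken)

  # permutation and duplication invariance
  set.seed(2)
  perm <- tie[sample(nrow(tie)), ]
  expect_equal(vote_patient(perm), vote_patient(tie))
  dup <- rbind(tie, tie)
  expect_equal(vote_patient(dup)$predicted_label, v$predicted_label)
  expect_equal(vote_patient(dup)$positive_fraction, v$positive_fraction)

  expect_error(vote_patient(tie[0, ]), "no patches")
})

test_that("accuracy rate reproduces printed one-decimal percentages", {
  expect_equal(accuracy_rate(13, 14), 92.9)
  expect_equal(accuracy_rate(10, 14), 71.4)
  expect_equal(accuracy_rate(12, 14), 85.7)
  expect_equal(accuracy_rate(0, 9), 0)
  expect_error(accuracy_rate(1, 0), "total")
  expect_error(accuracy_rate(5, 4), "correct")
})

test_that("confusion matrix equals a row-by-row tally", {
  n <- 20L
  perfect <- data.frame(true_label = rep(1L, n), score = 1)
  cm <- confusion(perfect, 0.5)
  expect_equal(cm[c("tp", "fp", "tn", "fn")],
               list(tp = n, fp = 0L, tn = 0L, fn = 0L))

  set.seed(33)
  for (i in 1:20) {
    st <- random_score_table(15)
    thr <- runif(1)
    cm <- confusion(st, thr)
    want <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    for (r in seq_len(nrow(st))) {
      pred <- st$score[r] > thr
      pos <- st$true_label[r] == 1L
      k <- if (pred && pos) "tp" else if (pred) "fp" else if (pos) "fn" else "tn"
      want[k] <- want[k] + 1L
    }
    expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]), want)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, nrow(st))
    expect_equal(cm$accuracy, mean((st$score > thr) == (st$true_label == 1L)))
  }
})

test_that("trapezoidal AUC equals pair counting on every table", {
  st <- data.frame(true_label = c(1, 0, 1, 0), score = c(0.8, 0.7, 0.6, 0.5))
  expect_equal(roc_auc(st)$auc, 0.75)

  sep <- data.frame(true_label = c(1, 1, 0, 0), score = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(roc_auc(sep)$auc, 1.0)
  flat <- data.frame(true_label = c(1, 0, 1, 0), score = rep(0.4, 4))
  expect_equal(roc_auc(flat)$auc, 0.5)

  set.seed(44)
  for (i in 1:40) {
    st <- random_score_table(sample(6:20, 1), ties = (i %% 2 == 0))
    r <- roc_auc(st)
    expect_equal(r$auc, pair_auc(st$score, st$true_label))
    # complement identity
    inv <- st; inv$score <- 1 - inv$score; inv$true_label <- st$true_label
    expect_equal(roc_auc(inv)$auc +
                   pair_auc(st$score, st$true_label), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
  }
  expect_error(roc_auc(data.frame(true_label = c(1, 1), score = c(0.1, 0.2))),
               "single class")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(55)
  for (i in 1:5) {
    st <- random_score_table(30)
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      st$true_label, st$score, quiet = TRUE,
      levels = c(0, 1), direction = "<"))))
    expect_equal(roc_auc(st)$auc, ref)
  }
})

test_that("step-wise AUPR equals exhaustive threshold enumeration", {
  sep <- data.frame(true_label = c(1, 1, 0, 0), score = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(pr_aupr(sep)$aupr, 1.0)
  flat <- data.frame(true_label = c(1, 0, 0, 1, 0), score = rep(0.7, 5))
  expect_equal(pr_aupr(flat)$aupr, 2 / 5)  # prevalence

  set.seed(66)
  for (i in 1:40) {
    st <- random_score_table(sample(6:15, 1), ties = (i %% 2 == 0))
    expect_equal(pr_aupr(st)$aupr, brute_aupr(st$score, st$true_label))
  }
  expect_error(pr_aupr(data.frame(true_label = c(0, 0), score = c(0.1, 0.2))),
               "positives")
})

test_that("evaluation report aggregates patients deterministically", {
  set.seed(77)
  st <- do.call(rbind, lapply(1:6, function(p) {
    lab <- as.integer(p <= 3)
    data.frame(item_path = sprintf("P%d_%d", p, 1:10),
               patient_id = sprintf("P%d", p), true_label = lab,
               score = pmin(pmax(rnorm(10, 0.3 + 0.4 * lab, 0.15), 0), 1))
  }))
  rep1 <- evaluation_report(st)
  rep2 <- evaluation_report(st)
  expect_identical(rep1, rep2)
  expect_equal(rep1$n_patients, 6L)
  expect_equal(rep1$patient_accuracy_rate,
               accuracy_rate(rep1$patient_correct, 6))
  pp <- rep1$patients
  expect_equal(pp$positive_fraction, pp$n_positive_votes / pp$n_patches)
})
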