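#' Patient-level majority vote
#'
#' Each patch is hard-labeled positive when its score exceeds the decision
#' threshold; the patient's predicted label is the majority patch label.
#' An exact tie (possible with an even patch count) is broken by comparing
#' the patient's mean score to the threshold, and flagged via `tie_broken`.
#'
#' @param scores Score-table rows (`true_label`, `score`) for one patient.
#' @param decision_threshold Patch decision threshold (default 0.5).
#' @param patient_id Identifier recorded in the result (taken from the rows
#'   if present).
#' @return A one-row data frame: `patient_id`, `n_patches`,
#'   `n_positive_votes`, `positive_fraction`, `mean_score`,
#'   `predicted_label`, `tie_broken`.
#' @export
vote_patient <- function(scores, decision_threshold = 0.5, patient_id = NULL) {
  if (nrow(scores) == 0L) stop("no patches to vote over", call. = FALSE)
  pid <- patient_id %||% unique(scores$patient_id)
  if (length(pid) != 1L) stop("rows span multiple patients", call. = FALSE)
  n <- nrow(scores)
  npos <- sum(scores$score > decision_threshold)
  ms <- mean(scores$score)
  tie <- (2L * npos == n)
  pred <- if (tie) as.integer(ms > decision_threshold) else as.integer(npos > n / 2)
  data.frame(patient_id = pid, n_patches = n, n_positive_votes = npos,
             positive_fraction = npos / n, mean_score = ms,
             predicted_label = pred, tie_broken = tie,
             stringsAsFactors = FALSE)
}

#' Aggregate a score table to per-patient predictions
#'
#' @param score_table Score table from [predict_proba()].
#' @param decision_threshold Patch decision threshold.
#' @return Data frame with one [vote_patient()] row per patient plus the
#'   patient's `true_label`.
#' @export
aggregate_patients <- function(score_table, decision_threshold = 0.5) {
  parts <- split(score_table, score_table$patient_id)
  rows <- lapply(parts, function(p) {
    out <- vote_patient(p, decision_threshold)
    out$true_label <- unique(p$true_label)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy rate as a printed percentage
#'
#' @param correct Number of correct predictions, `0 <= correct <= total`.
#' @param total Number of evaluated cases, `>= 1`.
#' @return `100 * correct / total` rounded to one decimal (e.g. 13 of 14
#'   gives 92.9).
#' @export
accuracy_rate <- function(correct, total) {
  if (total < 1L) stop("total must be >= 1", call. = FALSE)
  if (correct < 0L || correct > total) stop("correct must lie in [0, total]", call. = FALSE)
  round(100 * correct / total, 1)
}

#' Confusion matrix at a threshold
#'
#' @param score_table Score table (`true_label`, `score`).
#' @param threshold Scores strictly greater are predicted positive.
#' @return List with `tp`, `fp`, `tn`, `fn` and `accuracy`.
#' @export
confusion <- function(score_table, threshold = 0.5) {
  pred <- score_table$score > threshold
  truth <- score_table$true_label == 1L
  out <- list(tp = sum(pred & truth), fp = sum(pred & !truth),
              tn = sum(!pred & !truth), fn = sum(!pred & truth))
  out$accuracy <- (out$tp + out$tn) / nrow(score_table)
  out
}

## sweep points over distinct thresholds, scores descending; ties grouped
sweep_counts <- function(score_table) {
  o <- order(score_table$score, decreasing = TRUE)
  s <- score_table$score[o]
  y <- score_table$true_label[o] == 1L
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  list(tp = tp, fp = fp, P = sum(y), N = sum(!y))
}

#' ROC curve and AUC
#'
#' Operating points are generated by sweeping the decision threshold over
#' the distinct scores (ties grouped into single points), and the area is
#' the trapezoidal rule over the resulting curve — which equals the
#' pair-counting probability `P(score_pos > score_neg) + 0.5 P(equal)`.
#'
#' @param score_table Score table with both classes present.
#' @return List with `points` (data frame of `fpr`, `tpr`, ordered) and
#'   `auc`.
#' @export
roc_auc <- function(score_table) {
  if (length(unique(score_table$true_label)) < 2L) {
    stop("ROC is undefined with a single class", call. = FALSE)
  }
  sw <- sweep_counts(score_table)
  fpr <- c(0, sw$fp / sw$N)
  tpr <- c(0, sw$tp / sw$P)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and AUPR
#'
#' Threshold sweep as in [roc_auc()]; the area uses the step-wise
#' (right-continuous precision) convention, the conservative choice among
#' PR interpolation rules: `AUPR = sum (R_i - R_{i-1}) * P_i`. With all
#' scores identical the curve collapses to a single point and the area
#' equals the positive prevalence.
#'
#' @param score_table Score table with at least one positive.
#' @return List with `points` (data frame of `recall`, `precision`) and
#'   `aupr`.
#' @export
pr_aupr <- function(score_table) {
  if (!any(score_table$true_label == 1L)) {
    stop("PR curve is undefined without positives", call. = FALSE)
  }
  sw <- sweep_counts(score_table)
  recall <- sw$tp / sw$P
  precision <- sw$tp / (sw$tp + sw$fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision), aupr = aupr)
}

#' Full evaluation report
#'
#' Computes patch-level accuracy, confusion counts, ROC/AUC and PR/AUPR,
#' and (when requested) the per-patient majority-vote table with
#' patient-level accuracy.
#'
#' @param score_table Score table from [predict_proba()].
#' @param threshold Decision threshold.
#' @param per_patient If `TRUE`, include [aggregate_patients()] output and
#'   patient-level accuracy.
#' @return A list report, serializable to JSON.
#' @export
evaluation_report <- function(score_table, threshold = 0.5, per_patient = TRUE) {
  cm <- confusion(score_table, threshold)
  roc <- roc_auc(score_table)
  pr <- pr_aupr(score_table)
  report <- list(n_items = nrow(score_table), threshold = threshold,
                 accuracy = cm$accuracy,
                 confusion = cm[c("tp", "fp", "tn", "fn")],
                 auc = roc$auc, aupr = pr$aupr)
  if (per_patient) {
    pp <- aggregate_patients(score_table, threshold)
    report$patients <- pp
    report$n_patients <- nrow(pp)
    report$patient_correct <- sum(pp$predicted_label == pp$true_label)
    report$patient_accuracy_rate <- accuracy_rate(report$patient_correct, nrow(pp))
  }
  report
}
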