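# Evaluation: balanced accuracy, rank-based AUC, the zero-calibration
# protocol (prototypes from training subjects only) and paired Wilcoxon
# comparisons across subjects.

#' Balanced accuracy with confusion counts
#'
#' `BA = (TPR + TNR) / 2` with `TPR = TP / (TP + FN)` and
#' `TNR = TN / (TN + FP)`; 0.5 is chance for any label-independent
#' classifier under class imbalance.
#'
#' @param labels binary ground-truth vector (1 = target); both classes must
#'   be present.
#' @param predictions binary predicted labels.
#' @return a `metrics_report` list: `ba`, `tpr`, `tnr`, `tp`, `fp`, `fn`,
#'   `tn`, `n` (plus `auc = NA`, filled by callers that also have scores).
#' @export
balanced_accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop_shape("labels and predictions must have equal length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop_validation("labels and predictions must be binary")
  if (length(unique(labels)) < 2L)
    stop_validation("balanced accuracy is undefined when labels contain a single class")
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  structure(list(ba = (tpr + tnr) / 2, auc = NA_real_, tpr = tpr, tnr = tnr,
                 tp = tp, fp = fp, fn = fn, tn = tn, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  BA=%.4f  AUC=%s  TPR=%.4f  TNR=%.4f  (TP=%d FP=%d FN=%d TN=%d)\n",
              x$n, x$ba, ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              x$tpr, x$tnr, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' The probability that a random target outscores a random nontarget, with
#' ties counting 1/2; computed from mid-ranks, so it is exact under ties and
#' invariant to any strictly monotone transform of the scores.
#'
#' @param labels binary vector; both classes must be present.
#' @param scores numeric scores (larger = more target-like, e.g. `P(y = 1)`).
#' @return scalar AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_shape("labels and scores must have equal length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop_validation("AUC is undefined when labels contain a single class")
  r <- rank(scores)   # mid-ranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided paired Wilcoxon signed-rank test across subjects
#'
#' Zero differences are dropped (signed-rank convention); if every
#' difference is zero the test is degenerate and `p = 1` is returned with a
#' warning. The exact distribution is used when there are no ties among
#' the nonzero absolute differences and `n < 50`.
#'
#' @param metric_a,metric_b equal-length (`>= 5`) per-subject metric vectors.
#' @return the two-sided p-value.
#' @export
paired_wilcoxon <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop_shape("metric vectors must have equal length")
  if (length(metric_a) < 5L)
    stop_validation("need at least 5 paired observations")
  d <- metric_a - metric_b
  if (all(d == 0)) {
    warning("all paired differences are zero; Wilcoxon test is degenerate, p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                       alternative = "two.sided")$p.value
  )
}

#' Significance stars for a p-value
#'
#' `***` for `p < 0.001`, `**` for `p < 0.01`, `*` for `p < 0.05`, otherwise
#' empty -- the thresholds conventionally drawn on group-comparison figures.
#'
#' @param p p-value.
#' @return character string.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Zero-calibration evaluation of one held-out subject
#'
#' Builds class prototypes from the training subjects only (encoder in
#' evaluation mode, running batch-norm statistics), then classifies every
#' trial of the held-out subject by nearest attention-weighted prototype. No
#' test trial influences prototypes or model state; the only thing computed
#' from a test trial is its own feature vector and (when subject attention
#' is on) its per-trial support-subject weights.
#'
#' @param model a trained `pronet_model` (see [fit()]).
#' @param train_subjects `subject_collection` of training subjects.
#' @param test_subject `epoch_set` of the held-out subject; its id must not
#'   occur among the training subjects.
#' @return a `metrics_report` with `ba`, `auc`, `tpr`, `tnr`, counts, and
#'   attributes `scores` (per-trial `P(y = 1)`) and `predictions`.
#' @export
zero_calibration_eval <- function(model, train_subjects, test_subject) {
  test_subject <- validate_epoch_set(test_subject)
  if (test_subject$subject_id %in% subject_ids(train_subjects))
    stop_validation("protocol error: test subject ", test_subject$subject_id,
                    " also present in the training set")
  state <- support_state(model, train_subjects)
  fq <- encode(model$encoder, test_subject, training_mode = FALSE)$features
  res <- classify_with_state(model, state, fq)
  rep <- balanced_accuracy(test_subject$labels, res$labels)
  rep$auc <- auc_score(test_subject$labels, res$probs[, "p1"])
  attr(rep, "scores") <- res$probs[, "p1"]
  attr(rep, "predictions") <- res$labels
  rep
}

#' Leave-one-subject-out evaluation driver
#'
#' For each subject in turn: train on the remaining subjects (fresh model,
#' same config, fold-specific seed derived from `config$seed`) and evaluate
#' zero-calibration transfer to the held-out subject. Produces exactly one
#' report per subject.
#'
#' @param coll a `subject_collection` (`>= 3` subjects so every training
#'   fold still has two or more subjects).
#' @param encoder_cfg an [encoder_config()].
#' @param train_cfg a [train_config()].
#' @param feature_attention,subject_attention logical ablation flags.
#' @param encoder `"incepa"` or `"plain"`.
#' @param verbose print per-fold progress?
#' @return list with `reports` (named per-subject list of `metrics_report`)
#'   and `summary` (data.frame with one row per held-out subject).
#' @export
loso <- function(coll, encoder_cfg = encoder_config(), train_cfg = train_config(),
                 feature_attention = TRUE, subject_attention = TRUE,
                 encoder = "incepa", verbose = FALSE) {
  ids <- subject_ids(coll)
  if (length(ids) < 3L) stop_validation("leave-one-subject-out needs >= 3 subjects")
  reports <- list()
  for (k in seq_along(ids)) {
    held <- ids[k]
    train_coll <- coll[setdiff(ids, held)]
    fold_cfg <- train_cfg
    fold_cfg$seed <- train_cfg$seed + k
    fitted <- fit(train_coll, encoder_cfg = encoder_cfg, train_cfg = fold_cfg,
                  feature_attention = feature_attention,
                  subject_attention = subject_attention, encoder = encoder,
                  verbose = FALSE)
    reports[[held]] <- zero_calibration_eval(fitted$model, train_coll, coll[[held]])
    if (verbose)
      cat(sprintf("[loso] held-out %s: BA=%.3f AUC=%.3f\n",
                  held, reports[[held]]$ba, reports[[held]]$auc))
  }
  summary <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(subject = id, ba = r$ba, auc = r$auc, tpr = r$tpr, tnr = r$tnr,
               tp = r$tp, fp = r$fp, fn = r$fn, tn = r$tn, n = r$n)
  }))
  list(reports = reports, summary = summary)
}
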