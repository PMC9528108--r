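# Patient-disjoint cross-validation and classification metrics. The
# positive class throughout is "non-intact". PR-AUC uses the
# average-precision estimator (sum over recall steps of the precision at
# that threshold), with tied scores grouped into a single step.

#' Patient-disjoint k-fold split
#'
#' A seeded random permutation of the patients is cut into k consecutive
#' blocks. Rotation i uses fold i as the test set, fold (i mod k)+1 as the
#' validation set, and the remaining k-2 folds for training, so every fold
#' is the test fold exactly once.
#'
#' @param patients Character vector of patient ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `fold_split`: `folds` (list of patient-id sets)
#'   and `rotations` (list of `train`/`validation`/`test` id sets).
#' @export
make_patient_folds <- function(patients, k = 8, seed = 1L) {
  patients <- unique(patients)
  n <- length(patients)
  if (k > n) stop("k exceeds the number of patients", call. = FALSE)
  perm <- with_seed(seed, sample(patients))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) {
    sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    warning("patients not divisible by k; fold sizes differ by 1",
            call. = FALSE)
  }
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  folds <- lapply(seq_len(k), function(i) perm[starts[i]:ends[i]])
  rotations <- lapply(seq_len(k), function(i) {
    vi <- i %% k + 1L
    list(test = folds[[i]], validation = folds[[vi]],
         train = unlist(folds[setdiff(seq_len(k), c(i, vi))]))
  })
  structure(list(folds = folds, rotations = rotations, k = k, seed = seed),
            class = "fold_split")
}

#' Confusion counts
#'
#' Positive class = `"non-intact"`: TP counts non-intact joints called
#' non-intact, TN intact called intact.
#'
#' @param labels Character vector of ground-truth labels
#'   (`"intact"`/`"non-intact"`).
#' @param calls Character vector of predicted labels, same length.
#' @return Named numeric vector `c(TP=, FP=, TN=, FN=)`.
#' @export
confusion_counts <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    stop("labels and calls must have equal length", call. = FALSE)
  }
  ok <- c("intact", "non-intact")
  if (!all(labels %in% ok) || !all(calls %in% ok)) {
    stop("labels and calls must be 'intact' or 'non-intact'", call. = FALSE)
  }
  c(TP = sum(labels == "non-intact" & calls == "non-intact"),
    FP = sum(labels == "intact" & calls == "non-intact"),
    TN = sum(labels == "intact" & calls == "intact"),
    FN = sum(labels == "non-intact" & calls == "intact"))
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), F-measure = harmonic mean of sensitivity and precision.
#' Ratios with a zero denominator are reported as `NA`, never as 0.
#'
#' @param counts Named vector from [confusion_counts()].
#' @return Named list with `sensitivity`, `specificity`, `precision`,
#'   `f_measure` and the counts.
#' @export
summarize_counts <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)),
            all(counts >= 0))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(counts[["TP"]], counts[["TP"]] + counts[["FN"]])
  spec <- rat(counts[["TN"]], counts[["TN"]] + counts[["FP"]])
  prec <- rat(counts[["TP"]], counts[["TP"]] + counts[["FP"]])
  f <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * sens * prec / (sens + prec)
  list(sensitivity = sens, specificity = spec, precision = prec,
       f_measure = f, counts = counts)
}

#' Precision-recall curve and area
#'
#' Sweeps every distinct score as a threshold (descending; tied scores are
#' one step) and accumulates the average-precision estimator: the sum over
#' recall increments of the precision at that threshold.
#'
#' @param scores Numeric scores (higher = more non-intact).
#' @param labels Ground-truth labels (`"intact"`/`"non-intact"`).
#' @return Object of class `pr_curve`: data frame `points` (threshold,
#'   recall, precision) and scalar `auc`.
#' @export
pr_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  y <- labels == "non-intact"
  P <- sum(y)
  if (P == 0 || P == length(y)) {
    stop("PR-AUC needs at least one positive and one negative label",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # step boundaries: last index of each tied-score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(yy)[last]
  npred <- last
  prec <- tp / npred
  rec <- tp / P
  d_rec <- diff(c(0, rec))
  auc <- sum(d_rec * prec)
  structure(list(points = data.frame(threshold = s[last], recall = rec,
                                     precision = prec),
                 auc = auc),
            class = "pr_curve")
}

#' Pool cross-validation test predictions into stratified metrics
#'
#' Predictions from all test folds are pooled (each exam must appear in
#' exactly one test fold) and metrics are computed per joint group and for
#' the "All joints" stratum, mirroring the standard per-group reporting
#' layout.
#'
#' @param predictions Data frame with columns `patient_id`, `exam_idx`,
#'   `side`, `name`, `label`, `prob`, `call`, `fold` (test-fold index).
#' @param assessment `"erosion"` or `"jsn"`.
#' @return Data frame with one row per stratum: confusion counts,
#'   sensitivity, specificity, precision, F-measure and PR-AUC (PR-AUC is
#'   `NA` for single-class strata).
#' @export
aggregate_cv <- function(predictions, assessment) {
  key <- paste(predictions$patient_id, predictions$exam_idx,
               predictions$side, predictions$name)
  folds_per_key <- tapply(predictions$fold, key, function(f) length(unique(f)))
  if (any(folds_per_key > 1)) {
    stop("some joints appear in more than one test fold", call. = FALSE)
  }
  predictions$group <- joint_group(assessment, predictions$name)
  strata <- c(unique(target_joints(assessment, "right")$group), "All joints")
  rows <- lapply(strata, function(g) {
    sub <- if (g == "All joints") predictions else
      predictions[predictions$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sm <- summarize_counts(confusion_counts(sub$label, sub$call))
    auc <- if (length(unique(sub$label)) == 2L)
      pr_auc(sub$prob, sub$label)$auc else NA_real_
    data.frame(group = g, n = nrow(sub),
               TP = sm$counts[["TP"]], FP = sm$counts[["FP"]],
               TN = sm$counts[["TN"]], FN = sm$counts[["FN"]],
               sensitivity = sm$sensitivity, specificity = sm$specificity,
               precision = sm$precision, f_measure = sm$f_measure,
               pr_auc = auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
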