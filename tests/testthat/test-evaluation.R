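# Metric implementations are checked against independent brute-force
# oracles: exhaustive threshold enumeration for PR-AUC and direct formula
# evaluation for the confusion-derived metrics.

brute_force_f <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + fn == 0 || tp + fp == 0) return(NA_real_)
  sens <- tp / (tp + fn)
  prec <- tp / (tp + fp)
  if (sens + prec == 0) return(NA_real_)
  2 * sens * prec / (sens + prec)
}

# Average precision by explicit enumeration of every distinct threshold.
brute_force_ap <- function(scores, labels) {
  y <- labels == "non-intact"
  P <- sum(y)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    called <- scores >= t
    tp <- sum(called & y)
    rec <- tp / P
    prec <- tp / sum(called)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

test_that("confusion counts enumerate the four cells and conserve n", {
  l <- c("non-intact", "non-intact", "intact", "intact")
  expect_equal(confusion_counts(l, rep("non-intact", 4)),
               c(TP = 2, FP = 2, TN = 0, FN = 0))
  c2 <- confusion_counts(c("non-intact", "non-intact", "intact", "intact"),
                         c("non-intact", "intact", "non-intact", "intact"))
  expect_equal(c2, c(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(sum(c2), 4)
  expect_error(confusion_counts(l, l[1:2]), "equal length")
})

test_that("summary metrics match direct formulas on random tables", {
  sm <- summarize_counts(c(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(sm$sensitivity, 0.5)
  expect_equal(sm$specificity, 0.5)
  expect_equal(sm$f_measure, 0.5)
  expect_equal(summarize_counts(c(TP = 10, FP = 0, TN = 5, FN = 0))$f_measure, 1)
  # zero denominators reported as NA, never 0
  expect_true(is.na(summarize_counts(c(TP = 0, FP = 0, TN = 5, FN = 2))$precision))
  with_seed(52, {
    for (i in 1:200) {
      cnt <- c(TP = rpois(1, 5), FP = rpois(1, 5),
               TN = rpois(1, 5), FN = rpois(1, 5))
      got <- summarize_counts(cnt)$f_measure
      want <- brute_force_f(cnt)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("PR-AUC equals the exhaustive-threshold oracle, including ties", {
  # perfectly ranked -> 1; constant scores -> prevalence
  lab <- c(rep("non-intact", 3), rep("intact", 5))
  expect_equal(pr_auc(c(9, 8, 7, 1:5), lab)$auc, 1)
  expect_equal(pr_auc(rep(0.5, 8), lab)$auc, 3 / 8)
  # exhaustive label patterns of size <= 8 against the oracle
  with_seed(53, {
    for (n in 2:8) {
      for (rep in 1:6) {
        labels <- rep("intact", n)
        labels[sample(n, sample(n - 1, 1))] <- "non-intact"
        scores <- round(runif(n), 1)  # coarse grid forces ties
        expect_equal(pr_auc(scores, labels)$auc,
                     brute_force_ap(scores, labels), tolerance = 1e-12)
      }
    }
    # larger random instances
    for (rep in 1:50) {
      n <- sample(20:80, 1)
      labels <- ifelse(runif(n) < 0.3, "non-intact", "intact")
      if (length(unique(labels)) < 2) next
      scores <- rnorm(n)
      expect_equal(pr_auc(scores, labels)$auc,
                   brute_force_ap(scores, labels), tolerance = 1e-12)
    }
  })
  expect_error(pr_auc(1:3, rep("intact", 3)), "one positive and one negative")
})

test_that("adding a correctly called positive never lowers sensitivity or F", {
  with_seed(54, {
    for (i in 1:50) {
      cnt <- c(TP = rpois(1, 4) + 1, FP = rpois(1, 4),
               TN = rpois(1, 4), FN = rpois(1, 4))
      base <- summarize_counts(cnt)
      more <- summarize_counts(cnt + c(TP = 1, FP = 0, TN = 0, FN = 0))
      expect_gte(more$sensitivity, base$sensitivity)
      expect_gte(more$f_measure, base$f_measure)
    }
  })
})

test_that("patient folds are disjoint, exhaustive and deterministic", {
  pats <- sprintf("P%03d", 1:40)
  fs <- make_patient_folds(pats, k = 8, seed = 9)
  expect_equal(lengths(fs$folds), rep(5L, 8))
  expect_setequal(unlist(fs$folds), pats)
  expect_equal(anyDuplicated(unlist(fs$folds)), 0L)
  # every patient tested exactly once across rotations
  tested <- unlist(lapply(fs$rotations, `[[`, "test"))
  expect_setequal(tested, pats)
  expect_equal(anyDuplicated(tested), 0L)
  # train/validation/test partition each rotation
  for (rot in fs$rotations) {
    expect_setequal(c(rot$train, rot$validation, rot$test), pats)
    expect_equal(length(rot$train), 30L)
  }
  expect_identical(make_patient_folds(pats, k = 8, seed = 9)$folds, fs$folds)
  expect_error(make_patient_folds(pats[1:5], k = 8), "exceeds")
  expect_warning(make_patient_folds(pats[1:38], k = 8), "differ by 1")
})

test_that("pooled CV metrics equal per-fold metrics when folds agree", {
  mk <- function(fold) {
    data.frame(patient_id = paste0("P", fold, 1:4), exam_idx = 1,
               side = "right", name = c("mcp2", "mcp3", "pip2", "pip3"),
               label = c("non-intact", "intact", "non-intact", "intact"),
               prob = c(0.9, 0.2, 0.4, 0.6),
               call = c("non-intact", "intact", "intact", "non-intact"),
               fold = fold, stringsAsFactors = FALSE)
  }
  pooled <- aggregate_cv(rbind(mk(1), mk(2)), "jsn")
  single <- aggregate_cv(mk(1), "jsn")
  all1 <- single[single$group == "All joints", ]
  all2 <- pooled[pooled$group == "All joints", ]
  expect_equal(all2$sensitivity, all1$sensitivity)
  expect_equal(all2$f_measure, all1$f_measure)
  expect_equal(all2$pr_auc, all1$pr_auc)
  # conservation: stratum counts sum to the All joints counts
  strata <- pooled[pooled$group != "All joints", ]
  expect_equal(sum(strata$n), all2$n)
  expect_equal(sum(strata$TP), all2$TP)
  # duplicated test exams rejected
  dup <- rbind(mk(1), transform(mk(1), fold = 2))
  expect_error(aggregate_cv(dup, "jsn"), "more than one test fold")
})
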