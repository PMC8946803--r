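# ROC construction, AUC, Youden thresholds, confusion metrics, LOPO-CV,
# and the mean-row aggregation semantics.

test_that("ROC points collapse ties and hit the canonical endpoints", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.4, 0.1)
  labels <- c("tumor", "tumor", "non_tumor", "tumor", "non_tumor", "non_tumor")
  roc <- roc_points(scores, labels)
  expect_equal(nrow(roc), length(unique(scores)) + 1)  # + (0,0) endpoint
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # perfect and reversed rankings
  perf <- roc_points(c(2, 1), c("tumor", "non_tumor"))
  expect_true(any(perf$fpr == 0 & perf$tpr == 1))
  expect_equal(roc_auc(perf), 1)
  expect_equal(roc_auc(roc_points(c(1, 2), c("tumor", "non_tumor"))), 0)
  expect_equal(roc_auc(roc_points(rep(1, 10), rep(c("tumor", "non_tumor"), 5))),
               0.5)
  expect_error(roc_points(1:3, rep("tumor", 3)), "both classes")
})

test_that("trapezoidal AUC equals the all-pairs oracle on random instances", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(10:500, 1)
    labels <- sample(c("tumor", "non_tumor"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    expect_equal(roc_auc(roc_points(scores, labels)),
                 auc_pairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("Youden threshold maximizes J with ties to lower FPR", {
  roc <- data.frame(threshold = c(Inf, 3, 2, 1),
                    fpr = c(0, 0.1, 0.3, 1),
                    tpr = c(0, 0.5, 0.8, 1))
  yt <- youden_threshold(roc)
  expect_equal(yt$threshold, 2)  # J = 0, .4, .5, 0
  expect_equal(yt$j, 0.5)
  # exhaustive-maximization oracle on random ROC curves
  set.seed(13)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    labels <- sample(c("tumor", "non_tumor"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)
    r <- roc_points(scores, labels)
    j <- r$tpr - r$fpr
    best <- which(abs(j - max(j)) < 1e-12)
    best <- best[r$fpr[best] == min(r$fpr[best])]
    expect_equal(youden_threshold(r)$threshold, max(r$threshold[best]))
  }
  # uninformative scores: J = 0, tie rule picks the lowest-FPR point
  flat <- roc_points(rep(1, 8), rep(c("tumor", "non_tumor"), 4))
  expect_equal(youden_threshold(flat)$fpr, 0)
})

test_that("confusion metrics match direct arithmetic and NA semantics", {
  m <- classification_metrics(25, 25, 25, 25)
  expect_equal(unname(m), c(0.5, 0.5, 0.5, 0.5, 0))
  expect_equal(unname(classification_metrics(10, 0, 7, 0)), c(1, 1, 1, 1, 1))
  # printed-value example: TP=40, FN=10, TN=30, FP=20
  expect_equal(classification_metrics(40, 20, 30, 10)[["mcc"]],
               1000 / sqrt(60 * 50 * 50 * 40))
  expect_true(is.na(classification_metrics(0, 0, 5, 0)[["sensitivity"]]))
  expect_true(is.na(classification_metrics(0, 0, 5, 0)[["ppv"]]))
  # 1,000 random confusion matrices against the oracle
  set.seed(99)
  for (i in 1:1000) {
    cm <- rpois(4, sample(c(0, 2, 20), 4, replace = TRUE))
    got <- classification_metrics(cm[1], cm[2], cm[3], cm[4])
    want <- metrics_direct(cm[1], cm[2], cm[3], cm[4])
    expect_equal(got, want)
    if (!is.na(got[["mcc"]])) expect_true(abs(got[["mcc"]]) <= 1 + 1e-12)
  }
  # proportional rows give MCC exactly 0
  expect_equal(classification_metrics(10, 20, 10, 5)[["mcc"]], 0)
})

test_that("LOPO-CV separates separable patients and is deterministic", {
  tp <- toy_patches(n_per_class = 25, n_patients = 3, shift = 4, seed = 2)
  x <- as.matrix(tp[, c("f1", "f2")])
  r1 <- lopo_cv(x, tp$label, tp$patient)
  expect_true(all(r1$per_patient$auc == 1))
  expect_true(all(r1$per_patient$sensitivity == 1))
  expect_true(all(r1$per_patient$specificity == 1))
  r2 <- lopo_cv(x, tp$label, tp$patient)
  expect_identical(r1$per_patient, r2$per_patient)
  expect_error(lopo_cv(x, tp$label, rep("P1", nrow(tp))), "2 patients")
})

test_that("a tumor-free patient keeps only specificity, as in the report table", {
  tp <- toy_patches(n_per_class = 20, n_patients = 4, shift = 4, seed = 5,
                    tumor_free = 2)
  r <- lopo_cv(as.matrix(tp[, c("f1", "f2")]), tp$label, tp$patient)
  row <- r$per_patient[r$per_patient$patient == "P02", ]
  expect_true(row$tumor_free)
  expect_false(is.na(row$specificity))
  expect_true(all(is.na(row[c("sensitivity", "ppv", "npv", "auc", "mcc")])))
})

test_that("training folds that collapse to one class are skipped and recorded", {
  tp <- toy_patches(n_per_class = 10, n_patients = 2, shift = 4, seed = 6,
                    tumor_free = 2)
  # leaving out patient 2 leaves only patient 1 (both classes): fine;
  # leaving out patient 1 leaves only non-tumor -> recorded error
  r <- lopo_cv(as.matrix(tp[, c("f1", "f2")]), tp$label, tp$patient)
  expect_length(r$errors, 1)
  expect_match(r$errors[["P01"]], "single class")
  expect_true(all(is.na(r$per_patient[r$per_patient$patient == "P01",
                                      c("sensitivity", "auc")])))
})

test_that("identical class distributions give chance-level AUC over seeds", {
  aucs <- vapply(1:20, function(s) {
    tp <- toy_patches(n_per_class = 20, n_patients = 3, shift = 0, seed = s)
    r <- lopo_cv(as.matrix(tp[, c("f1", "f2")]), tp$label, tp$patient)
    mean(r$per_patient$auc)
  }, numeric(1))
  # mean over 20 seeds within 3 SE of 0.5
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("the mean row averages defined cells with tumor-free exclusions", {
  pp <- data.frame(
    patient = c("a", "b", "c"),
    sensitivity = c(0.9, NA, 0.7), specificity = c(0.5, 0.8, 0.6),
    ppv = c(0.9, 0.2, 0.4), npv = c(0.8, 0.9, 0.7),
    auc = c(0.95, NA, 0.85), mcc = c(0.5, NA, 0.3),
    tumor_free = c(FALSE, TRUE, FALSE))
  m <- aggregate_mean(pp)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], mean(c(0.5, 0.8, 0.6)))
  expect_equal(m[["ppv"]], mean(c(0.9, 0.4)))  # tumor-free ppv excluded
  single <- aggregate_mean(pp[1, ])
  expect_equal(single[["auc"]], 0.95)
  all_na <- aggregate_mean(transform(pp[2, ], specificity = NA))
  expect_true(is.na(all_na[["specificity"]]))
})

test_that("half-up display rounding reproduces exact decimal halves", {
  expect_equal(round_half_up(0.805, 2), 0.81)
  expect_equal(round_half_up(0.815, 2), 0.82)
  expect_equal(round_half_up(0.825, 2), 0.83)
  expect_equal(round_half_up(mean(c(0.91, 0.55, 0.66, 0.95, 0.85, 0.91)), 2),
               0.81)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_true(is.na(round_half_up(NA_real_, 2)))
})
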