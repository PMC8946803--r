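# ROC / Youden / confusion-matrix metrics and leave-one-patient-out CV.

#' ROC points of a score vector
#'
#' One point per distinct score value (ties collapse onto a single threshold),
#' monotone in both coordinates, with the endpoints (0,0) (threshold `Inf`,
#' nothing predicted positive) and (1,1) included.  The prediction rule is
#' "positive when score >= threshold".
#'
#' @param scores numeric decision scores.
#' @param labels class labels; both classes must be present.
#' @param positive positive class.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = "tumor") {
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("roc_points() needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  ctp <- cumsum(p); cfp <- cumsum(!p)
  last <- which(c(diff(s) != 0, TRUE))
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cfp[last] / nn),
             tpr = c(0, ctp[last] / np))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal integral of TPR over FPR; with tied scores collapsed this
#' equals the Mann-Whitney statistic with half credit for ties.
#'
#' @param roc output of [roc_points()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' Youden-index optimal threshold
#'
#' Maximizes `J = TPR - FPR` over the ROC points; ties are broken toward the
#' higher specificity (lower FPR), then toward the higher threshold.
#'
#' @param roc output of [roc_points()].
#' @return list with `threshold`, `j`, `fpr`, `tpr`.
#' @export
youden_threshold <- function(roc) {
  j <- roc$tpr - roc$fpr
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[roc$fpr[cand] <= min(roc$fpr[cand]) + 1e-12]
  k <- cand[which.max(roc$threshold[cand])]
  list(threshold = roc$threshold[k], j = j[k],
       fpr = roc$fpr[k], tpr = roc$tpr[k])
}

#' Confusion counts at a threshold
#' @param scores decision scores.
#' @param labels class labels.
#' @param threshold predict positive when `score >= threshold`.
#' @param positive positive class.
#' @return named integer vector (tp, fp, tn, fn).
#' @export
confusion_counts <- function(scores, labels, threshold, positive = "tumor") {
  pos <- labels == positive
  pred <- scores >= threshold
  c(tp = sum(pred & pos), fp = sum(pred & !pos),
    tn = sum(!pred & !pos), fn = sum(!pred & pos))
}

#' Confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)` and the Matthews correlation coefficient.  A metric whose
#' defining denominator is zero is undefined (`NA`), mirroring the "-" cells
#' of per-patient report tables.
#'
#' @param tp,fp,tn,fn confusion counts (or a single named vector as `tp`).
#' @return named numeric vector: sensitivity, specificity, ppv, npv, mcc.
#' @export
classification_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp)) { v <- tp; tp <- v[["tp"]]; fp <- v[["fp"]]
                     tn <- v[["tn"]]; fn <- v[["fn"]] }
  div <- function(a, b) if (b > 0) a / b else NA_real_
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_)
}

#' Leave-one-patient-out cross-validation of the weighted linear SVM
#'
#' For each patient: train the class-weighted linear SVM on every other
#' patient's patches (features z-scored with training-fold statistics),
#' score the held-out patient, build that patient's ROC, pick the
#' Youden-index threshold on it, and derive the confusion matrix and metrics.
#' Holding out whole patients prevents within-patient leakage.
#'
#' Patients whose held-out set has a single class cannot form a ROC: a
#' tumor-free patient gets only its specificity (computed at the SVM's own
#' decision boundary, score 0, or at the training-fold Youden threshold when
#' `threshold_mode = "train"`); all other metrics are undefined, mirroring the
#' "-" cells of per-patient report tables.  Training folds that collapse to a
#' single class are skipped with the error recorded in the report.
#'
#' @param x feature matrix (rows = patches).
#' @param y labels (`"tumor"` / `"non_tumor"`).
#' @param patient patient id per patch; at least 2 distinct patients.
#' @param C SVM regularization (default 1; no hyperparameter search).
#' @param threshold_mode `"heldout"` (Youden on the held-out patient's ROC,
#'   the default) or `"train"` (Youden on the pooled training-fold ROC).
#' @param positive positive class.
#' @return object of class `metrics_report`: `per_patient` data.frame,
#'   `mean` (aggregated mean row, see [aggregate_mean()]), `roc` (per-patient
#'   ROC point lists), `errors`.
#' @export
lopo_cv <- function(x, y, patient, C = 1,
                    threshold_mode = c("heldout", "train"),
                    positive = "tumor") {
  threshold_mode <- match.arg(threshold_mode)
  x <- as.matrix(x)
  patients <- unique(patient)
  if (length(patients) < 2) stop("lopo_cv() needs at least 2 patients")
  rows <- list(); rocs <- list(); errors <- list()
  for (p in patients) {
    test <- patient == p
    xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
    xte <- x[test, , drop = FALSE]; yte <- y[test]
    row <- data.frame(patient = p,
                      n_tumor = sum(yte == positive),
                      n_non_tumor = sum(yte != positive),
                      tp = NA_integer_, fp = NA_integer_,
                      tn = NA_integer_, fn = NA_integer_,
                      threshold = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      ppv = NA_real_, npv = NA_real_,
                      auc = NA_real_, mcc = NA_real_,
                      tumor_free = sum(yte == positive) == 0,
                      stringsAsFactors = FALSE)
    if (length(unique(ytr)) < 2) {
      errors[[p]] <- paste0("training fold for patient ", p,
                            " has a single class; fold skipped")
      rows[[p]] <- row
      next
    }
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    ztr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    zte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    wts <- class_weights(ytr, classes = sort(unique(as.character(ytr))))
    model <- fit_linear_svm(ztr, ytr, weights = wts, C = C,
                            positive = positive)
    sc <- predict(model, zte)
    both <- row$n_tumor > 0 && row$n_non_tumor > 0
    thr <- if (threshold_mode == "train") {
      youden_threshold(roc_points(predict(model, ztr), ytr, positive))$threshold
    } else if (both) {
      roc <- roc_points(sc, yte, positive)
      rocs[[p]] <- roc
      youden_threshold(roc)$threshold
    } else 0
    cm <- confusion_counts(sc, yte, thr, positive)
    met <- classification_metrics(cm)
    row[c("tp", "fp", "tn", "fn")] <- as.list(as.integer(cm))
    row$threshold <- thr
    if (both) {
      if (threshold_mode == "train") {
        rocs[[p]] <- roc_points(sc, yte, positive)
      }
      row$auc <- roc_auc(rocs[[p]])
      row[c("sensitivity", "specificity", "ppv", "npv", "mcc")] <-
        as.list(met[c("sensitivity", "specificity", "ppv", "npv", "mcc")])
    } else if (row$n_tumor == 0) {
      row$specificity <- met[["specificity"]]   # only defined quantity
    } else {
      row$sensitivity <- met[["sensitivity"]]   # all-tumor patient (no ROC)
    }
    rows[[p]] <- row
  }
  per_patient <- do.call(rbind, rows)
  rownames(per_patient) <- NULL
  structure(list(per_patient = per_patient,
                 mean = aggregate_mean(per_patient),
                 roc = rocs, errors = errors,
                 config = list(C = C, threshold_mode = threshold_mode,
                               positive = positive)),
            class = "metrics_report")
}

#' Cohort mean row of a per-patient metrics table
#'
#' Each metric is averaged over the patients where it is defined; tumor-free
#' patients contribute only to the specificity mean (their PPV/NPV, even when
#' printable, are excluded, as in the published table's footnote).  A metric
#' defined for no patient has an undefined mean.  Values are returned at full
#' precision; display rounding is 2 dp half-up.
#'
#' @param per_patient data.frame with columns sensitivity, specificity, ppv,
#'   npv, auc, mcc and logical `tumor_free`.
#' @return named numeric vector of means (full precision).
#' @export
aggregate_mean <- function(per_patient) {
  cols <- c("sensitivity", "specificity", "ppv", "npv", "auc", "mcc")
  stopifnot(all(cols %in% names(per_patient)))
  tf <- if ("tumor_free" %in% names(per_patient)) per_patient$tumor_free
        else rep(FALSE, nrow(per_patient))
  vapply(cols, function(cl) {
    v <- per_patient[[cl]]
    if (cl != "specificity") v[tf] <- NA_real_
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.metrics_report <- function(x, ...) {
  pp <- x$per_patient
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", round_half_up(v, 2)))
  disp <- data.frame(patient = pp$patient,
                     sensitivity = fmt(pp$sensitivity),
                     specificity = fmt(pp$specificity),
                     ppv = fmt(pp$ppv), npv = fmt(pp$npv),
                     auc = fmt(pp$auc), mcc = fmt(pp$mcc))
  print(disp, row.names = FALSE)
  cat("Mean:", paste(names(x$mean), fmt(x$mean), sep = "=", collapse = " "),
      "\n")
  if (length(x$errors)) {
    cat("Fold errors:\n")
    for (e in x$errors) cat("  -", e, "\n")
  }
  invisible(x)
}
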