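# Class-weighted linear SVM (primal hinge loss, solved in the dual by SMO).

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` with `N` the number of observations, `K = 2` classes
#' and `n_c` the class count, so the minority class is up-weighted and a
#' balanced problem gets unit weights.  Requested classes that are absent are
#' omitted with a warning.
#'
#' @param labels class label vector.
#' @param classes the classes to weight (default the two tissue classes).
#' @return named numeric vector of weights.
#' @export
class_weights <- function(labels, classes = c("non_tumor", "tumor")) {
  n <- length(labels)
  k <- length(classes)
  present <- classes[classes %in% labels]
  if (length(present) < length(classes)) {
    warning("class(es) absent from labels: ",
            paste(setdiff(classes, present), collapse = ", "))
  }
  vapply(present, function(cl) n / (k * sum(labels == cl)), numeric(1))
}

#' Fit a class-weighted linear SVM
#'
#' Minimizes `1/2 ||w||^2 + C * sum_i w_class(i) * hinge(y_i, w.x_i + b)` with
#' the hinge `max(0, 1 - y s)`, by sequential minimal optimization on the
#' dual.  Deterministic given the data and `C`.  The sign convention puts the
#' positive (tumor) class at positive decision scores.
#'
#' Feature standardization is the caller's responsibility (the
#' cross-validation driver standardizes with training-fold statistics).
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y label vector with exactly two classes.
#' @param weights named per-class weights; default [class_weights()] on `y`.
#' @param C regularization strength (default 1).
#' @param positive label of the positive class.
#' @param eps SMO duality-gap tolerance.
#' @param max_iter iteration cap.
#' @return object of class `linear_svm`: `w`, `b`, `C`, `weights`,
#'   `positive`, `converged`, `iterations`.
#' @export
fit_linear_svm <- function(x, y, weights = NULL, C = 1, positive = "tumor",
                           eps = 1e-5, max_iter = 1000000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(unique(y)) < 2) stop("fit_linear_svm() needs two classes")
  if (nrow(x) >= 2 && all(abs(sweep(x, 2, x[1, ])) < 1e-12)) {
    stop("degenerate training set: all feature rows are identical")
  }
  if (is.null(weights)) {
    weights <- class_weights(y, classes = sort(unique(as.character(y))))
  }
  ypm <- ifelse(y == positive, 1L, -1L)
  ci <- C * unname(weights[as.character(y)])
  if (any(is.na(ci))) stop("weights must be named for every label in y")
  fit <- .svm_smo(x, as.integer(ypm), as.numeric(ci), eps, as.integer(max_iter))
  if (!fit$converged) {
    warning("SMO did not reach tolerance ", eps, " (gap ",
            format(fit$gap), " after ", fit$iterations, " iterations)")
  }
  structure(list(w = as.numeric(fit$w), b = fit$b, C = C, weights = weights,
                 positive = positive, converged = fit$converged,
                 iterations = fit$iterations,
                 feature_names = colnames(x)),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$w) + object$b
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d features, C=%g, |w|=%.4g, b=%.4g (%s)\n",
              length(x$w), x$C, sqrt(sum(x$w^2)), x$b,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Weighted hinge-loss primal objective
#'
#' `1/2 ||w||^2 + sum_i Ci_i * max(0, 1 - y_i (w.x_i + b))`, the quantity the
#' solver minimizes; exposed so independent oracles can compare objectives.
#'
#' @param w,b hyperplane parameters.
#' @param x feature matrix.
#' @param y labels in \{-1, +1\} (or a label vector plus `positive`).
#' @param Ci per-observation penalty weights.
#' @param positive positive class used when `y` is not numeric.
#' @return objective value.
#' @export
svm_objective <- function(w, b, x, y, Ci, positive = "tumor") {
  if (!is.numeric(y)) y <- ifelse(y == positive, 1, -1)
  s <- drop(as.matrix(x) %*% w) + b
  0.5 * sum(w^2) + sum(Ci * pmax(0, 1 - y * s))
}
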