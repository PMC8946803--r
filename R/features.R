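# Spectral feature extraction and univariate feature screening.

#' Define one spectral feature
#'
#' @param name column name of the feature.
#' @param kind one of `"intensity"`, `"derivative"`, `"ratio"`.
#' @param wavelengths one wavelength (intensity) or two (derivative: value at
#'   the second minus value at the first; ratio: first over second), in nm.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("intensity", "derivative", "ratio"),
                         wavelengths) {
  kind <- match.arg(kind)
  nw <- if (kind == "intensity") 1L else 2L
  if (length(wavelengths) != nw) {
    stop("feature '", name, "' of kind ", kind, " needs ", nw, " wavelength(s)")
  }
  structure(list(name = name, kind = kind, wavelengths = wavelengths),
            class = "feature_spec")
}

#' The default set of 19 prognostic spectral features
#'
#' 9 band intensities (697, 775, 799, 823, 863, 872, 901, 910, 923 nm),
#' 4 derivatives, i.e. intensity differences (684-697, 882-892, 923-930,
#' 943-954 nm), and 6 intensity ratios (676/910, 697/910, 762/910, 872/910,
#' 923/910, 930/910 nm).  These are the wavelength combinations at which tumor
#' and non-tumor spectra separate most.
#'
#' @return list of 19 [feature_spec()] objects.
#' @export
default_feature_specs <- function() {
  ints <- c(697, 775, 799, 823, 863, 872, 901, 910, 923)
  ders <- list(c(684, 697), c(882, 892), c(923, 930), c(943, 954))
  rats <- list(c(676, 910), c(697, 910), c(762, 910), c(872, 910),
               c(923, 910), c(930, 910))
  c(lapply(ints, function(w) feature_spec(paste0("i", w), "intensity", w)),
    lapply(ders, function(w) {
      feature_spec(paste0("d", w[1], "_", w[2]), "derivative", w)
    }),
    lapply(rats, function(w) {
      feature_spec(paste0("q", w[1], "_", w[2]), "ratio", w)
    }))
}

#' Extract spectral features from one patch spectrum
#'
#' Feature definitions: `intensity(l) = I(band(l))`,
#' `derivative(l1-l2) = I(band(l2)) - I(band(l1))`,
#' `ratio(l1/l2) = I(band(l1)) / I(band(l2))`.  In the default `"mixed"` mode
#' the 9 intensities are read from the min-max normalized spectrum (shape
#' only) while derivatives and ratios are computed on the reflectance
#' spectrum, because normalization forces a zero into every spectrum, which
#' destabilizes ratios.  Modes `"reflectance"` and `"normalized"` apply one
#' representation to all features.
#'
#' @param spectrum reflectance spectrum (length 25).
#' @param bands band table.
#' @param specs list of [feature_spec()]s; default the 19-feature set.
#' @param mode `"mixed"`, `"reflectance"` or `"normalized"`.
#' @param eps ratios whose denominator has absolute value below `eps` are set
#'   to `sentinel`.
#' @param sentinel value substituted for unstable ratios (default `NA`).
#' @return named numeric vector, ordered as `specs`.
#' @export
extract_features <- function(spectrum, bands = make_band_table(),
                             specs = default_feature_specs(),
                             mode = c("mixed", "reflectance", "normalized"),
                             eps = 1e-8, sentinel = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(length(spectrum) == length(bands$centers_nm))
  norm <- minmax_normalize(as.numeric(spectrum))
  pick <- function(kind) {
    switch(mode,
           mixed = if (kind == "intensity") norm else spectrum,
           reflectance = spectrum,
           normalized = norm)
  }
  out <- vapply(specs, function(sp) {
    src <- pick(sp$kind)
    b <- nearest_band(sp$wavelengths, bands)
    switch(sp$kind,
           intensity = src[b[1]],
           derivative = src[b[2]] - src[b[1]],
           ratio = if (abs(src[b[2]]) < eps) sentinel else src[b[1]] / src[b[2]])
  }, numeric(1))
  names(out) <- vapply(specs, `[[`, character(1), "name")
  out
}

#' Build the feature table for a cohort of patches
#'
#' Vectorized [extract_features()] over the rows of a patch table, keeping
#' the patient/sample/label bookkeeping columns.
#'
#' @param patches a `patch_table` (rows with label `"excluded"` are dropped).
#' @param bands band table.
#' @param specs feature specs.
#' @param mode see [extract_features()].
#' @return data.frame: patient_id, sample_id, block_row, block_col, label,
#'   then one column per feature.
#' @export
build_feature_table <- function(patches, bands = make_band_table(),
                                specs = default_feature_specs(),
                                mode = "mixed") {
  keep <- patches$label %in% c("tumor", "non_tumor")
  pt <- patches[keep, , drop = FALSE]
  spec_mat <- patch_spectra(pt)
  feats <- t(apply(spec_mat, 1, extract_features, bands = bands,
                   specs = specs, mode = mode))
  if (nrow(pt) == 1) feats <- matrix(feats, nrow = 1,
                                     dimnames = list(NULL, names(
                                       extract_features(spec_mat[1, ], bands,
                                                        specs, mode))))
  out <- cbind(pt[, c("patient_id", "sample_id", "block_row", "block_col",
                      "label")],
               as.data.frame(feats))
  rownames(out) <- NULL
  out
}

#' Welch t-test screen over features
#'
#' Per-feature Welch two-sample t statistic comparing tumor vs non-tumor
#' patches (pooled across patients), ranked by `|t|`.  Provided to reproduce
#' the feature-screening procedure; the default pipeline uses the fixed
#' 19-feature list.
#'
#' @param x numeric matrix, one column per feature.
#' @param labels vector with two classes, each with at least 2 observations.
#' @param positive the positive class (default `"tumor"`).
#' @return data.frame: feature, t, p, rank (1 = largest `|t|`).
#' @export
ttest_screen <- function(x, labels, positive = "tumor") {
  x <- as.matrix(x)
  pos <- labels == positive
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("ttest_screen() needs at least 2 observations per class")
  }
  stat <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[pos, j]; b <- x[!pos, j]
    se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((stats::var(a) / length(a))^2 / (length(a) - 1) +
                     (stats::var(b) / length(b))^2 / (length(b) - 1))
    c(tt, 2 * stats::pt(-abs(tt), df))
  }, numeric(2))
  out <- data.frame(feature = colnames(x), t = stat[1, ], p = stat[2, ])
  out$rank <- rank(-abs(out$t), ties.method = "first")
  out[order(out$rank), ]
}

#' Univariate AUC of a single feature
#'
#' AUC of the feature used directly as a classifier score: the Mann-Whitney U
#' statistic normalized by `n_pos * n_neg`, with average ranks giving ties
#' half credit.  Orientation is chosen so the result is >= 0.5.
#'
#' @param x numeric feature values.
#' @param labels class labels.
#' @param positive positive class.
#' @return AUC in \[0.5, 1\].
#' @export
univariate_auc <- function(x, labels, positive = "tumor") {
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("univariate_auc() needs both classes")
  r <- rank(x)
  a <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  max(a, 1 - a)
}
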