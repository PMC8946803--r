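# Independent oracles and small fixtures used across the test files.

# All-pairs Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(equal).
auc_pairs <- function(scores, labels, positive = "tumor") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force binary erosion by a (2m+1)^2 square, border = invalid.
erode_brute <- function(V, m) {
  R <- nrow(V); C <- ncol(V)
  out <- matrix(FALSE, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    if (i - m < 1 || i + m > R || j - m < 1 || j + m > C) next
    out[i, j] <- all(V[(i - m):(i + m), (j - m):(j + m)])
  }
  out
}

# Direct-arithmetic confusion metrics (independent of the package formulas'
# code path; NA on zero denominators).
metrics_direct <- function(tp, fp, tn, fn) {
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(sensitivity = sdiv(tp, tp + fn), specificity = sdiv(tn, tn + fp),
    ppv = sdiv(tp, tp + fp), npv = sdiv(tn, tn + fn),
    mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den))
}

# A flat noiseless spectral library for exact-identity tests.
exact_library <- function(separation = 1) {
  default_spectral_library(separation = separation, amplitude_sd = 0,
                           noise_sd = 0)
}

# A two-rectangle scene (left region / right region) that survives the
# 20-pixel edge erosion with a predictable block count; used by the reduced
# cohorts of the parameter-recovery tests.
rect_scene <- function(rows = 200, cols = 200, classes, fracs, seed = 1, ...) {
  mid <- cols / 2
  regions <- list(
    list(polygon = cbind(c(5, mid, mid, 5), c(5, 5, rows - 5, rows - 5)),
         class = classes[1], tumor_fraction = fracs[1]),
    list(polygon = cbind(c(mid, cols - 5, cols - 5, mid),
                         c(5, 5, rows - 5, rows - 5)),
         class = classes[2], tumor_fraction = fracs[2]))
  scene_spec(rows, cols, regions, seed = seed, ...)
}

# Reduced cohort: n patients x 1 sample, two rectangular regions per scene
# (tumor left unless the patient is tumor-free), single non-tumor class so
# that separation = 0 is a true null.
rect_cohort <- function(n_patients = 10, separation = 1, seed = 1,
                        tumor_free = integer(0), rows = 200, cols = 200) {
  bands <- make_band_table()
  lib <- default_spectral_library(bands, separation = separation,
                                  heterogeneous = FALSE)
  samples <- vector("list", n_patients)
  manifest <- NULL
  seeds <- withr::with_seed(seed, sample.int(2147483646L, n_patients))
  for (p in seq_len(n_patients)) {
    has_tumor <- !(p %in% tumor_free)
    sc <- rect_scene(rows, cols,
                     classes = c("connective", "connective"),
                     fracs = if (has_tumor) c(1, 0) else c(0, 0),
                     seed = seeds[p])
    smp <- render_sample(sc, lib, bands)
    smp$patient_id <- sprintf("P%02d", p)
    smp$sample_id <- "A"
    smp$organ <- "ovary"
    samples[[p]] <- smp
    manifest <- rbind(manifest, data.frame(patient_id = smp$patient_id,
                                           sample_id = "A", organ = "ovary"))
  }
  structure(list(samples = samples, manifest = manifest, bands = bands,
                 library = lib, sim = list(), seed = seed),
            class = "hsi_cohort")
}

# Patch-level (no imaging) labelled feature fixture for classifier tests:
# Gaussian blobs per class, optional per-patient structure.
toy_patches <- function(n_per_class = 30, n_patients = 3, shift = 3,
                        seed = 1, tumor_free = integer(0)) {
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_patients)) {
      nt <- if (p %in% tumor_free) 0 else n_per_class
      nn <- n_per_class
      x <- rbind(matrix(rnorm(nt * 2, mean = shift), ncol = 2),
                 matrix(rnorm(nn * 2, mean = 0), ncol = 2))
      rows[[p]] <- data.frame(patient = sprintf("P%02d", p),
                              label = c(rep("tumor", nt),
                                        rep("non_tumor", nn)),
                              f1 = x[, 1], f2 = x[, 2])
    }
    do.call(rbind, rows)
  })
}
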