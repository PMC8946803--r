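# The 19-feature set, its invariances, and the univariate screens.

bt <- make_band_table()

test_that("the default feature set is the 19-feature list", {
  specs <- default_feature_specs()
  kinds <- vapply(specs, `[[`, character(1), "kind")
  expect_length(specs, 19)
  expect_equal(unname(table(kinds)[c("intensity", "derivative", "ratio")]),
               c(9L, 4L, 6L), ignore_attr = TRUE)
  f <- extract_features(runif(25, 0.2, 0.8), bt)
  expect_length(f, 19)
  expect_identical(names(f)[1], "i697")
  expect_identical(names(f)[19], "q930_910")
})

test_that("feature definitions collapse correctly on constant spectra", {
  f <- extract_features(rep(0.3, 25), bt, mode = "reflectance")
  expect_true(all(f[grep("^i", names(f))] == 0.3))
  expect_true(all(f[grep("^d", names(f))] == 0))
  expect_true(all(f[grep("^q", names(f))] == 1))
})

test_that("scaling the spectrum moves intensities but not ratios", {
  set.seed(5)
  x <- runif(25, 0.2, 0.8)
  f1 <- extract_features(x, bt, mode = "reflectance")
  f2 <- extract_features(2 * x, bt, mode = "reflectance")
  q <- grep("^q", names(f1))
  iv <- grep("^[id]", names(f1))
  expect_equal(f2[q], f1[q])            # ratios are scale-free
  expect_equal(f2[iv], 2 * f1[iv])      # intensities/derivatives scale
  # in mixed mode the normalized intensities become scale-free as well;
  # derivatives stay on the reflectance scale and therefore still scale
  m1 <- extract_features(x, bt, mode = "mixed")
  m2 <- extract_features(2 * x, bt, mode = "mixed")
  iq <- grep("^[iq]", names(m1))
  expect_equal(m1[iq], m2[iq])
  expect_equal(m2[grep("^d", names(m1))], 2 * m1[grep("^d", names(m1))])
})

test_that("near-zero ratio denominators yield the sentinel", {
  x <- rep(0.5, 25)
  x[which(bt$centers_nm == 910)] <- 0
  f <- extract_features(x, bt, mode = "reflectance")
  expect_true(all(is.na(f[grep("^q", names(f))])))
})

test_that("Welch screen matches the direct formula and ranks separation first", {
  set.seed(17)
  n <- 40
  labels <- rep(c("tumor", "non_tumor"), each = n)
  x <- cbind(sep = c(rnorm(n, 3, 0.1), rnorm(n, 0, 0.1)),
             null = rnorm(2 * n))
  out <- ttest_screen(x, labels)
  expect_identical(out$feature[1], "sep")
  # oracle: stats::t.test Welch statistic
  for (j in 1:2) {
    tt <- stats::t.test(x[labels == "tumor", j], x[labels != "tumor", j])
    expect_equal(out$t[out$feature == colnames(x)[j]],
                 unname(tt$statistic), tolerance = 1e-12)
  }
  # identical distributions give t = 0; ranking is scale-invariant
  same <- cbind(a = rep(c(1, 2, 3), 4))
  expect_equal(ttest_screen(same, rep(c("tumor", "non_tumor"), 6))$t, 0)
  out2 <- ttest_screen(x * 100, labels)
  expect_identical(out$feature, out2$feature)
  expect_error(ttest_screen(x, rep("tumor", 2 * n)), "class")
})

test_that("univariate AUC equals the pair-enumeration oracle", {
  expect_equal(univariate_auc(c(3, 4, 1, 2),
                              c("tumor", "tumor", "non_tumor", "non_tumor")), 1)
  # pair enumeration for {pos: 1,3; neg: 2,4}: wins (3,2) only -> 0.25,
  # oriented to >= 0.5 gives 0.75
  expect_equal(univariate_auc(c(1, 3, 2, 4),
                              c("tumor", "tumor", "non_tumor", "non_tumor")), 0.75)
  expect_equal(univariate_auc(c(1, 4, 2, 3),
                              c("tumor", "tumor", "non_tumor", "non_tumor")), 0.5)
  set.seed(23)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    labels <- sample(c("tumor", "non_tumor"), n, replace = TRUE,
                     prob = c(0.3, 0.7))
    if (length(unique(labels)) < 2) next
    x <- sample(round(rnorm(n), 1))  # rounded -> ties occur
    a <- auc_pairs(x, labels)
    expect_equal(univariate_auc(x, labels), max(a, 1 - a), tolerance = 1e-12)
  }
  expect_error(univariate_auc(1:4, rep("tumor", 4)), "class")
})
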