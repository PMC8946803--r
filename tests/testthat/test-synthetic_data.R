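# Generator: spectra, rendering, cohort bookkeeping, determinism.

test_that("sample_spectrum reduces to exact endmember mixtures at zero noise", {
  lib <- exact_library()
  em <- lib$endmembers
  expect_equal(sample_spectrum(lib, "connective", 0, seed = 1),
               em$connective)
  expect_equal(sample_spectrum(lib, "connective", 1, seed = 1), em$tumor)
  expect_equal(sample_spectrum(lib, "fat", 0.5, seed = 1),
               0.5 * em$tumor + 0.5 * em$fat)
  expect_error(sample_spectrum(lib, "nope"), "unknown")
})

test_that("same-class spectra run in parallel when band noise is off", {
  lib <- default_spectral_library(amplitude_sd = 0.3, noise_sd = 0)
  s1 <- sample_spectrum(lib, "stroma", seed = 11)
  s2 <- sample_spectrum(lib, "stroma", seed = 12)
  ratio <- s1 / s2
  expect_lt(diff(range(ratio)), 1e-12)  # one multiplicative constant
})

test_that("rendered glare pixel count follows Bernoulli sampling", {
  lib <- exact_library()
  sc <- rect_scene(100, 100, c("connective", "fat"), c(0, 0), seed = 5,
                   glare_fraction = 0.02, sensor_noise_sd = 0)
  smp <- render_sample(sc, lib)
  cube <- demosaic(smp$raw, smp$bands)
  sat_px <- apply(cube$data == sc$saturation, c(1, 2), all)
  n <- sum(sat_px)
  # 10,000 pixels at p = 0.02: expect 200 +/- 5 binomial sds (= 70)
  expect_gt(n, 130)
  expect_lt(n, 270)
})

test_that("regions with 1-50% tumor cells are marked mixed in the truth mask", {
  lib <- exact_library()
  sc <- rect_scene(100, 100, c("connective", "connective"), c(0.3, 0.8),
                   seed = 2, glare_fraction = 0)
  smp <- render_sample(sc, lib)
  expect_true(any(smp$truth == 3))           # mixed region present
  expect_true(any(smp$truth == 2))           # tumor region present
  # left half (cols < 100 in scene coords) is the 0.3 region
  expect_true(all(smp$truth[, 10:40] %in% c(0, 3)))
  expect_true(all(smp$truth[, 60:90] %in% c(0, 2)))
})

test_that("noiseless render is inverted exactly by demosaic + calibrate", {
  lib <- exact_library()
  sc <- rect_scene(60, 60, c("connective", "fat"), c(1, 0), seed = 3,
                   glare_fraction = 0, sensor_noise_sd = 0, quantize = FALSE,
                   illumination_gradient = 0.4)
  smp <- render_sample(sc, lib, keep_reflectance = TRUE)
  cube <- calibrate(demosaic(smp$raw, smp$bands),
                    reference_set(demosaic(smp$white, smp$bands),
                                  demosaic(smp$dark, smp$bands)))
  expect_lt(max(abs(cube$data - smp$reflectance)), 1e-10)
  expect_identical(cube$stage, "reflectance")
})

test_that("cohort generation books samples correctly and is deterministic", {
  sim <- default_sim_config(n_patients = 2, samples_per_patient = c(2, 1),
                            tumor_free_patients = 2,
                            scene_rows = 60, scene_cols = 60)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(d1, sim, seed = 9)
  m2 <- generate_cohort(d2, sim, seed = 9)
  expect_equal(nrow(m1), 3)
  expect_equal(sort(unique(m1$patient_id)), c("P01", "P02"))
  # byte-identical outputs for identical (config, seed)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, m1$raw[1])),
                   readLines(file.path(d2, m2$raw[1])))
  # refusing to clobber without force
  expect_error(generate_cohort(d1, sim, seed = 9), "force")
  # tumor-free patient has no tumor-labelled pixels in any truth mask
  for (k in which(m1$patient_id == "P02")) {
    expect_false(any(read_pgm(file.path(d1, m1$truth[k])) == 2))
  }
  # disk round trip preserves the frames
  co <- read_cohort(d1)
  sim_mem <- simulate_cohort(sim, seed = 9)
  expect_equal(co$samples[[1]]$raw, sim_mem$samples[[1]]$raw)
  expect_equal(co$samples[[1]]$annotation, sim_mem$samples[[1]]$annotation)
})

test_that("scene specification rejects invalid configurations", {
  regions <- list(list(polygon = cbind(c(1, 20, 20, 1), c(1, 1, 20, 20)),
                       class = "connective", tumor_fraction = 0))
  expect_error(scene_spec(50, 50, regions, glare_fraction = 1.5), "glare")
  bad <- list(list(polygon = cbind(c(1, 80, 80, 1), c(1, 1, 20, 20)),
                   class = "connective", tumor_fraction = 0))
  expect_error(scene_spec(50, 50, bad), "fit")
})
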