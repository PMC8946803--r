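# Demosaicing, calibration, normalization, masking, erosion, patching.

bt <- make_band_table()

test_that("demosaic separates the 5x5 mosaic without interpolation", {
  # mosaic whose value at each cell position is the band index
  frame <- matrix(0, 10, 10)
  offs <- bt$mosaic_offsets
  for (b in 1:25) {
    frame[cbind(offs$row_off[b] + c(1, 6, 1, 6),
                offs$col_off[b] + c(1, 1, 6, 6))] <- b
  }
  cube <- demosaic(frame, bt)
  expect_identical(dim(cube$data), c(2L, 2L, 25L))
  for (b in 1:25) expect_true(all(cube$data[, , b] == b))
  # round trip on a multiple-of-5 frame
  rnd <- matrix(rnorm(100), 10, 10)
  expect_equal(remosaic(demosaic(rnd, bt)), rnd)
})

test_that("demosaic floors the output size and warns on trailing pixels", {
  frame <- matrix(0, 2050, 1080)
  expect_silent(cube <- demosaic(frame, bt))
  expect_identical(dim(cube$data)[1:2], c(410L, 216L))
  expect_warning(demosaic(matrix(0, 52, 51), bt), "dropping")
})

test_that("calibration maps the references to 0/1 and is affine in the raw", {
  d <- c(4L, 4L, 25L)
  white <- array(9, d); dark <- array(1, d)
  refs <- reference_set(white, dark)
  as_cube <- function(a) hypercube(a, bt, "raw")
  expect_true(all(calibrate(as_cube(white), refs)$data == 1))
  expect_true(all(calibrate(as_cube(dark), refs)$data == 0))
  expect_true(all(calibrate(as_cube(array(5, d)), refs)$data == 0.5))
  # affine in I_raw: raw = dark + t (white - dark) -> reflectance t
  t0 <- 0.37
  raw <- array(1 + t0 * 8, d)
  expect_equal(max(abs(calibrate(as_cube(raw), refs)$data - t0)), 0, tolerance = 1e-12)
  expect_error(calibrate(as_cube(array(1, c(3, 3, 25))), refs), "match")
})

test_that("calibration flags invalid-reference pixels and zeroes them", {
  d <- c(3L, 3L, 25L)
  white <- array(9, d); dark <- array(1, d)
  white[2, 2, ] <- 1  # white == dark at one pixel
  cube <- calibrate(hypercube(array(5, d), bt, "raw"),
                    suppressWarnings(reference_set(white, dark)))
  inv <- attr(cube, "invalid")
  expect_identical(which(inv), 5L)
  expect_true(all(cube$data[2, 2, ] == 0))
})

test_that("min-max normalization pins [0,1] and ignores affine transforms", {
  x <- c(2, 4, 6, seq(2, 6, length.out = 22))
  n <- minmax_normalize(x)
  expect_equal(n[1:3], c(0, 0.5, 1))
  expect_equal(minmax_normalize(n), n, ignore_attr = TRUE)          # idempotent
  expect_equal(minmax_normalize(3 * x + 7), n, ignore_attr = TRUE)  # affine invariant
  flat <- minmax_normalize(rep(2, 25))
  expect_true(attr(flat, "degenerate"))
  expect_true(all(flat == 0))
  # matrix form agrees with row-wise application
  m <- matrix(rnorm(100), 4, 25)
  mm <- minmax_normalize(m)
  for (i in 1:4) {
    expect_equal(mm[i, ], as.numeric(minmax_normalize(m[i, ])))
  }
})

test_that("validity mask applies the max-glare and mean-background rules", {
  d <- c(6L, 6L, 25L)
  a <- array(0.5, d)
  a[1, 1, 13] <- 0.99      # single saturated band -> glare
  a[2, 2, ] <- 0.05        # dim spectrum -> background
  cube <- hypercube(a, bt, "reflectance")
  mask <- make_validity_mask(cube, glare_thr = 0.95, bg_thr = 0.10)
  expect_identical(mask$reason[1, 1], 2L)
  expect_identical(mask$reason[2, 2], 1L)
  expect_equal(sum(!mask$valid), 2)
  expect_error(make_validity_mask(cube, glare_thr = 0.05, bg_thr = 0.10),
               "exceed")
})

test_that("background regions of a rendered scene are flagged against truth", {
  lib <- exact_library()
  sc <- rect_scene(80, 80, c("connective", "fat"), c(0, 0), seed = 4,
                   glare_fraction = 0)
  smp <- render_sample(sc, lib)
  cube <- calibrate(demosaic(smp$raw, smp$bands),
                    reference_set(demosaic(smp$white, smp$bands),
                                  demosaic(smp$dark, smp$bands)))
  mask <- make_validity_mask(cube)
  bg_truth <- smp$truth == 0
  expect_gt(mean(mask$reason[bg_truth] == 1), 0.99)
  expect_gt(mean(mask$valid[!bg_truth]), 0.99)
})

test_that("edge erosion matches geometry and the brute-force oracle", {
  all_valid <- structure(list(valid = matrix(TRUE, 60, 60),
                              reason = matrix(0L, 60, 60)),
                         class = "validity_mask")
  er <- erode_edges(all_valid, 20)
  expect_equal(sum(er$valid), 400)
  expect_true(all(er$valid[21:40, 21:40]))
  expect_identical(erode_edges(all_valid, 0), all_valid)
  # random disconnected mask vs brute force (strict erosion of the valid set)
  set.seed(31)
  V <- matrix(runif(40 * 40) > 0.3, 40, 40)
  mask <- structure(list(valid = V, reason = matrix(0L, 40, 40)),
                    class = "validity_mask")
  for (m in c(1, 3)) {
    expect_identical(erode_edges(mask, m, support = "valid")$valid,
                     V & erode_brute(V, m))
  }
  # newly removed pixels carry the edge reason code
  er2 <- erode_edges(mask, 2, support = "valid")
  expect_true(all(er2$reason[V & !er2$valid] == 3L))
})

test_that("patch averaging obeys the grid, the purity rule and the pixel oracle", {
  d <- c(40L, 40L, 25L)
  cube <- hypercube(array(0.4, d), bt, "reflectance")
  mask <- structure(list(valid = matrix(TRUE, 40, 40),
                         reason = matrix(0L, 40, 40)), class = "validity_mask")
  ann <- matrix(2L, 40, 40)  # all tumor
  pt <- patch_average(cube, mask, ann, block = 20)
  expect_equal(nrow(pt), 4)
  expect_true(all(pt$label == "tumor"))
  expect_true(all(abs(patch_spectra(pt) - 0.4) < 1e-12))

  # a half tumor / half non-tumor block is excluded
  ann2 <- ann; ann2[1:10, 1:20] <- 1L
  pt2 <- patch_average(cube, mask, ann2, block = 20)
  expect_identical(pt2$label[pt2$block_row == 0 & pt2$block_col == 0],
                   "excluded")
  # any mixed contact excludes too
  ann3 <- ann; ann3[5, 5] <- 3L
  pt3 <- patch_average(cube, mask, ann3, block = 20)
  expect_identical(pt3$label[pt3$block_row == 0 & pt3$block_col == 0],
                   "excluded")

  # random cube + random mask against a per-pixel summation oracle
  set.seed(8)
  a <- array(runif(prod(d)), d)
  V <- matrix(runif(1600) > 0.25, 40, 40)
  cube_r <- hypercube(a, bt, "reflectance")
  mask_r <- structure(list(valid = V, reason = matrix(0L, 40, 40)),
                      class = "validity_mask")
  pt_r <- patch_average(cube_r, mask_r, ann, block = 20,
                        min_valid_fraction = 0)
  for (i in seq_len(nrow(pt_r))) {
    rr <- pt_r$block_row[i] * 20 + (1:20)
    cc <- pt_r$block_col[i] * 20 + (1:20)
    sub_v <- V[rr, cc]
    oracle <- vapply(1:25, function(b) mean(a[rr, cc, b][sub_v]), numeric(1))
    expect_equal(as.numeric(patch_spectra(pt_r)[i, ]), oracle)
  }

  # mass conservation: sum(mean * n_valid) == sum over valid pixels
  lhs <- colSums(patch_spectra(pt_r) * pt_r$n_valid)
  rhs <- vapply(1:25, function(b) sum(a[, , b][V]), numeric(1))
  expect_equal(lhs, rhs, ignore_attr = TRUE, tolerance = 1e-8)

  # nothing retained -> empty table with warning, not an error
  none <- structure(list(valid = matrix(FALSE, 40, 40),
                         reason = matrix(1L, 40, 40)), class = "validity_mask")
  expect_warning(pt0 <- patch_average(cube, none, ann), "no retained")
  expect_equal(nrow(pt0), 0)
})
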