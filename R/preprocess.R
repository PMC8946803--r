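# Preprocessing: demosaic -> calibrate -> normalize -> mask -> erode -> patch.

#' Construct a hypercube
#'
#' Thin container for a rows x cols x 25 intensity array, its band table and a
#' processing-stage tag (`raw`, `reflectance` or `normalized`).
#'
#' @param data 3-D numeric array, third dimension 25.
#' @param bands band table.
#' @param stage processing stage tag.
#' @return object of class `hypercube`.
#' @export
hypercube <- function(data, bands, stage = c("raw", "reflectance", "normalized")) {
  stage <- match.arg(stage)
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(bands$centers_nm))
  structure(list(data = data, bands = bands, stage = stage),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hypercube: %d x %d pixels, %d bands, stage=%s\n",
              d[1], d[2], d[3], x$stage))
  invisible(x)
}

#' Demosaic a raw snapshot-mosaic frame
#'
#' Rearranges the interleaved 5x5 mosaic into 25 per-band images, with no
#' interpolation: band `b` at demosaiced pixel (i,j) is the mosaic value at
#' `(5(i-1) + row_off_b + 1, 5(j-1) + col_off_b + 1)`.  The output spatial size
#' is `floor(H/5) x floor(W/5)`; trailing rows/columns beyond a multiple of 5
#' are dropped with a warning.
#'
#' @param frame numeric matrix, the raw mosaic (also used for white and dark
#'   reference frames).
#' @param bands band table carrying the mosaic offsets.
#' @return a `hypercube` with stage `"raw"`.
#' @export
demosaic <- function(frame, bands = make_band_table()) {
  stopifnot(is.matrix(frame), nrow(frame) >= 5, ncol(frame) >= 5)
  H <- nrow(frame); W <- ncol(frame)
  R <- H %/% 5L; C <- W %/% 5L
  if (H %% 5L != 0L || W %% 5L != 0L) {
    warning("frame size ", H, "x", W, " is not a multiple of 5; dropping ",
            H %% 5L, " trailing row(s) and ", W %% 5L, " trailing column(s)")
  }
  offs <- bands$mosaic_offsets
  cube <- .demosaic_core(frame, offs$row_off, offs$col_off, R, C)
  hypercube(cube, bands, "raw")
}

#' Reassemble a mosaic frame from a demosaiced cube (inverse of [demosaic()])
#' @param cube a raw-stage `hypercube`.
#' @return numeric matrix of size `5*rows x 5*cols`.
#' @export
remosaic <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  offs <- cube$bands$mosaic_offsets
  .remosaic_core(cube$data, offs$row_off, offs$col_off, d[1], d[2])
}

#' Pair white and dark reference cubes
#'
#' Validates that white exceeds dark on at least 99% of entries (pixels where
#' it does not are later flagged `invalid_reference` by [calibrate()]).
#'
#' @param white,dark rows x cols x 25 arrays or raw `hypercube`s.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(white, dark) {
  w <- if (inherits(white, "hypercube")) white$data else white
  d <- if (inherits(dark, "hypercube")) dark$data else dark
  stopifnot(identical(dim(w), dim(d)))
  frac <- mean(w > d)
  if (frac < 0.99) {
    warning(sprintf("white exceeds dark on only %.1f%% of entries", 100 * frac))
  }
  structure(list(white = w, dark = d), class = "reference_set")
}

#' Reference calibration to relative reflectance
#'
#' Computes `(raw - dark) / (white - dark)` per pixel per band, removing the
#' illumination field and the dark-current offset.  Entries whose denominator
#' is not larger than `eps` are set to 0 and the pixel is flagged
#' `invalid_reference` (retrievable via `attr(, "invalid")`).
#'
#' @param raw a raw-stage `hypercube`.
#' @param refs a [reference_set()] (or list with `white`/`dark` arrays).
#' @param eps positive guard for the denominator.
#' @return a `hypercube` with stage `"reflectance"` and an `"invalid"` logical
#'   matrix attribute marking invalid-reference pixels.
#' @export
calibrate <- function(raw, refs, eps = 1e-6) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$stage != "raw") stop("calibrate() expects a raw-stage hypercube")
  w <- refs$white; d <- refs$dark
  if (!identical(dim(raw$data), dim(w)) || !identical(dim(raw$data), dim(d))) {
    stop("raw and reference shapes do not match")
  }
  dm <- dim(raw$data)
  res <- .calibrate_core(raw$data, w, d, eps, dm[1] * dm[2], dm[3])
  cube <- hypercube(array(res$data, dm), raw$bands, "reflectance")
  attr(cube, "invalid") <- matrix(res$invalid, dm[1], dm[2])
  cube
}

#' Min-max normalize spectra to \[0, 1\]
#'
#' Rescales each spectrum across its 25 bands to minimum 0 and maximum 1,
#' which removes amplitude and leaves only the shape of the spectral
#' signature.  Invariant under positive affine transforms of the input.  Flat
#' spectra (max == min) cannot be rescaled: they come back as all zeros and
#' are flagged in the `"degenerate"` attribute.
#'
#' @param x numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return same shape as `x`, each spectrum in \[0,1\]; attribute
#'   `"degenerate"` is a logical (vector) marking flat spectra.
#' @export
minmax_normalize <- function(x) {
  if (is.matrix(x)) {
    lo <- do.call(pmin, as.data.frame(x))
    hi <- do.call(pmax, as.data.frame(x))
    rng <- hi - lo
    deg <- rng == 0
    rng[deg] <- 1
    out <- (x - lo) / rng
    out[deg, ] <- 0
    attr(out, "degenerate") <- deg
    return(out)
  }
  stopifnot(all(is.finite(x)))
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - lo) / (hi - lo)
  attr(out, "degenerate") <- FALSE
  out
}

VALIDITY_CODES <- c(none = 0L, background = 1L, glare = 2L, edge = 3L,
                    invalid_reference = 4L)

#' Flag glare, background and invalid-reference pixels
#'
#' A pixel is glare when its maximum reflectance over the 25 bands exceeds
#' `glare_thr`, background when its mean reflectance falls below `bg_thr`
#' (tissue sits on near-black paper), and invalid-reference when [calibrate()]
#' flagged it.  Each excluded pixel carries exactly one reason code
#' (precedence: invalid_reference > glare > background).
#'
#' @param cube a reflectance-stage `hypercube`.
#' @param glare_thr reflectance ceiling above which a pixel is glare.
#' @param bg_thr mean-reflectance floor below which a pixel is background.
#' @return object of class `validity_mask`: list with logical matrix `valid`
#'   and integer matrix `reason` (codes in `VALIDITY_CODES`).
#' @export
make_validity_mask <- function(cube, glare_thr = 0.95, bg_thr = 0.10) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$stage != "reflectance") {
    stop("make_validity_mask() expects a reflectance-stage hypercube")
  }
  if (glare_thr <= bg_thr) stop("glare_thr must exceed bg_thr")
  d <- dim(cube$data)
  st <- .band_stats_core(cube$data, d[1] * d[2], d[3])
  reason <- matrix(VALIDITY_CODES[["none"]], d[1], d[2])
  reason[matrix(st$mean < bg_thr, d[1], d[2])] <- VALIDITY_CODES[["background"]]
  reason[matrix(st$max > glare_thr, d[1], d[2])] <- VALIDITY_CODES[["glare"]]
  inv <- attr(cube, "invalid")
  if (!is.null(inv)) reason[inv] <- VALIDITY_CODES[["invalid_reference"]]
  structure(list(valid = reason == VALIDITY_CODES[["none"]], reason = reason),
            class = "validity_mask")
}

#' Remove tissue edges by morphological erosion
#'
#' Erodes with a square structuring element of radius `margin` (window
#' `(2*margin+1)^2`, image border counts as outside), because pixels near a
#' tissue edge are likely to carry mixed spectra.  Pixels that were valid but
#' whose window is not fully inside the support get reason code `edge`.
#' Disconnected components are eroded independently, as erosion is a purely
#' local operation.
#'
#' With the default `support = "tissue"` the eroded set is the tissue extent
#' (everything except background), so that isolated glare pixels inside a
#' tissue region stay individually excluded without carving out a whole
#' erosion window around themselves.  `support = "valid"` erodes the valid
#' set itself (strict morphological erosion of the mask).
#'
#' @param mask a `validity_mask`.
#' @param margin erosion radius in pixels (default 20); 0 is the identity.
#' @param support `"tissue"` (default) or `"valid"`, see above.
#' @return the eroded `validity_mask`.
#' @export
erode_edges <- function(mask, margin = 20, support = c("tissue", "valid")) {
  stopifnot(inherits(mask, "validity_mask"), margin >= 0)
  support <- match.arg(support)
  if (margin == 0) return(mask)
  V <- if (support == "valid") mask$valid
       else mask$reason != VALIDITY_CODES[["background"]]
  keep <- .erode_core(V, as.integer(margin))
  newly <- mask$valid & !keep
  reason <- mask$reason
  reason[newly] <- VALIDITY_CODES[["edge"]]
  structure(list(valid = mask$valid & keep, reason = reason),
            class = "validity_mask")
}

# Purity rule shared by patch_average() and label_patches(): a block is
# "tumor"/"non_tumor" when all its annotated contributing pixels agree and
# none is "mixed"; any mixed pixel, disagreement, or absence of annotation
# makes it "excluded".
block_label <- function(n_tumor, n_non_tumor, n_mixed) {
  ifelse(n_mixed > 0, "excluded",
         ifelse(n_tumor > 0 & n_non_tumor > 0, "excluded",
                ifelse(n_tumor > 0, "tumor",
                       ifelse(n_non_tumor > 0, "non_tumor", "excluded"))))
}

#' Average spectra over a fixed 20x20 block grid
#'
#' Divides the image into a grid of `block x block` pixel blocks anchored at
#' the origin and averages the spectra of the valid pixels inside each block,
#' increasing robustness to registration error.  A block is retained when its
#' valid-pixel fraction reaches `min_valid_fraction`; its label follows the
#' purity rule: all valid annotated pixels must agree on tumor or non_tumor,
#' any contact with a "mixed" annotation (1--50% tumor cells) excludes the
#' block.
#'
#' @param cube a reflectance (or normalized) `hypercube`.
#' @param mask a `validity_mask` of matching size.
#' @param annotation integer label matrix in hypercube coordinates
#'   (codes 0 unannotated / 1 non_tumor / 2 tumor / 3 mixed).
#' @param block block edge length in pixels (default 20).
#' @param min_valid_fraction minimum fraction of valid pixels for a block to
#'   be retained (relative to the block's own pixel count; boundary blocks may
#'   be smaller).
#' @param patient_id,sample_id identifiers copied into the table.
#' @return data.frame of class `patch_table`: patient_id, sample_id,
#'   block_row, block_col (0-based), n_pixels, n_valid, label, and one
#'   `r<center>` column per band with the mean reflectance.  Empty (with a
#'   warning) when nothing is retained.
#' @export
patch_average <- function(cube, mask, annotation, block = 20,
                          min_valid_fraction = 0.8,
                          patient_id = "P01", sample_id = "A") {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "validity_mask"),
            block >= 1)
  d <- dim(cube$data)
  stopifnot(identical(dim(mask$valid), d[1:2]),
            identical(dim(annotation), d[1:2]))
  R <- d[1]; C <- d[2]; nb <- d[3]
  brow <- (seq_len(R) - 1L) %/% block
  bcol <- (seq_len(C) - 1L) %/% block
  nbr <- max(brow) + 1L; nbc <- max(bcol) + 1L
  nblocks <- nbr * nbc
  ids <- outer(brow, bcol, function(a, b) a * nbc + b + 1L)  # R x C

  n_pixels <- tabulate(as.vector(ids), nbins = nblocks)
  v <- as.vector(mask$valid)
  ids_v <- as.vector(ids)[v]
  n_valid <- tabulate(ids_v, nbins = nblocks)

  ann_v <- as.vector(annotation)[v]
  n_t <- tabulate(ids_v[ann_v == LABEL_CODES[["tumor"]]], nbins = nblocks)
  n_nt <- tabulate(ids_v[ann_v == LABEL_CODES[["non_tumor"]]], nbins = nblocks)
  n_mx <- tabulate(ids_v[ann_v == LABEL_CODES[["mixed"]]], nbins = nblocks)
  labels <- block_label(n_t, n_nt, n_mx)

  keep <- n_valid > 0 & n_valid / n_pixels >= min_valid_fraction
  band_cols <- paste0("r", cube$bands$centers_nm)
  meta_cols <- c("patient_id", "sample_id", "block_row", "block_col",
                 "n_pixels", "n_valid", "label")
  if (!any(keep)) {
    warning("no retained patches for ", patient_id, "/", sample_id)
    empty <- as.data.frame(c(
      list(patient_id = character(0), sample_id = character(0),
           block_row = integer(0), block_col = integer(0),
           n_pixels = integer(0), n_valid = integer(0), label = character(0)),
      stats::setNames(rep(list(numeric(0)), nb), band_cols)))
    return(structure(empty, class = c("patch_table", "data.frame")))
  }

  m <- matrix(cube$data, R * C, nb)[v, , drop = FALSE]
  sums <- rowsum(m, ids_v)
  got <- as.integer(rownames(sums))
  means <- matrix(NA_real_, nblocks, nb)
  means[got, ] <- sums / n_valid[got]

  idx <- which(keep)
  df <- data.frame(patient_id = patient_id, sample_id = sample_id,
                   block_row = (idx - 1L) %/% nbc,
                   block_col = (idx - 1L) %% nbc,
                   n_pixels = n_pixels[idx], n_valid = n_valid[idx],
                   label = labels[idx], stringsAsFactors = FALSE)
  spec <- as.data.frame(means[idx, , drop = FALSE])
  names(spec) <- band_cols
  out <- cbind(df, spec)
  structure(out, class = c("patch_table", "data.frame"))
}

#' Extract the patch-mean spectra matrix from a patch table
#' @param pt a `patch_table`.
#' @return numeric matrix, one row per patch, 25 band columns.
#' @export
patch_spectra <- function(pt) {
  as.matrix(pt[, grep("^r[0-9]+$", names(pt)), drop = FALSE])
}
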