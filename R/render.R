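# Rendering a synthetic sample: reflectance scene -> raw mosaic + references
# + annotation image + ground truth.

# Label codes shared across the package (also the PGM palette for masks):
# 0 unannotated/background, 1 non_tumor, 2 tumor, 3 mixed.
LABEL_CODES <- c(unannotated = 0L, non_tumor = 1L, tumor = 2L, mixed = 3L)

ANNOTATION_COLORS <- list(
  tumor      = c(128L, 0L, 32L),    # bordeaux
  non_tumor  = c(0L, 0L, 255L),     # blue
  mixed      = c(0L, 160L, 0L),     # green marker for partially tumorous areas
  background = c(255L, 255L, 255L)  # unannotated
)

region_label_code <- function(tumor_fraction) {
  if (tumor_fraction > 0.5) LABEL_CODES[["tumor"]]
  else if (tumor_fraction > 0) LABEL_CODES[["mixed"]]
  else LABEL_CODES[["non_tumor"]]
}

#' Render one synthetic hyperspectral sample
#'
#' Renders a [scene_spec()] into the artifacts the camera workflow produces:
#' a raw snapshot-mosaic frame, white and dark reference frames (all
#' `5*rows x 5*cols`), an RGB annotation image (in its own, affinely
#' misaligned, "histology" frame), a control-point list linking the two
#' frames, and the ground-truth label mask in hyperspectral coordinates.
#'
#' The forward model per band is
#' `raw = illumination * white_level * reflectance + dark_current + noise`,
#' written in mosaic layout; the white frame images a unit-reflectance paper
#' (`illumination * white_level + dark + noise`) and the dark frame is
#' `dark + noise`, so reference calibration inverts the model exactly when all
#' noise is off.  Glare pixels are drawn per demosaiced pixel as i.i.d.
#' Bernoulli(`glare_fraction`) and set to the saturation value across the whole
#' 5x5 mosaic cell.
#'
#' @param scene a [scene_spec()].
#' @param library a [spectral_library()]; region spectra are drawn per pixel
#'   with one amplitude multiplier per spectrum.
#' @param bands band table.
#' @param keep_reflectance also return the noiseless-geometry reflectance cube
#'   that was rendered (for inversion tests).
#' @return a list of class `hsi_sample` with elements `raw`, `white`, `dark`
#'   (matrices), `annotation` (rows x cols x 3 integer array),
#'   `control_points` (data.frame x_src,y_src,x_dst,y_dst, 0-based),
#'   `truth` (integer label matrix, codes 0/1/2/3), `bands`, `scene`.
#' @export
render_sample <- function(scene, library, bands = make_band_table(),
                          keep_reflectance = FALSE) {
  stopifnot(inherits(scene, "scene_spec"), inherits(library, "spectral_library"))
  with_seed(scene$seed, {
    R <- scene$rows; C <- scene$cols; nb <- 25L
    npx <- R * C
    xs <- matrix(rep(seq_len(C) - 0.5, each = R), R, C)   # pixel-center x
    ys <- matrix(rep(seq_len(R) - 0.5, times = C), R, C)  # pixel-center y

    draw_pixels <- function(endmember, n) {
      amp <- exp(rnorm(n, 0, library$amplitude_sd))
      m <- outer(amp, endmember)
      if (library$noise_sd > 0) {
        m <- clip01(m + rnorm(n * nb, 0, library$noise_sd))
      } else if (library$amplitude_sd > 0) {
        m <- clip01(m)
      }
      m
    }

    refl <- matrix(0, npx, nb)
    truth <- matrix(LABEL_CODES[["unannotated"]], R, C)
    covered <- logical(npx)
    for (rg in scene$regions) {
      inside <- point_in_polygon(as.vector(xs), as.vector(ys), rg$polygon)
      idx <- which(inside)
      if (!length(idx)) next
      f <- rg$tumor_fraction
      base <- library$endmembers[[rg$class]]
      mix <- if (f > 0) f * library$endmembers[["tumor"]] + (1 - f) * base else base
      refl[idx, ] <- draw_pixels(mix, length(idx))
      truth[idx] <- region_label_code(f)
      covered[idx] <- TRUE
    }
    bg <- which(!covered)  # black-paper background
    refl[bg, ] <- draw_pixels(library$endmembers[["paper"]], length(bg))

    # smooth radial illumination fall-off, shared by raw and white frames
    g <- scene$illumination_gradient
    u <- (xs - C / 2) / (C / 2); v <- (ys - R / 2) / (R / 2)
    illum <- 1 - g * (u^2 + v^2) / 2

    glare <- matrix(runif(npx) < scene$glare_fraction, R, C)

    finish <- function(m) {
      .finish_frame_core(m, scene$sensor_noise_sd, scene$saturation,
                         scene$quantize)
    }

    offs <- bands$mosaic_offsets
    wsig <- illum * scene$white_level
    raw <- finish(.mosaic_render_core(refl, wsig, offs$row_off, offs$col_off,
                                      scene$dark_current))
    # white/dark have no band dependence beyond mosaic position, so they can
    # be assembled in one shot from the expanded illumination field
    white <- finish(.expand5_core(wsig, scene$dark_current))
    dark <- finish(matrix(scene$dark_current, 5 * R, 5 * C))
    if (any(glare)) {
      gm <- glare[rep(seq_len(R), each = 5), rep(seq_len(C), each = 5)]
      raw[gm] <- scene$saturation
    }

    # annotation frame: small affine misalignment dst (HSI) -> src (histology)
    wm <- scene$warp_magnitude
    theta <- runif(1, -2, 2) * pi / 180 * wm
    sc <- 1 + runif(1, -0.02, 0.02) * wm
    tr <- runif(2, -3, 3) * wm
    ctr <- c(C / 2, R / 2)
    fwd <- function(p) {  # p: n x 2 (x, y) in HSI coords -> annotation coords
      rot <- cbind(c(cos(theta), sin(theta)), c(-sin(theta), cos(theta)))
      sweep(sc * (sweep(p, 2, ctr) %*% t(rot)), 2, ctr + tr, `+`)
    }
    inv <- function(q) {
      rot <- cbind(c(cos(-theta), sin(-theta)), c(-sin(-theta), cos(-theta)))
      sweep(sweep(q, 2, ctr + tr) %*% t(rot) / sc, 2, ctr, `+`)
    }

    q <- cbind(as.vector(xs), as.vector(ys))
    p <- inv(q)
    src_col <- floor(p[, 1]) + 1L
    src_row <- floor(p[, 2]) + 1L
    ok <- src_col >= 1L & src_col <= C & src_row >= 1L & src_row <= R
    lab <- rep(LABEL_CODES[["unannotated"]], npx)
    lab[ok] <- truth[cbind(src_row[ok], src_col[ok])]
    annotation <- array(255L, c(R, C, 3))
    colmap <- rbind(ANNOTATION_COLORS$background, ANNOTATION_COLORS$non_tumor,
                    ANNOTATION_COLORS$tumor, ANNOTATION_COLORS$mixed)
    for (ch in 1:3) {
      annotation[, , ch] <- matrix(colmap[lab + 1L, ch], R, C)
    }

    gx <- seq(0.1, 0.9, length.out = 5) * C
    gy <- seq(0.1, 0.9, length.out = 4) * R
    dst <- as.matrix(expand.grid(x = gx, y = gy))
    src <- fwd(dst)
    control_points <- data.frame(x_src = src[, 1], y_src = src[, 2],
                                 x_dst = dst[, 1], y_dst = dst[, 2])

    out <- list(raw = raw, white = white, dark = dark,
                annotation = annotation, control_points = control_points,
                truth = truth, bands = bands, scene = scene)
    if (keep_reflectance) out$reflectance <- array(refl, c(R, C, nb))
    structure(out, class = "hsi_sample")
  })
}
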