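# Scene specification and polygon plumbing for the synthetic generator.
#
# Coordinates are 0-based with pixel (row i, col j), i,j starting at 1 in R,
# covering [j-1, j) x [i-1, i); pixel centers sit at (x, y) = (j-0.5, i-0.5).

#' Specify a synthetic imaging scene
#'
#' A scene describes, in demosaiced-grid coordinates, the tissue regions on the
#' black paper plateau and the camera parameters used to render a raw mosaic
#' frame from them.  The seed fully determines the rendered output.
#'
#' @param rows,cols size of the demosaiced per-band grid; the raw mosaic frame
#'   is `5*rows x 5*cols`.
#' @param regions list of regions, each a list with `polygon` (n x 2 matrix of
#'   x,y vertex coordinates, 0-based pixel units), `class` (endmember name) and
#'   `tumor_fraction` in \[0,1\].  Regions must not overlap and must fit inside
#'   the image.
#' @param glare_fraction per-pixel probability of a saturated glare pixel.
#' @param illumination_gradient strength of the smooth radial illumination
#'   fall-off (0 = perfectly uniform illumination).
#' @param dark_current mean dark-current offset in counts.
#' @param white_level full-reflectance signal level in counts.
#' @param saturation saturation value of the sensor's dynamic range (counts).
#' @param sensor_noise_sd additive read-noise sd in counts.
#' @param quantize round frames to integer counts and clamp to
#'   \[0, saturation\], like a real ADC.  Disable for exact-inversion tests.
#' @param warp_magnitude scale of the affine misalignment between the
#'   annotation image and the hyperspectral frame (0 = perfectly aligned).
#' @param seed integer seed that fully determines the rendered sample.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(rows, cols, regions,
                       glare_fraction = 0.01,
                       illumination_gradient = 0.3,
                       dark_current = 64,
                       white_level = 900,
                       saturation = 1023,
                       sensor_noise_sd = 2,
                       quantize = TRUE,
                       warp_magnitude = 1,
                       seed = 1) {
  stopifnot(rows >= 5, cols >= 5)
  if (glare_fraction < 0 || glare_fraction > 1) {
    stop("glare_fraction must lie in [0,1]")
  }
  for (k in seq_along(regions)) {
    rg <- regions[[k]]
    stopifnot(is.matrix(rg$polygon), ncol(rg$polygon) == 2,
              nrow(rg$polygon) >= 3)
    stopifnot(!is.null(rg$class), rg$tumor_fraction >= 0, rg$tumor_fraction <= 1)
    if (any(rg$polygon[, 1] < 0) || any(rg$polygon[, 1] > cols) ||
        any(rg$polygon[, 2] < 0) || any(rg$polygon[, 2] > rows)) {
      stop("region ", k, " does not fit inside the image")
    }
  }
  structure(list(rows = rows, cols = cols, regions = regions,
                 glare_fraction = glare_fraction,
                 illumination_gradient = illumination_gradient,
                 dark_current = dark_current, white_level = white_level,
                 saturation = saturation, sensor_noise_sd = sensor_noise_sd,
                 quantize = quantize, warp_magnitude = warp_magnitude,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  .pip_core(as.numeric(px), as.numeric(py), poly)
}

# Jittered-ellipse polygon (blob) used by the random cohort scenes.
blob_polygon <- function(cx, cy, radius, n = 24, jitter = 0.15) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- radius * (1 + runif(n, -jitter, jitter))
  cbind(cx + r * cos(th), cy + r * sin(th))
}

rect_polygon <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Random non-overlapping blob regions, one per quadrant of the canvas.
# Uses the current RNG state (callers seed it).
random_regions <- function(rows, cols, classes, tumor_fractions,
                           radius_range = c(0.34, 0.42)) {
  n <- length(classes)
  stopifnot(n >= 1, n <= 4)
  qr <- rows / 2; qc <- cols / 2
  centers <- list(c(qc / 2, qr / 2), c(3 * qc / 2, qr / 2),
                  c(qc / 2, 3 * qr / 2), c(3 * qc / 2, 3 * qr / 2))
  pick <- sample.int(4, n)
  lapply(seq_len(n), function(k) {
    ctr <- centers[[pick[k]]] + runif(2, -4, 4)
    rad <- min(qr, qc) * runif(1, radius_range[1], radius_range[2])
    poly <- blob_polygon(ctr[1], ctr[2], rad, jitter = 0.10)
    poly[, 1] <- pmin(pmax(poly[, 1], 1), cols - 1)
    poly[, 2] <- pmin(pmax(poly[, 2], 1), rows - 1)
    list(polygon = poly,
         class = classes[k], tumor_fraction = tumor_fractions[k])
  })
}
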