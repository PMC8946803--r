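# Histology annotation handling: HSV color thresholding and control-point
# thin-plate-spline registration into hyperspectral coordinates.

#' Default HSV windows for the annotation colors
#'
#' Windows follow the 8-bit OpenCV-style convention H in \[0,179\],
#' S and V in \[0,255\].  Tumor regions are painted bordeaux
#' (H in \[160,179\] or \[0,5\], S >= 100, V in \[60,200\]), non-tumor regions
#' blue (H in \[100,130\], S >= 100), and partially tumorous ("mixed") regions
#' carry a green marker (H in \[40,80\]).
#'
#' @return named list of windows, each with `h` (list of \[lo,hi\] hue
#'   intervals), `s` and `v` ranges.
#' @export
default_hsv_windows <- function() {
  list(
    tumor = list(h = list(c(160, 179), c(0, 5)), s = c(100, 255), v = c(60, 200)),
    non_tumor = list(h = list(c(100, 130)), s = c(100, 255), v = c(0, 255)),
    mixed = list(h = list(c(40, 80)), s = c(80, 255), v = c(0, 255))
  )
}

hue_windows_overlap <- function(windows) {
  cls <- names(windows)
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (j <= i) next
    for (a in windows[[i]]$h) for (b in windows[[j]]$h) {
      if (a[1] <= b[2] && b[1] <= a[2]) return(paste(cls[i], "vs", cls[j]))
    }
  }
  NULL
}

#' Segment an annotation RGB image by HSV thresholding
#'
#' Converts the 8-bit RGB annotation image to HSV and assigns each pixel the
#' class whose window contains it; pixels in no window are unannotated.
#'
#' @param rgb rows x cols x 3 array of 8-bit RGB values.
#' @param windows HSV windows, see [default_hsv_windows()].  Hue windows of
#'   different classes must not overlap.
#' @return integer label matrix (0 unannotated, 1 non_tumor, 2 tumor, 3 mixed).
#' @export
hsv_masks <- function(rgb, windows = default_hsv_windows()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  ov <- hue_windows_overlap(windows)
  if (!is.null(ov)) stop("overlapping hue windows: ", ov)
  R <- dim(rgb)[1]; C <- dim(rgb)[2]
  hsv <- .rgb_to_hsv_core(as.numeric(rgb[, , 1]), as.numeric(rgb[, , 2]),
                          as.numeric(rgb[, , 3]))
  h <- hsv[, 1]  # OpenCV-style half-degrees [0,180)
  s <- hsv[, 2]
  v <- hsv[, 3]
  lab <- rep(LABEL_CODES[["unannotated"]], R * C)
  for (cls in names(windows)) {
    w <- windows[[cls]]
    in_h <- Reduce(`|`, lapply(w$h, function(iv) h >= iv[1] & h <= iv[2]))
    hit <- in_h & s >= w$s[1] & s <= w$s[2] & v >= w$v[1] & v <= w$v[2]
    lab[hit] <- LABEL_CODES[[cls]]
  }
  matrix(lab, R, C)
}

# --- thin-plate spline ------------------------------------------------------

tps_kernel <- function(r2) {
  u <- r2
  pos <- r2 > 0
  u[pos] <- r2[pos] * log(r2[pos]) / 2  # r^2 log r
  u[!pos] <- 0
  u
}

#' Fit an interpolating thin-plate spline map R^2 -> R^2
#'
#' Zero-regularization TPS through the point pairs, so every control point is
#' interpolated exactly; the affine part is unpenalized, hence point sets
#' sampled from an affine map reproduce that map everywhere.
#'
#' @param from n x 2 matrix of source planar points (n >= 3, non-collinear).
#' @param to n x 2 matrix of target points.
#' @return object of class `tps_map`.
#' @export
tps_fit <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  stopifnot(ncol(from) == 2, ncol(to) == 2, nrow(from) == nrow(to),
            nrow(from) >= 3)
  n <- nrow(from)
  d2 <- outer(from[, 1], from[, 1], `-`)^2 + outer(from[, 2], from[, 2], `-`)^2
  K <- tps_kernel(d2)
  P <- cbind(1, from)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(to, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs), error = function(e) {
    stop("thin-plate spline system is singular (collinear or duplicated ",
         "control points): ", conditionMessage(e))
  })
  structure(list(centers = from, W = coef[1:n, , drop = FALSE],
                 A = coef[(n + 1):(n + 3), , drop = FALSE]),
            class = "tps_map")
}

#' Evaluate a fitted thin-plate spline map
#' @param fit a [tps_fit()] object.
#' @param pts m x 2 matrix of planar points.
#' @return m x 2 matrix of mapped points.
#' @export
tps_eval <- function(fit, pts) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  .tps_eval_core(pts, fit$centers, fit$W, fit$A)
}

#' Warp an image or label mask onto the hyperspectral frame
#'
#' Fits a TPS from destination (hyperspectral) to source (annotation)
#' coordinates using the control-point pairs, then resamples: label masks by
#' nearest neighbor (to avoid label mixing), numeric images bilinearly.
#' Output pixels that map outside the source get `background`.
#'
#' @param img numeric matrix (image) or integer matrix (label mask).
#' @param points data.frame with columns `x_src`, `y_src`, `x_dst`, `y_dst`
#'   (0-based pixel coordinates).
#' @param out_dim output (rows, cols); defaults to `dim(img)`.
#' @param method `"nearest"` (masks) or `"bilinear"` (images).
#' @param background fill value outside the source frame.
#' @return warped matrix of size `out_dim`.
#' @export
tps_warp <- function(img, points, out_dim = dim(img),
                     method = c("nearest", "bilinear"), background = 0) {
  method <- match.arg(method)
  stopifnot(all(c("x_src", "y_src", "x_dst", "y_dst") %in% names(points)))
  fit <- tps_fit(cbind(points$x_dst, points$y_dst),
                 cbind(points$x_src, points$y_src))
  R <- out_dim[1]; C <- out_dim[2]
  xs <- rep(seq_len(C) - 0.5, each = R)
  ys <- rep(seq_len(R) - 0.5, times = C)
  src <- tps_eval(fit, cbind(xs, ys))
  out <- matrix(background, R, C)
  if (method == "nearest") {
    storage.mode(out) <- storage.mode(img)  # masks keep their integer type
    sc <- floor(src[, 1]) + 1L
    sr <- floor(src[, 2]) + 1L
    ok <- sc >= 1L & sc <= ncol(img) & sr >= 1L & sr <= nrow(img)
    out[cbind(rep(seq_len(R), times = C)[ok], rep(seq_len(C), each = R)[ok])] <-
      img[cbind(sr[ok], sc[ok])]
  } else {
    x0 <- floor(src[, 1] - 0.5); y0 <- floor(src[, 2] - 0.5)
    fx <- (src[, 1] - 0.5) - x0; fy <- (src[, 2] - 0.5) - y0
    c0 <- x0 + 1L; r0 <- y0 + 1L
    ok <- c0 >= 1L & c0 + 1L <= ncol(img) & r0 >= 1L & r0 + 1L <= nrow(img)
    val <- rep(background, R * C)
    i <- which(ok)
    val[i] <- (1 - fx[i]) * (1 - fy[i]) * img[cbind(r0[i], c0[i])] +
      fx[i] * (1 - fy[i]) * img[cbind(r0[i], c0[i] + 1L)] +
      (1 - fx[i]) * fy[i] * img[cbind(r0[i] + 1L, c0[i])] +
      fx[i] * fy[i] * img[cbind(r0[i] + 1L, c0[i] + 1L)]
    out <- matrix(val, R, C)
  }
  out
}

#' Label grid blocks from a registered annotation mask
#'
#' Applies the same block purity rule as [patch_average()] to an annotation
#' mask already registered into hypercube coordinates, optionally restricted
#' to valid pixels.
#'
#' @param annotation integer label matrix (codes 0/1/2/3).
#' @param valid optional logical matrix restricting which pixels count.
#' @param block block edge length in pixels.
#' @return data.frame with `block_row`, `block_col` (0-based) and `label`.
#' @export
label_patches <- function(annotation, valid = NULL, block = 20) {
  R <- nrow(annotation); C <- ncol(annotation)
  if (is.null(valid)) valid <- matrix(TRUE, R, C)
  stopifnot(identical(dim(valid), dim(annotation)))
  brow <- (seq_len(R) - 1L) %/% block
  bcol <- (seq_len(C) - 1L) %/% block
  nbc <- max(bcol) + 1L
  nblocks <- (max(brow) + 1L) * nbc
  ids <- outer(brow, bcol, function(a, b) a * nbc + b + 1L)
  ids_v <- as.vector(ids)[as.vector(valid)]
  ann_v <- as.vector(annotation)[as.vector(valid)]
  n_t <- tabulate(ids_v[ann_v == LABEL_CODES[["tumor"]]], nbins = nblocks)
  n_nt <- tabulate(ids_v[ann_v == LABEL_CODES[["non_tumor"]]], nbins = nblocks)
  n_mx <- tabulate(ids_v[ann_v == LABEL_CODES[["mixed"]]], nbins = nblocks)
  data.frame(block_row = (seq_len(nblocks) - 1L) %/% nbc,
             block_col = (seq_len(nblocks) - 1L) %% nbc,
             label = block_label(n_t, n_nt, n_mx),
             stringsAsFactors = FALSE)
}
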