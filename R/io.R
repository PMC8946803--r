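# Plain-text raster I/O (ASCII NetPBM).  The pre-installed stack has no TIFF
# or PNG codec, so frames travel as PGM (P2, one integer matrix per file) and
# annotation images as PPM (P3).  Both are standard formats readable by any
# NetPBM-aware tool.

#' Write an integer matrix as ASCII PGM (P2)
#'
#' @param mat numeric matrix (values are rounded to integers on write).
#' @param path output file.
#' @param maxval maximum sample value declared in the header.
#' @export
write_pgm <- function(mat, path, maxval = max(1, max(mat))) {
  stopifnot(is.matrix(mat))
  m <- round(mat)
  if (any(m < 0) || any(m > maxval)) stop("PGM values outside [0, maxval]")
  rows <- vapply(seq_len(nrow(m)), function(i) paste(m[i, ], collapse = " "),
                 character(1))
  writeLines(c("P2", paste(ncol(m), nrow(m)), format(round(maxval)), rows), path)
  invisible(path)
}

#' Read an ASCII PGM (P2) file
#' @param path file path.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("truncated PGM: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an RGB array as ASCII PPM (P3)
#' @param img rows x cols x 3 array with values in \[0, maxval\].
#' @param path output file.
#' @param maxval maximum sample value (default 255).
#' @export
write_ppm <- function(img, path, maxval = 255) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  m <- round(img)
  if (any(m < 0) || any(m > maxval)) stop("PPM values outside [0, maxval]")
  h <- dim(m)[1]; w <- dim(m)[2]
  # interleave channels row-major: r g b r g b ...
  inter <- matrix(0L, h, 3 * w)
  inter[, seq(1, 3 * w, 3)] <- m[, , 1]
  inter[, seq(2, 3 * w, 3)] <- m[, , 2]
  inter[, seq(3, 3 * w, 3)] <- m[, , 3]
  rows <- vapply(seq_len(h), function(i) paste(inter[i, ], collapse = " "),
                 character(1))
  writeLines(c("P3", paste(w, h), format(maxval), rows), path)
  invisible(path)
}

#' Read an ASCII PPM (P3) file
#' @param path file path.
#' @return rows x cols x 3 integer array.
#' @export
read_ppm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P3") stop("not an ASCII PPM (P3) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  if (length(vals) != 3 * w * h) stop("truncated PPM: ", path)
  inter <- matrix(vals, nrow = h, ncol = 3 * w, byrow = TRUE)
  img <- array(0L, c(h, w, 3))
  img[, , 1] <- inter[, seq(1, 3 * w, 3)]
  img[, , 2] <- inter[, seq(2, 3 * w, 3)]
  img[, , 3] <- inter[, seq(3, 3 * w, 3)]
  img
}
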