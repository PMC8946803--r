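#' Default band centers of the 5x5 mosaic sensor
#'
#' 25 strictly increasing band centers (nm) spanning 665--975 nm.  The 17
#' wavelengths used by the default prognostic feature set (676, 684, 697, 762,
#' 775, 799, 823, 863, 872, 882, 892, 901, 910, 923, 930, 943, 954 nm) are all
#' present as exact centers; the remaining 8 centers fill the range
#' monotonically.  The true filter centers of the sensor are not public, so
#' this table is a reconstruction.
#'
#' @return numeric vector of length 25.
#' @export
default_band_centers <- function() {
  c(665, 676, 684, 697, 712, 728, 744, 762, 775, 787,
    799, 811, 823, 843, 863, 872, 882, 892, 901, 910,
    923, 930, 943, 954, 975)
}

#' Build the spectral band table
#'
#' Describes the 25 spectral bands of the snapshot-mosaic sensor: their center
#' wavelengths and the position of each band inside the repeating 5x5 mosaic
#' cell (row-major, band 1 at offset (0,0)).  The offsets form a bijection onto
#' \{0..4\} x \{0..4\}.
#'
#' @param centers_nm optional numeric vector of 25 strictly increasing center
#'   wavelengths in nanometers, all within \[665, 975\].  Defaults to
#'   [default_band_centers()].
#' @return an object of class `band_table` with fields `centers_nm` and
#'   `mosaic_offsets` (data.frame: band, row_off, col_off).
#' @export
#' @examples
#' bt <- make_band_table()
#' length(bt$centers_nm)  # 25
make_band_table <- function(centers_nm = NULL) {
  if (is.null(centers_nm)) centers_nm <- default_band_centers()
  centers_nm <- as.numeric(centers_nm)
  if (length(centers_nm) != 25) {
    stop("band table needs exactly 25 center wavelengths, got ",
         length(centers_nm))
  }
  if (any(!is.finite(centers_nm)) || any(diff(centers_nm) <= 0)) {
    stop("band centers must be finite and strictly increasing")
  }
  if (min(centers_nm) < 665 || max(centers_nm) > 975) {
    stop("band centers must lie within [665, 975] nm")
  }
  offs <- data.frame(band = 1:25,
                     row_off = (0:24) %/% 5L,
                     col_off = (0:24) %% 5L)
  structure(list(centers_nm = centers_nm, mosaic_offsets = offs),
            class = "band_table")
}

#' @export
print.band_table <- function(x, ...) {
  cat("band_table: 25 bands,", min(x$centers_nm), "-", max(x$centers_nm),
      "nm, 5x5 mosaic\n")
  invisible(x)
}

#' Map a wavelength to the nearest band index
#'
#' Index minimizing the absolute distance to a band center; exact midpoints
#' between two centers resolve to the lower index.
#'
#' @param wavelength_nm numeric vector of wavelengths in \[600, 1050\] nm.
#' @param bands a [make_band_table()] object.
#' @return integer vector of band indices (1-based).
#' @export
nearest_band <- function(wavelength_nm, bands = make_band_table()) {
  stopifnot(all(wavelength_nm >= 600), all(wavelength_nm <= 1050))
  vapply(wavelength_nm, function(w) {
    which.min(abs(bands$centers_nm - w))  # which.min takes the first = lower
  }, integer(1))
}
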