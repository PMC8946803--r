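#' Spectral endmember library
#'
#' A named set of per-tissue-class reflectance endmembers (length 25, values in
#' \[0,1\]) plus the two noise parameters of the generative model: a per-spectrum
#' multiplicative log-normal amplitude spread (`amplitude_sd`, the sd on the log
#' scale) and an additive per-band Gaussian noise sd (`noise_sd`).  The single
#' scalar amplitude per spectrum is what makes spectra of a class run "in
#' parallel", the structure that motivates ratio features.
#'
#' @param endmembers named list of numeric vectors, each length 25 with values
#'   in \[0,1\].  One entry must be named `"tumor"` if mixtures are to be drawn.
#' @param amplitude_sd log-scale sd of the per-spectrum amplitude multiplier.
#' @param noise_sd sd of additive per-band reflectance noise.
#' @return object of class `spectral_library`.
#' @export
spectral_library <- function(endmembers, amplitude_sd = 0.15, noise_sd = 0.01) {
  stopifnot(is.list(endmembers), length(names(endmembers)) == length(endmembers))
  for (nm in names(endmembers)) {
    e <- endmembers[[nm]]
    if (length(e) != 25) stop("endmember '", nm, "' must have length 25")
    if (any(e < 0 | e > 1)) stop("endmember '", nm, "' must lie in [0,1]")
  }
  stopifnot(amplitude_sd >= 0, noise_sd >= 0)
  structure(list(endmembers = endmembers,
                 amplitude_sd = amplitude_sd,
                 noise_sd = noise_sd),
            class = "spectral_library")
}

#' Default synthetic tissue endmembers
#'
#' Smooth synthetic reflectance curves (linear continuum plus a few Gaussian
#' bumps/dips placed at plausible NIR chromophore wavelengths: ~760 nm
#' deoxyhemoglobin, ~930 nm lipid, ~970 nm water).  They are stand-ins with the
#' right statistical structure, not digitized tissue spectra.
#'
#' The tumor endmember is `connective + separation * delta`, where `delta` is a
#' fixed smooth difference curve.  `separation = 0` makes tumor identical to
#' connective tissue (the null world); larger values scale the class contrast.
#'
#' @param bands band table (for the wavelength grid).
#' @param separation scale applied to the tumor-vs-connective difference curve.
#' @param heterogeneous include additional non-tumor classes (`fat`, `stroma`)
#'   beside `connective`, emulating within-class tissue heterogeneity.
#' @param amplitude_sd,noise_sd passed to [spectral_library()].
#' @return a `spectral_library` with classes `tumor`, `connective`, optionally
#'   `fat` and `stroma`, and the black-paper background class `paper`.
#' @export
default_spectral_library <- function(bands = make_band_table(),
                                     separation = 1,
                                     heterogeneous = TRUE,
                                     amplitude_sd = 0.15,
                                     noise_sd = 0.01) {
  l <- bands$centers_nm
  gauss <- function(mu, s) exp(-0.5 * ((l - mu) / s)^2)
  connective <- 0.42 + 0.00035 * (l - 665) -
    0.06 * gauss(760, 18) - 0.07 * gauss(970, 22)
  delta <- -0.08 * gauss(745, 25) + 0.05 * gauss(905, 35) - 0.04 * gauss(840, 30)
  tumor <- connective + separation * delta
  em <- list(tumor = clip01(tumor), connective = clip01(connective))
  if (heterogeneous) {
    em$fat <- clip01(0.50 + 0.0004 * (l - 665) - 0.12 * gauss(928, 20) -
                       0.05 * gauss(760, 20) - 0.05 * gauss(970, 25))
    em$stroma <- clip01(0.36 + 0.0003 * (l - 665) - 0.08 * gauss(760, 22) -
                          0.09 * gauss(970, 25) + 0.03 * gauss(880, 45))
  }
  em$paper <- rep(0.02, 25)  # black-paper background
  spectral_library(em, amplitude_sd = amplitude_sd, noise_sd = noise_sd)
}

#' Draw one spectrum from the generative model
#'
#' Returns `f * tumor + (1 - f) * class` scaled by a single log-normal
#' amplitude draw, plus independent per-band Gaussian noise, clipped to
#' \[0,1\].  With both noise parameters at zero this reduces exactly to the
#' convex combination of the endmembers.
#'
#' @param library a [spectral_library()].
#' @param class_name endmember name for the non-tumor component.
#' @param tumor_fraction mixing fraction `f` in \[0,1\].
#' @param seed optional integer; when given, the draw is deterministic and the
#'   caller's RNG state is untouched.
#' @return numeric reflectance vector of length 25.
#' @export
sample_spectrum <- function(library, class_name, tumor_fraction = 0,
                            seed = NULL) {
  stopifnot(inherits(library, "spectral_library"))
  if (!class_name %in% names(library$endmembers)) {
    stop("unknown spectral class '", class_name, "'")
  }
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1)
  base <- library$endmembers[[class_name]]
  mix <- if (tumor_fraction > 0) {
    tumor_fraction * library$endmembers[["tumor"]] + (1 - tumor_fraction) * base
  } else base
  with_seed(seed, {
    amp <- exp(rnorm(1, 0, library$amplitude_sd))
    clip01(amp * mix + rnorm(25, 0, library$noise_sd))
  })
}
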