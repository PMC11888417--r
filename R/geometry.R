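# Analytic instrument-geometry helpers for spectral-domain / swept-source
# OCT optoretinography. These are closed-form sanity checks on an imaging
# configuration, not measurements.

#' OCT axial resolution from source bandwidth
#'
#' Coherence-length axial resolution of a Gaussian-spectrum OCT source:
#' `2 ln(2) / pi * lambda0^2 / dlambda / n`.
#'
#' @param center_nm Source center wavelength, nm.
#' @param bandwidth_nm Swept/source bandwidth (FWHM), nm.
#' @param n Refractive index of the medium (1 for air; ~1.38 in retinal
#'   tissue).
#' @return Axial resolution, um.
#' @examples
#' oct_axial_resolution(850, 50)            # ~6.4 um in air
#' oct_axial_resolution(850, 50, n = 1.38)  # ~4.6 um in the eye
#' @export
oct_axial_resolution <- function(center_nm, bandwidth_nm, n = 1) {
  stopifnot(center_nm > 0, bandwidth_nm > 0, n > 0)
  2 * log(2) / pi * center_nm^2 / bandwidth_nm / n / 1000
}

#' Retinal sampling pitch of a camera pixel
#'
#' Lateral extent of one camera pixel referred to the retina.
#'
#' @param pixel_um Physical pixel size, um.
#' @param magnification Retina-to-camera magnification (dimensionless).
#' @return Retinal sampling pitch, um.
#' @export
retinal_sampling_pitch <- function(pixel_um, magnification) {
  stopifnot(pixel_um > 0, magnification > 0)
  pixel_um / magnification
}

#' Cone center-to-center spacing from row spacing
#'
#' For a triangular cone mosaic, center-to-center spacing is row spacing
#' divided by sqrt(3)/2.
#'
#' @param row_spacing_um Row-to-row spacing, um.
#' @return Center-to-center spacing, um.
#' @export
cone_center_spacing <- function(row_spacing_um) {
  stopifnot(row_spacing_um > 0)
  row_spacing_um / (sqrt(3) / 2)
}

#' Unambiguous OPL range of phase-difference detection
#'
#' A phase difference wraps at +/- pi, i.e. at an OPL excursion of
#' lambda/4; larger excursions require temporal unwrapping.
#'
#' @param lambda_nm Imaging wavelength, nm.
#' @return Half-range of unambiguous OPL, nm.
#' @export
opl_unambiguous_range <- function(lambda_nm) {
  stopifnot(lambda_nm > 0)
  lambda_nm / 4
}
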