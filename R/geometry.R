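# Coordinate frames and Ewald-sphere mapping.
#
# Laboratory frame: X-ray beam along +X, spindle along +Z. The flat detector
# sits normal to the beam at x = D; its Xd axis is parallel to lab Y and its
# Yd axis to lab Z. Spot files store absolute detector mm; beam-relative
# coordinates are formed inside the mapping so that the direct-beam position
# can be varied without rewriting spot lists.

#' Experiment geometry
#'
#' @param wavelength X-ray wavelength in angstroms.
#' @param distance crystal-to-detector distance D in mm.
#' @param beam_centre numeric length-2, direct-beam position `(bx, by)` in mm
#'   in the detector frame.
#' @param spindle_sense `+1` or `-1`: sign of the rotation about the lab Z
#'   axis per increasing phi. Most beamlines use `+1`; a few spin the other
#'   way, which breaks multi-image indexing unless declared.
#' @return an object of class `fftindex_geometry`.
#' @export
experiment_geometry <- function(wavelength, distance, beam_centre = c(0, 0),
                                spindle_sense = 1L) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
            is.numeric(distance), length(distance) == 1L, distance > 0,
            is.numeric(beam_centre), length(beam_centre) == 2L,
            all(is.finite(beam_centre)),
            spindle_sense %in% c(-1, 1))
  structure(list(wavelength = as.numeric(wavelength),
                 distance = as.numeric(distance),
                 beam_centre = as.numeric(beam_centre),
                 spindle_sense = as.integer(spindle_sense)),
            class = "fftindex_geometry")
}

#' @export
print.fftindex_geometry <- function(x, ...) {
  cat(sprintf(
    "Experiment geometry: wavelength %.4f A, distance %.2f mm,\n  beam (%.3f, %.3f) mm, spindle sense %+d\n",
    x$wavelength, x$distance, x$beam_centre[1], x$beam_centre[2],
    x$spindle_sense))
  invisible(x)
}

validate_spots <- function(spots) {
  need <- c("image_id", "x_mm", "y_mm", "phi_start_deg", "phi_end_deg",
            "intensity", "sigma")
  miss <- setdiff(need, names(spots))
  if (length(miss))
    stop("spot list is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(spots)) {
    if (any(!is.finite(spots$x_mm)) || any(!is.finite(spots$y_mm)))
      stop("non-finite spot coordinates")
    if (any(spots$phi_end_deg < spots$phi_start_deg))
      stop("phi_end_deg < phi_start_deg for some spots")
    if (any(!is.finite(spots$sigma)) || any(spots$sigma <= 0))
      stop("sigma must be positive")
  }
  invisible(spots)
}

#' Map spot positions to dimensionless scattering vectors
#'
#' Applies the Ewald-sphere construction: with beam-relative detector
#' coordinates `(Xd, Yd) = (x_mm - bx, y_mm - by)` and
#' `R = sqrt(D^2 + Xd^2 + Yd^2)`, the scattering vector in dimensionless
#' reciprocal-lattice units is `s = (D/R - 1, Xd/R, Yd/R)`; the Ewald sphere
#' then has unit radius and every mapped vector satisfies `|s + x_hat| = 1`.
#' Each spot's phi is taken as the midpoint of its oscillation range.
#'
#' @param spots data frame with columns `image_id, x_mm, y_mm,
#'   phi_start_deg, phi_end_deg, intensity, sigma` (see [read_spot_list()]).
#' @param geom an [experiment_geometry()].
#' @param common_origin if `TRUE` (default), rotate each vector about the
#'   spindle axis by `-spindle_sense * phi_mid` so vectors from all images
#'   share the phi = 0 frame.
#' @return data frame with columns `sx, sy, sz, phi_mid_deg, spot` (row index
#'   into `spots`).
#' @export
map_spots <- function(spots, geom, common_origin = TRUE) {
  validate_spots(spots)
  stopifnot(inherits(geom, "fftindex_geometry"))
  xd <- spots$x_mm - geom$beam_centre[1]
  yd <- spots$y_mm - geom$beam_centre[2]
  D <- geom$distance
  R <- sqrt(D^2 + xd^2 + yd^2)
  s <- cbind(sx = D / R - 1, sy = xd / R, sz = yd / R)
  phi_mid <- (spots$phi_start_deg + spots$phi_end_deg) / 2
  out <- data.frame(s, phi_mid_deg = phi_mid,
                    spot = seq_len(nrow(spots)))
  if (common_origin) out <- rotate_to_common_origin(out, geom)
  out
}

#' Rotate scattering vectors to the common phi origin
#'
#' Applies the spindle rotation `Phi(-spindle_sense * phi_mid)` about the lab
#' Z axis to each vector, so that vectors from all images are expressed in
#' the phi = 0 frame. The norm and the spindle-axis component are preserved.
#'
#' @param svecs data frame as returned by [map_spots()] (columns
#'   `sx, sy, sz, phi_mid_deg`).
#' @param geom an [experiment_geometry()].
#' @return `svecs` with rotated `sx, sy` components.
#' @export
rotate_to_common_origin <- function(svecs, geom) {
  th <- deg2rad(-geom$spindle_sense * svecs$phi_mid_deg)
  c_ <- cos(th); s_ <- sin(th)
  sx <- svecs$sx * c_ - svecs$sy * s_
  sy <- svecs$sx * s_ + svecs$sy * c_
  svecs$sx <- sx
  svecs$sy <- sy
  svecs
}

svec_matrix <- function(svecs) {
  m <- as.matrix(svecs[, c("sx", "sy", "sz")])
  dimnames(m) <- NULL
  m
}

#' Resolution of scattering vectors
#'
#' In dimensionless reciprocal-lattice units the resolution of a reflection
#' is `d = wavelength / |s|`.
#'
#' @param svecs data frame from [map_spots()], or a numeric vector of `|s|`.
#' @param geom an [experiment_geometry()].
#' @return resolutions in angstroms; `Inf` (with a warning) where `|s| = 0`,
#'   i.e. a spot at the beam centre carries no resolution information.
#' @export
resolution_of <- function(svecs, geom) {
  ns <- if (is.data.frame(svecs)) sqrt(svecs$sx^2 + svecs$sy^2 + svecs$sz^2)
        else as.numeric(svecs)
  d <- ifelse(ns > 0, geom$wavelength / ns, Inf)
  if (any(ns == 0)) warning("zero-length scattering vector: undefined resolution")
  d
}
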