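# Forward diffraction-geometry simulator. Inverse of the Ewald mapping in
# geometry.R: enumerate reciprocal-lattice points of known crystals, find the
# spindle angles at which each crosses the Ewald sphere, and project the
# diffracted ray onto the flat detector. Intensities are deliberately crude
# (an exponential decay with resolution plus lognormal scatter): indexing
# uses positions only, and intensities exist to exercise I/sigma filtering.

#' Describe one crystal in a synthetic scene
#'
#' @param cell numeric `(a, b, c, alpha, beta, gamma)` in angstroms/degrees.
#' @param orientation 3x3 rotation matrix applied to the standard
#'   orthogonalized basis, or `NULL` for a deterministic pseudo-random
#'   orientation drawn from the scene seed.
#' @param mosaicity_deg mosaic spread in degrees. Modelled as a hard widening
#'   of the Ewald-crossing acceptance window by `mosaicity/2` on either side
#'   of the image's oscillation range, not as a reflection profile.
#' @param share relative spot share of this crystal (shares are normalised
#'   over the scene).
#' @return a `fftindex_crystal` list.
#' @export
crystal <- function(cell, orientation = NULL, mosaicity_deg = 0, share = 1) {
  stopifnot(length(cell) == 6L, mosaicity_deg >= 0, share > 0)
  if (!is.null(orientation)) {
    stopifnot(is.matrix(orientation), all(dim(orientation) == 3L))
    if (max(abs(t(orientation) %*% orientation - diag(3))) > 1e-8)
      stop("orientation must be a rotation matrix")
  }
  structure(list(cell = as.numeric(cell), orientation = orientation,
                 mosaicity_deg = mosaicity_deg, share = share),
            class = "fftindex_crystal")
}

#' Define a synthetic diffraction scene
#'
#' @param crystals a [crystal()] or list of them.
#' @param geom an [experiment_geometry()].
#' @param images two-column matrix or data frame of `(phi_start, phi_end)`
#'   in degrees, one row per image.
#' @param d_min_A resolution limit in angstroms.
#' @param noise_sigma_mm Gaussian positional noise added independently to the
#'   detector x and y of every spot (mm).
#' @param detector_half_mm half-width of the square detector aperture (mm),
#'   centred on the beam.
#' @param intensity list with `scale` (typical I/sigma at zero scattering
#'   angle) and `decay` (exponential fall-off per squared dimensionless
#'   `|s|`, normalised to the resolution limit).
#' @param spot_fraction global random thinning of the emitted spot list
#'   (emulates a spot finder keeping the stronger fraction of a dense
#'   pattern while leaving the per-spot error structure untouched).
#' @param seed integer seed; the same seed gives byte-identical spot lists.
#' @return a `fftindex_scene` list.
#' @export
synthetic_scene <- function(crystals, geom, images = rbind(c(0, 1), c(90, 91)),
                            d_min_A = 3.0, noise_sigma_mm = 0.03,
                            detector_half_mm = 100,
                            intensity = list(scale = 40, decay = 2),
                            spot_fraction = 1, seed = 1L) {
  if (inherits(crystals, "fftindex_crystal")) crystals <- list(crystals)
  stopifnot(length(crystals) >= 1L,
            all(vapply(crystals, inherits, TRUE, "fftindex_crystal")),
            inherits(geom, "fftindex_geometry"), d_min_A > 0,
            noise_sigma_mm >= 0, spot_fraction > 0, spot_fraction <= 1)
  images <- as.matrix(images)
  stopifnot(ncol(images) == 2L, all(images[, 2] >= images[, 1]))
  shares <- vapply(crystals, `[[`, 0, "share")
  structure(list(crystals = crystals, geom = geom, images = images,
                 d_min_A = d_min_A, noise_sigma_mm = noise_sigma_mm,
                 detector_half_mm = detector_half_mm, intensity = intensity,
                 spot_fraction = spot_fraction,
                 shares = shares / sum(shares), seed = as.integer(seed)),
            class = "fftindex_scene")
}

# Spindle angles (deg, within [lo, hi]) at which rlp r0 crosses the Ewald
# sphere. r(phi) = Rz(sense*phi) r0; crossing when r_x(phi) = -|r0|^2/2.
# Returns a list of numeric vectors (0, 1 or 2 angles per rlp).
ewald_crossings <- function(r0, sense, lo, hi) {
  rho <- sqrt(r0[1, ]^2 + r0[2, ]^2)
  delta <- atan2(r0[2, ], r0[1, ])
  # crossing when cos(sense*phi + delta) = q, q = -|r0|^2 / (2 rho)
  q <- -(r0[1, ]^2 + r0[2, ]^2 + r0[3, ]^2) / (2 * rho)
  ok <- rho > 0 & abs(q) <= 1
  n <- ncol(r0)
  out <- vector("list", n)
  acq <- acos(pmin(1, pmax(-1, q)))
  for (j in which(ok)) {
    psi <- c(acq[j], -acq[j]) - delta[j]
    phi <- rad2deg(psi) / sense
    # fold into [lo, lo + 360)
    phi <- lo + (phi - lo) %% 360
    out[[j]] <- phi[phi >= lo & phi <= hi]
  }
  out
}

#' Generate spot lists from a synthetic scene
#'
#' Enumerates all reciprocal-lattice points of every crystal inside the
#' resolution sphere, records a spot whenever the Ewald condition is met for
#' some phi within an image's (mosaicity-widened) oscillation range, projects
#' the diffracted ray onto the detector and adds positional noise.
#'
#' @param scene a [synthetic_scene()].
#' @return list with `spots` (standard spot-list data frame), `truth`
#'   (per-spot ledger: crystal id, Miller indices, true phi of diffraction,
#'   noiseless detector position) and `orientations` (the realised rotation
#'   matrix of each crystal, so results can be scored against the truth).
#' @export
generate_spots <- function(scene) {
  geom <- scene$geom
  lam <- geom$wavelength
  smax <- lam / scene$d_min_A
  sense <- geom$spindle_sense
  rows_s <- list(); rows_t <- list()
  orientations <- vector("list", length(scene$crystals))
  keep_p <- scene$spot_fraction * scene$shares / max(scene$shares)
  with_seed(scene$seed, {
    for (ci in seq_along(scene$crystals)) {
      cr <- scene$crystals[[ci]]
      U <- cr$orientation
      if (is.null(U)) U <- rot_axis_angle(rnorm(3), runif(1, 0, 360))
      orientations[[ci]] <- U
      A <- U %*% basis_from_cell(cr$cell)
      Brec <- reciprocal_basis(A)        # columns a*,b*,c* (1/A)
      # hkl box covering |B h| <= 1/d_min: bound per index by row norms of A
      hmax <- ceiling(sqrt(colSums(A^2)) / scene$d_min_A)
      grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                    k = -hmax[2]:hmax[2],
                                    l = -hmax[3]:hmax[3]))
      grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
      r0 <- lam * (Brec %*% t(grid))     # dimensionless rlps at phi = 0
      ns <- sqrt(colSums(r0^2))
      inside <- ns <= smax & ns > 1e-9
      grid <- grid[inside, , drop = FALSE]
      r0 <- r0[, inside, drop = FALSE]
      for (im in seq_len(nrow(scene$images))) {
        lo <- scene$images[im, 1] - cr$mosaicity_deg / 2
        hi <- scene$images[im, 2] + cr$mosaicity_deg / 2
        cross <- ewald_crossings(r0, sense, lo, hi)
        hit <- which(lengths(cross) > 0)
        if (!length(hit)) next
        phi_star <- vapply(cross[hit], `[[`, 0, 1L)
        s <- r0[, hit, drop = FALSE]
        cs <- cos(deg2rad(sense * phi_star)); sn <- sin(deg2rad(sense * phi_star))
        sx <- s[1, ] * cs - s[2, ] * sn
        sy <- s[1, ] * sn + s[2, ] * cs
        sz <- s[3, ]
        ux <- sx + 1
        on_det <- ux > 1e-6
        xd <- geom$distance * sy / ux
        yd <- geom$distance * sz / ux
        on_det <- on_det & abs(xd) <= scene$detector_half_mm &
          abs(yd) <= scene$detector_half_mm
        if (!any(on_det)) next
        idx <- which(on_det)
        keep <- idx[runif(length(idx)) <= keep_p[ci]]
        if (!length(keep)) next
        snorm2 <- sx[keep]^2 + sy[keep]^2 + sz[keep]^2
        iosig <- scene$intensity$scale *
          exp(-scene$intensity$decay * snorm2 / smax^2) *
          exp(rnorm(length(keep), 0, 0.5))
        sig <- sqrt(pmax(iosig, 1))
        x_true <- geom$beam_centre[1] + xd[keep]
        y_true <- geom$beam_centre[2] + yd[keep]
        rows_s[[length(rows_s) + 1L]] <- data.frame(
          image_id = im,
          x_mm = x_true + rnorm(length(keep), 0, scene$noise_sigma_mm),
          y_mm = y_true + rnorm(length(keep), 0, scene$noise_sigma_mm),
          phi_start_deg = scene$images[im, 1],
          phi_end_deg = scene$images[im, 2],
          intensity = iosig * sig, sigma = sig)
        rows_t[[length(rows_t) + 1L]] <- data.frame(
          crystal = ci, h = grid[hit[keep], 1], k = grid[hit[keep], 2],
          l = grid[hit[keep], 3], phi_true_deg = phi_star[keep],
          x_true_mm = x_true, y_true_mm = y_true)
      }
    }
  })
  if (!length(rows_s)) stop("scene produced no spots")
  spots <- do.call(rbind, rows_s)
  truth <- do.call(rbind, rows_t)
  ord <- order(spots$image_id, seq_len(nrow(spots)))
  spots <- spots[ord, ]; truth <- truth[ord, ]
  rownames(spots) <- rownames(truth) <- NULL
  list(spots = spots, truth = truth, orientations = orientations)
}

#' Clone a crystal into several misoriented lattices
#'
#' Builds a scene containing copies of a base crystal rotated by the listed
#' misorientation angles (about deterministic pseudo-random axes), emulating
#' split crystals (about 1-2 degrees) through to independently oriented
#' crystals (tens of degrees) in the same beam.
#'
#' @param cell base cell `(a, b, c, alpha, beta, gamma)`.
#' @param misorientations_deg rotation angle of each lattice relative to the
#'   first; the first entry is usually 0. Must be distinct.
#' @param shares relative spot share per lattice (recycled to length).
#' @param geom,images,seed,... passed to [synthetic_scene()].
#' @return a `fftindex_scene`.
#' @export
multilattice_scene <- function(cell, misorientations_deg, shares = 1,
                               geom, images = rbind(c(0, 1), c(90, 91)),
                               seed = 1L, ...) {
  stopifnot(!anyDuplicated(misorientations_deg))
  shares <- rep_len(shares, length(misorientations_deg))
  U0 <- random_rotation(seed * 1000L + 17L)
  crystals <- lapply(seq_along(misorientations_deg), function(i) {
    Ri <- if (misorientations_deg[i] == 0) diag(3)
          else rot_axis_angle(with_seed(seed * 1000L + i, rnorm(3)),
                              misorientations_deg[i])
    crystal(cell, orientation = Ri %*% U0, share = shares[i])
  })
  synthetic_scene(crystals, geom = geom, images = images, seed = seed, ...)
}
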