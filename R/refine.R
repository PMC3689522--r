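# Constrained refinement of indexing solutions. For each lattice character
# that passes the distortion-penalty gate, the conventional cell (under the
# character's metric constraints), three orientation angles, the direct-beam
# position and optionally the crystal-to-detector distance are refined by
# least squares against the observed spot positions. Each spot is predicted
# at the spindle angle that puts its reciprocal-lattice point on the Ewald
# sphere (the crossing nearest the oscillation midpoint).

# free-parameter layout per Bravais system
bravais_constraints <- function(bravais) {
  sys <- substr(bravais, 1L, 1L)
  switch(sys,
    a = list(free = c("a", "b", "c", "alpha", "beta", "gamma"),
             build = function(p) p,
             init = function(cl) cl),
    m = list(free = c("a", "b", "c", "beta"),
             build = function(p) c(p[1], p[2], p[3], 90, p[4], 90),
             init = function(cl) cl[c(1, 2, 3, 5)]),
    o = list(free = c("a", "b", "c"),
             build = function(p) c(p, 90, 90, 90),
             init = function(cl) cl[1:3]),
    t = list(free = c("a", "c"),
             build = function(p) c(p[1], p[1], p[2], 90, 90, 90),
             init = function(cl) c(mean(cl[1:2]), cl[3])),
    h = list(free = c("a", "c"),
             build = function(p) c(p[1], p[1], p[2], 90, 90, 120),
             init = function(cl) c(mean(cl[1:2]), cl[3])),
    c = list(free = "a",
             build = function(p) c(p, p, p, 90, 90, 90),
             init = function(cl) mean(cl[1:3])))
}

#' Impose exact Bravais-lattice metric constraints on a cell
#'
#' @param bravais Bravais symbol (e.g. `"oP"`, `"mC"`, `"hR"`).
#' @param cell numeric cell `(a, b, c, alpha, beta, gamma)`.
#' @return the constrained cell (free parameters kept, constrained ones set
#'   exactly; paired lengths averaged).
#' @export
constrain_cell <- function(bravais, cell) {
  cs <- bravais_constraints(bravais)
  cs$build(cs$init(cell))
}

# Spindle angle (deg) nearest phi_mid at which each rlp (columns of r0, the
# phi = 0 frame) crosses the Ewald sphere; falls back to the angle of
# closest approach when no crossing exists.
phi_of_crossing <- function(r0, sense, phi_mid) {
  rho <- sqrt(r0[1, ]^2 + r0[2, ]^2)
  delta <- atan2(r0[2, ], r0[1, ])
  q <- ifelse(rho > 0, -(colSums(r0^2)) / (2 * rho), 2)
  have <- abs(q) <= 1
  acq <- acos(pmin(1, pmax(-1, q)))
  psi1 <- acq - delta
  psi2 <- -acq - delta
  # no crossing: closest approach of r_x(phi) to the target value
  psi_near <- ifelse(q > 1, -delta, pi - delta)
  phi1 <- rad2deg(psi1) / sense
  phi2 <- rad2deg(psi2) / sense
  d1 <- (phi1 - phi_mid + 180) %% 360 - 180
  d2 <- (phi2 - phi_mid + 180) %% 360 - 180
  dn <- (rad2deg(psi_near) / sense - phi_mid + 180) %% 360 - 180
  dd <- ifelse(have, ifelse(abs(d1) <= abs(d2), d1, d2), dn)
  phi_mid + dd
}

# Predicted detector positions for integer indices H (n x 3) under basis A
# (conventional, lab frame, phi = 0) and geometry; phi chosen nearest the
# spot's oscillation midpoint.
predict_positions <- function(A, H, geom, phi_mid) {
  Brec <- reciprocal_basis(A)
  r0 <- geom$wavelength * (Brec %*% t(H))
  phi <- phi_of_crossing(r0, geom$spindle_sense, phi_mid)
  th <- deg2rad(geom$spindle_sense * phi)
  cs <- cos(th); sn <- sin(th)
  sx <- r0[1, ] * cs - r0[2, ] * sn
  sy <- r0[1, ] * sn + r0[2, ] * cs
  ux <- sx + 1
  valid <- ux > 1e-6
  x <- geom$beam_centre[1] + geom$distance * sy / ux
  y <- geom$beam_centre[2] + geom$distance * r0[3, ] / ux
  list(x = x, y = y, phi = phi, valid = valid)
}

#' Refine one indexing solution under its lattice constraints
#'
#' @param entry one row of the [character_penalties()] table (fields `id`,
#'   `bravais`, `penalty`, cell).
#' @param reduced the `fftindex_reduced` cell the table was computed from.
#' @param spots spot-list data frame.
#' @param geom an [experiment_geometry()].
#' @param refine_distance also refine the crystal-to-detector distance
#'   (appropriate for high-resolution data only, off by default because of
#'   its correlation with the cell parameters).
#' @param refine_beam refine the direct-beam position (on by default; the
#'   beam grid search fixes it so that the per-node residual measures the
#'   node's beam error).
#' @param dev_threshold spots whose fractional indices deviate by at least
#'   this much under the starting basis are left out of the fit (the
#'   conventional single-lattice indexing gate).
#' @return list of class `fftindex_solution`: `character_id`, `bravais`,
#'   `penalty`, `cell` (constraints hold exactly), `A_refined`,
#'   `sigma_xy_mm`, `sigma_phi_deg`, `delta_beam_mm`, `beam`, `distance`,
#'   `n_fit`, `converged`.
#' @export
refine_solution <- function(entry, reduced, spots, geom,
                            refine_distance = FALSE, dev_threshold = 0.3,
                            refine_beam = TRUE) {
  bv <- entry$bravais
  Bconv0 <- make_right_handed(conventional_basis(reduced, entry$id))
  cs <- bravais_constraints(bv)
  cl_raw <- cell_params(Bconv0)
  O_raw <- basis_from_cell(cl_raw)
  U0 <- nearest_rotation(Bconv0 %*% solve(O_raw))
  p_cell0 <- cs$init(cl_raw)

  svecs <- map_spots(spots, geom)
  idx0 <- indices_from_basis(Bconv0, svecs, geom$wavelength)
  use <- idx0$deviation < dev_threshold
  npar <- length(p_cell0) + 2L + 2L * refine_beam + as.integer(refine_distance)
  fail <- function(msg) {
    structure(list(character_id = entry$id, bravais = bv,
                   penalty = entry$penalty, cell = constrain_cell(bv, cl_raw),
                   A_refined = Bconv0, sigma_xy_mm = NA_real_,
                   sigma_phi_deg = NA_real_, delta_beam_mm = NA_real_,
                   beam = geom$beam_centre, distance = geom$distance,
                   n_fit = sum(use), converged = FALSE, message = msg),
              class = "fftindex_solution")
  }
  if (sum(use) < npar + 3L) return(fail("too few well-indexed spots"))
  H <- round(idx0$hkl[use, , drop = FALSE])
  phi_mid <- svecs$phi_mid_deg[use]
  xo <- spots$x_mm[use]; yo <- spots$y_mm[use]

  # orientation: two angles about lab X and Y; a rotation about the spindle
  # (Z) axis leaves every predicted position unchanged (all crossing angles
  # shift together), so it is a null direction of the fit and stays fixed at
  # the azimuth delivered by indexing
  nc <- length(p_cell0)
  par0 <- c(p_cell0, 0, 0,
            if (refine_beam) geom$beam_centre,
            if (refine_distance) geom$distance)
  resid_fn <- function(par) {
    cell <- cs$build(par[seq_len(nc)])
    if (any(cell[1:3] <= 1) || any(cell[4:6] <= 10) || any(cell[4:6] >= 170))
      return(rep(100, 2 * length(xo)))
    O <- tryCatch(basis_from_cell(cell), error = function(e) NULL)
    if (is.null(O)) return(rep(100, 2 * length(xo)))
    ang <- par[nc + 1:2]
    U <- rot_axis_angle(c(1, 0, 0), ang[1]) %*%
         rot_axis_angle(c(0, 1, 0), ang[2])
    g2 <- geom
    if (refine_beam) g2$beam_centre <- par[nc + 3:4]
    if (refine_distance) g2$distance <- par[nc + 3L + 2L * refine_beam]
    pr <- predict_positions(U %*% U0 %*% O, H, g2, phi_mid)
    dx <- xo - pr$x; dy <- yo - pr$y
    bad <- !pr$valid | !is.finite(dx) | !is.finite(dy)
    dx[bad] <- 10; dy[bad] <- 10
    c(dx, dy)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200L, ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("least-squares failure"))
  par <- fit$par
  cell <- cs$build(par[seq_len(nc)])
  ang <- par[nc + 1:2]
  U <- rot_axis_angle(c(1, 0, 0), ang[1]) %*%
       rot_axis_angle(c(0, 1, 0), ang[2])
  A_ref <- U %*% U0 %*% basis_from_cell(cell)
  g2 <- geom
  if (refine_beam) g2$beam_centre <- par[nc + 3:4]
  if (refine_distance) g2$distance <- par[nc + 3L + 2L * refine_beam]
  pr <- predict_positions(A_ref, H, g2, phi_mid)
  dx <- xo - pr$x; dy <- yo - pr$y
  okp <- pr$valid & is.finite(dx) & is.finite(dy)
  structure(list(
    character_id = entry$id, bravais = bv, penalty = entry$penalty,
    cell = cell, A_refined = A_ref,
    sigma_xy_mm = sqrt(mean(dx[okp]^2 + dy[okp]^2)),
    sigma_phi_deg = sqrt(mean((pr$phi[okp] - phi_mid[okp])^2)),
    delta_beam_mm = sqrt(sum((g2$beam_centre - geom$beam_centre)^2)),
    beam = g2$beam_centre, distance = g2$distance,
    n_fit = sum(okp), converged = TRUE, message = "ok"),
    class = "fftindex_solution")
}

#' Rank refined solutions and flag pseudo-symmetry
#'
#' Marks as a pseudo-symmetry suspect any solution whose positional residual
#' exceeds 1.3 times that of the triclinic (aP) solution, then highlights
#' the highest-symmetry non-suspect solution with penalty below 20; failing
#' that, the best non-suspect below the refinement gate (50); failing that,
#' the triclinic solution itself.
#'
#' @param solutions data frame of refined solutions (columns `bravais`,
#'   `penalty`, `sigma_xy_mm`, logical `converged`).
#' @param rmsd_factor the pseudo-symmetry threshold on
#'   `sigma_xy / sigma_xy(aP)`.
#' @return `solutions` with added logical columns `pseudo_symmetry_suspect`
#'   and `highlighted` (exactly one `TRUE` row when any solution refined).
#' @export
rank_solutions <- function(solutions, rmsd_factor = 1.3) {
  if (!nrow(solutions)) stop("no solutions to rank")
  ok <- !is.na(solutions$sigma_xy_mm) & solutions$converged
  ap <- ok & solutions$bravais == "aP"
  if (!any(ap)) stop("triclinic solution missing: cannot rank")
  sig_ap <- min(solutions$sigma_xy_mm[ap])
  suspect <- ok & solutions$sigma_xy_mm > rmsd_factor * sig_ap
  solutions$pseudo_symmetry_suspect <- suspect & !is.na(suspect)
  solutions$highlighted <- FALSE
  pick_from <- function(cand) {
    if (!any(cand)) return(NA_integer_)
    i <- which(cand)
    i[order(-bravais_rank(solutions$bravais[i]),
            solutions$penalty[i], solutions$sigma_xy_mm[i])][1]
  }
  pick <- pick_from(ok & !suspect & solutions$penalty < 20)
  if (is.na(pick)) pick <- pick_from(ok & !suspect & solutions$penalty < 50)
  if (is.na(pick)) pick <- which(ap)[order(solutions$sigma_xy_mm[ap])][1]
  solutions$highlighted[pick] <- TRUE
  solutions
}
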