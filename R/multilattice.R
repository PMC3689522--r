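# Iterative indexing of multiple lattices by outlier rejection. The full
# spot list is indexed as a single lattice (the method assumes this first
# pass succeeds); spots whose calculated indices deviate from integers by at
# least a threshold (default 0.2, tighter than the 0.3 used for conventional
# single-lattice work) are moved to a rejected list; the accepted spots are
# re-indexed and any further outliers appended; the rejected list then seeds
# a fresh indexing pass for the next lattice, until the rejected list falls
# below a fixed fraction of all spots found or a lattice cap is reached.

#' Configuration for multi-lattice indexing
#'
#' @param dhkl_threshold maximum deviation of calculated indices from
#'   integers before a spot is declared an outlier (default 0.2).
#' @param min_rejected_fraction stop when the rejected list holds less than
#'   this fraction of the total number of spots found (default 0.10).
#' @param criterion outlier criterion: deviation from integral indices
#'   (`"hkl"`, the default — found to separate lattices better) or the
#'   difference between observed and calculated spot positions
#'   (`"positional"`).
#' @param positional_threshold_mm outlier threshold for the positional
#'   criterion.
#' @param max_lattices cap on the number of lattices.
#' @return a `fftindex_mlconfig` list.
#' @export
multilattice_config <- function(dhkl_threshold = 0.2,
                                min_rejected_fraction = 0.10,
                                criterion = c("hkl", "positional"),
                                positional_threshold_mm = 0.25,
                                max_lattices = 8L) {
  stopifnot(dhkl_threshold > 0, dhkl_threshold <= 0.5,
            min_rejected_fraction > 0, min_rejected_fraction < 1,
            positional_threshold_mm > 0, max_lattices >= 1L)
  criterion <- match.arg(criterion)
  structure(as.list(environment()), class = "fftindex_mlconfig")
}

# indices of `which_idx` (rows of spots) that are outliers against the
# indexing result's refined triclinic basis
ml_outliers <- function(result, spots, which_idx, geom, config) {
  ap_ids <- names(result$refined)[vapply(result$refined, function(s)
    s$bravais == "aP" && s$converged, TRUE)]
  sol <- if (length(ap_ids)) result$refined[[ap_ids[1]]] else result$best
  A <- sol$A_refined
  sub <- spots[which_idx, , drop = FALSE]
  if (config$criterion == "hkl") {
    svecs <- map_spots(sub, geom)
    dev <- indices_from_basis(A, svecs, geom$wavelength)$deviation
    which_idx[dev >= config$dhkl_threshold]
  } else {
    g2 <- geom
    g2$beam_centre <- sol$beam
    g2$distance <- sol$distance
    svecs <- map_spots(sub, g2)
    idx <- indices_from_basis(A, svecs, g2$wavelength)
    pr <- predict_positions(A, round(idx$hkl), g2, svecs$phi_mid_deg)
    dpos <- sqrt((sub$x_mm - pr$x)^2 + (sub$y_mm - pr$y)^2)
    dpos[!pr$valid] <- Inf
    which_idx[dpos >= config$positional_threshold_mm]
  }
}

#' Index multiple lattices by iterative outlier rejection
#'
#' @param spots spot-list data frame.
#' @param geom an [experiment_geometry()].
#' @param config a [multilattice_config()].
#' @param params an [axis_search_params()].
#' @param ... further arguments passed to [index_spots()].
#' @return object of class `fftindex_multilattice`: `lattices` (list of
#'   `fftindex_indexing`, one per lattice), `assignment` (per-spot lattice
#'   number, `NA` for unassigned), `misorientation_deg` (per lattice, angle
#'   to lattice 1), `n_rejected_final`, `config`.
#' @export
index_multilattice <- function(spots, geom, config = multilattice_config(),
                               params = axis_search_params(), ...) {
  validate_spots(spots)
  total <- nrow(spots)
  assignment <- rep(NA_integer_, total)
  lattices <- list()
  current <- seq_len(total)
  repeat {
    k <- length(lattices) + 1L
    res1 <- tryCatch(index_spots(spots[current, , drop = FALSE], geom,
                                 params = params,
                                 max_reject_fraction = 0.9, ...),
                     error = function(e) e)
    if (inherits(res1, "error")) {
      if (k == 1L)
        stop("multi-lattice indexing unavailable: the full spot list did not index as a single lattice (",
             conditionMessage(res1), ")")
      break
    }
    out1 <- ml_outliers(res1, spots, current, geom, config)
    accepted <- setdiff(current, out1)
    res2 <- tryCatch(index_spots(spots[accepted, , drop = FALSE], geom,
                                 params = params,
                                 max_reject_fraction = 0.9, ...),
                     error = function(e) e)
    if (inherits(res2, "error")) {
      if (k == 1L)
        stop("multi-lattice indexing unavailable: second pass failed (",
             conditionMessage(res2), ")")
      break
    }
    out2 <- ml_outliers(res2, spots, accepted, geom, config)
    rejected <- c(out1, out2)
    keep <- setdiff(accepted, out2)
    assignment[keep] <- k
    # report the lattice from a clean re-index of exactly the spots it owns
    # (the pass-2 result was computed before its own outliers left the set)
    res_final <- tryCatch(index_spots(spots[keep, , drop = FALSE], geom,
                                      params = params,
                                      max_reject_fraction = 0.9, ...),
                          error = function(e) res2)
    lattices[[k]] <- res_final
    if (length(rejected) < config$min_rejected_fraction * total) break
    if (k >= config$max_lattices) break
    current <- sort(rejected)
  }
  mis <- vapply(seq_along(lattices), function(k) {
    if (k == 1L) return(0)
    tryCatch(misorientation_angle(best_triclinic_basis(lattices[[1L]]),
                                  best_triclinic_basis(lattices[[k]])),
             error = function(e) NA_real_)
  }, 0)
  structure(list(lattices = lattices, assignment = assignment,
                 misorientation_deg = mis,
                 n_rejected_final = sum(is.na(assignment)),
                 config = config),
            class = "fftindex_multilattice")
}

best_triclinic_basis <- function(result) {
  ap <- Filter(function(s) s$bravais == "aP" && s$converged, result$refined)
  if (length(ap)) ap[[1L]]$A_refined else result$basis$A
}

#' @export
print.fftindex_multilattice <- function(x, ...) {
  cat(sprintf("Multi-lattice indexing: %d lattice(s), %d of %d spots unassigned\n",
              length(x$lattices), x$n_rejected_final, length(x$assignment)))
  for (k in seq_along(x$lattices)) {
    b <- x$lattices[[k]]$best
    cat(sprintf(
      "  lattice %d: %4d spots, %s cell %.2f %.2f %.2f / %.1f %.1f %.1f, misorientation %.2f deg\n",
      k, sum(x$assignment == k, na.rm = TRUE), b$bravais,
      b$cell[1], b$cell[2], b$cell[3], b$cell[4], b$cell[5], b$cell[6],
      x$misorientation_deg[k]))
  }
  invisible(x)
}

# proper rotations of the lattice point group, as integer matrices on the
# basis (entries in -1..1 suffice for a reduced basis). The tolerance is
# deliberately generous (1% of the mean metric diagonal): refined bases
# carry small metric errors, and missing a symmetry op turns a sign-flip of
# convention into a spurious near-180-degree misorientation.
lattice_symmetry_ops <- function(basis, tol = 1e-2) {
  G <- t(basis) %*% basis
  scale <- mean(diag(G))
  cb <- as.matrix(expand.grid(rep(list(-1:1), 9L)))
  dets <- cb[, 1] * (cb[, 5] * cb[, 9] - cb[, 6] * cb[, 8]) -
          cb[, 4] * (cb[, 2] * cb[, 9] - cb[, 3] * cb[, 8]) +
          cb[, 7] * (cb[, 2] * cb[, 6] - cb[, 3] * cb[, 5])
  cb <- cb[dets == 1, , drop = FALSE]
  ops <- list()
  for (i in seq_len(nrow(cb))) {
    H <- matrix(cb[i, ], 3L)
    if (max(abs(t(H) %*% G %*% H - G)) < tol * scale)
      ops[[length(ops) + 1L]] <- H
  }
  ops
}

#' Misorientation angle between two crystal orientations
#'
#' Returns the minimal rotation angle relating two orientation matrices of
#' the same lattice, minimised over the proper symmetry operations of the
#' lattice (so symmetry-equivalent orientations give 0).
#'
#' @param A1,A2 3x3 basis matrices (columns are cell vectors, lab frame).
#' @param cell_tol relative tolerance on the agreement of the two reduced
#'   cells; beyond it the lattices are declared incomparable.
#' @return angle in degrees.
#' @export
misorientation_angle <- function(A1, A2, cell_tol = 0.05) {
  r1 <- niggli_reduce(A1); r2 <- niggli_reduce(A2)
  c1 <- r1$cell; c2 <- r2$cell
  if (any(abs(c1[1:3] - c2[1:3]) > cell_tol * c1[1:3]) ||
      any(abs(c1[4:6] - c2[4:6]) > 5))
    stop("incomparable lattices: reduced cells differ beyond tolerance")
  B1 <- make_right_handed(r1$basis); B2 <- make_right_handed(r2$basis)
  ops <- lattice_symmetry_ops(B1)
  angles <- vapply(ops, function(H) {
    R <- nearest_rotation(B2 %*% H %*% solve(B1))
    rotation_angle_deg(R)
  }, 0)
  min(angles)
}
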