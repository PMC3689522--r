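# Basis selection: choose three candidate axes, form the orientation matrix
# [A] (columns a, b, c in the lab frame at phi = 0), and score it by how well
# it assigns integral indices to the observed scattering vectors, via
# h' = (1/wavelength) * t(A) %*% s.

#' Fractional Miller indices of scattering vectors under a basis
#'
#' @param A 3x3 basis matrix (columns are the real-space cell vectors, in
#'   angstroms, lab frame at phi = 0).
#' @param svecs data frame from [map_spots()], or an n x 3 matrix of s.
#' @param wavelength X-ray wavelength in angstroms.
#' @return list with `hkl` (n x 3 matrix of real-valued indices) and
#'   `deviation` (per reflection, the maximum over h, k, l of the distance
#'   to the nearest integer; always in `[0, 0.5]`).
#' @export
indices_from_basis <- function(A, svecs, wavelength) {
  if (abs(det(A)) < 1e-9) stop("degenerate basis: singular [A] matrix")
  S <- if (is.data.frame(svecs)) svec_matrix(svecs) else svecs
  hkl <- S %*% A / wavelength            # rows: h' = t(A) s / lambda
  dev <- abs(hkl - round(hkl))
  list(hkl = hkl, deviation = pmin(apply(dev, 1L, max), 0.5))
}

#' Count index-agreement rejections for a basis
#'
#' A reflection is rejected (counted once) when any of its three fractional
#' indices deviates from the nearest integer by at least `dev_threshold`.
#'
#' @inheritParams indices_from_basis
#' @param dev_threshold maximum tolerated deviation from integral indices
#'   (the conventional single-lattice value is 0.3).
#' @return integer rejection count.
#' @export
score_basis <- function(A, svecs, wavelength, dev_threshold = 0.3) {
  sum(indices_from_basis(A, svecs, wavelength)$deviation >= dev_threshold)
}

# right-handed copy of a basis (negate c if needed)
make_right_handed <- function(A) {
  if (det(A) < 0) A[, 3] <- -A[, 3]
  A
}

#' Select the best crystal basis from candidate axes
#'
#' Enumerates all triplets of the retained candidate axes, discards
#' degenerate ones (scaled triple product below `volume_floor` times the
#' product of lengths), and scores each by its rejection count. Among bases
#' whose count is within `max(3, slack_fraction * n)` of the minimum, the
#' smallest cell volume wins ("smallest number of rejections without having
#' a significantly larger unit cell"); remaining ties break on the larger
#' summed FFT peak height, then on candidate order, so the choice is
#' deterministic.
#'
#' @param candidates data frame from [find_axis_candidates()].
#' @param svecs data frame from [map_spots()].
#' @param geom an [experiment_geometry()].
#' @param dev_threshold index-deviation rejection threshold (default 0.3).
#' @param slack_fraction rejection slack as a fraction of the vector count.
#' @param volume_floor degenerate-triplet floor on the scaled triple product.
#' @param min_volume_A3 absolute floor on the cell volume in cubic
#'   angstroms (a cell this small indexes any spot list trivially).
#' @param max_reject_fraction give up when no triplet indexes at least this
#'   fraction of the vectors.
#' @param refine if `TRUE` (default), polish the chosen basis by linear least
#'   squares of the scattering vectors on their rounded integer indices
#'   (two rounds), which removes the small direction/length errors that the
#'   FFT candidates carry into triplet combinations.
#' @param n_alternatives how many runner-up bases (distinct reduced cells,
#'   in pool order) to return for downstream residual verification; thin
#'   single-image slabs admit near-degenerate bases that only the
#'   positional residual can reject.
#' @return list with `A` (3x3 right-handed basis), `cell`, `volume`,
#'   `rejections`, `n_vectors`, `mean_deviation`, `triplet` (candidate ranks
#'   used), and `alternatives` (list of runner-up bases in the same form).
#' @export
select_best_basis <- function(candidates, svecs, geom, dev_threshold = 0.3,
                              slack_fraction = 0.05, volume_floor = 0.01,
                              min_volume_A3 = 125,
                              max_reject_fraction = 0.5, refine = TRUE,
                              n_alternatives = 4L) {
  if (nrow(candidates) < 3L)
    stop("indexing failure: fewer than 3 candidate axes")
  n <- nrow(svecs)
  S <- svec_matrix(svecs)
  V <- as.matrix(candidates[, c("dx", "dy", "dz")]) * candidates$length_A
  lens <- candidates$length_A

  # per-candidate fractional index of every vector: Q[i, j] = v_i . s_j / lambda
  Q <- V %*% t(S) / geom$wavelength
  devC <- abs(Q - round(Q))                   # candidate x vector
  ok <- devC < dev_threshold
  ok_sharp <- devC < dev_threshold / 3
  # information gate: an axis shorter than the sampled reciprocal slab
  # assigns (nearly) the same integer to every reflection and so indexes
  # anything; require a minimal spread of assigned indices per axis
  n_distinct <- apply(round(Q), 1L, function(r) length(unique(r)))
  usable <- n_distinct >= 3L
  if (sum(usable) >= 3L && any(!usable)) {
    candidates <- candidates[usable, , drop = FALSE]
    V <- V[usable, , drop = FALSE]
    lens <- lens[usable]
    Q <- Q[usable, , drop = FALSE]
    devC <- devC[usable, , drop = FALSE]
    ok <- ok[usable, , drop = FALSE]
    ok_sharp <- ok_sharp[usable, , drop = FALSE]
  }
  if (nrow(candidates) < 3L)
    stop("indexing failure: fewer than 3 informative candidate axes")

  trip <- combn(nrow(candidates), 3L)
  cross_len <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                                u[3] * v[1] - u[1] * v[3],
                                u[1] * v[2] - u[2] * v[1])
  stats <- matrix(NA_real_, ncol(trip), 4L)  # rejections, volume, peaks, dev
  sharp <- rep(NA_real_, ncol(trip))
  for (ti in seq_len(ncol(trip))) {
    i <- trip[1L, ti]; j <- trip[2L, ti]; k <- trip[3L, ti]
    vol <- abs(sum(cross_len(V[i, ], V[j, ]) * V[k, ]))
    if (vol < max(volume_floor * lens[i] * lens[j] * lens[k], min_volume_A3)) next
    acc <- ok[i, ] & ok[j, ] & ok[k, ]
    rej <- n - sum(acc)
    stats[ti, ] <- c(rej, vol,
                     sum(candidates$peak_height[c(i, j, k)]),
                     mean(pmax(devC[i, ], devC[j, ], devC[k, ])))
    sharp[ti] <- sum(ok_sharp[i, ] & ok_sharp[j, ] & ok_sharp[k, ]) / max(sum(acc), 1L)
  }
  valid <- which(is.finite(stats[, 1]))
  if (!length(valid)) stop("indexing failure: all axis triplets degenerate")
  # acceptance-sharpness gate: for a basis that truly indexes a lattice most
  # accepted reflections sit close to integral indices, while a compromise
  # basis straddling several misoriented lattices fills the tolerance band
  # uniformly; prefer sharp triplets when any exist
  valid2 <- valid[sharp[valid] >= 0.5]
  if (length(valid2)) valid <- valid2
  min_rej <- min(stats[valid, 1])
  if (min_rej > max_reject_fraction * n)
    stop(sprintf(
      "indexing failure: best triplet rejects %d of %d vectors (over %.0f%%)",
      as.integer(min_rej), n, 100 * max_reject_fraction))
  slack <- max(3, slack_fraction * n)
  pool <- valid[stats[valid, 1] <= min_rej + slack]
  # a basis can slip under the rejection threshold yet misfit every index;
  # keep the volume preference among bases whose typical deviation is close
  # to the best seen, so a small accidental cell cannot outrank the lattice
  # that actually indexes the data
  dev_best <- min(stats[pool, 4])
  pool <- pool[stats[pool, 4] <= 1.5 * dev_best + 0.01]
  pool <- pool[order(stats[pool, 2], -stats[pool, 3], pool)]
  build <- function(ti) {
    A <- make_right_handed(t(V[trip[, ti], ]))
    if (refine) A <- refine_basis_linear(A, S, geom$wavelength, dev_threshold)
    dev <- indices_from_basis(A, S, geom$wavelength)$deviation
    list(A = A, cell = cell_params(A), volume = cell_volume(A),
         rejections = sum(dev >= dev_threshold), n_vectors = n,
         mean_deviation = mean(dev),
         triplet = candidates$rank[trip[, ti]])
  }
  # walk the pool collecting informative bases with distinct reduced cells:
  # a near-coplanar triplet reduces to a cell with one tiny axis along which
  # every reflection gets the same index — it fits a thin reciprocal slab
  # perfectly while saying nothing about the third dimension
  informative <- function(red_b) {
    Qr <- S %*% red_b$basis / geom$wavelength
    all(apply(round(Qr), 2L, function(x) length(unique(x))) >= 3L)
  }
  kept <- list(); seen <- character(0)
  for (ti in head(pool, 200L)) {
    if (length(kept) > n_alternatives) break
    b <- tryCatch(build(ti), error = function(e) NULL)
    if (is.null(b)) next
    red_b <- tryCatch(niggli_reduce(b$A), error = function(e) NULL)
    if (is.null(red_b) || !informative(red_b)) next
    k <- paste(round(sort(red_b$cell[1:3]), 1), collapse = ",")
    if (k %in% seen) next
    seen <- c(seen, k)
    kept[[length(kept) + 1L]] <- b
  }
  if (!length(kept)) kept <- list(build(pool[1L]))   # degrade gracefully
  out <- kept[[1L]]
  out$alternatives <- kept[-1L]
  out
}

# Linear least-squares polish of a basis: round the fractional indices of
# the well-indexed vectors and solve s ~ lambda * Brec h for the reciprocal
# basis. Two rounds of reassign-and-solve.
refine_basis_linear <- function(A, S, wavelength, dev_threshold = 0.3) {
  for (round_i in 1:2) {
    idx <- indices_from_basis(A, S, wavelength)
    use <- idx$deviation < dev_threshold
    if (sum(use) < 6L) return(A)
    H <- round(idx$hkl[use, , drop = FALSE])
    XtX <- crossprod(H)
    if (rcond(XtX) < 1e-10) return(A)
    Bt <- tryCatch(solve(XtX, crossprod(H, S[use, , drop = FALSE] / wavelength)),
                   error = function(e) NULL)
    if (is.null(Bt)) return(A)
    # S[use,] / lambda = H %*% t(Brec)  (least squares for Brec)
    Anew <- tryCatch(t(solve(t(Bt))), error = function(e) NULL)
    if (is.null(Anew) || abs(det(Anew)) < 0.5 * abs(det(A))) return(A)
    A <- make_right_handed(Anew)
  }
  A
}
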