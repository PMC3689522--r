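# One-dimensional FFT direction search: candidate real-space axes are found
# by projecting the scattering vectors onto a quasi-uniform hemisphere of
# directions and looking for periodicity in each projection. A direction
# parallel to a real-space axis of length a produces projections clustered
# with period wavelength/a, hence a strong non-origin FFT peak whose
# frequency index m maps back to the axis length as
# length = wavelength * m / (2 * smax).

#' Default parameters of the axis search
#'
#' @param angular_step_deg coarse hemisphere sampling step (degrees).
#' @param n_bins FFT length for the final length estimate (power of two).
#' @param coarse_bins FFT length used during the coarse hemisphere scan.
#' @param max_cell_A upper bound on recoverable axis lengths (angstroms);
#'   ribosome-like cells need headroom, hence the generous default.
#' @param min_cell_A lower bound on axis lengths; also excludes the FFT
#'   origin region.
#' @param max_vectors number of retained candidate axes.
#' @param peak_fraction acceptance threshold for a direction, as a fraction
#'   of the number of scattering vectors.
#' @param collinear_tol_deg two candidates closer than this (or closer than
#'   this to antiparallel) are considered collinear; the longer one is
#'   eliminated.
#' @param refine_stages,refine_shrink number of successive local grid
#'   refinements of each direction and the step shrink factor per stage.
#' @return list of parameters.
#' @export
axis_search_params <- function(angular_step_deg = 1.7, n_bins = 8192L,
                               coarse_bins = 2048L, max_cell_A = 300,
                               min_cell_A = 5, max_vectors = 30L,
                               peak_fraction = 0.2, collinear_tol_deg = 2,
                               refine_stages = 2L, refine_shrink = 5) {
  stopifnot(angular_step_deg > 0, angular_step_deg <= 10,
            max_cell_A > min_cell_A, min_cell_A > 0)
  as.list(environment())
}

#' Quasi-uniform sampling of a hemisphere of directions
#'
#' Latitude rings at the requested angular step, with the azimuthal step
#' widened by `1/sin(polar)` so neighbouring samples keep roughly the
#' requested spacing. Only `z >= 0` is covered; a projection axis and its
#' negation are equivalent, so the equator ring spans half a turn.
#'
#' @param angular_step_deg target nearest-neighbour spacing in degrees.
#' @return matrix with one unit row vector per direction.
#' @export
sample_hemisphere <- function(angular_step_deg) {
  stopifnot(angular_step_deg > 0, angular_step_deg <= 90)
  step <- deg2rad(angular_step_deg)
  n_pol <- max(1L, round(pi / 2 / step))
  polar <- (0:n_pol) * (pi / 2) / n_pol
  rows <- lapply(polar, function(th) {
    if (th < 1e-9) return(matrix(c(0, 0, 1), nrow = 1L))
    half <- abs(th - pi / 2) < 1e-9     # equator: axes, so half a turn
    span <- if (half) pi else 2 * pi
    n_az <- max(1L, round(span * sin(th) / step))
    az <- (seq_len(n_az) - 1L) * span / n_az
    cbind(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  })
  do.call(rbind, rows)
}

fft_m_range <- function(smax, wavelength, params) {
  # length = wavelength * m / (2 smax)  =>  m = 2 smax * length / wavelength
  c(lo = max(1, ceiling(2 * smax * params$min_cell_A / wavelength)),
    hi = floor(2 * smax * params$max_cell_A / wavelength))
}

#' Project scattering vectors onto a direction and FFT the projection
#'
#' @param svecs data frame from [map_spots()].
#' @param t unit 3-vector, the projection axis.
#' @param geom an [experiment_geometry()] (for the wavelength).
#' @param params an [axis_search_params()].
#' @param n_bins FFT length; defaults to `params$n_bins`.
#' @return list with `peak_height` (magnitude of the strongest in-range
#'   non-origin peak above the local spectral background — the smooth
#'   projection density leaks power into low frequencies, so raw magnitudes
#'   overstate weak directions), `raw_magnitude` (uncorrected magnitude at
#'   the peak), `peak_index` (FFT frequency index, 0 when no peak exists),
#'   `axis_length_A` (from the sub-bin interpolated peak frequency) and
#'   `n_vectors`.
#' @export
project_and_fft <- function(svecs, t, geom, params = axis_search_params(),
                            n_bins = params$n_bins) {
  if (nrow(svecs) < 3L) stop("insufficient data: need at least 3 vectors")
  stopifnot(bitwAnd(n_bins, n_bins - 1L) == 0L)
  S <- svec_matrix(svecs)
  smax <- max(sqrt(rowSums(S^2)))
  if (smax <= 0) return(list(peak_height = 0, raw_magnitude = 0,
                             peak_index = 0L,
                             axis_length_A = NA_real_, n_vectors = nrow(S)))
  t <- t / sqrt(sum(t^2))
  mr <- fft_m_range(smax, geom$wavelength, params)
  res <- cpp_fft_scan(S, matrix(t, nrow = 1L), smax, as.integer(n_bins),
                      as.integer(mr["lo"]), as.integer(mr["hi"]))
  list(peak_height = res[1, 2], raw_magnitude = res[1, 1],
       peak_index = as.integer(res[1, 3]),
       axis_length_A = if (res[1, 3] > 0)
         geom$wavelength * res[1, 4] / (2 * smax) else NA_real_,
       n_vectors = nrow(S))
}

# Local tangent-plane grid of directions around t0 (5 x 5, +-2 steps).
local_direction_grid <- function(t0, step_deg) {
  t0 <- t0 / sqrt(sum(t0^2))
  ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * t0) * t0; u <- u / sqrt(sum(u^2))
  v <- c(t0[2] * u[3] - t0[3] * u[2],
         t0[3] * u[1] - t0[1] * u[3],
         t0[1] * u[2] - t0[2] * u[1])
  g <- expand.grid(a = -2:2, b = -2:2)
  s <- tan(deg2rad(step_deg))
  dirs <- t(vapply(seq_len(nrow(g)), function(i) {
    w <- t0 + s * (g$a[i] * u + g$b[i] * v)
    w / sqrt(sum(w^2))
  }, numeric(3)))
  dirs
}

# canonical sign for an axis direction: z > 0, ties broken on x then y
canonical_direction <- function(t) {
  key <- c(t[3], t[1], t[2])
  flip <- key[which(abs(key) > 1e-12)[1]] < 0
  if (isTRUE(flip)) -t else t
}

#' Find candidate real-space axes by the hemisphere FFT search
#'
#' Runs the coarse hemisphere scan, keeps directions whose best in-range FFT
#' peak exceeds the acceptance fraction, condenses them to local maxima,
#' refines each by two successive local grid searches with step sizes shrunk
#' by `refine_shrink` per stage, prunes collinear duplicates (eliminating the
#' longer axis) and returns up to `max_vectors` axes sorted by descending
#' peak height. Deterministic for identical input.
#'
#' @param svecs data frame from [map_spots()].
#' @param geom an [experiment_geometry()].
#' @param params an [axis_search_params()].
#' @return data frame with columns `dx, dy, dz` (unit direction),
#'   `length_A`, `peak_height` (background-corrected peak magnitude, see
#'   [project_and_fft()]), `raw_magnitude`, `rank`.
#' @export
find_axis_candidates <- function(svecs, geom, params = axis_search_params()) {
  n <- nrow(svecs)
  if (n < 3L) stop("insufficient data: need at least 3 vectors")
  if (n < 30L)
    warning("only ", n, " vectors: indexing may be unreliable below 30")
  S <- svec_matrix(svecs)
  smax <- max(sqrt(rowSums(S^2)))
  if (smax <= 0) stop("indexing failure: all scattering vectors are zero")
  mr <- fft_m_range(smax, geom$wavelength, params)
  if (mr["hi"] < mr["lo"])
    stop("indexing failure: no admissible FFT frequency range")
  thresh <- params$peak_fraction * n

  dirs <- sample_hemisphere(params$angular_step_deg)
  coarse <- cpp_fft_scan(S, dirs, smax, as.integer(params$coarse_bins),
                         as.integer(mr["lo"]), as.integer(mr["hi"]))
  keep <- which(coarse[, 1] >= thresh & coarse[, 2] > 0)
  if (!length(keep))
    stop(sprintf(
      "indexing failure: no direction reached the acceptance peak height (best %.1f of %.1f needed, %d vectors)",
      max(coarse[, 1]), thresh, n))

  # condense to local maxima: greedy pick by contrast with an exclusion radius
  ord <- keep[order(coarse[keep, 2], decreasing = TRUE)]
  excl <- cos(deg2rad(2 * params$angular_step_deg))
  seeds <- integer(0)
  for (i in ord) {
    if (length(seeds) >= 2L * params$max_vectors) break
    if (!length(seeds) ||
        all(abs(dirs[seeds, , drop = FALSE] %*% dirs[i, ]) < excl))
      seeds <- c(seeds, i)
  }

  refined <- lapply(seeds, function(i) {
    t0 <- dirs[i, ]
    step <- params$angular_step_deg
    for (st in seq_len(params$refine_stages)) {
      step <- step / params$refine_shrink
      grid <- local_direction_grid(t0, step)
      r <- cpp_fft_scan(S, grid, smax, as.integer(params$coarse_bins),
                        as.integer(mr["lo"]), as.integer(mr["hi"]))
      t0 <- grid[which.max(r[, 2]), ]
    }
    r <- cpp_fft_scan(S, matrix(t0, nrow = 1L), smax,
                      as.integer(params$n_bins),
                      as.integer(mr["lo"]), as.integer(mr["hi"]))
    t0 <- canonical_direction(t0)
    c(t0, geom$wavelength * r[1, 4] / (2 * smax), r[1, 2], r[1, 1])
  })
  cand <- do.call(rbind, refined)
  colnames(cand) <- c("dx", "dy", "dz", "length_A", "peak_height", "raw_magnitude")
  cand <- as.data.frame(cand)
  cand <- cand[cand$raw_magnitude >= thresh & !is.na(cand$length_A) &
                 cand$length_A > 0, , drop = FALSE]
  # leakage guard: a genuine axis peak rises from a low spectral floor, so
  # its background-corrected height is close to the raw magnitude; short
  # pseudo-periodicities of the Ewald-slab geometry (lune spacings) ride on
  # the leakage background instead and index trivially downstream
  cand <- cand[cand$peak_height >= 0.6 * cand$raw_magnitude, , drop = FALSE]
  if (!nrow(cand)) stop("indexing failure: no candidate axis above the leakage background")
  if (!nrow(cand)) stop("indexing failure: refinement lost all candidates")

  # collinearity pruning: among collinear axes keep the shortest
  cand <- cand[order(cand$length_A), , drop = FALSE]
  ctol <- cos(deg2rad(params$collinear_tol_deg))
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ti <- as.numeric(cand[i, 1:3])
    if (!length(kept) ||
        all(abs(as.matrix(cand[kept, 1:3]) %*% ti) < ctol))
      kept <- c(kept, i)
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$peak_height, decreasing = TRUE), , drop = FALSE]
  cand <- head(cand, params$max_vectors)
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}
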