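# Spot filtering and practical aids: automatic I/sigma thresholds, false-
# spot exclusion by intensity / resolution / ice rings / size, selection of
# an image pair near 90 degrees apart, and the direct-beam grid search.

#' Ice-ring resolution bands for hexagonal ice
#'
#' The strongest powder rings of hexagonal ice; disabled unless explicitly
#' passed to a [filter_policy()].
#'
#' @param half_width_A half-width of each excluded band in angstroms.
#' @return two-column matrix `(d_centre_A, half_width_A)`.
#' @export
default_ice_bands <- function(half_width_A = 0.03) {
  cbind(d_centre_A = c(3.90, 3.67, 3.44, 2.67, 2.25, 2.07, 1.95, 1.92, 1.88),
        half_width_A = half_width_A)
}

#' Spot-filtering policy
#'
#' @param i_over_sigma `"auto"` (threshold from [auto_threshold()]) or an
#'   explicit value. Very large explicit values (50-100) are the recommended
#'   strategy for highly mosaic crystals, where the strongest spots are the
#'   ones whose true phi lies closest to the oscillation midpoint.
#' @param d_min_A,d_max_A resolution window in angstroms.
#' @param ice_bands `NULL`, or a matrix as from [default_ice_bands()].
#' @param size_window_mm optional `(min, max)` spot size window.
#' @return a `fftindex_filter_policy` list.
#' @export
filter_policy <- function(i_over_sigma = "auto", d_min_A = 0, d_max_A = Inf,
                          ice_bands = NULL, size_window_mm = NULL) {
  if (!identical(i_over_sigma, "auto"))
    stopifnot(is.numeric(i_over_sigma), i_over_sigma > 0)
  stopifnot(d_min_A >= 0, d_max_A > d_min_A)
  if (!is.null(ice_bands)) {
    ice_bands <- as.matrix(ice_bands)
    stopifnot(ncol(ice_bands) == 2L, all(ice_bands > 0))
    lo <- ice_bands[, 1] - ice_bands[, 2]
    hi <- ice_bands[, 1] + ice_bands[, 2]
    ord <- order(lo)
    if (any(lo[ord][-1] < hi[ord][-length(hi)]))
      stop("ice bands overlap")
  }
  structure(list(i_over_sigma = i_over_sigma, d_min_A = d_min_A,
                 d_max_A = d_max_A, ice_bands = ice_bands,
                 size_window_mm = size_window_mm),
            class = "fftindex_filter_policy")
}

#' Automatic I/sigma threshold
#'
#' The threshold is 20 when the image(s) show strong diffraction, dropping
#' to 10 and then 5 for weaker data: strong means at least `min_usable`
#' spots survive the candidate threshold.
#'
#' @param spots spot-list data frame.
#' @param min_usable how many surviving spots qualify an image set as strong
#'   enough for a threshold level.
#' @return 20, 10 or 5.
#' @export
auto_threshold <- function(spots, min_usable = 200L) {
  stopifnot(nrow(spots) >= 1L)
  isig <- spots$intensity / spots$sigma
  if (sum(isig >= 20) >= min_usable) return(20)
  if (sum(isig >= 10) >= min_usable) return(10)
  5
}

#' Filter a spot list for indexing
#'
#' Keeps spots that pass the I/sigma threshold, lie inside the resolution
#' window, avoid all ice bands, and (when spot sizes are present) fall
#' inside the size window. Input order is preserved; filtering is
#' idempotent.
#'
#' @param spots spot-list data frame.
#' @param policy a [filter_policy()].
#' @param geom an [experiment_geometry()] (for resolutions).
#' @return the accepted subset of `spots` (warning below 30 survivors,
#'   error when none survive).
#' @export
filter_spots <- function(spots, policy = filter_policy(), geom) {
  validate_spots(spots)
  stopifnot(inherits(policy, "fftindex_filter_policy"))
  thr <- if (identical(policy$i_over_sigma, "auto")) auto_threshold(spots)
         else policy$i_over_sigma
  keep <- spots$intensity / spots$sigma >= thr
  svecs <- map_spots(spots, geom, common_origin = FALSE)
  ns <- sqrt(svecs$sx^2 + svecs$sy^2 + svecs$sz^2)
  d <- ifelse(ns > 0, geom$wavelength / ns, Inf)
  keep <- keep & d >= policy$d_min_A & (d <= policy$d_max_A | is.infinite(d))
  if (!is.null(policy$ice_bands)) {
    for (i in seq_len(nrow(policy$ice_bands))) {
      ctr <- policy$ice_bands[i, 1]; hw <- policy$ice_bands[i, 2]
      keep <- keep & !(d >= ctr - hw & d <= ctr + hw)
    }
  }
  if (!is.null(policy$size_window_mm) && "size_mm" %in% names(spots)) {
    keep <- keep & spots$size_mm >= policy$size_window_mm[1] &
      spots$size_mm <= policy$size_window_mm[2]
  }
  out <- spots[keep, , drop = FALSE]
  if (!nrow(out)) stop("no spots survive the filter")
  if (nrow(out) < 30L)
    warning("only ", nrow(out),
            " spots survive the filter; indexing may be unreliable")
  rownames(out) <- NULL
  out
}

#' Select the image pair closest to 90 degrees apart
#'
#' @param images data frame with columns `image` and `phi_mid_deg` (one row
#'   per available image), or a spot list (pairs derived from its images).
#' @return the selected image identifiers (length 1 when only one image is
#'   available); ties break on the earliest images.
#' @export
select_image_pair <- function(images) {
  if (!("phi_mid_deg" %in% names(images)) && "phi_start_deg" %in% names(images)) {
    phi <- (images$phi_start_deg + images$phi_end_deg) / 2
    images <- unique(data.frame(image = images$image_id, phi_mid_deg = phi))
  }
  stopifnot(nrow(images) >= 1L)
  if (nrow(images) == 1L) return(images$image[1L])
  pairs <- combn(nrow(images), 2L)
  sep <- abs(abs(images$phi_mid_deg[pairs[1, ]] -
                 images$phi_mid_deg[pairs[2, ]]) - 90)
  best <- which(sep == min(sep))[1L]
  images$image[pairs[, best]]
}

#' Two-dimensional grid search for the direct-beam position
#'
#' Indexing is attempted over a grid of beam positions (by default +-2 steps
#' of 0.5 mm in each direction from the starting position, 25 positions).
#' For each position the triclinic positional residual (with the beam held
#' fixed at the node, so the residual measures the node's beam error), the
#' refined beam position and the primitive cell volume are recorded.
#' Solutions whose volume exceeds 1.5x the grid-wide median are discarded
#' (oversized cells reach low residuals even when wrong); among the rest,
#' different starting positions that refine to the same beam are the
#' signature of the correct solution family, so the recommendation is the
#' lowest-residual node within the largest cluster of refined beams. A
#' re-indexing by +-1 along a cell axis can mimic a beam shift of about
#' wavelength x distance / axis and produce isolated low-residual nodes;
#' the consistency rule rejects those.
#'
#' @param spots filtered spot-list data frame.
#' @param geom an [experiment_geometry()] holding the starting beam.
#' @param step_mm grid step in mm.
#' @param n_steps number of steps on each side of the start.
#' @param params an [axis_search_params()]; the search runs the indexing
#'   pipeline with triclinic-only refinement at every node, the residual
#'   being the search metric.
#' @param volume_factor volume-outlier cut relative to the median.
#' @param cluster_radius_mm radius within which refined beams from
#'   different nodes count as agreeing.
#' @return list with `table` (per-position `bx, by, sigma_xy_mm, volume_A3,
#'   ref_bx, ref_by, ok`), `recommended` (row index of the best position),
#'   `best_beam` (grid node) and `refined_beam` (beam refined from that
#'   node).
#' @export
beam_grid_search <- function(spots, geom, step_mm = 0.5, n_steps = 2L,
                             params = axis_search_params(),
                             volume_factor = 1.5, cluster_radius_mm = 0.25) {
  validate_spots(spots)
  offs <- seq(-n_steps, n_steps) * step_mm
  grid <- expand.grid(dx = offs, dy = offs)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g2 <- geom
    g2$beam_centre <- geom$beam_centre + c(grid$dx[i], grid$dy[i])
    res <- tryCatch(index_spots(spots, g2, params = params,
                                characters = "aP", refine_beam = FALSE),
                    error = function(e) NULL)
    rows[[i]] <- if (is.null(res)) {
      data.frame(bx = g2$beam_centre[1], by = g2$beam_centre[2],
                 sigma_xy_mm = NA_real_, volume_A3 = NA_real_,
                 ref_bx = NA_real_, ref_by = NA_real_, ok = FALSE)
    } else {
      b <- res$best
      ref <- tryCatch(
        refine_solution(data.frame(id = 31L, bravais = "aP", penalty = 0L),
                        res$reduced, spots, g2, refine_beam = TRUE),
        error = function(e) NULL)
      data.frame(bx = g2$beam_centre[1], by = g2$beam_centre[2],
                 sigma_xy_mm = b$sigma_xy_mm, volume_A3 = res$basis$volume,
                 ref_bx = if (is.null(ref)) NA_real_ else ref$beam[1],
                 ref_by = if (is.null(ref)) NA_real_ else ref$beam[2],
                 ok = b$converged)
    }
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$ok)) stop("beam search failed at every grid position")
  med_vol <- median(tab$volume_A3[tab$ok])
  admissible <- tab$ok & tab$volume_A3 <= volume_factor * med_vol
  if (!any(admissible)) admissible <- tab$ok
  idx <- which(admissible & is.finite(tab$ref_bx) & is.finite(tab$ref_by))
  if (length(idx) > 1L) {
    nb <- vapply(idx, function(i) sum(
      sqrt((tab$ref_bx[idx] - tab$ref_bx[i])^2 +
           (tab$ref_by[idx] - tab$ref_by[i])^2) <= cluster_radius_mm), 0L)
    centre <- idx[order(-nb, tab$sigma_xy_mm[idx])][1L]
    cluster <- idx[sqrt((tab$ref_bx[idx] - tab$ref_bx[centre])^2 +
                        (tab$ref_by[idx] - tab$ref_by[centre])^2) <=
                     cluster_radius_mm]
    rec <- cluster[order(tab$sigma_xy_mm[cluster])][1L]
  } else {
    rec <- which(admissible)[order(tab$sigma_xy_mm[admissible])][1L]
  }
  list(table = tab, recommended = rec,
       best_beam = c(tab$bx[rec], tab$by[rec]),
       refined_beam = c(tab$ref_bx[rec], tab$ref_by[rec]))
}
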