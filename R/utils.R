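#' @useDynLib fftindex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median rnorm runif setNames
#' @importFrom utils combn head read.delim write.table
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about the laboratory Z (spindle) axis
#'
#' @param angle_deg rotation angle in degrees (right-handed about +Z).
#' @return a 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(angle_deg) {
  th <- deg2rad(angle_deg)
  c_ <- cos(th); s_ <- sin(th)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), nrow = 3L)
}

# General axis-angle rotation (Rodrigues), axis need not be unit length.
rot_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  k <- axis / n
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), nrow = 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Angle (deg) of a rotation matrix from its trace, clamped for roundoff.
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

# Nearest proper rotation to a 3x3 matrix (special orthogonal Procrustes).
nearest_rotation <- function(M) {
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# Angle in degrees between two directions, ignoring sign (axes, not rays).
axis_angle_between <- function(u, v) {
  cu <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  rad2deg(acos(pmin(1, cu)))
}

#' Cell parameters of a real-space basis
#'
#' @param A 3x3 matrix whose columns are the real-space cell vectors (in
#'   angstroms, laboratory frame).
#' @return named numeric vector `(a, b, c, alpha, beta, gamma)` in angstroms
#'   and degrees.
#' @export
cell_params <- function(A) {
  a <- A[, 1]; b <- A[, 2]; c <- A[, 3]
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(c^2))
  ang <- function(u, v) rad2deg(acos(pmin(1, pmax(-1, sum(u * v) /
    sqrt(sum(u^2) * sum(v^2))))))
  c(a = la, b = lb, c = lc,
    alpha = ang(b, c), beta = ang(a, c), gamma = ang(a, b))
}

#' Build a real-space basis matrix from cell parameters
#'
#' Uses the standard orthogonalization: a along x, b in the xy plane.
#'
#' @param cell numeric vector `(a, b, c, alpha, beta, gamma)` (angstroms,
#'   degrees).
#' @return 3x3 matrix with the cell vectors as columns.
#' @export
basis_from_cell <- function(cell) {
  stopifnot(length(cell) == 6L, all(is.finite(cell)), all(cell[1:3] > 0))
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  al <- deg2rad(cell[[4]]); be <- deg2rad(cell[[5]]); ga <- deg2rad(cell[[6]])
  cx <- cos(be)
  cy <- (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- 1 - cx^2 - cy^2
  if (cz2 <= 0) stop("cell parameters do not define a valid cell")
  matrix(c(a, 0, 0,
           b * cos(ga), b * sin(ga), 0,
           cc * cx, cc * cy, cc * sqrt(cz2)), nrow = 3L)
}

#' Volume of a cell given its basis
#' @param A 3x3 basis matrix (columns are cell vectors).
#' @return volume in cubic angstroms (absolute value of the determinant).
#' @export
cell_volume <- function(A) abs(det(A))

# Reciprocal basis (columns a*, b*, c* in 1/angstrom): t(solve(A)).
reciprocal_basis <- function(A) t(solve(A))

# Deterministic RNG scope: runs `expr` under `seed` and restores the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic random rotation matrix from a seed (used by the simulator).
random_rotation <- function(seed) {
  with_seed(seed, {
    ax <- rnorm(3)
    rot_axis_angle(ax, runif(1, 0, 360))
  })
}
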