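# Niggli cell reduction by the Krivy-Gruber stepwise algorithm, applied as
# integer column operations on the basis matrix so the lab-frame orientation
# is carried through. Comparisons are tolerance-guarded; the iteration is
# capped (a valid basis converges in far fewer steps).

niggli_scalars <- function(basis) {
  G <- t(basis) %*% basis
  c(A = G[1, 1], B = G[2, 2], C = G[3, 3],
    D = G[2, 3], E = G[1, 3], F = G[1, 2])
}

#' Niggli-reduce a crystal basis
#'
#' Returns a basis spanning the same lattice (the accumulated transformation
#' is unimodular) that satisfies the Niggli conditions: ordered metric
#' diagonal `A <= B <= C`, all-positive or all-non-positive scalar products,
#' and the main reduction inequalities.
#'
#' @param basis 3x3 matrix, columns are the cell vectors (lab frame).
#' @param rel_tol relative comparison tolerance.
#' @param max_iter iteration cap; exceeding it raises a reduction-failure
#'   error (unreachable for valid input).
#' @return list with `basis` (reduced, columns), `G` (named six scalars
#'   `A, B, C, D, E, F` = `a.a, b.b, c.c, b.c, a.c, a.b`), `transform`
#'   (integer matrix, `basis %*% transform` = reduced basis), `cell`.
#' @export
niggli_reduce <- function(basis, rel_tol = 1e-5, max_iter = 1000L) {
  if (abs(det(basis)) < 1e-9) stop("degenerate basis cannot be reduced")
  Tm <- diag(3)
  B0 <- basis
  apply_M <- function(M) {
    Tm <<- Tm %*% M
    B0 <<- B0 %*% M
  }
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("Niggli reduction failed to converge")
    g <- niggli_scalars(B0)
    A <- g["A"]; B <- g["B"]; C <- g["C"]
    xi <- 2 * g["D"]; eta <- 2 * g["E"]; zeta <- 2 * g["F"]
    eps <- rel_tol * mean(c(A, B, C))
    gt <- function(x, y) x > y + eps
    eq <- function(x, y) abs(x - y) <= eps

    if (gt(A, B) || (eq(A, B) && gt(abs(xi), abs(eta)))) {
      apply_M(matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3L))   # swap a,b
      next
    }
    if (gt(B, C) || (eq(B, C) && gt(abs(eta), abs(zeta)))) {
      apply_M(matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3L))   # swap b,c
      next
    }
    # sign normalisation (steps 3/4)
    pos <- c(gt(xi, 0), gt(eta, 0), gt(zeta, 0))
    neg <- c(gt(0, xi), gt(0, eta), gt(0, zeta))
    f <- c(1, 1, 1); zslot <- 0L
    if (prod(ifelse(pos, 1, ifelse(neg, -1, 0))) > 0) {
      f <- ifelse(neg, -1, 1)
    } else {
      for (i in 1:3) {
        if (pos[i]) f[i] <- -1 else if (!neg[i]) zslot <- i
      }
      if (prod(f) < 0) {
        if (zslot == 0L) stop("Niggli sign normalisation failed")
        f[zslot] <- -1
      }
    }
    if (any(f != 1)) {
      apply_M(diag(f))
      g <- niggli_scalars(B0)
      xi <- 2 * g["D"]; eta <- 2 * g["E"]; zeta <- 2 * g["F"]
    }
    if (gt(abs(xi), B) || (eq(xi, B) && gt(zeta, 2 * eta)) ||
        (eq(xi, -B) && gt(0, zeta))) {
      s <- if (xi > 0) 1 else -1
      M <- diag(3); M[2, 3] <- -s                     # c' = c - sign(xi) b
      apply_M(M); next
    }
    if (gt(abs(eta), A) || (eq(eta, A) && gt(zeta, 2 * xi)) ||
        (eq(eta, -A) && gt(0, zeta))) {
      s <- if (eta > 0) 1 else -1
      M <- diag(3); M[1, 3] <- -s                     # c' = c - sign(eta) a
      apply_M(M); next
    }
    if (gt(abs(zeta), A) || (eq(zeta, A) && gt(eta, 2 * xi)) ||
        (eq(zeta, -A) && gt(0, eta))) {
      s <- if (zeta > 0) 1 else -1
      M <- diag(3); M[1, 2] <- -s                     # b' = b - sign(zeta) a
      apply_M(M); next
    }
    if (gt(0, xi + eta + zeta + A + B) ||
        (eq(xi + eta + zeta + A + B, 0) && gt(2 * (A + eta) + zeta, 0))) {
      M <- diag(3); M[1, 3] <- 1; M[2, 3] <- 1        # c' = a + b + c
      apply_M(M); next
    }
    break
  }
  g <- niggli_scalars(B0)
  Tm <- round(Tm)
  structure(list(basis = B0, G = g, transform = Tm,
                 cell = cell_params(B0)),
            class = "fftindex_reduced")
}

#' @export
print.fftindex_reduced <- function(x, ...) {
  cl <- x$cell
  cat(sprintf("Niggli-reduced cell: %.3f %.3f %.3f A, %.3f %.3f %.3f deg\n",
              cl[1], cl[2], cl[3], cl[4], cl[5], cl[6]))
  invisible(x)
}
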