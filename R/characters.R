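# Classification of a Niggli-reduced cell against the 44 lattice characters.
# Each character is a set of equality conditions on the metric scalars
# (A, B, C, D, E, F) = (a.a, b.b, c.c, b.c, a.c, a.b) together with an
# integer transformation from the reduced to the conventional cell. The
# table ships as a versioned JSON data file, loadable independently of the
# code. A distortion penalty on a 0-999 scale measures how far a cell is
# from satisfying a character's conditions.

the <- new.env(parent = emptyenv())

#' The 44 lattice characters
#'
#' @return list of 44 entries, each with `id`, `bravais`, `type` (1 =
#'   all-acute, 2 = all-non-acute reduced form), `conditions` (list of
#'   equality constraints as expression strings over `A, B, C, D, E, F`)
#'   and `M` (3x3 integer reduced-to-conventional transformation, rows =
#'   conventional vectors in the reduced basis).
#' @export
lattice_characters <- function() {
  if (is.null(the$characters)) {
    path <- system.file("extdata", "lattice_characters.json",
                        package = "fftindex", mustWork = TRUE)
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    the$characters <- lapply(raw, function(ch) {
      list(id = ch$id, case = ch$case, type = ch$type, bravais = ch$bravais,
           conditions = lapply(ch$conditions, unlist),
           M = do.call(rbind, lapply(ch$M, unlist)))
    })
    stopifnot(length(the$characters) == 44L)
  }
  the$characters
}

# symmetry rank for sorting/highlighting: higher = more symmetric
bravais_rank <- function(bravais) {
  system <- substr(bravais, 1L, 1L)
  rank <- c(a = 1, m = 2, o = 3, t = 4, h = 5, c = 6)[system]
  unname(rank + ifelse(bravais == "hR", -0.5, 0))  # hR below hP
}

condition_value <- function(expr, G) {
  eval(parse(text = expr)[[1]],
       envir = list(A = G[["A"]], B = G[["B"]], C = G[["C"]],
                    D = G[["D"]], E = G[["E"]], F = G[["F"]]),
       enclos = baseenv())
}

# relative violation of one condition lhs = rhs
condition_violation <- function(cond, G) {
  x <- condition_value(cond[[1]], G)
  y <- condition_value(cond[[2]], G)
  if (identical(cond[[2]], "0")) return(abs(x) / G[["C"]])
  epsG <- 1e-6 * G[["C"]]
  abs(x - y) / max(abs(x), abs(y), epsG)
}

#' Distortion penalties of a reduced cell against all 44 lattice characters
#'
#' For each character the penalty is `round(999 * mean relative violation)`
#' of its conditions, capped at 999; the violation of an equality `X = Y` is
#' `|X - Y| / max(|X|, |Y|, epsG)` and of `X = 0` is `|X| / C`. The scale is
#' calibrated so that a distortion of about 1% of the metric yields a small
#' two-digit penalty, keeping the conventional screening thresholds (20 for
#' "low", 50 for the refinement gate) meaningful. Exact matches give 0.
#'
#' @param reduced a `fftindex_reduced` from [niggli_reduce()].
#' @return data frame with one row per character: `id, bravais, penalty`,
#'   the conventional cell `(a, b, c, alpha, beta, gamma)` obtained through
#'   the character's transformation, and `det` (centring multiplicity of the
#'   transformation). Sorted by penalty, then by descending symmetry.
#' @export
character_penalties <- function(reduced) {
  stopifnot(inherits(reduced, "fftindex_reduced"))
  G <- reduced$G
  chars <- lattice_characters()
  rows <- lapply(chars, function(ch) {
    viol <- if (length(ch$conditions))
      vapply(ch$conditions, condition_violation, 0, G = G) else 0
    pen <- min(999, round(999 * mean(viol)))
    Bconv <- reduced$basis %*% t(ch$M)
    cl <- cell_params(Bconv)
    data.frame(id = ch$id, bravais = ch$bravais, penalty = pen,
               a = cl[1], b = cl[2], c = cl[3],
               alpha = cl[4], beta = cl[5], gamma = cl[6],
               det = abs(det(ch$M)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$penalty, -bravais_rank(out$bravais), out$id), ]
  rownames(out) <- NULL
  out
}

# conventional basis (columns) for one character id
conventional_basis <- function(reduced, id) {
  ch <- Filter(function(x) x$id == id, lattice_characters())[[1]]
  reduced$basis %*% t(ch$M)
}
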