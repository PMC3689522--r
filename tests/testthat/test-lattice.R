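# Niggli reduction and the 44 lattice characters.

test_that("an already-reduced cell is a fixed point and volume is invariant", {
  B <- basis_from_cell(c(50, 60, 70, 90, 90, 90))
  red <- niggli_reduce(B)
  expect_equal(red$cell, cell_params(B), tolerance = 1e-10)
  expect_equal(abs(det(red$transform)), 1)
  # scrambled basis: same lattice, same reduced scalars
  B2 <- B %*% matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 1), 3)  # c' = a + b + c
  red2 <- niggli_reduce(B2)
  expect_equal(red2$G, red$G, tolerance = 1e-8)
  expect_equal(abs(det(red2$basis)), abs(det(B2)), tolerance = 1e-8)
})

test_that("reduced vectors are the shortest lattice vectors (brute force)", {
  set.seed(31)
  for (i in 1:5) {
    cl <- c(sort(runif(3, 25, 80)), runif(3, 75, 115))
    B <- tryCatch(basis_from_cell(cl), error = function(e) NULL)
    if (is.null(B)) next
    B2 <- B %*% matrix(c(1, -1, 0, 0, 1, 0, 2, 1, 1), 3)
    red <- niggli_reduce(B2)
    # brute-force enumeration of integer combinations with |coef| <= 3
    combos <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
    combos <- combos[rowSums(abs(combos)) > 0, ]
    lens <- sort(sqrt(rowSums((combos %*% t(B))^2)))
    expect_equal(red$cell[["a"]], lens[1], tolerance = 1e-8)
    # Niggli ordering and sign conventions
    G <- red$G
    expect_true(G[["A"]] <= G[["B"]] + 1e-6 && G[["B"]] <= G[["C"]] + 1e-6)
    s <- sign(round(c(G[["D"]], G[["E"]], G[["F"]]), 8))
    expect_true(all(s >= 0) || all(s <= 0))
    # transformation is unimodular and consistent
    expect_equal(abs(det(red$transform)), 1)
    expect_lt(max(abs(B2 %*% red$transform - red$basis)), 1e-8)
  }
})

test_that("the character table has 44 self-consistent entries", {
  chars <- lattice_characters()
  expect_length(chars, 44L)
  expect_setequal(vapply(chars, `[[`, 0, "id"), 1:44)
  dets <- vapply(chars, function(ch) round(abs(det(ch$M))), 0)
  expect_true(all(dets %in% c(1, 2, 3, 4)))
  bv <- vapply(chars, `[[`, "", "bravais")
  expect_true(all(bv %in% c("aP", "mP", "mC", "mI", "oP", "oC", "oF", "oI",
                            "tP", "tI", "hP", "hR", "cP", "cF", "cI")))
})

test_that("exact cells score zero for their characters, positive elsewhere", {
  # cubic
  pen <- character_penalties(niggli_reduce(basis_from_cell(c(50, 50, 50, 90, 90, 90))))
  expect_equal(pen$penalty[pen$bravais == "cP"][1], 0)
  expect_true(all(pen$penalty[pen$bravais %in% c("cF", "cI")] > 0))
  # orthorhombic: oP and aP zero, all tetragonal/cubic positive
  pen <- character_penalties(niggli_reduce(basis_from_cell(c(50, 60, 70, 90, 90, 90))))
  expect_equal(min(pen$penalty[pen$bravais == "oP"]), 0)
  expect_true(all(pen$penalty[pen$bravais == "aP"] == 0))
  expect_true(all(pen$penalty[substr(pen$bravais, 1, 1) %in% c("t", "c")] > 0))
  # monoclinic
  pen <- character_penalties(niggli_reduce(basis_from_cell(c(50, 60, 70, 90, 101, 90))))
  expect_equal(min(pen$penalty[pen$bravais == "mP"]), 0)
  expect_true(all(pen$penalty[substr(pen$bravais, 1, 1) == "o"] > 0))
  # always exactly 44 rows
  expect_equal(nrow(pen), 44L)
})

test_that("penalties grow monotonically with metric distortion", {
  tp <- function(b) {
    pen <- character_penalties(niggli_reduce(basis_from_cell(c(50, b, 70, 90, 90, 90))))
    min(pen$penalty[pen$bravais == "tP"])
  }
  p <- vapply(c(50.5, 51, 52, 54), tp, 0)
  expect_true(all(p > 0))
  expect_true(all(diff(p) > 0))
})

test_that("generated Bravais lattices are recovered with exact conventional metric", {
  centrings <- list(
    P = diag(3),
    C = matrix(c(.5, -.5, 0, .5, .5, 0, 0, 0, 1), 3),
    I = matrix(c(1, 0, 0, 0, 1, 0, .5, .5, .5), 3),
    F = matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3),
    R = matrix(c(2/3, 1/3, 1/3, -1/3, 1/3, 1/3, -1/3, -2/3, 1/3), 3))
  cases <- list(
    list(bv = "cI", cell = c(64, 64, 64, 90, 90, 90)),
    list(bv = "cF", cell = c(83, 83, 83, 90, 90, 90)),
    list(bv = "tI", cell = c(46, 46, 91, 90, 90, 90)),
    list(bv = "hP", cell = c(58, 58, 77, 90, 90, 120)),
    list(bv = "hR", cell = c(55, 55, 98, 90, 90, 120)),
    list(bv = "oC", cell = c(41, 72, 66, 90, 90, 90)),
    list(bv = "oF", cell = c(43, 66, 95, 90, 90, 90)),
    list(bv = "oI", cell = c(44, 58, 83, 90, 90, 90)),
    list(bv = "mC", cell = c(52, 38, 67, 90, 107, 90)))
  set.seed(41)
  for (cs in cases) {
    Bc <- basis_from_cell(cs$cell)
    Bp <- fftindex:::rot_axis_angle(rnorm(3), runif(1, 0, 360)) %*%
      Bc %*% centrings[[substr(cs$bv, 2, 2)]]
    red <- niggli_reduce(Bp)
    pen <- character_penalties(red)
    hit <- pen[pen$penalty == 0 & pen$bravais == cs$bv, , drop = FALSE]
    expect_gt(nrow(hit), 0)
    got <- sort(as.numeric(hit[1, c("a", "b", "c")]))
    expect_equal(got, sort(cs$cell[1:3]), tolerance = 1e-4)
  }
})

test_that("zero-penalty conventional cells contain the reduced lattice", {
  red <- niggli_reduce(basis_from_cell(c(50, 60, 70, 90, 90, 90)))
  pen <- character_penalties(red)
  for (id in pen$id[pen$penalty == 0]) {
    Bconv <- fftindex:::conventional_basis(red, id)
    coords <- solve(red$basis, Bconv)
    expect_lt(max(abs(coords - round(coords))), 1e-8)
  }
})
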