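test_that("fractional indices solve the reciprocal linear system", {
  set.seed(3)
  cell <- c(47, 55, 80, 85, 95, 100)
  A <- fftindex:::rot_axis_angle(rnorm(3), 77) %*% basis_from_cell(cell)
  lam <- 1.2
  H <- matrix(sample(-8:8, 30, TRUE), ncol = 3)
  S <- lam * t(t(solve(A)) %*% t(H))     # forward model s = lambda B h
  idx <- indices_from_basis(A, S, lam)
  expect_lt(max(abs(idx$hkl - H)), 1e-9)
  expect_lt(max(idx$deviation), 1e-9)
  # independent oracle: solve the 3x3 linear system per vector
  h_solve <- t(apply(S, 1L, function(s) solve(lam * t(solve(A)), s)))
  expect_equal(unname(idx$hkl), unname(h_solve), tolerance = 1e-9)
  # zero vector indexes as the origin
  expect_equal(indices_from_basis(A, matrix(0, 1, 3), lam)$deviation, 0)
})

test_that("rejection counting is per reflection and monotone in the threshold", {
  set.seed(5)
  A <- basis_from_cell(c(50, 60, 70, 90, 90, 90))
  H <- matrix(sample(-6:6, 60, TRUE), ncol = 3)
  S <- t(t(solve(A)) %*% t(H))
  expect_equal(score_basis(A, S, 1), 0L)
  # perturb one vector so its deviation is 0.35 in one index
  S2 <- S
  S2[4, ] <- S2[4, ] + 0.35 * t(solve(A))[, 1]
  expect_equal(score_basis(A, S2, 1), 1L)
  # non-increasing as the threshold grows
  thr <- seq(0.05, 0.45, by = 0.05)
  rej <- vapply(thr, function(t) score_basis(A, S2, 1, dev_threshold = t), 0L)
  expect_true(all(diff(rej) <= 0))
})

test_that("a halved axis is rejected on odd-index-rich data", {
  set.seed(8)
  A <- basis_from_cell(c(50, 60, 70, 90, 90, 90))
  H <- matrix(sample(c(-5, -3, -1, 1, 3, 5), 300, TRUE), ncol = 3)  # odd h
  S <- t(t(solve(A)) %*% t(H))
  A_half <- A
  A_half[, 1] <- A_half[, 1] / 2
  expect_gt(score_basis(A_half, S, 1), 0.5 * nrow(S))
})

test_that("best basis recovers the cell; a doubled axis loses on volume", {
  gen <- cached_ortho(1)
  geom <- std_geom()
  sv <- map_spots(gen$spots, geom)
  cand <- find_axis_candidates(sv, geom)
  sel <- select_best_basis(cand, sv, geom)
  red <- niggli_reduce(sel$A)
  expect_cell_close(red$cell, c(50, 60, 70, 90, 90, 90))
  # inject a doubled a axis as an extra candidate: equal rejections but
  # double volume, so the true cell must still win
  i50 <- which.min(abs(cand$length_A - 50))
  dup <- cand[i50, ]
  dup$length_A <- dup$length_A * 2
  cand2 <- rbind(cand, dup)
  cand2$rank <- seq_len(nrow(cand2))
  sel2 <- select_best_basis(cand2, sv, geom)
  expect_equal(cell_volume(sel2$A), cell_volume(sel$A), tolerance = 0.02)
  # determinism
  expect_identical(select_best_basis(cand, sv, geom)$triplet, sel$triplet)
})

test_that("collinear triplets are degenerate and failures are signalled", {
  geom <- std_geom()
  sv <- data.frame(sx = runif(50, -0.2, 0.2), sy = runif(50, -0.2, 0.2),
                   sz = runif(50, -0.2, 0.2), phi_mid_deg = 0, spot = 1:50)
  coll <- data.frame(dx = c(1, 1, 1) / sqrt(3), dy = c(1, 1, 1) / sqrt(3),
                     dz = c(1, 1, 1) / sqrt(3),
                     length_A = c(50, 51, 52), peak_height = 1,
                     raw_magnitude = 1, rank = 1:3)
  expect_error(select_best_basis(coll, sv, geom), "degenerate")
  expect_error(select_best_basis(coll[1:2, ], sv, geom), "fewer than 3")
})

test_that("exact reciprocal-lattice clouds index to machine precision", {
  # scattering vectors placed exactly on reciprocal-lattice points (no
  # oscillation smearing): the selected and polished basis must reproduce
  # every integer index essentially exactly
  set.seed(12)
  A <- fftindex:::rot_axis_angle(rnorm(3), 130) %*%
    basis_from_cell(c(50, 60, 70, 90, 90, 90))
  H <- as.matrix(expand.grid(h = -18:18, k = -21:21, l = -25:25))
  S <- t(t(solve(A)) %*% t(H))
  S <- S[sqrt(rowSums(S^2)) <= 0.35 & rowSums(abs(H)) > 0, ]
  S <- S[sample(nrow(S), 400), ]
  sv <- data.frame(sx = S[, 1], sy = S[, 2], sz = S[, 3],
                   phi_mid_deg = 0, spot = seq_len(nrow(S)))
  geom <- std_geom()
  cand <- find_axis_candidates(sv, geom)
  sel <- select_best_basis(cand, sv, geom)
  dev <- indices_from_basis(sel$A, sv, geom$wavelength)$deviation
  expect_lt(max(dev), 1e-6)
  expect_equal(sel$rejections, 0L)
})
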