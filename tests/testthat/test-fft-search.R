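# direct-DFT oracle on a binned series, independent of the compiled path
direct_dft_mag <- function(p, smax, n_bins, m) {
  b <- pmin(pmax(floor((p + smax) / (2 * smax) * n_bins), 0), n_bins - 1)
  counts <- tabulate(b + 1L, nbins = n_bins)
  k <- 0:(n_bins - 1)
  abs(sum(counts * exp(-2i * pi * m * k / n_bins)))
}

comb_svecs <- function(a = 50, lambda = 1, smax = 0.5, n = 100) {
  p <- rep(seq(-floor(smax * a / lambda), floor(smax * a / lambda)) *
             lambda / a, length.out = n)
  rbind(data.frame(sx = p, sy = 0, sz = 0, phi_mid_deg = 0, spot = seq_len(n)),
        data.frame(sx = smax, sy = 0, sz = 0, phi_mid_deg = 0, spot = n + 1L))
}

test_that("hemisphere sampling is quasi-uniform and one-sided", {
  d90 <- sample_hemisphere(90)
  expect_true(nrow(d90) <= 6)
  expect_true(any(abs(d90[, 3] - 1) < 1e-12))   # pole present
  d <- sample_hemisphere(1.7)
  expect_gt(nrow(d), 5000)
  expect_lt(nrow(d), 12000)
  expect_true(all(d[, 3] >= -1e-12))
  expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-12)
  expect_identical(d, sample_hemisphere(1.7))   # deterministic
})

test_that("a synthetic comb peaks at m = 2 smax a / lambda and lengths calibrate", {
  sv <- comb_svecs(a = 50, smax = 0.5)
  r <- project_and_fft(sv, c(1, 0, 0), std_geom(), n_bins = 8192L)
  expect_identical(r$peak_index, 50L)
  expect_equal(r$axis_length_A, 50, tolerance = 0.01)
  # magnitude agrees with the direct-DFT oracle at the peak
  oracle <- direct_dft_mag(sv$sx, 0.5, 8192L, 50)
  expect_equal(r$raw_magnitude, oracle, tolerance = 1e-6)
  expect_gt(r$peak_height, 0.5 * nrow(sv))
})

test_that("quarter-bin jitter does not move the comb peak", {
  sv <- comb_svecs(a = 50, smax = 0.5)
  set.seed(11)
  binw <- 2 * 0.5 / 8192
  sv$sx <- sv$sx + runif(nrow(sv), -binw / 4, binw / 4)
  sv$sx <- pmin(pmax(sv$sx, -0.5), 0.5)
  r <- project_and_fft(sv, c(1, 0, 0), std_geom(), n_bins = 8192L)
  expect_identical(r$peak_index, 50L)
})

test_that("degenerate projections report no axis", {
  sv <- data.frame(sx = 0, sy = 0, sz = 0, phi_mid_deg = 0, spot = 1:10)
  r <- project_and_fft(sv, c(1, 0, 0), std_geom())
  expect_equal(r$peak_height, 0)
  expect_error(project_and_fft(sv[1:2, ], c(1, 0, 0), std_geom()),
               "insufficient")
})

test_that("axes of an aligned crystal are recovered along the beam", {
  cell <- c(50, 60, 70, 90, 90, 90)
  gen <- generate_spots(synthetic_scene(crystal(cell, orientation = diag(3)),
                                        std_geom(), noise_sigma_mm = 0,
                                        seed = 2))
  sv <- map_spots(gen$spots, std_geom())
  cand <- find_axis_candidates(sv, std_geom())
  i <- which.min(abs(cand$length_A - 50))
  expect_lt(abs(cand$length_A[i] - 50) / 50, 0.01)
  expect_lt(fftindex:::axis_angle_between(as.numeric(cand[i, 1:3]),
                                          c(1, 0, 0)), 0.5)
})

test_that("all three cell axes appear among the retained candidates", {
  cell <- c(50, 60, 70, 90, 90, 90)
  gen <- cached_ortho(1)
  sv <- map_spots(gen$spots, std_geom())
  cand <- find_axis_candidates(sv, std_geom())
  for (len in cell[1:3])
    expect_true(any(abs(cand$length_A - len) / len < 0.01),
                label = sprintf("axis %g among retained candidates", len))
  # determinism
  cand2 <- find_axis_candidates(sv, std_geom())
  expect_identical(cand, cand2)
})

test_that("recovered directions rotate with the data (equivariance)", {
  gen <- cached_ortho(1)
  sv <- map_spots(gen$spots, std_geom())
  cand <- find_axis_candidates(sv, std_geom())
  R <- fftindex:::rot_axis_angle(c(1, 2, 3), 23)
  sv2 <- sv
  S2 <- as.matrix(sv[, 1:3]) %*% t(R)
  sv2$sx <- S2[, 1]; sv2$sy <- S2[, 2]; sv2$sz <- S2[, 3]
  cand2 <- find_axis_candidates(sv2, std_geom())
  # each recovered cell axis appears rotated by R with its length unchanged
  for (len in c(50, 60, 70)) {
    i <- which(abs(cand$length_A - len) / len < 0.01)[1]
    expect_false(is.na(i))
    t_rot <- R %*% as.numeric(cand[i, 1:3])
    ang <- apply(as.matrix(cand2[, 1:3]), 1L, function(u)
      fftindex:::axis_angle_between(u, t_rot))
    j <- which.min(ang)
    expect_lt(ang[j], 0.5)
    expect_lt(abs(cand2$length_A[j] - cand$length_A[i]) / cand$length_A[i],
              0.01)
  }
})

test_that("retained list caps at max_vectors with no collinear pairs", {
  gen <- cached_ortho(1)
  sv <- map_spots(gen$spots, std_geom())
  cand <- find_axis_candidates(sv, std_geom())
  expect_lte(nrow(cand), 30L)
  D <- as.matrix(cand[, 1:3])
  dots <- abs(D %*% t(D))
  diag(dots) <- 0
  expect_lt(max(dots), cos(fftindex:::deg2rad(2)))
})
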