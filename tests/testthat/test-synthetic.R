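# independent brute-force spot counter: dense phi scan with sign-change
# detection of the Ewald condition, no closed-form crossing solver
brute_count_spots <- function(cell, U, geom, image, d_min, half_mm) {
  A <- U %*% basis_from_cell(cell)
  Brec <- t(solve(A))
  hmax <- ceiling(sqrt(colSums(A^2)) / d_min)
  H <- as.matrix(expand.grid(-hmax[1]:hmax[1], -hmax[2]:hmax[2],
                             -hmax[3]:hmax[3]))
  H <- H[rowSums(abs(H)) > 0, ]
  r0 <- geom$wavelength * (Brec %*% t(H))
  ok <- sqrt(colSums(r0^2)) <= geom$wavelength / d_min
  r0 <- r0[, ok, drop = FALSE]
  phis <- seq(image[1], image[2], length.out = 400L)
  n <- 0L
  for (j in seq_len(ncol(r0))) {
    f <- vapply(phis, function(p) {
      r <- fftindex:::rot_z(geom$spindle_sense * p) %*% r0[, j]
      sum((r + c(1, 0, 0))^2) - 1
    }, 0)
    cross <- which(f[-1] * f[-length(f)] <= 0 & f[-1] != f[-length(f)])
    if (!length(cross)) next
    p <- phis[cross[1L]]
    r <- fftindex:::rot_z(geom$spindle_sense * p) %*% r0[, j]
    u <- r + c(1, 0, 0)
    if (u[1] <= 1e-6) next
    if (max(abs(geom$distance * u[2:3] / u[1])) <= half_mm) n <- n + 1L
  }
  n
}

test_that("spot counts match a brute-force Ewald-crossing counter", {
  geom <- std_geom()
  cell <- c(30, 34, 40, 90, 90, 90)      # small cell keeps the scan fast
  sc <- synthetic_scene(crystal(cell), geom, images = rbind(c(10, 11)),
                        d_min_A = 3.5, noise_sigma_mm = 0, seed = 13)
  gen <- generate_spots(sc)
  expected <- brute_count_spots(cell, gen$orientations[[1]], geom,
                                c(10, 11), 3.5, 100)
  expect_equal(nrow(gen$spots), expected)
})

test_that("generation is deterministic and the truth ledger is complete", {
  sc <- synthetic_scene(crystal(c(50, 60, 70, 90, 90, 90)), std_geom(),
                        seed = 17)
  g1 <- generate_spots(sc)
  g2 <- generate_spots(sc)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$truth), nrow(g1$spots))
  expect_true(all(c("crystal", "h", "k", "l", "phi_true_deg",
                    "x_true_mm", "y_true_mm") %in% names(g1$truth)))
  # every true phi lies inside its image's oscillation range
  expect_true(all(g1$truth$phi_true_deg >= g1$spots$phi_start_deg - 1e-9 &
                  g1$truth$phi_true_deg <= g1$spots$phi_end_deg + 1e-9))
  # a different seed changes the output
  g3 <- generate_spots(synthetic_scene(crystal(c(50, 60, 70, 90, 90, 90)),
                                       std_geom(), seed = 18))
  expect_false(identical(g1$spots, g3$spots))
})

test_that("positional noise has r.m.s. sigma * sqrt(2) per spot", {
  sc <- synthetic_scene(crystal(c(50, 60, 70, 90, 90, 90)), std_geom(),
                        d_min_A = 2.0, noise_sigma_mm = 0.05, seed = 19)
  gen <- generate_spots(sc)
  expect_gt(nrow(gen$spots), 1000)
  rms <- sqrt(mean((gen$spots$x_mm - gen$truth$x_true_mm)^2 +
                   (gen$spots$y_mm - gen$truth$y_true_mm)^2))
  expect_equal(rms, 0.05 * sqrt(2), tolerance = 0.05)
})

test_that("multilattice scenes honour misorientations and shares", {
  sc <- multilattice_scene(c(50, 60, 70, 90, 90, 90), c(0, 10), c(0.6, 0.4),
                           geom = std_geom(), seed = 5)
  expect_length(sc$crystals, 2L)
  expect_equal(sc$shares, c(0.6, 0.4))
  R12 <- sc$crystals[[2]]$orientation %*% t(sc$crystals[[1]]$orientation)
  expect_equal(fftindex:::rotation_angle_deg(R12), 10, tolerance = 1e-9)
  expect_error(multilattice_scene(c(50, 60, 70, 90, 90, 90), c(0, 0),
                                  geom = std_geom()))
  # single-entry misorientation collapses to a single-crystal scene
  sc1 <- multilattice_scene(c(50, 60, 70, 90, 90, 90), 0, geom = std_geom(),
                            seed = 5)
  expect_length(sc1$crystals, 1L)
})

test_that("mosaicity widens the phi acceptance window", {
  base <- synthetic_scene(crystal(c(50, 60, 70, 90, 90, 90)), std_geom(),
                          images = rbind(c(0, 1)), seed = 23)
  wide <- synthetic_scene(crystal(c(50, 60, 70, 90, 90, 90),
                                  mosaicity_deg = 1.0), std_geom(),
                          images = rbind(c(0, 1)), seed = 23)
  n0 <- nrow(generate_spots(base)$spots)
  n1 <- nrow(generate_spots(wide)$spots)
  expect_gt(n1, n0)
})
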