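mk_spots <- function(isig, d_A = NULL, geom = std_geom()) {
  n <- length(isig)
  if (is.null(d_A)) {
    x <- runif(n, 60, 140); y <- runif(n, 60, 140)
  } else {
    # place each spot at the radius matching the requested resolution
    stopifnot(length(d_A) == n)
    th2 <- 2 * asin(geom$wavelength / (2 * d_A))
    r <- geom$distance * tan(th2)
    ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
    x <- geom$beam_centre[1] + r * cos(ang)
    y <- geom$beam_centre[2] + r * sin(ang)
  }
  data.frame(image_id = 1, x_mm = x, y_mm = y,
             phi_start_deg = 0, phi_end_deg = 1,
             intensity = isig * 10, sigma = 10)
}

test_that("automatic threshold follows the 20 / 10 / 5 ladder", {
  expect_equal(auto_threshold(mk_spots(rep(100, 500))), 20)
  expect_equal(auto_threshold(mk_spots(rep(12, 300))), 10)
  expect_equal(auto_threshold(mk_spots(rep(6, 50))), 5)
  # boundary: exactly min_usable strong spots still qualifies for 20
  expect_equal(auto_threshold(mk_spots(c(rep(25, 200), rep(3, 300)))), 20)
  expect_equal(auto_threshold(mk_spots(c(rep(25, 199), rep(3, 300)))), 5)
})

test_that("intensity filtering keeps exactly the above-threshold spots", {
  isig <- c(25, 22, 19, 18, 30, 4, 21, 20, 7, 50)
  sp <- mk_spots(isig)
  suppressWarnings(
    out <- filter_spots(sp, filter_policy(i_over_sigma = 20), std_geom()))
  expect_equal(nrow(out), 6L)
  expect_equal(out$intensity / out$sigma, isig[isig >= 20])
  # idempotent
  suppressWarnings(
    out2 <- filter_spots(out, filter_policy(i_over_sigma = 20), std_geom()))
  expect_equal(out2, out)
})

test_that("ice bands and resolution windows exclude the right spots", {
  geom <- std_geom()
  sp <- mk_spots(rep(50, 4), d_A = c(3.67, 3.50, 2.50, 10.0), geom = geom)
  pol <- filter_policy(i_over_sigma = 5,
                       ice_bands = cbind(3.67, 0.03))
  suppressWarnings(out <- filter_spots(sp, pol, geom))
  d_kept <- resolution_of(map_spots(out, geom, common_origin = FALSE), geom)
  expect_equal(nrow(out), 3L)
  expect_false(any(abs(d_kept - 3.67) < 0.02))
  # resolution window
  pol2 <- filter_policy(i_over_sigma = 5, d_min_A = 3.0, d_max_A = 8)
  suppressWarnings(out2 <- filter_spots(sp, pol2, geom))
  expect_equal(nrow(out2), 2L)
  # overlapping bands are rejected at construction
  expect_error(filter_policy(ice_bands = rbind(c(3.67, 0.05), c(3.70, 0.05))),
               "overlap")
})

test_that("image pairs are chosen closest to 90 degrees apart", {
  im <- data.frame(image = c("a", "b", "c"), phi_mid_deg = c(0, 45, 90))
  expect_equal(select_image_pair(im), c("a", "c"))
  expect_equal(select_image_pair(im[1, ]), "a")
  im2 <- data.frame(image = 1:2, phi_mid_deg = c(0, 40))
  expect_equal(select_image_pair(im2), 1:2)
  # also accepts a spot list
  sp <- rbind(mk_spots(rep(50, 5)), transform(mk_spots(rep(50, 5)),
                                              image_id = 2,
                                              phi_start_deg = 88,
                                              phi_end_deg = 89))
  expect_equal(select_image_pair(sp), c(1, 2))
})

test_that("reverse-spindle data show the two-image failure pattern", {
  # generated with sense -1, indexed with the default +1: the two-image run
  # must fail outright or produce an implausible residual, the single-image
  # run and the corrected-flag run must both succeed cleanly
  gen <- generate_spots(synthetic_scene(
    crystal(c(50, 60, 70, 90, 90, 90)), std_geom(sense = -1L), seed = 21))
  wrong <- tryCatch(index_spots(gen$spots, std_geom()), error = function(e) e)
  if (inherits(wrong, "error")) {
    expect_match(conditionMessage(wrong), "indexing failure")
  } else {
    expect_gt(wrong$best$sigma_xy_mm, 1.0)
  }
  single <- index_spots(gen$spots[gen$spots$image_id == 1, ], std_geom())
  expect_lt(single$best$sigma_xy_mm, 0.2)
  expect_cell_close(single$best$cell, c(50, 60, 70, 90, 90, 90),
                    len_tol_frac = 0.01, ang_tol_deg = 0.5)
  fixed <- index_spots(gen$spots, std_geom(sense = -1L))
  expect_lt(fixed$best$sigma_xy_mm, 0.2)
  expect_cell_close(fixed$best$cell, c(50, 60, 70, 90, 90, 90))
})
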