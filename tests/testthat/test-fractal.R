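test_that("box counts match exact tilings of simple shapes", {
  ln <- matrix(0L, 8, 8); ln[1, 1:8] <- 1L
  expect_equal(box_count(ln, sizes = c(1, 2, 4, 8), pixel_size = 1)$N,
               c(8, 4, 2, 1))
  sq <- matrix(1L, 8, 8)
  expect_equal(box_count(sq, sizes = c(1, 2, 4, 8), pixel_size = 1)$N,
               c(64, 16, 4, 1))
  expect_error(box_count(matrix(0L, 8, 8)), "empty mask")
})

test_that("fixed-grid box counts equal brute-force cell enumeration", {
  set.seed(99)
  for (i in 1:20) {
    m <- matrix(as.integer(runif(64 * 64) < runif(1, 0.02, 0.4)), 64, 64)
    if (!any(m > 0)) next
    sizes <- c(1, 3, 4, 7, 8, 16, 32)
    got <- box_count(m, sizes = sizes, n_offsets = 1, pixel_size = 1)$N
    want <- vapply(sizes, function(L) brute_force_box_count(m, L), 0L)
    expect_equal(got, as.numeric(want))
  }
})

test_that("N(L) is non-increasing in L and at least 1", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(as.integer(runif(48 * 48) < 0.1), 48, 48)
    if (!any(m > 0)) next
    tab <- box_count(m, sizes = c(1, 2, 3, 5, 8, 13, 21), pixel_size = 1)
    expect_true(all(diff(tab$N) <= 0))
    expect_true(all(tab$N >= 1))
  }
})

test_that("dendrite width matches bar fixtures", {
  bar3 <- matrix(0L, 21, 41); bar3[10:12, 5:35] <- 1L
  expect_equal(estimate_dendrite_width(bar3, 1), 3, tolerance = 1e-9)
  expect_equal(estimate_dendrite_width(line_mask(30), 1), 1, tolerance = 1e-9)
  bar5 <- matrix(0L, 25, 61); bar5[11:15, 5:55] <- 1L
  expect_equal(estimate_dendrite_width(bar5, PX), 5 * PX, tolerance = 1e-9)
  expect_error(estimate_dendrite_width(matrix(0L, 5, 5)), "empty")
})

test_that("scaling cut-offs follow width and 20% of the arbor width", {
  m <- matrix(0L, 160, 220)
  m[6, 6:205] <- 1L; m[155, 6:205] <- 1L; m[6:155, 6] <- 1L
  # bounding box 150 x 200 px at 1 um/px
  cut <- scaling_cutoffs(m, dendrite_width = 1, pixel_size = 1)
  expect_equal(cut$L_min, 1)
  expect_equal(cut$L_max, 0.2 * 200)
  expect_error(scaling_cutoffs(line_mask(10), dendrite_width = 3,
                               pixel_size = 1),
               "insufficient scaling range")
})

test_that("exact power laws are fitted exactly", {
  ln <- matrix(0L, 8, 8); ln[1, 1:8] <- 1L
  est <- estimate_dimension(box_count(ln, sizes = c(1, 2, 4, 8), pixel_size = 1),
                            c(1, 8))
  expect_equal(est$D, 1, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  sq <- matrix(1L, 8, 8)
  est2 <- estimate_dimension(box_count(sq, sizes = c(1, 2, 4, 8), pixel_size = 1),
                             c(1, 8))
  expect_equal(est2$D, 2, tolerance = 1e-12)
  expect_error(estimate_dimension(box_count(ln, sizes = c(1, 2, 4, 8),
                                            pixel_size = 1), c(1, 2)),
               "insufficient scaling range")
})

test_that("estimator calibration: line, filled square, Koch curve", {
  ln <- calibration_shape("line", 1024)
  est_l <- estimate_dimension(box_count(ln, pixel_size = 1),
                              c(1, 0.2 * 1024))
  expect_gte(est_l$n_points_in_fit, 10)
  expect_lt(abs(est_l$D - 1), 0.03)

  sq <- calibration_shape("filled_square", 1024)
  est_s <- estimate_dimension(box_count(sq, pixel_size = 1),
                              c(1, 0.2 * 1024))
  expect_lt(abs(est_s$D - 2), 0.05)

  ko <- calibration_shape("koch_curve", 2048)
  est_k <- fractal_dimension(ko, pixel_size = 1)
  expect_gte(est_k$n_points_in_fit, 10)
  expect_lt(abs(est_k$D - log(4) / log(3)), 0.05)
})

test_that("fitted D is stable under 2x upscaling of a calibration mask", {
  ko <- calibration_shape("koch_curve", 729)
  big <- ko[rep(seq_len(nrow(ko)), each = 2), rep(seq_len(ncol(ko)), each = 2)]
  d1 <- fractal_dimension(ko, pixel_size = 1, dendrite_width = 1)$D
  d2 <- fractal_dimension(big, pixel_size = 1, dendrite_width = 2)$D
  expect_lt(abs(d1 - d2), 0.03)
})

test_that("recovered dimension tracks the nominal tree dimension", {
  ds <- c(1.1, 1.2, 1.4)
  means <- vapply(ds, function(D) {
    attr(dimension_recovery_experiment(D, n_seeds = 2, seed = 5), "mean_D")
  }, 0)
  # monotone in the nominal dimension, and calibrated near the group means
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[1] - 1.1), 0.05)
  expect_lt(abs(means[2] - 1.2), 0.05)
})

test_that("hull area matches simple shapes and ignores interior points", {
  tri <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  expect_equal(convex_hull_area(tri)$S_um2, 0.5)
  sqr <- rbind(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE),
               cbind(runif(20, 0.1, 0.9), runif(20, 0.1, 0.9)))
  expect_equal(convex_hull_area(sqr)$S_um2, 1)
  expect_warning(res <- convex_hull_area(matrix(c(0, 0, 1, 1), 2, 2,
                                                byrow = TRUE)),
                 "S = 0")
  expect_equal(res$S_um2, 0)
  collinear <- cbind(1:5, 2 * (1:5))
  expect_warning(res2 <- convex_hull_area(collinear), "S = 0")
  expect_equal(res2$S_um2, 0)
})

test_that("hull area equals the exhaustive extreme-point oracle", {
  set.seed(31)
  for (i in 1:20) {
    pts <- cbind(runif(20, 0, 50), runif(20, 0, 50))
    expect_equal(convex_hull_area(pts)$S_um2, oracle_hull_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("hull area is permutation invariant and scales quadratically", {
  set.seed(17)
  pts <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  a <- convex_hull_area(pts)$S_um2
  expect_equal(convex_hull_area(pts[sample(40), ])$S_um2, a, tolerance = 1e-12)
  for (k in c(0.5, 3)) {
    expect_equal(convex_hull_area(pts * k)$S_um2, k^2 * a, tolerance = 1e-9)
  }
})
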