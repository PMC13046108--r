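test_that("depth profiles equal brute-force lateral means on a hand-set grid", {
  # 2 x 2 x 3 grid with hand-set values; oracle computed by explicit loops
  vals <- array(c(1, 2, 3, 4,  5, 6, 7, 8,  2, 2, 2, 2), dim = c(2, 2, 3))
  g <- dose_grid(vals, array(0.1, dim = dim(vals)),
                 x_edges = c(-2, 0, 2), y_edges = c(-2, 0, 2),
                 z_edges = c(0, 0.1, 0.2, 0.3),
                 n_histories = 1L, seed = 1L)
  oracle <- numeric(3)
  for (k in 1:3) {
    s <- 0
    for (i in 1:2) for (j in 1:2) s <- s + vals[i, j, k]
    oracle[k] <- s / 4
  }
  p <- depth_profile(g, "field")
  expect_equal(p$mean_dose, oracle)          # (2.5, 6.5, 2)
  expect_equal(p$mean_dose, c(2.5, 6.5, 2))
  # sd propagation: sqrt(sum (0.1 v)^2) / 4 per depth
  expect_equal(p$sd[1], sqrt(sum((0.1 * vals[, , 1])^2)) / 4)
})

test_that("profile masks select the requested lateral bins", {
  q <- make_toy_dose_grid(c(4, 4, 3), "quadrant", value = 1)
  m <- outer(q$x_edges[-1] > 0, q$y_edges[-1] > 0, "&")  # doubled quadrant only
  p <- depth_profile(q, mask = m)
  expect_equal(p$mean_dose, rep(2, 3))
  expect_error(depth_profile(q, mask = matrix(FALSE, 4, 4)), "empty")
})

test_that("integrated skin dose sums the 24 depth bins", {
  u <- make_toy_dose_grid(c(2, 2, 24), "uniform", value = 3)
  expect_equal(as.numeric(integrated_skin_dose(depth_profile(u, "field"))),
               24 * 3)
  r <- make_toy_dose_grid(c(2, 2, 24), "ramp", value = 1)
  expect_equal(as.numeric(integrated_skin_dose(depth_profile(r, "field"))),
               sum(1:24))  # arithmetic series, 300
  short <- make_toy_dose_grid(c(2, 2, 5), "uniform")
  expect_error(integrated_skin_dose(depth_profile(short, "field")), "2.4")
})

test_that("DEF statistics reproduce hand-computed ratios", {
  mk <- function(v) structure(list(
    z_centers = c(0.05, 0.15, 0.25), z_edges = c(0, 0.1, 0.2, 0.3),
    mean_dose = v, sd = rep(0, 3), n_lateral = 1, mask = "field"),
    class = "depth_dose")
  d <- def_statistics(mk(c(2, 3, 4)), mk(c(1, 1, 2)))
  expect_equal(d$def_curve, c(2, 3, 2))
  expect_equal(d$peak_def, 3)
  expect_equal(d$peak_z_mm, 0.15)
  expect_equal(d$integrated_def, 9 / 4)
  # identical profiles give DEF exactly 1 everywhere
  self <- def_statistics(mk(c(5, 6, 7)), mk(c(5, 6, 7)))
  expect_equal(self$def_curve, rep(1, 3))
  expect_equal(self$peak_def, 1)
  # a single doubled bin is the peak
  one <- def_statistics(mk(c(1, 2, 1)), mk(c(1, 1, 1)))
  expect_equal(one$peak_def, 2)
  expect_equal(sum(one$def_curve == 1), 2)
  expect_error(def_statistics(mk(c(1, 1, 1)), mk(c(1, 0, 1))), "undefined DEF")
})

test_that("tattoo-layer and sub-layer summary bins cover the right depths", {
  u <- make_toy_dose_grid(c(2, 2, 24), "uniform")
  p <- depth_profile(u, "field")
  d <- def_statistics(p, p)
  # bins covering 1.25-1.55 mm: the four 0.1 mm bins spanning 1.2-1.6 mm
  expect_equal(d$tattoo_bins, 13:16)
  expect_equal(d$sub_layer_bins, 17:20)
  expect_equal(d$tattoo_mean_def, 1)
  expect_equal(d$sub_layer_min_def, 1)
})

test_that("DEF of a run against itself is exactly one and analysis is pure", {
  r <- run_simulation(control_phantom(), beam_spec("photon", 6), 2e4,
                      seed = 55, xs = standard_xs())
  p1 <- depth_profile(r, "field")
  p2 <- depth_profile(r, "field")
  expect_identical(p1, p2)
  d <- def_statistics(p1, p2)
  expect_equal(d$def_curve, rep(1, 24))
  expect_equal(d$integrated_def, 1)
})

test_that("lateral maps quantify quadrant uniformity", {
  u <- make_toy_dose_grid(c(4, 4, 24), "uniform", value = 2)
  lu <- lateral_map(u)
  expect_equal(lu$uniformity, 0)
  expect_equal(unname(lu$quadrants$mean), rep(48, 4))  # 24 bins x 2

  q <- make_toy_dose_grid(c(4, 4, 24), "quadrant", value = 1)
  lq <- lateral_map(q)
  expect_equal(lq$uniformity, 1.0)   # (2 - 1) / 1

  # map summed over all depths is consistent with the integrated skin dose
  p <- depth_profile(q, "field")
  expect_equal(mean(lq$map), as.numeric(integrated_skin_dose(p)))
  expect_error(lateral_map(q, z_range = c(5, 6)), "empty")
})
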