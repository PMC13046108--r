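test_that("packaged reference tables load with all invariants satisfied", {
  tab <- ref_tables
  epi <- tab$skin_layers[!grepl("dermis", tab$skin_layers$name), ]
  expect_equal(sum(epi$thickness_um), 100.1)
  expect_equal(sum(tab$skin_elemental_fractions), 1, tolerance = 1e-12)
  expect_equal(sum(tab$skin_elemental_fractions_raw), 0.99902, tolerance = 1e-6)
  expect_true(all(names(tab$reach_limits) %in%
                    names(tab$ink_compositions$brown)))
  need <- c("Al", "V", "Cr", "Fe", "Co", "Ni", "Cu", "Cd", "Ba", "Hg", "Pb")
  for (ink in c("brown", "orange", "black"))
    expect_setequal(names(tab$ink_compositions[[ink]]), need)
  expect_identical(tab$below_loq$orange, "Cu")
  expect_equal(tab$ink_compositions$orange[["Cu"]], 0)
})

test_that("packaged values match the published survey table", {
  tab <- ref_tables
  expect_equal(tab$ink_compositions$brown[["Fe"]], 88400)
  expect_equal(tab$ink_compositions$orange[["Al"]], 1830)
  expect_equal(tab$reach_limits[["Pb"]], 0.7)
  expect_equal(tab$dry_matter_fraction, 0.47)
  expect_equal(tab$dry_matter_range, c(0.31, 0.62))
  expect_equal(unname(tab$compound_densities[c("Fe2O3", "Al(OH)3", "carbon-black")]),
               c(5.3, 2.4, 1.8))
})

test_that("reference tables round-trip losslessly through CSV serialization", {
  dir <- withr::local_tempdir()
  write_reference_tables(ref_tables, dir)
  back <- load_reference_tables(dir)
  expect_equal(back$ink_compositions, ref_tables$ink_compositions)
  expect_equal(back$reach_limits, ref_tables$reach_limits)
  expect_equal(back$skin_layers, ref_tables$skin_layers)
  expect_equal(back$skin_elemental_fractions, ref_tables$skin_elemental_fractions)
  expect_equal(back$dry_matter_fraction, ref_tables$dry_matter_fraction)
  expect_equal(back$compound_composition, ref_tables$compound_composition)
})

test_that("corrupted packaged data is rejected with an integrity error", {
  dir <- withr::local_tempdir()
  write_reference_tables(ref_tables, dir)
  sl <- read.csv(file.path(dir, "skin_layers.csv"))
  sl$thickness_um[1] <- 20
  write.csv(sl, file.path(dir, "skin_layers.csv"), row.names = FALSE)
  expect_error(load_reference_tables(dir), "integrity")
})

test_that("random ink generator is deterministic and respects the surveyed range", {
  a <- make_random_ink(7, 5, ref_tables)
  b <- make_random_ink(7, 5, ref_tables)
  expect_identical(a, b)
  expect_error(make_random_ink(1, 0), "n_elements")
  fdry <- vapply(1:100, function(s)
    make_random_ink(s, 4, ref_tables)$dry_matter_fraction, numeric(1))
  expect_true(all(fdry >= 0.31 & fdry <= 0.62))
  # every random ink yields a valid normalized pigment composition
  for (s in c(3, 17, 99)) {
    f <- dry_mass_fractions(make_random_ink(s, 6, ref_tables), tables = ref_tables)
    expect_equal(sum(f$fractions), 1, tolerance = 1e-12)
    expect_true(all(f$fractions >= 0))
  }
})

test_that("toy dose grids have analytically known structure", {
  u <- make_toy_dose_grid(c(2, 2, 3), "uniform", value = 4)
  expect_equal(depth_profile(u, "field")$mean_dose, rep(4, 3))
  r <- make_toy_dose_grid(c(2, 2, 5), "ramp", value = 2)
  expect_equal(depth_profile(r, "field")$mean_dose, 2 * (1:5))
  q <- make_toy_dose_grid(c(4, 4, 3), "quadrant")
  lm <- lateral_map(q, z_range = c(0, 0.3))
  m <- lm$quadrants$mean
  expect_equal(sort(m / min(m)), c(1, 1, 1, 2))
  expect_error(make_toy_dose_grid(c(0, 2, 2), "uniform"), "positive")
})
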