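test_that("phantom layers tile the slab without gaps or overlaps", {
  ph <- control_phantom()
  L <- ph$layers
  expect_equal(L$z_top_mm[1], 0)
  expect_equal(L$z_top_mm[-1], L$z_bottom_mm[-nrow(L)])
  # epidermal stack ends at 0.1001 mm (8.5+12.8+12.8+8+50+8 um)
  expect_equal(L$z_bottom_mm[L$name == "stratum_basale"], 0.1001)
  # tattoo sublayer strictly inside the reticular dermis
  t <- L[L$is_tattoo, ]
  expect_equal(c(t$z_top_mm, t$z_bottom_mm), c(1.25, 1.55))
  expect_equal(ph$tattoo_z_mm, c(1.25, 1.55))
  # scoring mesh: exactly [0, 2.4] mm in 24 z-bins, lateral covers the field
  expect_equal(ph$z_edges, seq(0, 2.4, by = 0.1))
  expect_equal(range(ph$x_edges), c(-5, 5))
})

test_that("material lookup matches layer bookkeeping at key depths", {
  brown <- ink_phantom("brown")
  expect_equal(material_at(brown, 0, 0, 1.40)$density, 5.3)
  # depth 50 um lies in the stratum spinosum (spans 42.1-92.1 um)
  expect_identical(material_at(brown, 0, 0, 0.05)$name, "stratum_spinosum")
  expect_identical(material_at(brown, 0, 0, 3.0)$name, "water")
  # boundary points belong to the deeper layer
  expect_equal(material_at(brown, 0, 0, 1.25)$density, 5.3)
  expect_equal(material_at(brown, 0, 0, 1.55)$density, 1.1)
  ctrl <- control_phantom()
  expect_identical(material_at(ctrl, 0, 0, 1.40)$name, "reticular_dermis")
  expect_error(material_at(ctrl, 0, 0, 200), "bounds")
  expect_error(material_at(ctrl, 20, 0, 1), "bounds")
})

test_that("voxel lookup agrees with an independent interval-search oracle", {
  ph <- ink_phantom("brown")
  L <- ph$layers
  set.seed(42)
  z <- runif(1e4, 0, ph$total_depth_mm * 0.999)
  x <- runif(1e4, -14, 14); y <- runif(1e4, -14, 14)
  for (i in seq_len(1e4)) {
    # oracle: linear scan over half-open layer intervals
    hit <- which(z[i] >= L$z_top_mm & z[i] < L$z_bottom_mm)[1]
    expected <- if (L$is_tattoo[hit]) "brown@100"
                else if (L$name[hit] == "water_backing") "water"
                else sub("_(upper|lower)$", "", L$name[hit])
    got <- material_at(ph, x[i], y[i], z[i])$name
    expect_identical(got, expected)
  }
})

test_that("quadrant layout places the four materials per the standard map", {
  qm <- list(top_left = NULL,
             top_right = tattoo_mixture("black", 100, tables = ref_tables),
             bottom_left = tattoo_mixture("orange", 100, tables = ref_tables),
             bottom_right = tattoo_mixture("brown", 100, tables = ref_tables))
  ph <- build_phantom(layout = "quadrant", quadrant_materials = qm,
                      tables = ref_tables)
  z <- 1.4
  expect_identical(material_at(ph, -2, 2, z)$name, "reticular_dermis")
  expect_identical(material_at(ph, 2, 2, z)$name, "black@100")
  expect_identical(material_at(ph, -2, -2, z)$name, "orange@100")
  expect_identical(material_at(ph, 2, -2, z)$name, "brown@100")
  # outside the tattoo depth range all quadrants are identical
  expect_identical(material_at(ph, 2, -2, 1.0)$name, "reticular_dermis")
  # quadrant scoring bins (2.5 mm) nest inside the 5 mm quadrants
  expect_equal(diff(ph$x_edges)[1], 2.5)
  expect_error(build_phantom(layout = "quadrant"), "quadrant_materials")
})

test_that("phantom mass responds to pigment loading exactly as density mixing", {
  m0 <- phantom_mass(control_phantom())$total
  m100 <- phantom_mass(ink_phantom("brown"))$total
  # 0.3 mm sublayer over 1 cm^2: mass change = delta_rho * 0.03 cm^3
  expect_equal(m100 - m0, (5.3 - 1.1) * 0.03, tolerance = 1e-12)
  m50 <- phantom_mass(build_phantom(tattoo_mixture("brown", 50, tables = ref_tables),
                                    tables = ref_tables))$total
  expect_equal(m50 - m0, (mix_density(0.5, 5.3, 1.1) - 1.1) * 0.03,
               tolerance = 1e-12)
  # control skin slab mass: sum of layer thickness x density over 1 cm^2
  L <- control_phantom()$layers
  skin <- L$region == "skin"
  dens <- c(1.3, 1.2, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1)
  expect_equal(m0, sum((L$z_bottom_mm - L$z_top_mm)[skin] / 10 * dens),
               tolerance = 1e-12)
})
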