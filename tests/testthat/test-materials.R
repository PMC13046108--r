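test_that("volume-fraction density mixing reproduces the published table", {
  expect_equal(mix_density(0.50, 5.3, 1.1), 3.2)
  expect_equal(mix_density(0, 99, 1.1), 1.1)
  expect_equal(round(mix_density(0.75, 2.4, 1.1), 1), 2.1)
  got <- mixture_density_table(ref_tables)
  expected <- read.csv(tattoodose:::tattoodose_extdata("table1_expected.csv"))
  expect_equal(got, expected)   # all 21 cells after one-decimal rounding
  expect_error(mix_density(1.5, 5.3, 1.1), "v_ink")
  expect_error(mix_density(0.5, -1, 1.1), "positive")
})

test_that("mixture density is monotone in loading when the ink is denser", {
  v <- seq(0, 1, by = 0.01)
  for (rho in c(5.3, 2.4, 1.8))
    expect_true(all(diff(mix_density(v, rho, 1.1)) >= 0))
})

test_that("volume-to-mass fraction conversion follows w_i = v_i rho_i / sum", {
  w <- mixture_mass_fractions(c(0.5, 0.5), c(5.3, 1.1))
  expect_equal(w, c(2.65, 0.55) / 3.20)                   # 0.8281, 0.1719
  expect_equal(round(w, 4), c(0.8281, 0.1719))
  expect_equal(sum(w), 1)
  expect_equal(mixture_mass_fractions(c(1, 0), c(5.3, 1.1)), c(1, 0))
  expect_equal(mixture_mass_fractions(c(0.3, 0.7), c(2, 2)), c(0.3, 0.7))
  # mass fraction increases with density at fixed volumes
  w2 <- mixture_mass_fractions(c(0.5, 0.5), c(8, 1.1))
  expect_gt(w2[1], w[1])
  expect_error(mixture_mass_fractions(c(0.5, 0.5), c(0, 0)), "positive")
  expect_error(mixture_mass_fractions(c(0.6, 0.6), c(1, 1)), "sum to 1")
})

test_that("blending conserves mass and is idempotent for one component", {
  dermis <- skin_material("reticular_dermis", ref_tables)
  blend1 <- blend_materials(mixture_spec(list(dermis), 1, name = "reticular_dermis"))
  expect_equal(blend1$density, dermis$density)
  expect_equal(blend1$elements, dermis$elements)

  brown100 <- tattoo_mixture("brown", 100, tables = ref_tables)
  expect_equal(brown100$density, 5.3)
  pig <- ink_material(packaged_ink("brown", ref_tables), tables = ref_tables)
  expect_equal(sort(names(brown100$elements)), sort(names(pig$elements)))

  brown50 <- tattoo_mixture("brown", 50, tables = ref_tables)
  expect_equal(brown50$density, 3.2)
  w <- mixture_mass_fractions(c(0.5, 0.5), c(5.3, 1.1))
  dermis50 <- skin_material("reticular_dermis", ref_tables)
  expect_equal(brown50$elements[["Fe"]],
               w[1] * pig$elements[["Fe"]] + w[2] * dermis50$elements[["Fe"]],
               tolerance = 1e-12)
  # elemental mass conservation: weighted component fractions sum to 1
  # before renormalization
  for (L in c(5, 25, 75)) {
    m <- tattoo_mixture("brown", L, tables = ref_tables)
    expect_equal(sum(m$elements), 1, tolerance = 1e-9)
  }
})

test_that("skin strata share one elemental vector with per-layer densities", {
  expect_equal(skin_material("reticular_dermis", ref_tables)$density, 1.1)
  expect_equal(skin_material("upper_SC", ref_tables)$density, 1.3)
  expect_equal(skin_material("middle_SC", ref_tables)$density, 1.2)
  for (nm in ref_tables$skin_layers$name) {
    m <- skin_material(nm, ref_tables)
    expect_equal(sum(m$elements), 1, tolerance = 1e-12)
    expect_equal(m$elements, skin_material("upper_SC", ref_tables)$elements)
  }
  expect_error(skin_material("hypodermis", ref_tables), "unknown")
})

test_that("material cards serialize name, density and fractions", {
  path <- withr::local_tempfile(fileext = ".mat")
  write_material_card(tattoo_mixture("orange", 50, tables = ref_tables), path)
  lines <- readLines(path)
  expect_match(lines[1], "orange@50")
  expect_match(lines[2], "1.75")
  expect_true(any(grepl("^Al: ", lines)))
})
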