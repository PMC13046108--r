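test_that("wet-to-dry conversion is the exact quotient and scales linearly", {
  expect_equal(wet_to_dry(88400, 0.47), 188085.1, tolerance = 1e-6)
  expect_equal(wet_to_dry(1830, 0.47), 3893.617, tolerance = 1e-6)
  x <- c(0, 1, 250, 88400)
  expect_identical(wet_to_dry(x, 1.0), x)
  # linear in c_wet, scales as 1/f_dry
  expect_equal(wet_to_dry(3 * x, 0.4), 3 * wet_to_dry(x, 0.4))
  expect_equal(wet_to_dry(x, 0.2), 2 * wet_to_dry(x, 0.4))
  expect_error(wet_to_dry(10, 0), "f_dry")
  expect_error(wet_to_dry(10, 1.2), "f_dry")
  expect_error(wet_to_dry(-1, 0.5), "c_wet")
})

test_that("REACH screening reproduces the published compliance column", {
  expected <- read.csv(tattoodose:::tattoodose_extdata("table2_compliance_expected.csv"),
                       stringsAsFactors = FALSE)
  for (ink in c("brown", "orange", "black")) {
    rep <- reach_compliance(packaged_ink(ink, ref_tables), ref_tables$reach_limits)
    got <- rep$verdict[match(expected$element, rep$element)]
    expect_identical(got, expected[[ink]])
  }
})

test_that("compliance verdicts follow the limit comparison exactly", {
  rep <- reach_compliance(packaged_ink("brown", ref_tables))
  expect_identical(rep$verdict[rep$element == "Cr"], "exceeds")   # 147 > 0.5
  expect_identical(rep$verdict[rep$element == "Cd"], "within")    # 0.35 <= 0.5
  expect_identical(rep$verdict[rep$element == "Fe"], "not_applicable")
  # exceeds iff a limit exists and the measured value is above it
  lim <- rep$limit_ppm
  expect_identical(rep$verdict == "exceeds",
                   !is.na(lim) & rep$measured_ppm > lim)
})

test_that("dry pigment compositions are normalized and stoichiometric", {
  for (ink in c("brown", "orange", "black")) {
    f <- dry_mass_fractions(packaged_ink(ink, ref_tables), tables = ref_tables)
    expect_equal(sum(f$fractions), 1, tolerance = 1e-12)
    expect_true(all(f$fractions >= 0))
  }
  black <- dry_mass_fractions(packaged_ink("black", ref_tables), tables = ref_tables)
  expect_gt(black$fractions[["C"]], 0.99)
  brown <- dry_mass_fractions(packaged_ink("brown", ref_tables), tables = ref_tables)
  # O bound to Fe as Fe2O3: mass ratio O/Fe = 3*15.999 / (2*55.845)
  expect_gte(brown$fractions[["O"]],
             0.4297 * brown$fractions[["Fe"]])
  # binder closure keeps the measured dry-basis Fe and fills with carbon
  brown_b <- dry_mass_fractions(packaged_ink("brown", ref_tables),
                                residual = "binder", tables = ref_tables)
  expect_equal(brown_b$fractions[["Fe"]], 88400 / 0.47 * 1e-6, tolerance = 1e-9)
  expect_gt(brown_b$fractions[["C"]], 0.7)
  # compound closure makes the pigment essentially pure Fe2O3
  expect_gt(brown$meta$dominant_compound_mass_fraction, 0.99)
})

test_that("impossible compositions raise a composition error", {
  bad <- ink_composition("bad", c(Fe = 9e5, Al = 2e5), 0.9, "Fe2O3", 5.3)
  expect_error(dry_mass_fractions(bad, tables = ref_tables), "composition")
})

test_that("ink materials carry the packaged compound bulk density", {
  m <- ink_material(packaged_ink("brown", ref_tables), tables = ref_tables)
  expect_s3_class(m, "material")
  expect_equal(m$density, 5.3)
  expect_equal(ink_material(packaged_ink("orange", ref_tables),
                            tables = ref_tables)$density, 2.4)
})
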