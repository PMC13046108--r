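test_that("Compton samples conserve energy exactly and respect the Compton edge", {
  for (E in c(1, 6, 18)) {
    s <- sample_photon_interaction(E, water_material(), n = 5000, seed = 3,
                                   xs = standard_xs())
    cmp <- s[s$type == "compton", ]
    expect_gt(nrow(cmp), 2500)  # Compton share shrinks toward 65% at 18 MeV
    expect_equal(cmp$E_photon_out + cmp$E_electron, rep(E, nrow(cmp)),
                 tolerance = 1e-12)
    edge <- 2 * E^2 / (0.51099895 + 2 * E)
    expect_true(all(cmp$E_electron <= edge + 1e-9))
    expect_gt(max(cmp$E_electron), 0.97 * edge)  # edge is approached
    expect_true(all(abs(cmp$cos_theta_photon) <= 1))
  }
})

test_that("sampled mean scattered fraction matches the Klein-Nishina integral", {
  E <- 1
  k <- E / 0.51099895
  # quadrature oracle: <eps> from the KN differential cross section in eps
  dkn <- function(eps) {
    t <- (1 - eps) / (k * eps)
    sint2 <- t * (2 - t)
    (1 / eps + eps) * (1 - eps * sint2 / (1 + eps^2))
  }
  lo <- 1 / (1 + 2 * k)
  norm <- integrate(dkn, lo, 1, rel.tol = 1e-10)$value
  mean_eps <- integrate(function(e) e * dkn(e), lo, 1, rel.tol = 1e-10)$value / norm
  kn <- tattoodose:::cpp_sample_compton(E, 1e5, 4)
  se <- sd(kn[, 1]) / sqrt(nrow(kn))
  expect_lt(abs(mean(kn[, 1]) - mean_eps), 3 * se)
})

test_that("interaction channels appear in cross-section proportion", {
  # at 18 MeV in ferric oxide pigment, pair production is a large channel
  s <- sample_photon_interaction(18, tattoo_mixture("brown", 100,
                                                    tables = ref_tables),
                                 n = 5000, seed = 5, xs = standard_xs())
  frac_pair <- mean(s$type == "pair")
  xs <- standard_xs()
  expected <- xs_lookup(xs, "brown@100", "pair", 18) /
    xs_lookup(xs, "brown@100", "total", 18)
  expect_lt(abs(frac_pair - expected), 3 * sqrt(expected * (1 - expected) / 5000))
  pr <- s[s$type == "pair", ]
  expect_equal(pr$E_electron + pr$E_positron,
               rep(18 - 1.0219979, nrow(pr)), tolerance = 1e-12)
})

test_that("free-path depths follow Beer-Lambert attenuation", {
  E <- 6
  xs <- standard_xs()
  mu <- xs_lookup(xs, "water", "total", E)   # density 1: per cm
  d <- photon_free_depths(E, water_material(), n = 2e4, seed = 6, xs = xs)
  for (z in c(5, 15, 30)) {
    p_surv <- mean(d > z)
    expected <- exp(-mu * z)
    se <- sqrt(expected * (1 - expected) / length(d))
    expect_lt(abs(p_surv - expected), 3 * se + 1e-12)
  }
})

test_that("condensed electron steps lose energy monotonically and deposit", {
  wat <- water_material()
  xs <- standard_xs()
  st <- list(energy = 6, direction = c(0, 0, 1), position = c(0, 0, 0))
  # zero-length step: state unchanged, zero deposit
  z <- step_electron(st, wat, max_step_mm = 0, seed = 1, xs = xs)
  expect_equal(z$energy, 6)
  expect_equal(z$deposit, 0)
  expect_equal(z$position, c(0, 0, 0))
  prev <- st$energy
  for (i in 1:50) {
    st <- step_electron(st, wat, max_step_mm = 0.02, seed = 9, substream = i,
                        xs = xs)
    expect_lt(st$energy, prev)
    expect_gt(st$deposit, 0)
    prev <- st$energy
  }
  expect_gt(st$position[3], 0)  # net forward motion over 1 mm of water
})

test_that("angular deflection is larger in dense high-Z pigment than dermis", {
  brown <- tattoo_mixture("brown", 100, tables = ref_tables)
  dermis <- skin_material("reticular_dermis", ref_tables)
  xs <- standard_xs()
  ang <- function(mat) {
    vapply(1:400, function(i) {
      st <- step_electron(list(energy = 6, direction = c(0, 0, 1)),
                          mat, max_step_mm = 0.02, seed = 11, substream = i,
                          xs = xs)
      acos(min(1, st$direction[3]))
    }, numeric(1))
  }
  expect_gt(sqrt(mean(ang(brown)^2)), 1.5 * sqrt(mean(ang(dermis)^2)))
})

test_that("simulations are bit-identical for a fixed seed and differ across seeds", {
  ph <- ink_phantom("brown")
  b <- beam_spec("photon", 6)
  r1 <- run_simulation(ph, b, 2e4, seed = 77, xs = standard_xs())
  r2 <- run_simulation(ph, b, 2e4, seed = 77, xs = standard_xs())
  expect_identical(r1$dose, r2$dose)
  expect_identical(r1$rel_uncertainty, r2$rel_uncertainty)
  expect_identical(r1$audit, r2$audit)
  r3 <- run_simulation(ph, b, 2e4, seed = 78, xs = standard_xs())
  expect_false(identical(r1$dose, r3$dose))
})

test_that("every run conserves energy: deposited never exceeds emitted", {
  xs <- standard_xs()
  for (b in list(beam_spec("photon", 6), beam_spec("photon", 18),
                 beam_spec("electron", 6), beam_spec("electron", 18))) {
    r <- run_simulation(ink_phantom("brown"), b,
                        if (b$particle == "photon") 3e4 else 5e3,
                        seed = 21, xs = xs)
    expect_lte(r$audit$deposited, r$audit$emitted)
    expect_lte(r$audit$deposited + r$audit$escaped + r$audit$radiated,
               r$audit$emitted * (1 + 1e-9))
    expect_true(all(r$dose >= 0))
  }
})

test_that("point-divergent source and energy spread options run", {
  b <- beam_spec("electron", 6, energy_sigma_rel = 0.05,
                 source = "point_divergent")
  r <- run_simulation(control_phantom(), b, 2e3, seed = 31, xs = standard_xs())
  expect_gt(sum(r$dose), 0)
  expect_error(beam_spec("photon", -1), "positive")
})

test_that("dose CSV export and import round-trip the grid", {
  r <- run_simulation(control_phantom(), beam_spec("photon", 6), 2e4,
                      seed = 41, xs = standard_xs())
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_csv(r, path, extended = TRUE)
  back <- read_dose_csv(path)
  expect_equal(back$dose, r$dose, tolerance = 1e-12)
  expect_equal(back$rel_uncertainty, r$rel_uncertainty, tolerance = 1e-12)
  expect_equal(back$z_edges, r$z_edges)
})
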