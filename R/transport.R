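#' Beam specification
#'
#' Describes the incident beam. Clinical "MV" photon beams are modeled as
#' monoenergetic photons of the nominal energy with a small Gaussian energy
#' spread; electron beams likewise. The default source is a parallel beam
#' collimated to the field at the surface (at SSD 100 cm the divergence
#' across a 2.4 mm slab is negligible); a point-divergent mode is available.
#'
#' @param particle `"photon"` or `"electron"`.
#' @param energy Nominal energy, MeV (> 0).
#' @param energy_sigma_rel Relative Gaussian energy spread (default 0.02).
#' @param field_cm Square field side length at the surface, cm.
#' @param ssd_cm Source-to-surface distance, cm.
#' @param source `"parallel"` or `"point_divergent"`.
#' @return Object of class `beam_spec`.
#' @examples
#' beam_spec("photon", 6)     # the 6 MV model beam
#' beam_spec("electron", 18)  # the 18 MeV electron beam
#' @export
beam_spec <- function(particle = c("photon", "electron"), energy,
                      energy_sigma_rel = 0.02, field_cm = 1, ssd_cm = 100,
                      source = c("parallel", "point_divergent")) {
  particle <- match.arg(particle)
  source <- match.arg(source)
  if (energy <= 0) stop("nominal_energy must be positive")
  if (field_cm <= 0 || ssd_cm <= 0) stop("field size and SSD must be positive")
  structure(list(particle = particle, energy = energy,
                 energy_sigma_rel = energy_sigma_rel, field_cm = field_cm,
                 ssd_cm = ssd_cm, source = source),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat("<beam_spec> ", x$energy, " MeV ", x$particle, ", ",
      x$field_cm, " x ", x$field_cm, " cm^2, SSD ", x$ssd_cm, " cm (",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Scored dose grid
#'
#' Container for a 3D scored dose distribution: dose per primary particle
#' with per-voxel relative statistical uncertainty (1 sigma, batch method)
#' on the standard scoring mesh.
#'
#' @param dose 3D array, Gy per primary.
#' @param rel_uncertainty 3D array of fractional 1-sigma uncertainties.
#' @param x_edges,y_edges,z_edges Bin edges, mm.
#' @param n_histories,seed Run provenance.
#' @param dose_medium,rel_uncertainty_medium Optional dose-to-medium arrays.
#' @param audit Optional energy-audit list (MeV totals).
#' @param meta Optional metadata list.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(dose, rel_uncertainty, x_edges, y_edges, z_edges,
                      n_histories, seed, dose_medium = NULL,
                      rel_uncertainty_medium = NULL, audit = NULL,
                      meta = list()) {
  stopifnot(length(dim(dose)) == 3, all(dose >= 0),
            all(rel_uncertainty >= 0),
            length(x_edges) == dim(dose)[1] + 1,
            length(y_edges) == dim(dose)[2] + 1,
            length(z_edges) == dim(dose)[3] + 1)
  structure(list(dose = dose, rel_uncertainty = rel_uncertainty,
                 x_edges = x_edges, y_edges = y_edges, z_edges = z_edges,
                 n_histories = n_histories, seed = seed,
                 dose_medium = dose_medium,
                 rel_uncertainty_medium = rel_uncertainty_medium,
                 audit = audit, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$dose)
  cat("<dose_grid> ", d[1], "x", d[2], "x", d[3], " voxels, ",
      format(x$n_histories, big.mark = ","), " histories (seed ",
      x$seed, ")\n", sep = "")
  if (!is.null(x$audit))
    cat(sprintf("  energy audit: deposited/emitted = %.4f\n",
                x$audit$deposited / x$audit$emitted))
  invisible(x)
}

# Pack per-material physics tables into the per-cm form the C++ kernel uses.
#' @noRd
pack_material <- function(xsm) {
  rho <- xsm$density
  list(mu_pe = xsm$pe * rho, mu_inc = xsm$incoh * rho, mu_pair = xsm$pair * rho,
       s_col = xsm$s_col * rho, s_tot = (xsm$s_col + xsm$s_rad) * rho,
       spr = xsm$spr_water, range_cm = xsm$range_gcm2 / rho,
       density = rho, invX0_cm = rho / xsm$X0_gcm2,
       hsA = pi * .const$re_cm^2 * .const$avogadro * xsm$ZZ1A * rho)
}

#' Run a Monte Carlo simulation
#'
#' Transports `n_histories` primaries from `beam` through `phantom` and
#' scores dose on the standard mesh (0.1 mm depth bins over 0-2.4 mm; 2 mm or
#' 2.5 mm lateral bins over the 1 x 1 cm^2 field). Runs are deterministic for
#' a fixed seed. Secondary electrons below 50 keV (10 keV inside the tattoo
#' sublayer, emulating a finer production cut there) and photons below 10 keV
#' deposit locally. Dose is scored both to medium and to water (converted by
#' the water/medium mass collision stopping-power ratio at the depositing
#' electron's energy); the `dose` component follows `scoring`.
#'
#' @param phantom A [build_phantom()] grid.
#' @param beam A [beam_spec()].
#' @param n_histories Number of primary particles (>= 1).
#' @param seed Integer seed; identical (phantom, beam, n, seed) give
#'   bit-identical results.
#' @param n_batches Batch count for the statistical uncertainty estimate.
#' @param scoring `"water"` (standard skin-dosimetry convention, default) or
#'   `"medium"` selects which convention fills the `dose` slot; both are
#'   always returned.
#' @param xs Optional precomputed [build_cross_sections()] set covering the
#'   phantom materials.
#' @return A [dose_grid()] with energy-audit totals (MeV):
#'   `emitted` (primary kinetic energy plus annihilation quanta),
#'   `deposited`, `escaped`, and `radiated` (continuous radiative losses, not
#'   deposited).
#' @export
run_simulation <- function(phantom, beam, n_histories, seed,
                           n_batches = 10, scoring = c("water", "medium"),
                           xs = NULL) {
  stopifnot(inherits(phantom, "phantom_grid"), inherits(beam, "beam_spec"))
  scoring <- match.arg(scoring)
  if (n_histories < 1) stop("n_histories must be >= 1")
  n_histories <- as.integer(round(n_histories))
  if (n_batches < 2) stop("need at least 2 batches for uncertainty estimates")

  if (is.null(xs)) xs <- build_cross_sections(phantom$materials)
  mat_names <- vapply(phantom$materials, `[[`, character(1), "name")
  packed <- lapply(mat_names, function(nm) pack_material(xs$materials[[nm]]))

  zb_cm <- c(phantom$layers$z_top_mm[1], phantom$layers$z_bottom_mm) / 10
  zone_mat <- as.integer(t(phantom$layer_material)) - 1L

  nx <- length(phantom$x_edges) - 1
  ny <- length(phantom$y_edges) - 1
  nz <- length(phantom$z_edges) - 1

  eng <- list(
    egrid = xs$energies,
    materials = packed,
    geometry = list(zb = zb_cm, zone_mat = zone_mat,
                    hw = phantom$lateral_halfwidth_mm / 10,
                    zbot = phantom$total_depth_mm / 10,
                    tz0 = phantom$tattoo_z_mm[1] / 10,
                    tz1 = phantom$tattoo_z_mm[2] / 10),
    scoring = list(x0 = phantom$x_edges[1] / 10, dx = diff(phantom$x_edges)[1] / 10,
                   nx = nx,
                   y0 = phantom$y_edges[1] / 10, dy = diff(phantom$y_edges)[1] / 10,
                   ny = ny,
                   dz = diff(phantom$z_edges)[1] / 10, nz = nz,
                   nbatch = as.integer(n_batches)),
    beam = list(ptype = if (beam$particle == "photon") 0L else 1L,
                E0 = beam$energy, sigE = beam$energy_sigma_rel,
                half_field = beam$field_cm / 2,
                source = if (beam$source == "parallel") 0L else 1L,
                ssd = beam$ssd_cm),
    cuts = list(g_cut = 0.010, e_cut = 0.050, e_cut_tattoo = 0.010),
    run = list(n_histories = as.double(n_histories), seed = as.double(seed),
               step_skin = 0.002, step_water = 0.1, skin_fine_zmax = 0.26)
  )

  res <- cpp_run_engine(eng)

  mass <- scoring_voxel_masses(phantom)                   # g
  conv <- .const$mev_to_j * 1e3                           # MeV/g -> Gy
  per_batch <- n_histories / n_batches

  to_dose <- function(edep) {
    tot <- rowSums(edep)
    dose <- array(tot / as.vector(mass) / n_histories * conv, dim = c(nx, ny, nz))
    bd <- sweep(edep, 1, as.vector(mass), "/") / per_batch * conv
    bm <- rowMeans(bd)
    bsd <- apply(bd, 1, sd) / sqrt(n_batches)
    rel <- ifelse(bm > 0, bsd / bm, 0)
    list(dose = dose, rel = array(rel, dim = c(nx, ny, nz)))
  }
  dw <- to_dose(res$edep_water)
  dm <- to_dose(res$edep_medium)

  audit <- list(emitted = res$e_emitted, deposited = res$e_deposited,
                escaped = res$e_escaped, radiated = res$e_radiated)
  main <- if (scoring == "water") dw else dm
  dose_grid(dose = main$dose, rel_uncertainty = main$rel,
            x_edges = phantom$x_edges, y_edges = phantom$y_edges,
            z_edges = phantom$z_edges,
            n_histories = n_histories, seed = seed,
            dose_medium = dm$dose, rel_uncertainty_medium = dm$rel,
            audit = audit,
            meta = list(beam = beam, scoring = scoring,
                        layout = phantom$layout,
                        quadrant_map = phantom$quadrant_map,
                        n_batches = n_batches,
                        cuts = eng$cuts))
}

#' Sample single photon interactions
#'
#' Draws `n` interaction outcomes for a photon of the given energy in a
#' material, using the same sampling routines as the transport engine:
#' interaction type proportional to the partial attenuation components,
#' Klein-Nishina kinematics for Compton events (exact energy-momentum
#' conservation), full absorption onto a photoelectron for the photoelectric
#' effect, and a uniform energy split for pair production.
#'
#' @param energy Photon energy, MeV.
#' @param mat A [material()].
#' @param n Number of samples.
#' @param seed Seed.
#' @param xs Optional precomputed cross-section set.
#' @return data.frame with columns `type` (`"photoelectric"`, `"compton"`,
#'   `"pair"`), `E_photon_out`, `E_electron`, `E_positron`,
#'   `cos_theta_photon`, `cos_theta_electron`.
#' @export
sample_photon_interaction <- function(energy, mat, n = 1, seed = 1, xs = NULL) {
  stopifnot(inherits(mat, "material"))
  if (is.null(xs)) xs <- build_cross_sections(list(mat))
  comp <- vapply(c("pe", "incoh", "pair"), function(cc)
    xs_lookup(xs, mat$name, cc, energy), numeric(1))
  probs <- comp / sum(comp)
  with_private_seed(seed, {
    type_i <- sample.int(3, n, replace = TRUE, prob = probs)
    out <- data.frame(type = c("photoelectric", "compton", "pair")[type_i],
                      E_photon_out = 0, E_electron = 0, E_positron = 0,
                      cos_theta_photon = NA_real_, cos_theta_electron = NA_real_)
    nc <- sum(type_i == 2)
    if (nc > 0) {
      kn <- cpp_sample_compton(energy, nc, seed)
      out$E_photon_out[type_i == 2] <- kn[, 1] * energy
      out$cos_theta_photon[type_i == 2] <- kn[, 2]
      out$E_electron[type_i == 2] <- kn[, 3]
      out$cos_theta_electron[type_i == 2] <- kn[, 4]
    }
    out$E_electron[type_i == 1] <- energy
    if (any(type_i == 3)) {
      if (energy <= .const$pair_thresh)
        stop("pair production sampled below threshold") # unreachable: zero weight
      f <- runif(sum(type_i == 3))
      ek <- energy - .const$pair_thresh
      out$E_electron[type_i == 3] <- f * ek
      out$E_positron[type_i == 3] <- (1 - f) * ek
    }
    out
  })
}

#' One condensed-history electron step
#'
#' Advances an electron by one condensed-history step in an infinite medium:
#' continuous (CSDA) energy loss along the step, collision deposit, and
#' angular deflection by Gaussian multiple scattering plus a hard-tail single
#' scatter -- the identical code path used inside the transport engine. The
#' step length is `min(max_step, 5% energy-loss distance)`.
#'
#' @param state List with `energy` (MeV), `direction` (unit 3-vector), and
#'   optionally `position` (mm).
#' @param mat A [material()].
#' @param max_step_mm Maximum step length, mm.
#' @param seed,substream RNG seed and substream index (advance `substream`
#'   between successive calls for independent steps).
#' @param cutoff Electron kinetic-energy cutoff, MeV.
#' @param xs Optional precomputed cross-section set.
#' @return Updated state list: `energy`, `direction`, `position`,
#'   `deposit` (MeV, collision), `path_mm` (path length actually traversed).
#' @export
step_electron <- function(state, mat, max_step_mm = 0.02, seed = 1,
                          substream = 1, cutoff = 0.05, xs = NULL) {
  stopifnot(inherits(mat, "material"))
  if (is.null(xs)) xs <- build_cross_sections(list(mat))
  E <- state$energy
  dir <- state$direction
  pos <- if (is.null(state$position)) c(0, 0, 0) else state$position
  if (E <= cutoff)
    return(list(energy = 0, direction = dir, position = pos,
                deposit = E, path_mm = 0))
  xsm <- xs$materials[[mat$name]]
  rho <- mat$density
  s_col <- xs_lookup(xs, mat$name, "s_col", E) * rho
  s_tot <- s_col + xs_lookup(xs, mat$name, "s_rad", E) * rho
  s_cm <- min(max_step_mm / 10, 0.05 * E / s_tot)
  res <- cpp_condensed_step(E, dir, s_cm, s_col, s_tot,
                            rho / xsm$X0_gcm2,
                            pi * .const$re_cm^2 * .const$avogadro * xsm$ZZ1A * rho,
                            cutoff, as.double(seed), as.integer(substream))
  list(energy = res$energy, direction = res$dir,
       position = pos + dir * res$path * 10,
       deposit = res$deposit, path_mm = res$path * 10)
}

#' Free-path depths of the photon flight sampler
#'
#' Samples first-interaction depths for a pencil beam in a homogeneous medium
#' with total attenuation coefficient taken from the cross-section model, for
#' validating exponential (Beer-Lambert) attenuation of primaries.
#'
#' @param energy Photon energy, MeV.
#' @param mat A [material()].
#' @param n Number of samples.
#' @param seed Seed.
#' @param xs Optional precomputed cross-section set.
#' @return Numeric vector of depths, cm.
#' @export
photon_free_depths <- function(energy, mat, n, seed = 1, xs = NULL) {
  stopifnot(inherits(mat, "material"))
  if (is.null(xs)) xs <- build_cross_sections(list(mat))
  mu <- xs_lookup(xs, mat$name, "total", energy) * mat$density
  cpp_sample_free_depth(mu, as.integer(n), as.double(seed))
}

#' Export a dose grid as CSV
#'
#' Writes the standard post-processing dialect: columns `X`, `Y`, `Z` (bin
#' centers, mm) and `Dose` (Gy per primary). With `extended = TRUE` a
#' `RelUncertainty` column is appended.
#'
#' @param grid A [dose_grid()].
#' @param path Output path.
#' @param extended Include the uncertainty column.
#' @return `path`, invisibly.
#' @export
write_dose_csv <- function(grid, path, extended = FALSE) {
  stopifnot(inherits(grid, "dose_grid"))
  ctr <- function(e) (e[-1] + e[-length(e)]) / 2
  g <- expand.grid(X = ctr(grid$x_edges), Y = ctr(grid$y_edges),
                   Z = ctr(grid$z_edges))
  g$Dose <- as.vector(grid$dose)
  if (extended) g$RelUncertainty <- as.vector(grid$rel_uncertainty)
  write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose CSV into a dose grid
#'
#' Reads the `X, Y, Z, Dose` dialect (including files produced by external
#' Monte Carlo codes with the same columns) back into a [dose_grid()]. Bins
#' are reconstructed from the unique sorted coordinates, assumed uniform.
#'
#' @param path CSV path.
#' @return A [dose_grid()] (zero uncertainty unless a `RelUncertainty`
#'   column is present).
#' @export
read_dose_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("X", "Y", "Z", "Dose") %in% names(d)))
    stop("dose CSV must have columns X, Y, Z, Dose")
  ax <- function(v) {
    u <- sort(unique(v))
    w <- if (length(u) > 1) diff(u)[1] else 1
    list(centers = u, edges = c(u - w / 2, u[length(u)] + w / 2))
  }
  xs <- ax(d$X); ys <- ax(d$Y); zs <- ax(d$Z)
  nx <- length(xs$centers); ny <- length(ys$centers); nz <- length(zs$centers)
  dose <- array(0, dim = c(nx, ny, nz))
  unc <- array(0, dim = c(nx, ny, nz))
  ix <- match(d$X, xs$centers); iy <- match(d$Y, ys$centers); iz <- match(d$Z, zs$centers)
  dose[cbind(ix, iy, iz)] <- d$Dose
  if ("RelUncertainty" %in% names(d)) unc[cbind(ix, iy, iz)] <- d$RelUncertainty
  dose_grid(dose, unc, xs$edges, ys$edges, zs$edges,
            n_histories = NA_integer_, seed = NA_integer_,
            meta = list(source = path))
}
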