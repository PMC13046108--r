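#' Load the packaged reference tables
#'
#' Reads the constants packaged with tattoodose: elemental compositions (wet
#' basis, ppm) of three commercial tattoo inks, EU REACH concentration limits,
#' the skin-layer stack (names, thicknesses, densities), the shared skin
#' elemental mass-fraction vector, the representative dry-matter fraction of
#' liquid ink, and the dominant pigment compounds with their bulk densities.
#' All tables are validated against structural invariants before being
#' returned.
#'
#' @param dir Optional directory containing the CSV tables. Defaults to the
#'   copies installed with the package. A user-supplied directory must follow
#'   the same file names and schemas (see `write_reference_tables()`).
#' @return An object of class `reference_tables`: a list with components
#'   `ink_compositions` (named list, ink -> named ppm vector), `below_loq`
#'   (named list, ink -> character vector of elements reported below the limit
#'   of quantification, stored as 0 ppm), `reach_limits` (named numeric, ppm),
#'   `skin_layers` (data.frame), `skin_elemental_fractions` (normalized named
#'   numeric), `skin_elemental_fractions_raw` (as printed, summing to ~0.999),
#'   `dry_matter_fraction`, `dry_matter_range`, `tattoo_z_mm`,
#'   `compound_densities` (named numeric, g/cm^3), `compound_composition`
#'   (named list of elemental mass-fraction vectors), and `ink_compounds`
#'   (data.frame: ink, dominant_compound, bulk_density_g_cm3).
#' @examples
#' tab <- load_reference_tables()
#' tab$ink_compositions$brown[["Fe"]]   # 88400 ppm, wet basis
#' tab$reach_limits[["Pb"]]             # 0.7 ppm
#' @export
load_reference_tables <- function(dir = NULL) {
  path <- function(f) if (is.null(dir)) tattoodose_extdata(f) else file.path(dir, f)

  ink_raw  <- read.csv(path("ink_compositions.csv"), stringsAsFactors = FALSE)
  limits   <- read.csv(path("reach_limits.csv"), stringsAsFactors = FALSE)
  layers   <- read.csv(path("skin_layers.csv"), stringsAsFactors = FALSE)
  skinfrac <- read.csv(path("skin_elemental_fractions.csv"), stringsAsFactors = FALSE)
  consts   <- read.csv(path("constants.csv"), stringsAsFactors = FALSE)
  stoich   <- read.csv(path("compound_stoichiometry.csv"), stringsAsFactors = FALSE)
  inkcomp  <- read.csv(path("ink_compounds.csv"), stringsAsFactors = FALSE)
  elements <- read.csv(path("element_data.csv"), stringsAsFactors = FALSE)

  cval <- function(n) consts$value[match(n, consts$name)]

  inks <- split(ink_raw, ink_raw$ink)
  inks <- inks[order(names(inks), method = "radix")]  # locale-invariant order
  ink_compositions <- lapply(inks, function(d) setNames(d$wet_ppm, d$element))
  below_loq <- lapply(inks, function(d) d$element[d$below_loq == 1])

  amass <- setNames(elements$atomic_mass, elements$element)
  comp_split <- split(stoich, stoich$compound)
  comp_split <- comp_split[order(names(comp_split), method = "radix")]
  compound_composition <- lapply(comp_split, function(d) {
    m <- d$n_atoms * amass[d$element]
    setNames(as.numeric(m / sum(m)), d$element)
  })
  compound_densities <- vapply(comp_split, function(d) d$density_g_cm3[1], numeric(1))

  raw <- setNames(skinfrac$mass_fraction, skinfrac$element)

  tab <- structure(list(
    ink_compositions = ink_compositions,
    below_loq = below_loq,
    reach_limits = setNames(limits$limit_ppm, limits$element),
    skin_layers = layers,
    skin_elemental_fractions_raw = raw,
    skin_elemental_fractions = raw / sum(raw),
    dry_matter_fraction = cval("dry_matter_fraction"),
    dry_matter_range = c(cval("dry_matter_min"), cval("dry_matter_max")),
    tattoo_z_mm = c(cval("tattoo_z_top_mm"), cval("tattoo_z_bottom_mm")),
    compound_densities = compound_densities,
    compound_composition = compound_composition,
    ink_compounds = inkcomp,
    element_data = elements
  ), class = "reference_tables")

  validate_reference_tables(tab)
  tab
}

#' @noRd
validate_reference_tables <- function(tab) {
  epi <- tab$skin_layers[tab$skin_layers$name != "papillary_dermis" &
                           tab$skin_layers$name != "reticular_dermis", ]
  if (abs(sum(epi$thickness_um) - 100.1) > 1e-9)
    stop("reference data integrity: epidermal sublayer thicknesses do not sum to 100.1 um")
  if (abs(sum(tab$skin_elemental_fractions) - 1) > 1e-12)
    stop("reference data integrity: normalized skin elemental fractions do not sum to 1")
  if (abs(sum(tab$skin_elemental_fractions_raw) - 0.999) > 2e-3)
    stop("reference data integrity: raw skin elemental fractions far from printed total ~0.999")
  for (el in names(tab$reach_limits)) {
    present <- any(vapply(tab$ink_compositions, function(v) el %in% names(v), logical(1)))
    if (!present)
      stop("reference data integrity: REACH-limited element ", el, " absent from all inks")
  }
  need <- c("Al", "V", "Cr", "Fe", "Co", "Ni", "Cu", "Cd", "Ba", "Hg", "Pb")
  for (ink in names(tab$ink_compositions))
    if (!all(need %in% names(tab$ink_compositions[[ink]])))
      stop("reference data integrity: ink ", ink, " is missing elements")
  if (!all(tab$ink_compounds$ink %in% names(tab$ink_compositions)))
    stop("reference data integrity: compound table names an unknown ink")
  invisible(tab)
}

#' Write reference tables to a directory of CSV files
#'
#' Serializes a `reference_tables` object using the same plain-text schema the
#' package ships, so that edited copies can be reloaded with
#' `load_reference_tables(dir)`. Round-tripping is lossless.
#'
#' @param tab A `reference_tables` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_tables <- function(tab, dir) {
  stopifnot(inherits(tab, "reference_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ink_rows <- do.call(rbind, lapply(names(tab$ink_compositions), function(ink) {
    v <- tab$ink_compositions[[ink]]
    data.frame(ink = ink, element = names(v), wet_ppm = as.numeric(v),
               below_loq = as.integer(names(v) %in% tab$below_loq[[ink]]))
  }))
  write.csv(ink_rows, file.path(dir, "ink_compositions.csv"), row.names = FALSE)
  write.csv(data.frame(element = names(tab$reach_limits),
                       limit_ppm = as.numeric(tab$reach_limits)),
            file.path(dir, "reach_limits.csv"), row.names = FALSE)
  write.csv(tab$skin_layers, file.path(dir, "skin_layers.csv"), row.names = FALSE)
  write.csv(data.frame(element = names(tab$skin_elemental_fractions_raw),
                       mass_fraction = as.numeric(tab$skin_elemental_fractions_raw)),
            file.path(dir, "skin_elemental_fractions.csv"), row.names = FALSE)
  write.csv(data.frame(
    name = c("dry_matter_fraction", "dry_matter_min", "dry_matter_max",
             "tattoo_z_top_mm", "tattoo_z_bottom_mm"),
    value = c(tab$dry_matter_fraction, tab$dry_matter_range, tab$tattoo_z_mm)),
    file.path(dir, "constants.csv"), row.names = FALSE)
  # stoichiometry and element data are copied verbatim from the package copies
  for (f in c("compound_stoichiometry.csv", "ink_compounds.csv", "element_data.csv"))
    file.copy(tattoodose_extdata(f), file.path(dir, f), overwrite = TRUE)
  invisible(dir)
}

#' Generate a randomized synthetic ink composition
#'
#' Property-test generator: draws a synthetic ink with `n_elements` trace
#' metals (log-uniform ppm between 0.01 and 1e5), a dry-matter fraction
#' uniform over the surveyed commercial range 0.31-0.62, and a dominant
#' pigment compound drawn from the packaged compound list. Deterministic for a
#' fixed seed; the caller's RNG state is untouched.
#'
#' @param seed Integer seed.
#' @param n_elements Number of trace elements to include (>= 1).
#' @param tables Reference tables (defaults to the packaged set).
#' @return An [ink_composition()] object with color `"synthetic"`.
#' @export
make_random_ink <- function(seed, n_elements = 5, tables = load_reference_tables()) {
  if (!is.numeric(n_elements) || n_elements < 1)
    stop("n_elements must be >= 1")
  n_elements <- as.integer(n_elements)
  pool <- names(tables$ink_compositions[[1]])
  with_private_seed(seed, {
    els <- sample(pool, min(n_elements, length(pool)))
    ppm <- 10^runif(length(els), -2, 5)
    fdry <- runif(1, tables$dry_matter_range[1], tables$dry_matter_range[2])
    comp <- sample(names(tables$compound_densities), 1)
    ink_composition(
      color = "synthetic",
      wet_ppm = setNames(ppm, els),
      dry_matter_fraction = fdry,
      dominant_compound = comp,
      bulk_density = tables$compound_densities[[comp]]
    )
  })
}

#' Build a toy dose grid with an analytically known structure
#'
#' Fixture generator for the analysis operations: returns a `dose_grid` whose
#' depth profile and quadrant means are known in closed form, with zero
#' statistical uncertainty.
#'
#' @param shape Integer vector `c(nx, ny, nz)`, all entries >= 1.
#' @param pattern One of `"uniform"` (constant `value`), `"ramp"` (dose equal
#'   to `value * iz` in depth bin `iz`), or `"quadrant"` (constant `value`,
#'   doubled in the x>0, y>0 quadrant).
#' @param value Base dose value (Gy per primary), default 1.
#' @return A [dose_grid] object. Depth bins are 0.1 mm; when `nz = 24` the
#'   grid spans the standard 0-2.4 mm scoring extent. Lateral bins are 2 mm
#'   centered on the beam axis.
#' @export
make_toy_dose_grid <- function(shape, pattern = c("uniform", "ramp", "quadrant"),
                               value = 1) {
  pattern <- match.arg(pattern)
  if (length(shape) != 3 || any(shape < 1) || any(shape != round(shape)))
    stop("shape must be three positive integers")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  dose <- array(value, dim = c(nx, ny, nz))
  if (pattern == "ramp")
    for (k in seq_len(nz)) dose[, , k] <- value * k
  x_edges <- seq(-nx, nx, length.out = nx + 1)  # 2 mm bins
  y_edges <- seq(-ny, ny, length.out = ny + 1)
  z_edges <- seq(0, 0.1 * nz, by = 0.1)
  if (pattern == "quadrant") {
    xc <- (x_edges[-1] + x_edges[-(nx + 1)]) / 2
    yc <- (y_edges[-1] + y_edges[-(ny + 1)]) / 2
    dose[xc > 0, yc > 0, ] <- 2 * value
  }
  dose_grid(dose = dose, rel_uncertainty = array(0, dim = dim(dose)),
            x_edges = x_edges, y_edges = y_edges, z_edges = z_edges,
            n_histories = 0L, seed = NA_integer_,
            meta = list(source = "toy", pattern = pattern, value = value))
}
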