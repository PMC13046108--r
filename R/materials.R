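#' Transport material
#'
#' A named medium: mass density plus a normalized elemental mass-fraction
#' vector. This is the unit consumed by the cross-section builder and the
#' transport engine.
#'
#' @param name Label.
#' @param density Mass density, g/cm^3 (> 0).
#' @param elements Named numeric vector of elemental mass fractions; must be
#'   nonnegative and sum to 1 within 1e-9 (exactly renormalized on
#'   construction).
#' @return Object of class `material`.
#' @export
material <- function(name, density, elements) {
  if (!is.numeric(density) || density <= 0) stop("density must be positive")
  if (is.null(names(elements)) || any(!nzchar(names(elements))))
    stop("elements must be a named vector of mass fractions")
  if (any(elements < 0)) stop("elemental mass fractions must be >= 0")
  s <- sum(elements)
  if (abs(s - 1) > 1e-9)
    stop("elemental mass fractions must sum to 1 (got ", format(s), ")")
  elements <- elements[elements > 0]
  structure(list(name = name, density = density, elements = elements / sum(elements)),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material> ", x$name, "  rho = ", x$density, " g/cm^3\n  ",
      paste0(names(x$elements), ": ", signif(x$elements, 4), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Liquid water material
#' @return A [material()] for water at 1.0 g/cm^3.
#' @export
water_material <- function() {
  mH <- 2 * 1.008; mO <- 15.999
  material("water", 1.0, c(H = mH, O = mO) / (mH + mO))
}

#' Volume-fraction mixture density
#'
#' Linear volume-weighted density of a two-component tattoo-dermis mixture:
#' `rho_mix = v_ink * rho_ink + (1 - v_ink) * rho_dermis`. Reproduces the
#' packaged mixture-density table after rounding to one decimal.
#'
#' @param v_ink Ink volume fraction in \[0, 1\] (vectorized).
#' @param rho_ink,rho_dermis Component densities, g/cm^3 (> 0).
#' @return Mixture density, g/cm^3.
#' @examples
#' mix_density(0.50, 5.3, 1.1)  # 3.2
#' @export
mix_density <- function(v_ink, rho_ink, rho_dermis) {
  if (any(v_ink < 0 | v_ink > 1)) stop("v_ink must lie in [0, 1]")
  if (any(rho_ink <= 0) || any(rho_dermis <= 0)) stop("densities must be positive")
  v_ink * rho_ink + (1 - v_ink) * rho_dermis
}

#' Mass fractions of a volume-specified mixture
#'
#' Converts component volume fractions to mass fractions:
#' `w_i = v_i * rho_i / sum_j v_j * rho_j`.
#'
#' @param volumes Numeric vector of volume fractions (>= 0, summing to 1
#'   within 1e-12).
#' @param densities Component densities, g/cm^3 (> 0), same length.
#' @return Mass fractions `w_i` (>= 0, summing to 1).
#' @examples
#' mixture_mass_fractions(c(0.5, 0.5), c(5.3, 1.1))  # 0.8281, 0.1719
#' @export
mixture_mass_fractions <- function(volumes, densities) {
  if (length(volumes) != length(densities)) stop("length mismatch")
  if (any(volumes < 0)) stop("volume fractions must be >= 0")
  if (abs(sum(volumes) - 1) > 1e-12) stop("volume fractions must sum to 1")
  if (any(densities <= 0)) stop("densities must be positive")
  m <- volumes * densities
  if (sum(m) == 0) stop("degenerate mixture: zero total mass")
  m / sum(m)
}

#' Mixture specification
#'
#' @param materials List of [material()] objects.
#' @param volumes Volume fractions, one per material (>= 0, summing to 1).
#' @param name Optional mixture label.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(materials, volumes, name = "mixture") {
  if (!all(vapply(materials, inherits, logical(1), "material")))
    stop("materials must be a list of material objects")
  if (length(materials) != length(volumes)) stop("length mismatch")
  if (any(volumes < 0) || abs(sum(volumes) - 1) > 1e-12)
    stop("volume fractions must be >= 0 and sum to 1")
  structure(list(materials = materials, volumes = volumes, name = name),
            class = "mixture_spec")
}

#' Blend materials by volume fractions
#'
#' Builds the mixture [material()]: density by volume-weighted mixing
#' ([mix_density()] generalized to any number of components), elemental mass
#' fractions as the mass-fraction-weighted sum of component vectors.
#' Idempotent for a single component.
#'
#' @param spec A [mixture_spec()].
#' @return A [material()].
#' @export
blend_materials <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  dens <- vapply(spec$materials, `[[`, numeric(1), "density")
  rho_mix <- sum(spec$volumes * dens)
  w <- mixture_mass_fractions(spec$volumes, dens)
  els <- list()
  for (i in seq_along(spec$materials)) {
    ev <- spec$materials[[i]]$elements * w[i]
    for (el in names(ev))
      els[[el]] <- (if (is.null(els[[el]])) 0 else els[[el]]) + ev[[el]]
  }
  material(spec$name, rho_mix, unlist(els))
}

#' Skin-layer material
#'
#' Returns the [material()] for a named skin stratum: the layer's packaged
#' density together with the shared normalized skin elemental vector (the
#' same average composition is applied uniformly across strata).
#'
#' @param layer_name One of the packaged layer names (see
#'   `load_reference_tables()$skin_layers$name`).
#' @param tables Reference tables.
#' @return A [material()].
#' @examples
#' skin_material("reticular_dermis")$density  # 1.1
#' @export
skin_material <- function(layer_name, tables = load_reference_tables()) {
  i <- match(layer_name, tables$skin_layers$name)
  if (is.na(i)) stop("unknown skin layer: ", layer_name)
  material(layer_name, tables$skin_layers$density_g_cm3[i],
           tables$skin_elemental_fractions)
}

#' Tattoo-dermis mixture at a given pigment loading
#'
#' Blends an ink's dry pigment with reticular dermis at `loading` vol%
#' pigment, the standard mixture series 0, 5, 10, 25, 50, 75, 100 vol%.
#'
#' @param ink An [ink_composition()] (or a packaged color label).
#' @param loading Pigment loading in vol% (0-100).
#' @param residual Dry-mass closure passed to [dry_mass_fractions()].
#' @param tables Reference tables.
#' @return A [material()] named `"<color>@<loading>"`.
#' @examples
#' tattoo_mixture("brown", 50)$density  # 3.2
#' @export
tattoo_mixture <- function(ink, loading, residual = c("compound", "binder"),
                           tables = load_reference_tables()) {
  if (is.character(ink)) ink <- packaged_ink(ink, tables)
  if (loading < 0 || loading > 100) stop("loading must be in [0, 100] vol%")
  v <- loading / 100
  dermis <- skin_material("reticular_dermis", tables)
  if (v == 0) return(dermis)
  pig <- ink_material(ink, residual = residual, tables = tables)
  blend_materials(mixture_spec(list(pig, dermis), c(v, 1 - v),
                               name = sprintf("%s@%g", ink$color, loading)))
}

#' Reproduce the packaged mixture-density table
#'
#' Computes mixture densities for the three packaged inks across the seven
#' standard loadings and rounds to one decimal for comparison with the
#' printed table (IEEE round-half-even on doubles, the convention that
#' reproduces the published values).
#'
#' @param tables Reference tables.
#' @return data.frame with `loading_vol_pct` and one rounded-density column
#'   per ink.
#' @export
mixture_density_table <- function(tables = load_reference_tables()) {
  loadings <- c(0, 5, 10, 25, 50, 75, 100)
  dermis_rho <- tables$skin_layers$density_g_cm3[
    tables$skin_layers$name == "reticular_dermis"]
  out <- data.frame(loading_vol_pct = loadings)
  for (ink in c("brown", "orange", "black")) {
    rho_ink <- tables$ink_compounds$bulk_density_g_cm3[
      tables$ink_compounds$ink == ink]
    out[[ink]] <- round(mix_density(loadings / 100, rho_ink, dermis_rho), 1)
  }
  out
}

#' Write a material card
#'
#' Serializes a material to a plain-text card (name, density, element:fraction
#' lines), mirroring common Monte Carlo material-definition formats.
#'
#' @param mat A [material()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_material_card <- function(mat, path) {
  stopifnot(inherits(mat, "material"))
  lines <- c(paste0("material: ", mat$name),
             paste0("density_g_cm3: ", format(mat$density, digits = 15)),
             paste0(names(mat$elements), ": ",
                    format(unname(mat$elements), digits = 15)))
  writeLines(lines, path)
  invisible(path)
}
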