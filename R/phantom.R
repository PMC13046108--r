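#' Build the voxelized multilayer skin phantom
#'
#' Constructs the layered tattooed-skin geometry: six epidermal sublayers
#' (0.1001 mm total), a 0.4 mm papillary dermis and 1.9 mm reticular dermis,
#' with a 0.3 mm tattoo sublayer embedded in the reticular dermis at
#' 1.25-1.55 mm below the surface, and a water backing beneath the skin for
#' backscatter. The lateral extent is wider than the 1 x 1 cm^2 field to
#' capture lateral scatter. Depth increases downward from the surface (z = 0);
#' voxel intervals are half-open `[top, bottom)`, so a point on a shared
#' boundary belongs to the deeper layer.
#'
#' @param tattoo_material A [material()] filling the tattoo sublayer
#'   uniformly, or `NULL` for the no-ink control (sublayer stays reticular
#'   dermis). Ignored when `layout = "quadrant"`.
#' @param layout `"uniform"` (one material across the whole sublayer) or
#'   `"quadrant"` (the 1 x 1 cm^2 plane is split into four 0.5 x 0.5 cm^2
#'   quadrants with per-quadrant materials).
#' @param quadrant_materials For the quadrant layout: named list with entries
#'   `top_left`, `top_right`, `bottom_left`, `bottom_right`, each a
#'   [material()] or `NULL` (control quadrant). The standard multi-color
#'   arrangement is no ink top-left, black top-right, orange bottom-left,
#'   brown bottom-right.
#' @param xy_bin_mm Lateral scoring bin width. Defaults to 2 mm for uniform
#'   layouts (the standard scoring mesh) and 2.5 mm for quadrant layouts so
#'   that scoring bins nest inside quadrants.
#' @param lateral_halfwidth_mm Lateral half-extent of the phantom slab, mm.
#' @param water_depth_mm Thickness of the water backing, mm.
#' @param tables Reference tables.
#' @return Object of class `phantom_grid`: list with `layers` (data.frame:
#'   name, z_top_mm, z_bottom_mm, region, is_tattoo), `materials` (list),
#'   `layer_material` (integer matrix, layers x 4 quadrants TL/TR/BL/BR),
#'   `quadrant_map`, `tattoo_z_mm`, scoring edges `x_edges`/`y_edges`/
#'   `z_edges` (mm), and `lateral_halfwidth_mm`.
#' @export
build_phantom <- function(tattoo_material = NULL,
                          layout = c("uniform", "quadrant"),
                          quadrant_materials = NULL,
                          xy_bin_mm = NULL,
                          lateral_halfwidth_mm = 15,
                          water_depth_mm = 100,
                          tables = load_reference_tables()) {
  layout <- match.arg(layout)
  sl <- tables$skin_layers
  z <- cumsum(c(0, sl$thickness_um)) / 1000  # mm
  layers <- data.frame(name = sl$name,
                       z_top_mm = z[-length(z)], z_bottom_mm = z[-1],
                       density = sl$density_g_cm3,
                       region = "skin", is_tattoo = FALSE,
                       stringsAsFactors = FALSE)

  tz <- tables$tattoo_z_mm
  ret <- which(layers$name == "reticular_dermis")
  if (tz[1] <= layers$z_top_mm[ret] || tz[2] >= layers$z_bottom_mm[ret])
    stop("geometry error: tattoo sublayer must lie strictly inside the reticular dermis")

  split_ret <- data.frame(
    name = c("reticular_dermis_upper", "tattoo_sublayer", "reticular_dermis_lower"),
    z_top_mm = c(layers$z_top_mm[ret], tz[1], tz[2]),
    z_bottom_mm = c(tz[1], tz[2], layers$z_bottom_mm[ret]),
    density = layers$density[ret], region = "skin",
    is_tattoo = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  total_depth <- layers$z_bottom_mm[nrow(layers)]
  water_row <- data.frame(name = "water_backing", z_top_mm = total_depth,
                          z_bottom_mm = total_depth + water_depth_mm,
                          density = 1.0, region = "water", is_tattoo = FALSE,
                          stringsAsFactors = FALSE)
  layers <- rbind(layers[seq_len(ret - 1), ], split_ret, water_row)
  rownames(layers) <- NULL

  # material catalogue: one per skin stratum (reticular dermis shared by the
  # split pieces), plus water and the tattoo mixture(s)
  mats <- list()
  add_mat <- function(m) {
    for (i in seq_along(mats)) if (identical(mats[[i]], m)) return(i)
    mats[[length(mats) + 1]] <<- m
    length(mats)
  }
  dermis <- skin_material("reticular_dermis", tables)
  idx_of_layer <- function(nm) {
    if (nm == "water_backing") add_mat(water_material())
    else if (nm %in% c("reticular_dermis_upper", "reticular_dermis_lower",
                       "tattoo_sublayer")) add_mat(dermis)
    else add_mat(skin_material(nm, tables))
  }
  base_idx <- vapply(layers$name, idx_of_layer, integer(1))
  layer_material <- matrix(base_idx, nrow = nrow(layers), ncol = 4)
  colnames(layer_material) <- c("top_left", "top_right", "bottom_left", "bottom_right")

  trow <- which(layers$is_tattoo)
  quadrant_map <- setNames(rep(NA_character_, 4), colnames(layer_material))
  if (layout == "uniform") {
    if (!is.null(tattoo_material)) {
      stopifnot(inherits(tattoo_material, "material"))
      layer_material[trow, ] <- add_mat(tattoo_material)
      quadrant_map[] <- tattoo_material$name
    }
  } else {
    if (is.null(quadrant_materials) ||
        !all(colnames(layer_material) %in% names(quadrant_materials)))
      stop("quadrant layout requires a quadrant_materials list naming all four quadrants")
    for (q in colnames(layer_material)) {
      m <- quadrant_materials[[q]]
      if (!is.null(m)) {
        stopifnot(inherits(m, "material"))
        layer_material[trow, q] <- add_mat(m)
        quadrant_map[q] <- m$name
      }
    }
  }

  if (is.null(xy_bin_mm)) xy_bin_mm <- if (layout == "quadrant") 2.5 else 2
  nxy <- 10 / xy_bin_mm
  if (abs(nxy - round(nxy)) > 1e-9)
    stop("xy_bin_mm must divide the 10 mm field evenly")

  structure(list(
    layers = layers, materials = mats, layer_material = layer_material,
    quadrant_map = quadrant_map, tattoo_z_mm = tz, layout = layout,
    x_edges = seq(-5, 5, by = xy_bin_mm),
    y_edges = seq(-5, 5, by = xy_bin_mm),
    z_edges = seq(0, 2.4, by = 0.1),
    lateral_halfwidth_mm = lateral_halfwidth_mm,
    total_depth_mm = water_row$z_bottom_mm
  ), class = "phantom_grid")
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat("<phantom_grid> ", nrow(x$layers), " z-layers, layout = ", x$layout,
      "\n  tattoo sublayer: ", x$tattoo_z_mm[1], "-", x$tattoo_z_mm[2],
      " mm; lateral halfwidth ", x$lateral_halfwidth_mm, " mm\n", sep = "")
  tm <- x$quadrant_map
  if (any(!is.na(tm)))
    cat("  tattoo fill:", paste(names(tm), "=", ifelse(is.na(tm), "none", tm),
                                collapse = ", "), "\n")
  invisible(x)
}

# Quadrant index (TL, TR, BL, BR) for a lateral position; boundary points
# belong to the right/top side.
#' @noRd
quadrant_index <- function(x, y) {
  if (y >= 0) { if (x < 0) 1L else 2L } else { if (x < 0) 3L else 4L }
}

#' Material at a point
#'
#' Constant-time voxel lookup for the transport engine and for geometry
#' audits. Depth intervals are half-open `[top, bottom)`.
#'
#' @param grid A `phantom_grid`.
#' @param x,y,z Position, mm (z measured downward from the surface).
#' @return The [material()] at that point.
#' @export
material_at <- function(grid, x, y, z) {
  stopifnot(inherits(grid, "phantom_grid"))
  if (abs(x) > grid$lateral_halfwidth_mm || abs(y) > grid$lateral_halfwidth_mm)
    stop("point outside lateral bounds")
  bounds <- c(grid$layers$z_top_mm[1], grid$layers$z_bottom_mm)
  i <- findInterval(z, bounds)
  if (i < 1 || i > nrow(grid$layers)) stop("point outside depth bounds")
  grid$materials[[grid$layer_material[i, quadrant_index(x, y)]]]
}

#' Phantom mass summary
#'
#' Integrates density over the skin portion of the phantom (one lateral
#' quadrant column of 0.5 x 0.5 cm^2 each, 0-2.4 mm depth), for mass audits.
#'
#' @param grid A `phantom_grid`.
#' @return List with `per_quadrant` (g, named) and `total` (g) over the
#'   2.4 mm skin slab across the 1 x 1 cm^2 field.
#' @export
phantom_mass <- function(grid) {
  stopifnot(inherits(grid, "phantom_grid"))
  skin <- grid$layers$region == "skin"
  thick_cm <- (grid$layers$z_bottom_mm - grid$layers$z_top_mm)[skin] / 10
  area_cm2 <- 0.25
  per_q <- setNames(numeric(4), colnames(grid$layer_material))
  for (q in 1:4) {
    dens <- vapply(grid$layer_material[skin, q],
                   function(i) grid$materials[[i]]$density, numeric(1))
    per_q[q] <- sum(thick_cm * dens) * area_cm2
  }
  list(per_quadrant = per_q, total = sum(per_q))
}

# Mass (g) of each scoring voxel, from exact layer-overlap integration of
# density. Scoring bins nest inside quadrants for both standard bin widths.
#' @noRd
scoring_voxel_masses <- function(grid) {
  nx <- length(grid$x_edges) - 1
  ny <- length(grid$y_edges) - 1
  nz <- length(grid$z_edges) - 1
  xc <- (grid$x_edges[-1] + grid$x_edges[-(nx + 1)]) / 2
  yc <- (grid$y_edges[-1] + grid$y_edges[-(ny + 1)]) / 2
  area_cm2 <- diff(grid$x_edges)[1] * diff(grid$y_edges)[1] / 100
  mass <- array(0, dim = c(nx, ny, nz))
  for (iz in seq_len(nz)) {
    z0 <- grid$z_edges[iz]; z1 <- grid$z_edges[iz + 1]
    ov <- pmax(0, pmin(grid$layers$z_bottom_mm, z1) -
                  pmax(grid$layers$z_top_mm, z0)) / 10  # cm
    lay <- which(ov > 0)
    for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      q <- quadrant_index(xc[ix], yc[iy])
      dens <- vapply(grid$layer_material[lay, q],
                     function(i) grid$materials[[i]]$density, numeric(1))
      mass[ix, iy, iz] <- sum(ov[lay] * dens) * area_cm2
    }
  }
  mass
}
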