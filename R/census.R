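# Geometric census of a cylindrical S-layer: lattice repeats, copy
# numbers, the pore count with interface sharing, surface-to-volume
# comparison and the dimpled-surface area-enhancement model.

#' Cell geometry for the census
#'
#' Defaults describe the canonical cell tube: 0.4 um across (the published
#' "0.4-um" figure is taken as the diameter — the only reading consistent
#' with the 466 x 96 repeat counts), 7 um long, with 15-nm lattice unit
#' distance and a 9.5-nm tile height.
#'
#' @param diameter,length,unit_distance,tile_height Lengths in nm.
#' @return A list of class `cell_geometry`.
#' @export
cell_geometry <- function(diameter = 400, length = 7000, unit_distance = 15,
                          tile_height = 9.5) {
  stopifnot(diameter > 0, length > 0, unit_distance > 0, tile_height > 0)
  structure(list(diameter = diameter, length = length,
                 unit_distance = unit_distance, tile_height = tile_height),
            class = "cell_geometry")
}

#' Pore complement of one hexamer tile and its interfaces
#'
#' Defaults follow the five observed pore classes: one central pore (SP-1)
#' and six peripheral pores (SP-2) intrinsic to each tile; one pore on each
#' of the two alternating trimeric-vertex classes (SP-3 and SP-4), each
#' vertex shared by three tiles; and one pore per dimeric edge (SP-5),
#' each edge shared by two tiles.
#'
#' @param intrinsic_central SP-1 count per tile.
#' @param intrinsic_peripheral SP-2 count per tile.
#' @param trimeric_types Numeric vector of per-vertex pore counts for the
#'   alternating trimeric-vertex classes (default `c(SP3 = 1, SP4 = 1)`).
#' @param dimeric_per_edge SP-5 count per dimeric edge.
#' @param pore_diameter_range Pore diameter range (Angstrom), reported for
#'   context only.
#' @return A list of class `pore_spec`.
#' @export
pore_spec <- function(intrinsic_central = 1, intrinsic_peripheral = 6,
                      trimeric_types = c(SP3 = 1, SP4 = 1),
                      dimeric_per_edge = 1,
                      pore_diameter_range = c(5, 10)) {
  stopifnot(intrinsic_central >= 0, intrinsic_peripheral >= 0,
            all(trimeric_types >= 0), length(trimeric_types) == 2,
            dimeric_per_edge >= 0)
  structure(list(intrinsic_central = intrinsic_central,
                 intrinsic_peripheral = intrinsic_peripheral,
                 trimeric_types = trimeric_types,
                 dimeric_per_edge = dimeric_per_edge,
                 pore_diameter_range = pore_diameter_range),
            class = "pore_spec")
}

#' Lattice repeat counts of the cylindrical tube
#'
#' Axial repeats: `floor(length / a)`. Circumferential repeats:
#' `floor(pi * diameter / (a * sqrt(3) / 2))` — rows around the
#' circumference are spaced by the triangular-lattice row height. Floor
#' (not round) counting reproduces 466 from 7000/15 = 466.7 and 96 from
#' 1256.6/12.99 = 96.7.
#'
#' @param geom A [cell_geometry()].
#' @return Named integer vector `c(n_axial, n_circumferential)`.
#' @export
lattice_repeats <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  a <- geom$unit_distance
  c(n_axial = floor(geom$length / a),
    n_circumferential = floor(pi * geom$diameter / (a * sqrt(3) / 2)))
}

#' Hexamer and monomer copy numbers from repeat counts
#' @param repeats Output of [lattice_repeats()].
#' @return Named vector `c(n_hexamers, n_monomers)` with
#'   `n_monomers = 6 * n_hexamers`.
#' @export
copy_numbers <- function(repeats) {
  n_hex <- as.numeric(repeats[["n_axial"]]) * repeats[["n_circumferential"]]
  c(n_hexamers = n_hex, n_monomers = 6 * n_hex)
}

#' Pore census of the infinite hexagonal lattice
#'
#' Per tile, the infinite lattice carries the intrinsic pores plus a share
#' of the interface pores: six trimeric vertices per tile in two
#' alternating classes (3 + 3), each vertex shared by three tiles, and six
#' dimeric edges per tile, each shared by two:
#' \deqn{pores/tile = SP1 + SP2 + (3 t_1 + 3 t_2)/3 + 6 e / 2.}
#' With the default complement this gives 7 intrinsic + 2 trimeric + 3
#' dimeric = 12 pores per hexamer.
#'
#' @param spec A [pore_spec()].
#' @param n_hexamers Number of hexamer tiles on the cell.
#' @return Named vector `c(pores_per_hexamer, n_pores_cell)` with
#'   `n_pores_cell = round(pores_per_hexamer * n_hexamers)`.
#' @export
pore_census <- function(spec = pore_spec(), n_hexamers = 1) {
  stopifnot(inherits(spec, "pore_spec"), n_hexamers >= 0)
  per_tile <- spec$intrinsic_central + spec$intrinsic_peripheral +
    (3 * spec$trimeric_types[[1]] + 3 * spec$trimeric_types[[2]]) / 3 +
    6 * spec$dimeric_per_edge / 2
  c(pores_per_hexamer = per_tile,
    n_pores_cell = round(per_tile * n_hexamers))
}

#' Surface-to-volume ratio: cylinder versus equal-volume sphere
#'
#' Closed forms: a capped cylinder of diameter d and length L has
#' SA/V = (pi d L + pi d^2 / 2) / (pi d^2 L / 4); the sphere of equal
#' volume has SA/V = 3 / r_eq. For the canonical cell dimensions the ratio
#' is ~2: the cylindrical shape doubles the surface available per unit
#' volume relative to a sphere.
#'
#' @param geom A [cell_geometry()].
#' @param caps Include the two end caps in the cylinder surface (default
#'   TRUE; negligible at the canonical aspect ratio).
#' @return Named vector `c(sa_v_cylinder, sa_v_sphere, ratio)` (1/nm,
#'   1/nm, unitless).
#' @export
sa_v_comparison <- function(geom, caps = TRUE) {
  stopifnot(inherits(geom, "cell_geometry"))
  r <- geom$diameter / 2
  L <- geom$length
  vol <- pi * r^2 * L
  sa <- 2 * pi * r * L + if (caps) 2 * pi * r^2 else 0
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  sav_c <- sa / vol
  sav_s <- 3 / r_eq
  c(sa_v_cylinder = sav_c, sa_v_sphere = sav_s, ratio = sav_c / sav_s)
}

#' Area enhancement of the dimpled tile surface over a flat sheet
#'
#' The exposed S-layer surface is not flat: each hexamer tile is a dome
#' with a raised cap, giving the sheet an "egg carton" relief. The factor
#' reported is the area of one lattice unit cell of a parametric model
#' surface divided by the flat unit-cell area; it is explicitly
#' model-dependent and is always reported with the model name.
#'
#' Models: `"sinusoidal"` — a three-wave hexagonal corrugation
#' `z = A (cos k1.r + cos k2.r + cos k3.r)` with wavevectors 120 degrees
#' apart and peak-to-trough height `tile_height`, integrated by midpoint
#' quadrature over one unit cell with grid-doubling convergence control;
#' `"spherical_cap"` — a spherical cap of height `tile_height` over a
#' circular base of diameter `unit_distance` inscribed in the hexagonal
#' cell, closed form `1 + pi h^2 / ((sqrt(3)/2) a^2)`.
#'
#' @param tile_height Relief height h (nm).
#' @param unit_distance Lattice period a (nm).
#' @param model `"sinusoidal"` or `"spherical_cap"`.
#' @param n_grid Starting quadrature grid (sinusoidal model).
#' @param rel_tol Relative convergence tolerance for grid doubling.
#' @return The unitless area factor (>= 1), with attributes `model` and
#'   `parameters`.
#' @export
dimple_area_factor <- function(tile_height, unit_distance,
                               model = c("sinusoidal", "spherical_cap"),
                               n_grid = 64, rel_tol = 1e-5) {
  stopifnot(tile_height >= 0, unit_distance > 0)
  model <- match.arg(model)
  a <- unit_distance
  if (model == "spherical_cap") {
    fac <- 1 + pi * tile_height^2 / (sqrt(3) / 2 * a^2)
  } else {
    amp <- tile_height / 4.5 # three-wave sum spans [-1.5, 3]
    kmag <- 4 * pi / (sqrt(3) * a)
    kvecs <- rbind(c(0, 1), c(sqrt(3) / 2, -0.5), c(-sqrt(3) / 2, -0.5)) * kmag
    a1 <- c(a, 0); a2 <- c(a / 2, a * sqrt(3) / 2)
    integrand_mean <- function(ng) {
      s <- (seq_len(ng) - 0.5) / ng
      st <- expand.grid(s = s, t = s)
      xy <- cbind(st$s * a1[1] + st$t * a2[1], st$s * a1[2] + st$t * a2[2])
      gx <- gy <- numeric(nrow(xy))
      for (m in 1:3) {
        ph <- xy %*% kvecs[m, ]
        gx <- gx - amp * kvecs[m, 1] * sin(ph)
        gy <- gy - amp * kvecs[m, 2] * sin(ph)
      }
      mean(sqrt(1 + gx^2 + gy^2))
    }
    prev <- integrand_mean(n_grid)
    ng <- n_grid
    repeat {
      ng <- ng * 2
      cur <- integrand_mean(ng)
      if (abs(cur - prev) <= rel_tol * abs(cur)) break
      if (ng > 2048)
        stop(sprintf(paste0("dimple quadrature not converged: grid %d gives ",
                            "%.8f, grid %d gives %.8f"), ng / 2, prev, ng, cur))
      prev <- cur
    }
    fac <- cur
  }
  structure(fac, model = model,
            parameters = c(tile_height = tile_height, unit_distance = a))
}

#' Mean layer radii and envelope spacings from a labelled point cloud
#'
#' Measures the mean radial distance of each labelled envelope layer from
#' the cell axis, and the successive gaps: PS-1 (membrane to S-layer
#' base), the S-layer height (base to cap), and PS-2 (cap to sheath).
#'
#' @param cloud Labelled layer point cloud from
#'   [generate_envelope_layers()] (columns x, y, z, layer).
#' @param fit Optional [fit_cylinder()] result giving the axis; defaults
#'   to the z axis through the origin (the generator's frame).
#' @return A list: `radii` (named mean radius per layer, nm) and `gaps`
#'   (named: ps1, slayer_height, ps2; NA where a layer is missing).
#' @export
layer_spacing <- function(cloud, fit = NULL) {
  stopifnot(is.data.frame(cloud), all(c("x", "y", "z", "layer") %in% names(cloud)))
  pos <- as.matrix(cloud[, c("x", "y", "z")])
  if (is.null(fit)) {
    rad <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  } else {
    rel <- sweep(pos, 2, fit$axis_point)
    v <- fit$axis_direction
    rad <- sqrt(rowSums((rel - (rel %*% v) %*% t(v))^2))
  }
  layers <- c("membrane", "slayer_base", "slayer_cap", "sheath")
  radii <- vapply(layers, function(l) {
    sel <- cloud$layer == l
    if (!any(sel)) NA_real_ else mean(rad[sel])
  }, numeric(1))
  list(radii = radii,
       gaps = c(ps1 = radii[["slayer_base"]] - radii[["membrane"]],
                slayer_height = radii[["slayer_cap"]] - radii[["slayer_base"]],
                ps2 = radii[["sheath"]] - radii[["slayer_cap"]]))
}

#' Full geometric census of the S-layer tube
#'
#' Chains [lattice_repeats()], [copy_numbers()], [pore_census()],
#' [sa_v_comparison()] and [dimple_area_factor()] into one report.
#'
#' @param geom A [cell_geometry()].
#' @param pores A [pore_spec()].
#' @param dimple_model Model passed to [dimple_area_factor()].
#' @param caps Passed to [sa_v_comparison()].
#' @return A list of class `census_result` with fields n_axial,
#'   n_circumferential, n_hexamers, n_monomers, pores_per_hexamer,
#'   n_pores_cell, sa_v_cylinder, sa_v_equal_volume_sphere, sa_v_ratio,
#'   dimple_area_factor, dimple_model.
#' @export
run_census <- function(geom = cell_geometry(), pores = pore_spec(),
                       dimple_model = "sinusoidal", caps = TRUE) {
  reps <- lattice_repeats(geom)
  cn <- copy_numbers(reps)
  pc <- pore_census(pores, cn[["n_hexamers"]])
  sv <- sa_v_comparison(geom, caps = caps)
  df <- dimple_area_factor(geom$tile_height, geom$unit_distance,
                           model = dimple_model)
  structure(list(
    n_axial = as.integer(reps[["n_axial"]]),
    n_circumferential = as.integer(reps[["n_circumferential"]]),
    n_hexamers = cn[["n_hexamers"]],
    n_monomers = cn[["n_monomers"]],
    pores_per_hexamer = pc[["pores_per_hexamer"]],
    n_pores_cell = pc[["n_pores_cell"]],
    sa_v_cylinder = sv[["sa_v_cylinder"]],
    sa_v_equal_volume_sphere = sv[["sa_v_sphere"]],
    sa_v_ratio = sv[["ratio"]],
    dimple_area_factor = as.numeric(df),
    dimple_model = attr(df, "model")
  ), class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat("<census_result>\n")
  cat(sprintf("  repeats: %d axial x %d circumferential\n",
              x$n_axial, x$n_circumferential))
  cat(sprintf("  copies: %s hexamers, %s monomers\n",
              format(x$n_hexamers, big.mark = ","),
              format(x$n_monomers, big.mark = ",")))
  cat(sprintf("  pores: %.1f per hexamer, %s per cell\n",
              x$pores_per_hexamer, format(x$n_pores_cell, big.mark = ",")))
  cat(sprintf("  SA/V: cylinder %.5f /nm vs equal-volume sphere %.5f /nm (ratio %.3f)\n",
              x$sa_v_cylinder, x$sa_v_equal_volume_sphere, x$sa_v_ratio))
  cat(sprintf("  dimple area factor: %.3f (%s model)\n",
              x$dimple_area_factor, x$dimple_model))
  invisible(x)
}
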