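#' Specification of a synthetic cylindrical S-layer lattice
#'
#' Describes a hexagonal lattice of hexamer centres wrapped on a cylinder,
#' emulating the S-layer tube of a rod-shaped cell imaged by cryo-ET. The
#' defaults reproduce the geometry of the *M. hungatei* cell tube: a 15-nm
#' centre-to-centre unit distance on a cylinder 0.4 um across and 7 um long.
#' The 0.4-um figure is interpreted as the cell DIAMETER: only that reading
#' is consistent with the published repeat counts (466 axial x 96
#' circumferential) and with the reported cell widths of 0.4-0.5 um.
#'
#' @param unit_distance Centre-to-centre lattice spacing a (nm).
#' @param cell_diameter Cylinder diameter (nm).
#' @param cell_length Cylinder length (nm).
#' @param helix_angle Offset (degrees) of the axial tiling direction
#'   (direction-1) from the cylinder axis; sign sets the chirality.
#' @param noise_sigma Isotropic Gaussian positional noise (nm per axis),
#'   applied after wrapping.
#' @param dropout_fraction Probability that a lattice site is unobserved.
#' @param flattening Elliptical flattening of the cross-section in [0, 1),
#'   emulating compression at the air-water interface during vitrification;
#'   0 keeps the circular cylinder.
#' @param orient_sigma Optional Gaussian orientation noise (degrees,
#'   axis-angle magnitude); default 0.
#' @param seed Integer RNG seed; the generated set is a pure function of the
#'   spec including this seed.
#' @return A list of class `lattice_spec`.
#' @export
lattice_spec <- function(unit_distance = 15, cell_diameter = 400,
                         cell_length = 7000, helix_angle = 0,
                         noise_sigma = 0, dropout_fraction = 0,
                         flattening = 0, orient_sigma = 0, seed = 1L) {
  stopifnot(unit_distance > 0, cell_diameter > 0, cell_length > 0,
            abs(helix_angle) < 30, noise_sigma >= 0,
            dropout_fraction >= 0, dropout_fraction < 1,
            flattening >= 0, flattening < 1, orient_sigma >= 0)
  structure(list(unit_distance = unit_distance, cell_diameter = cell_diameter,
                 cell_length = cell_length, helix_angle = helix_angle,
                 noise_sigma = noise_sigma, dropout_fraction = dropout_fraction,
                 flattening = flattening, orient_sigma = orient_sigma,
                 seed = as.integer(seed)),
            class = "lattice_spec")
}

#' Generate a hexagonal lattice of particle poses wrapped on a cylinder
#'
#' Builds the triangular lattice of hexamer centres in the unrolled
#' (circumference, axis) plane, optionally rotates the lattice basis by the
#' helix angle, and wraps it onto the cylinder surface. Rows are kept at
#' exactly `a * sqrt(3)/2` spacing; the non-integer remainder of the
#' circumference is absorbed in a single seam gap, and seam-adjacent
#' particles are marked in the truth labels. The axial extent covered is
#' exactly `floor(cell_length / a)` repeats, so for `helix_angle = 0` the
#' particle count equals the product of the two repeat counts reported by
#' [lattice_repeats()].
#'
#' Each particle's Euler orientation (intrinsic ZYZ) encodes its outward
#' surface normal (third frame axis) and the in-plane direction-1 vector
#' (first frame axis). Flattening, positional noise and dropout from the
#' spec are applied in that order after wrapping.
#'
#' @param spec A [lattice_spec()].
#' @param cell_id Cell/tomogram label for the generated particles.
#' @return A [particle_set()] with truth labels `truth_ring_index`,
#'   `truth_axial_index`, `truth_seam`, `truth_near_vacancy` (all FALSE
#'   here) and, when flattening is applied, `truth_curvature` (the true
#'   cross-sectional principal curvature, 1/nm). The spec is attached as
#'   attribute `"lattice_spec"`.
#' @export
generate_cylinder_lattice <- function(spec, cell_id = "cell_001") {
  stopifnot(inherits(spec, "lattice_spec"))
  a <- spec$unit_distance
  w <- a * sqrt(3) / 2                      # row spacing around circumference
  circ <- pi * spec$cell_diameter
  n_circ <- floor(circ / w)
  if (n_circ < 3)
    stop(sprintf(paste0("circumference %.1f nm holds only %d lattice rows at ",
                        "unit distance %.1f nm; at least 3 are required"),
                 circ, n_circ, a))
  n_ax <- floor(spec$cell_length / a)
  if (n_ax < 1) stop("cell_length shorter than one lattice repeat")
  U <- n_circ * w                           # circumferential extent actually tiled
  V <- n_ax * a                             # axial extent actually tiled

  alpha <- deg2rad(spec$helix_angle)
  # lattice basis in the unrolled (u = circumferential, v = axial) plane
  e1 <- c(sin(alpha), cos(alpha))                       # direction-1
  e2 <- c(sin(alpha + pi / 3), cos(alpha + pi / 3))     # direction-2
  B <- a * cbind(e1, e2)
  Binv <- solve(B)
  corners <- rbind(c(0, 0), c(U, 0), c(0, V), c(U, V))
  mn <- corners %*% t(Binv)
  m_range <- floor(min(mn[, 1]) - 2):ceiling(max(mn[, 1]) + 2)
  n_range <- floor(min(mn[, 2]) - 2):ceiling(max(mn[, 2]) + 2)
  grid <- expand.grid(m = m_range, n = n_range)
  uv <- as.matrix(grid) %*% t(B)
  tol <- 1e-9 * a
  keep <- uv[, 1] >= -tol & uv[, 1] < U - tol &
          uv[, 2] >= -tol & uv[, 2] < V - tol
  grid <- grid[keep, , drop = FALSE]
  uv <- uv[keep, , drop = FALSE]

  R <- spec$cell_diameter / 2
  theta <- uv[, 1] / R
  pos <- cbind(R * cos(theta), R * sin(theta), uv[, 2])
  seam <- uv[, 1] < 0.5 * w | uv[, 1] > U - 1.5 * w

  # orientation: normal radial, tilt 90; direction-1 tilted by helix angle
  rot <- wrap180(rad2deg(theta))
  tilt <- rep(90, nrow(pos))
  psi <- rep(wrap180(180 - spec$helix_angle), nrow(pos))

  out <- particle_set(
    particle_id = seq_len(nrow(pos)),
    cell_id = rep(cell_id, nrow(pos)),
    position = pos,
    euler = cbind(rot, tilt, psi),
    truth = tibble::tibble(
      ring_index = grid$n, axial_index = grid$m,
      seam = seam, near_vacancy = rep(FALSE, nrow(pos))
    )
  )
  attr(out, "lattice_spec") <- spec

  with_seed(spec$seed, {
    if (spec$flattening > 0)
      out <- apply_flattening(out, spec$flattening)
    if (spec$noise_sigma > 0) {
      out$x <- out$x + stats::rnorm(nrow(out), 0, spec$noise_sigma)
      out$y <- out$y + stats::rnorm(nrow(out), 0, spec$noise_sigma)
      out$z <- out$z + stats::rnorm(nrow(out), 0, spec$noise_sigma)
    }
    if (spec$orient_sigma > 0)
      out <- perturb_orientations(out, spec$orient_sigma)
    if (spec$dropout_fraction > 0) {
      keep <- stats::runif(nrow(out)) >= spec$dropout_fraction
      out <- out[keep, ]
      class(out) <- c("particle_set", setdiff(class(out), "particle_set"))
    }
  })
  attr(out, "lattice_spec") <- spec
  out
}

# Small-angle Gaussian orientation noise: random axis, Gaussian angle.
perturb_orientations <- function(particles, sigma_deg) {
  n <- nrow(particles)
  ax <- matrix(stats::rnorm(3 * n), n, 3)
  ax <- ax / sqrt(rowSums(ax^2))
  ang <- deg2rad(stats::rnorm(n, 0, sigma_deg))
  eul <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    M <- rotmat_from_euler(particles$rot[i], particles$tilt[i], particles$psi[i])
    k <- ax[i, ]; th <- ang[i]
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
    Rk <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    eul[i, ] <- euler_from_rotmat(Rk %*% M)
  }
  particles$rot <- eul[, 1]; particles$tilt <- eul[, 2]; particles$psi <- eul[, 3]
  particles
}

# Arc-length geometry of the flattened (elliptical) cross-section.
# Semi-minor axis b = R * (1 - flattening); semi-major axis a solves
# perimeter(a, b) = 2*pi*R, so geodesic distances along the surface are
# preserved to first order.
ellipse_geometry <- function(R, flattening, n_grid = 8192) {
  b <- R * (1 - flattening)
  target <- 2 * pi * R
  tg <- seq(0, 2 * pi, length.out = n_grid + 1)
  perim <- function(a) {
    sp <- sqrt(a^2 * sin(tg)^2 + b^2 * cos(tg)^2)
    sum((sp[-1] + sp[-length(sp)]) / 2) * (tg[2] - tg[1])
  }
  a <- stats::uniroot(function(a) perim(a) - target,
                      lower = R, upper = 4 * R / max(1 - flattening, 1e-3),
                      tol = 1e-10 * R)$root
  sp <- sqrt(a^2 * sin(tg)^2 + b^2 * cos(tg)^2)
  s <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2) * (tg[2] - tg[1]))
  s <- s * (target / s[length(s)])          # exact closure
  t_of_s <- stats::approxfun(s, tg, rule = 2)
  list(a = a, b = b, t_of_s = t_of_s,
       curvature = function(t) a * b / (a^2 * sin(t)^2 + b^2 * cos(t)^2)^1.5)
}

#' Flatten a cylindrical particle set into an elliptical tube
#'
#' Maps the circular cross-section to an ellipse of equal perimeter,
#' preserving arc length along the circumference (and hence lattice
#' spacing to first order), emulating compression of plunge-frozen cells
#' near the air-water interface. Orientations are updated to the new
#' outward surface normals, and the true cross-sectional curvature at each
#' particle is recorded in `truth_curvature`.
#'
#' @param particles A cylindrical [particle_set()] (z along the cylinder
#'   axis, cross-section centred on the origin).
#' @param flattening Eccentricity parameter in [0, 1); 0 is the identity.
#' @return The flattened `particle_set`.
#' @export
apply_flattening <- function(particles, flattening) {
  assert_particle_set(particles)
  if (flattening < 0 || flattening >= 1)
    stop("flattening must lie in [0, 1)")
  if (flattening == 0) return(particles)
  spec <- attr(particles, "lattice_spec")
  R <- if (!is.null(spec)) spec$cell_diameter / 2 else
    stats::median(sqrt(particles$x^2 + particles$y^2))
  geo <- ellipse_geometry(R, flattening)
  theta <- atan2(particles$y, particles$x) %% (2 * pi)
  t_new <- geo$t_of_s(R * theta)
  particles$x <- geo$a * cos(t_new)
  particles$y <- geo$b * sin(t_new)
  # outward normal of the ellipse: grad(x^2/a^2 + y^2/b^2)
  nx <- cos(t_new) / geo$a
  ny <- sin(t_new) / geo$b
  particles$rot <- wrap180(rad2deg(atan2(ny, nx)))
  particles$truth_curvature <- geo$curvature(t_new)
  particles
}

#' Insert lattice vacancies with ground-truth labels
#'
#' Removes `n_vacancies` particles chosen uniformly at random and marks the
#' surviving former neighbours of each removed site (within 1.3 unit
#' distances) with `truth_near_vacancy = TRUE`, giving the coordination-
#' defect detector a truth set. On a noiseless lattice each interior
#' vacancy leaves exactly its six neighbours at coordination 5.
#'
#' @param particles A [particle_set()].
#' @param n_vacancies Number of sites to remove (< particle count).
#' @param seed RNG seed for the vacancy draw.
#' @param unit_distance Lattice unit distance (nm); taken from the attached
#'   generator spec when omitted.
#' @return The reduced `particle_set`; removed sites are attached as
#'   attribute `"vacancies"` (tibble of ids and positions).
#' @export
add_defects <- function(particles, n_vacancies, seed = 1L, unit_distance = NULL) {
  assert_particle_set(particles)
  stopifnot(n_vacancies >= 0, n_vacancies < nrow(particles))
  if (n_vacancies == 0) return(particles)
  a <- unit_distance %||% attr(particles, "lattice_spec")$unit_distance
  if (is.null(a)) stop("unit_distance must be given when the particle set carries no generator spec")
  idx <- with_seed(seed, sample.int(nrow(particles), n_vacancies))
  removed <- particles[idx, ]
  kept <- particles[-idx, ]
  pk <- positions(kept)
  near <- rep(FALSE, nrow(kept))
  for (i in seq_len(nrow(removed))) {
    d2 <- (pk[, 1] - removed$x[i])^2 + (pk[, 2] - removed$y[i])^2 +
      (pk[, 3] - removed$z[i])^2
    near <- near | d2 <= (1.3 * a)^2
  }
  kept$truth_near_vacancy <- near
  class(kept) <- c("particle_set", setdiff(class(kept), "particle_set"))
  attr(kept, "lattice_spec") <- attr(particles, "lattice_spec")
  attr(kept, "vacancies") <- tibble::as_tibble(
    removed[, c("particle_id", "x", "y", "z")])
  kept
}

#' Specification of the concentric cell-envelope layers
#'
#' Four concentric cylindrical point layers emulate the envelope seen in
#' tomogram cross-sections: the lipid membrane, the S-layer base and cap
#' surfaces, and the outer sheath. Defaults reproduce the canonical
#' spacings: a 12-nm periplasmic gap (PS-1) between membrane and S-layer
#' base, the 9.5-nm S-layer tile height, and a 4-nm gap (PS-2) from the
#' S-layer cap to the sheath.
#'
#' @param membrane_radius Membrane layer radius (nm).
#' @param ps1_spacing Membrane to S-layer-base gap (nm), default 12.
#' @param slayer_height S-layer tile height (nm), default 9.5.
#' @param ps2_spacing S-layer-cap to sheath gap (nm), default 4.
#' @param points_per_layer Points sampled per layer.
#' @param cell_length Axial extent of the sampled layers (nm).
#' @param noise_sigma Isotropic Gaussian noise on layer points (nm).
#' @param seed RNG seed.
#' @return A list of class `envelope_spec`.
#' @export
envelope_spec <- function(membrane_radius = 180, ps1_spacing = 12,
                          slayer_height = 9.5, ps2_spacing = 4,
                          points_per_layer = 2000, cell_length = 1000,
                          noise_sigma = 0, seed = 1L) {
  stopifnot(membrane_radius > 0, ps1_spacing >= 0, slayer_height >= 0,
            ps2_spacing >= 0, points_per_layer > 0, cell_length > 0,
            noise_sigma >= 0)
  structure(list(membrane_radius = membrane_radius, ps1_spacing = ps1_spacing,
                 slayer_height = slayer_height, ps2_spacing = ps2_spacing,
                 points_per_layer = as.integer(points_per_layer),
                 cell_length = cell_length, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "envelope_spec")
}

#' Generate labelled concentric envelope layer point clouds
#'
#' @param spec An [envelope_spec()].
#' @return A tibble with columns `x`, `y`, `z` (nm) and `layer` (factor:
#'   membrane, slayer_base, slayer_cap, sheath), points uniform on each
#'   cylindrical layer.
#' @export
generate_envelope_layers <- function(spec) {
  stopifnot(inherits(spec, "envelope_spec"))
  r <- c(membrane = spec$membrane_radius,
         slayer_base = spec$membrane_radius + spec$ps1_spacing,
         slayer_cap = spec$membrane_radius + spec$ps1_spacing + spec$slayer_height,
         sheath = spec$membrane_radius + spec$ps1_spacing + spec$slayer_height +
           spec$ps2_spacing)
  with_seed(spec$seed, {
    out <- lapply(names(r), function(lab) {
      th <- stats::runif(spec$points_per_layer, 0, 2 * pi)
      z <- stats::runif(spec$points_per_layer, 0, spec$cell_length)
      tibble::tibble(x = r[[lab]] * cos(th), y = r[[lab]] * sin(th), z = z,
                     layer = lab)
    })
    out <- do.call(rbind, out)
    if (spec$noise_sigma > 0) {
      out$x <- out$x + stats::rnorm(nrow(out), 0, spec$noise_sigma)
      out$y <- out$y + stats::rnorm(nrow(out), 0, spec$noise_sigma)
      out$z <- out$z + stats::rnorm(nrow(out), 0, spec$noise_sigma)
    }
    out$layer <- factor(out$layer, levels = names(r))
    out
  })
}
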