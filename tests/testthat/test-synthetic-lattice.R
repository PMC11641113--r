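test_that("ZYZ Euler angles and rotation matrices round-trip", {
  set.seed(42)
  for (k in 1:25) {
    M <- random_rigid_motion()$R
    e <- euler_from_rotmat(M)
    expect_equal(rotmat_from_euler(e[1], e[2], e[3]), M, tolerance = 1e-10)
  }
  # degenerate tilts
  expect_equal(euler_from_rotmat(diag(3))[["tilt"]], 0)
  e <- euler_from_rotmat(rotmat_from_euler(25, 0, 0))
  expect_equal(((e[["rot"]] + e[["psi"]] + 180) %% 360) - 180, 25,
               tolerance = 1e-10)
})

test_that("full-size tube reproduces the published lattice count", {
  ps <- generate_cylinder_lattice(lattice_spec())
  expect_equal(nrow(ps), 44736)
  expect_equal(length(unique(ps$truth_ring_index)), 96)
  expect_equal(max(table(ps$truth_ring_index)), 466)
  # count formula holds across geometries
  for (geom in list(c(13, 350, 1300), c(18, 500, 900))) {
    a <- geom[1]; d <- geom[2]; L <- geom[3]
    n <- nrow(generate_cylinder_lattice(lattice_spec(
      unit_distance = a, cell_diameter = d, cell_length = L)))
    expect_equal(n, floor(L / a) * floor(pi * d / (a * sqrt(3) / 2)))
  }
})

test_that("noiseless lattice has exact unit spacing and radial poses", {
  ps <- tube_lattice(cell_length = 300)
  pos <- positions(ps)
  # along each axial row the spacing is exactly the unit distance
  ord <- order(ps$truth_ring_index, ps$truth_axial_index)
  same_row <- diff(ps$truth_ring_index[ord]) == 0
  step <- sqrt(rowSums(diff(pos[ord, ])^2))[same_row]
  expect_equal(max(abs(step - 15)), 0, tolerance = 1e-9)
  # nearest neighbours sit at the unit distance (diagonals are chords of
  # the cylinder, shorter by < 0.02%)
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  expect_lt(max(abs(nnd - 15)), 0.005)
  # all particles on the cylinder surface
  expect_equal(sqrt(ps$x^2 + ps$y^2), rep(200, nrow(ps)), tolerance = 1e-9)
  # Euler-encoded normals are the outward radial directions
  nrm <- pose_normals(ps)
  rad <- cbind(ps$x, ps$y, 0) / 200
  expect_equal(max(abs(nrm - rad)), 0, tolerance = 1e-9)
})

test_that("helix angle tilts direction-1 away from the axis by construction", {
  for (hx in c(-2.83, 2.83, 10)) {
    ps <- tube_lattice(cell_length = 300, helix_angle = hx)
    d1 <- rotmat_from_euler(ps$rot[1], ps$tilt[1], ps$psi[1])[, 1]
    expect_equal(rad2deg_test(acos(abs(d1[3]))), abs(hx), tolerance = 1e-6)
  }
})

test_that("seeded generation is reproducible and dropout is binomial", {
  sp <- lattice_spec(cell_length = 600, noise_sigma = 0.5,
                     dropout_fraction = 0.1, seed = 77)
  ps1 <- generate_cylinder_lattice(sp)
  ps2 <- generate_cylinder_lattice(sp)
  expect_identical(as.data.frame(ps1), as.data.frame(ps2))
  n_full <- floor(600 / 15) * 96
  expect_lt(abs(nrow(ps1) - 0.9 * n_full), 4 * sqrt(n_full * 0.1 * 0.9))
  ps3 <- generate_cylinder_lattice(lattice_spec(
    cell_length = 600, noise_sigma = 0.5, dropout_fraction = 0.1, seed = 78))
  expect_false(identical(as.data.frame(ps1), as.data.frame(ps3)))
})

test_that("too-small circumference is rejected with an explanation", {
  expect_error(generate_cylinder_lattice(lattice_spec(cell_diameter = 10)),
               "at least 3")
  expect_error(lattice_spec(dropout_fraction = 1))
  expect_error(lattice_spec(flattening = 1.2))
})

test_that("flattening is identity at zero and preserves the perimeter", {
  ps <- tube_lattice(cell_length = 300)
  expect_identical(apply_flattening(ps, 0), ps)
  pf <- apply_flattening(ps, 0.5)
  # recover the semi-axes and check perimeter against 2*pi*R numerically
  a_fit <- max(abs(pf$x)); b_fit <- max(abs(pf$y))
  expect_lt(abs(ellipse_perimeter(a_fit, b_fit) - 2 * pi * 200) / (2 * pi * 200),
            1e-3)
  # tight-side curvature exceeds the original 1/R = 2/d (closed form a/b^2)
  expect_gt(a_fit / b_fit^2, 2 / 400)
  expect_equal(max(pf$truth_curvature), a_fit / b_fit^2, tolerance = 1e-3)
  # flattening preserves z and in-surface spacing to first order
  expect_identical(pf$z, ps$z)
  expect_error(apply_flattening(ps, 1))
})

test_that("vacancies mark exactly their neighbours, reproducibly", {
  ps <- tube_lattice(cell_length = 600)
  expect_identical(add_defects(ps, 0), ps)
  psd <- add_defects(ps, 1, seed = 11)
  vac <- attr(psd, "vacancies")
  expect_equal(nrow(psd), nrow(ps) - 1)
  # oracle: neighbours of the removed site by direct distance scan
  d2 <- (ps$x - vac$x)^2 + (ps$y - vac$y)^2 + (ps$z - vac$z)^2
  nb_truth <- sort(ps$particle_id[d2 > 1e-9 & d2 < (1.3 * 15)^2])
  expect_identical(sort(psd$particle_id[psd$truth_near_vacancy]), nb_truth)
  expect_identical(as.data.frame(add_defects(ps, 5, seed = 3)),
                   as.data.frame(add_defects(ps, 5, seed = 3)))
  expect_error(add_defects(ps, nrow(ps)))
})

test_that("envelope layers sit at the canonical radii and spacings", {
  env <- generate_envelope_layers(envelope_spec())
  r <- tapply(sqrt(env$x^2 + env$y^2), env$layer, mean)
  expect_equal(unname(r[["slayer_base"]] - r[["membrane"]]), 12, tolerance = 1e-9)
  expect_equal(unname(r[["slayer_cap"]] - r[["slayer_base"]]), 9.5, tolerance = 1e-9)
  expect_equal(unname(r[["sheath"]] - r[["slayer_cap"]]), 4, tolerance = 1e-9)
  env0 <- generate_envelope_layers(envelope_spec(ps1_spacing = 0))
  r0 <- tapply(sqrt(env0$x^2 + env0$y^2), env0$layer, mean)
  expect_equal(unname(r0[["membrane"]]), unname(r0[["slayer_base"]]),
               tolerance = 1e-9)
})

test_that("truth labels survive a STAR round-trip", {
  ps <- add_defects(tube_lattice(cell_length = 300), 2, seed = 5)
  star <- withr::local_tempfile(fileext = ".star")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_particles(ps, star, pixel_size = 10, truth_path = tsv)
  back <- read_particles(star, pixel_size = 10, truth_path = tsv)
  expect_identical(back$truth_ring_index, ps$truth_ring_index)
  expect_identical(back$truth_seam, ps$truth_seam)
  expect_identical(back$truth_near_vacancy, ps$truth_near_vacancy)
})
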