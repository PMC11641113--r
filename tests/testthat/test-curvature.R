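test_that("quadric fit reproduces analytic limits: plane, cylinder, sphere", {
  # plane
  grid <- as.matrix(expand.grid(x = -3:3 * 5, y = -3:3 * 5))
  plane <- cbind(grid, 0)
  rec <- fit_local_quadric(c(0, 0, 0), plane[rowSums(grid^2) > 0, ])
  expect_lt(abs(rec$k1), 1e-6)
  expect_lt(abs(rec$k2), 1e-6)
  expect_lt(rec$fit_rms, 1e-9)
  # sphere, radius 100: k1 = k2 = 1/100, positive under the outward normal
  sph <- sphere_cap_points(100, c(0.12, 0.2, 0.3))
  rec <- fit_local_quadric(c(0, 0, 100), sph, outward = c(0, 0, 1))
  expect_lt(abs(rec$k1 - 0.01) / 0.01, 0.05)
  expect_lt(abs(rec$k2 - 0.01) / 0.01, 0.05)
  # cylinder, diameter 400: median interior k1 = 1/200, k2 ~ 0
  ps <- cached("tube900", tube_lattice(cell_length = 900))
  cv <- cached("curv900", estimate_curvature(ps, a_est = 15))
  g <- cached("graph900", build_graph(ps, 15))
  ok <- cv$valid & !g$nodes$is_boundary
  expect_lt(abs(median(cv$k1[ok]) - 1 / 200) * 200, 0.05)
  expect_lt(abs(median(cv$k2[ok])) * 200, 0.1)
  expect_true(all(cv$k1[cv$valid] >= cv$k2[cv$valid]))
})

test_that("degenerate neighbourhoods are marked invalid", {
  line <- cbind(seq(-3, 3), 0, 0) * 5
  rec <- fit_local_quadric(c(0, 0, 0), line)
  expect_false(rec$valid)
  rec2 <- fit_local_quadric(c(0, 0, 0), cbind(1:3, 1, 0))
  expect_false(rec2$valid) # fewer than 6 neighbours
})

test_that("curvature is rigid-motion invariant and scale-equivariant", {
  ps <- tube_lattice(cell_length = 450, noise_sigma = 0.2, seed = 51)
  cv1 <- estimate_curvature(ps, a_est = 15)
  ps2 <- apply_rigid(ps, withr::with_seed(9, random_rigid_motion()))
  cv2 <- estimate_curvature(ps2, a_est = 15)
  ok <- cv1$valid & cv2$valid
  expect_equal(cv1$k1[ok], cv2$k1[ok], tolerance = 1e-6)
  expect_equal(cv1$k2[ok], cv2$k2[ok], tolerance = 1e-6)
  ps3 <- ps
  ps3$x <- ps3$x * 2; ps3$y <- ps3$y * 2; ps3$z <- ps3$z * 2
  cv3 <- estimate_curvature(ps3, a_est = 30)
  ok3 <- cv1$valid & cv3$valid
  expect_equal(cv3$k1[ok3], cv1$k1[ok3] / 2, tolerance = 1e-9)
})

test_that("fit residuals vanish on true quadrics and grow with noise", {
  # a symmetric paraboloid patch is fitted exactly
  grid <- as.matrix(expand.grid(x = -3:3 * 5, y = -3:3 * 5))
  para <- cbind(grid, (0.004 * grid[, 1]^2 + 0.002 * grid[, 2]^2) / 2)
  rec <- fit_local_quadric(c(0, 0, 0), para[rowSums(grid^2) > 0, ],
                           outward = c(0, 0, -1))
  expect_lt(rec$fit_rms, 1e-6)
  expect_equal(rec$k1, 0.004, tolerance = 1e-6)
  expect_equal(rec$k2, 0.002, tolerance = 1e-6)
  # on a cylinder (not a quadric) residuals grow monotonically with noise
  rms <- vapply(c(0, 0.3, 0.6), function(s) {
    ps <- tube_lattice(cell_length = 450, noise_sigma = s, seed = 61)
    cv <- estimate_curvature(ps, a_est = 15)
    mean(cv$fit_rms[cv$valid])
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("flattened tubes split into curved flanks and flat tops", {
  pf <- cached("flat600", generate_cylinder_lattice(
    lattice_spec(cell_length = 600, flattening = 0.5, seed = 71)))
  cv <- cached("curvflat600", estimate_curvature(pf, a_est = 15))
  # threshold midway between the two truth mean curvatures (k2 = 0 on a tube)
  thr <- mean(range(pf$truth_curvature)) / 2
  truth_curved <- pf$truth_curvature / 2 >= thr
  part <- classify_particles(cv, thr)
  est <- part$assignment$class
  ok <- !is.na(est)
  sens <- mean(est[ok & truth_curved] == "curved")
  spec_ <- mean(est[ok & !truth_curved] == "flat")
  expect_gte((sens + spec_) / 2, 0.9)
  expect_equal(part$n_flat + part$n_curved + part$n_invalid, nrow(pf))
})

test_that("threshold edge cases: zero threshold and the cylinder default", {
  ps <- cached("tube900", tube_lattice(cell_length = 900))
  cv <- cached("curv900", estimate_curvature(ps, a_est = 15))
  all_curved <- classify_particles(cv, 0)
  expect_equal(all_curved$n_flat, 0)
  expect_equal(all_curved$n_curved, sum(cv$valid))
  # default threshold 0.5 * (1 / (2 R_fit)): every interior tube particle curved
  fit <- cached("fit900", fit_cylinder(ps))
  part <- classify_particles(cv, curvature_threshold(fit))
  g <- cached("graph900", build_graph(ps, 15))
  interior <- g$nodes$particle_id[!g$nodes$is_boundary]
  cls <- part$assignment$class[match(interior, part$assignment$particle_id)]
  expect_true(all(cls == "curved", na.rm = TRUE))
})

test_that("subset export preserves poses and round-trips through STAR", {
  pf <- cached("flat600", generate_cylinder_lattice(
    lattice_spec(cell_length = 600, flattening = 0.5, seed = 71)))
  cv <- cached("curvflat600", estimate_curvature(pf, a_est = 15))
  part <- classify_particles(cv, mean(range(pf$truth_curvature)) / 2)
  curved <- export_subset(pf, part, "curved")
  flat <- export_subset(pf, part, "flat")
  expect_equal(nrow(curved) + nrow(flat) + part$n_invalid, nrow(pf))
  f <- withr::local_tempfile(fileext = ".star")
  write_particles(curved, f, pixel_size = 10)
  back <- read_particles(f, pixel_size = 10)
  expect_equal(nrow(back), nrow(curved))
  expect_lt(max(abs(positions(back) - positions(curved))), 1e-3)
  # all-flat input gives an empty curved subset with a warning
  allflat <- classify_particles(cv, 10)
  expect_warning(empty <- export_subset(pf, allflat, "curved"), "empty")
  expect_equal(nrow(empty), 0)
})
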