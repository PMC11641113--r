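test_that("repeat counting uses floors and reproduces the canonical tube", {
  reps <- lattice_repeats(cell_geometry())
  expect_equal(unname(reps), c(466, 96))
  expect_equal(lattice_repeats(cell_geometry(length = 15, diameter = 40,
                                             unit_distance = 15))[["n_axial"]], 1)
  # doubling both length and diameter doubles both counts away from floor edges
  r1 <- lattice_repeats(cell_geometry(length = 6000, diameter = 370))
  r2 <- lattice_repeats(cell_geometry(length = 12000, diameter = 740))
  expect_equal(unname(r2), 2 * unname(r1))
})

test_that("copy numbers follow the repeat product and the hexamer stoichiometry", {
  cn <- copy_numbers(c(n_axial = 466, n_circumferential = 96))
  expect_equal(cn[["n_hexamers"]], 44736)
  expect_equal(cn[["n_monomers"]], 268416)
  expect_equal(unname(copy_numbers(c(n_axial = 1, n_circumferential = 1))),
               c(1, 6))
})

test_that("pore census matches the published per-tile complement", {
  pc <- pore_census(pore_spec(), 44736)
  expect_equal(pc[["pores_per_hexamer"]], 12)
  expect_equal(pc[["n_pores_cell"]], 536832)
  # intrinsic-only: seven pores per isolated tile
  iso <- pore_spec(trimeric_types = c(0, 0), dimeric_per_edge = 0)
  expect_equal(pore_census(iso, 1)[["pores_per_hexamer"]], 7)
})

test_that("pore formula equals brute-force toroidal enumeration", {
  sizes <- list(c(6, 6), c(8, 11), c(20, 20), c(30, 30))
  specs <- c(list(pore_spec()), lapply(1:4, function(k) withr::with_seed(k, {
    pore_spec(intrinsic_central = sample(0:3, 1),
              intrinsic_peripheral = sample(0:8, 1),
              trimeric_types = sample(0:4, 2, replace = TRUE),
              dimeric_per_edge = sample(0:3, 1))
  })))
  for (sz in sizes) for (sp in specs) {
    n_tiles <- sz[1] * sz[2]
    expect_equal(pore_census(sp, n_tiles)[["pores_per_hexamer"]],
                 toroidal_pore_total(sz[1], sz[2], sp) / n_tiles)
  }
})

test_that("the cylindrical cell doubles SA/V relative to an equal-volume sphere", {
  sv <- sa_v_comparison(cell_geometry())
  expect_lt(abs(sv[["ratio"]] - 2) / 2, 0.05)
  # closed-form agreement to near machine precision
  r <- 200; L <- 7000
  sav_c <- (2 * pi * r * L + 2 * pi * r^2) / (pi * r^2 * L)
  r_eq <- (3 * pi * r^2 * L / (4 * pi))^(1 / 3)
  expect_equal(sv[["sa_v_cylinder"]], sav_c, tolerance = 1e-12)
  expect_equal(sv[["ratio"]], sav_c * r_eq / 3, tolerance = 1e-12)
  # a squat capped cylinder still beats the sphere, per the closed form
  squat <- sa_v_comparison(cell_geometry(length = 100, diameter = 400))
  expect_gt(squat[["ratio"]], 1)
  # ratio is invariant under uniform rescaling of all lengths
  scaled <- sa_v_comparison(cell_geometry(diameter = 4000, length = 70000))
  expect_equal(scaled[["ratio"]], sv[["ratio"]], tolerance = 1e-12)
  expect_lt(sa_v_comparison(cell_geometry(), caps = FALSE)[["sa_v_cylinder"]],
            sv[["sa_v_cylinder"]])
})

test_that("dimple area factor: flat limit, height monotonicity, period scaling", {
  for (model in c("sinusoidal", "spherical_cap")) {
    expect_equal(as.numeric(dimple_area_factor(1e-9, 15, model)), 1,
                 tolerance = 1e-6)
    heights <- seq(2, 12, by = 2)
    f <- vapply(heights,
                function(h) as.numeric(dimple_area_factor(h, 15, model)),
                numeric(1))
    expect_true(all(diff(f) > 0))
    expect_gt(as.numeric(dimple_area_factor(9.5, 7.5, model)),
              as.numeric(dimple_area_factor(9.5, 15, model)))
    expect_identical(attr(dimple_area_factor(9.5, 15, model), "model"), model)
  }
  # spherical-cap closed form against direct quadrature of the cap surface
  h <- 4; a <- 15; rho <- a / 2
  Rc <- (rho^2 + h^2) / (2 * h)
  cap_area <- stats::integrate(function(r) {
    2 * pi * r / sqrt(1 - (r / Rc)^2)
  }, 0, rho, rel.tol = 1e-10)$value
  hex_area <- sqrt(3) / 2 * a^2
  expect_equal(as.numeric(dimple_area_factor(h, a, "spherical_cap")),
               (hex_area - pi * rho^2 + cap_area) / hex_area, tolerance = 1e-6)
})

test_that("layer spacings are measured from labelled envelope clouds", {
  env <- generate_envelope_layers(envelope_spec())
  gaps <- layer_spacing(env)$gaps
  expect_equal(unname(gaps), c(12, 9.5, 4), tolerance = 0.1)
  envn <- generate_envelope_layers(envelope_spec(noise_sigma = 0.5, seed = 8))
  gapsn <- layer_spacing(envn)$gaps
  expect_lt(max(abs(gapsn - c(12, 9.5, 4))), 0.2)
  env0 <- generate_envelope_layers(envelope_spec(ps2_spacing = 0))
  expect_equal(layer_spacing(env0)$gaps[["ps2"]], 0, tolerance = 1e-9)
  missing <- env[env$layer != "sheath", ]
  expect_true(is.na(layer_spacing(missing)$gaps[["ps2"]]))
})

test_that("census results are internally consistent and JSON-stable", {
  cs <- run_census()
  expect_equal(cs$n_monomers, 6 * cs$n_hexamers)
  expect_equal(cs$n_pores_cell, round(cs$pores_per_hexamer * cs$n_hexamers))
  expect_equal(cs$sa_v_ratio, cs$sa_v_cylinder / cs$sa_v_equal_volume_sphere,
               tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cs), f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  for (field in c("n_axial", "n_circumferential", "n_hexamers", "n_monomers",
                  "pores_per_hexamer", "n_pores_cell", "sa_v_ratio"))
    expect_equal(as.numeric(back[[field]]), as.numeric(cs[[field]]),
                 tolerance = 1e-12)
  # census count matches the generator's particle count at helix 0
  geom <- cell_geometry(length = 600)
  n_gen <- nrow(generate_cylinder_lattice(lattice_spec(cell_length = 600)))
  expect_equal(prod(lattice_repeats(geom)), n_gen)
})
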