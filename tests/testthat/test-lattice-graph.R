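test_that("unit distance is recovered exactly, under noise, and at the end-plug spacing", {
  ps <- cached("tube900", tube_lattice(cell_length = 900))
  # diagonal neighbours are chords of the cylinder, so the first-shell
  # peak sits a hair below the unit distance even without noise
  expect_equal(estimate_unit_distance(ps), 15, tolerance = 1e-3)
  psn <- cached("tube900n", tube_lattice(cell_length = 900, noise_sigma = 0.5,
                                         seed = 21))
  expect_lt(abs(estimate_unit_distance(psn) - 15) / 15, 0.02)
  # end-plug preset: larger 18-nm unit distance
  pse <- generate_cylinder_lattice(lattice_spec(unit_distance = 18,
                                                cell_length = 540, seed = 2))
  expect_lt(abs(estimate_unit_distance(pse) - 18) / 18, 0.02)
  expect_error(estimate_unit_distance(ps[1:5, ]), "at least 10")
})

test_that("unit-distance estimate is scale-equivariant", {
  psn <- cached("tube900n", tube_lattice(cell_length = 900, noise_sigma = 0.5,
                                         seed = 21))
  a1 <- estimate_unit_distance(psn)
  scaled <- psn
  scaled$x <- scaled$x * 2.5; scaled$y <- scaled$y * 2.5; scaled$z <- scaled$z * 2.5
  expect_equal(estimate_unit_distance(scaled), 2.5 * a1, tolerance = 0.01)
})

test_that("graph edges match the brute-force all-pairs oracle", {
  ps <- tube_lattice(cell_length = 180, noise_sigma = 0.5, seed = 31)
  expect_lte(nrow(ps), 2000)
  g <- build_graph(ps, 15, tol_fraction = 0.2)
  oracle <- brute_force_pairs(positions(ps), 15 * 0.8, 15 * 1.2)
  got <- data.frame(i = match(g$edges$id1, ps$particle_id),
                    j = match(g$edges$id2, ps$particle_id))
  got <- got[order(got$i, got$j), ]
  expect_equal(got$i, oracle$i)
  expect_equal(got$j, oracle$j)
  expect_equal(sort(g$edges$length_nm), sort(oracle$d), tolerance = 1e-12)
})

test_that("interior coordination of a perfect lattice is exactly 6", {
  ps <- cached("tube900", tube_lattice(cell_length = 900))
  g <- cached("graph900", build_graph(ps, 15))
  interior <- !g$nodes$is_boundary
  expect_gt(sum(interior), 0.8 * nrow(ps))
  expect_true(all(g$nodes$coordination[interior] == 6))
  expect_error(build_graph(ps, 15, tol_fraction = 0.7), "tol_fraction")
})

test_that("direction classes: class 1 hugs the axis, two edges per class per node", {
  ps <- cached("tube900", tube_lattice(cell_length = 900))
  g <- cached("dirs900", assign_edge_directions(cached(
    "graph900", build_graph(ps, 15))))
  e <- g$edges
  expect_true(all(!is.na(e$direction_class)))
  a1 <- e$angle_to_axis[e$direction_class == 1]
  expect_lt(max(pmin(a1 %% 180, 180 - a1 %% 180)), 1)
  # each interior node sees exactly 2 edges of each class
  interior_ids <- g$nodes$particle_id[!g$nodes$is_boundary]
  inc <- rbind(data.frame(id = e$id1, cl = e$direction_class),
               data.frame(id = e$id2, cl = e$direction_class))
  inc <- inc[inc$id %in% interior_ids, ]
  tab <- table(inc$id, inc$cl)
  expect_true(all(tab == 2))
  # class sizes equal within boundary effects
  expect_lt(diff(range(table(e$direction_class))) / nrow(e), 0.02)
})

test_that("direction classification is invariant under rigid motion", {
  ps <- tube_lattice(cell_length = 450, noise_sigma = 0.3, seed = 41)
  g1 <- assign_edge_directions(build_graph(ps, 15))
  motion <- withr::with_seed(7, random_rigid_motion())
  ps2 <- apply_rigid(ps, motion)
  g2 <- assign_edge_directions(build_graph(ps2, 15))
  # same edges in the same order -> class partition must agree up to the
  # (arbitrary) labelling of classes 2 and 3
  expect_identical(g1$edges$id1, g2$edges$id1)
  expect_identical(g1$edges$id2, g2$edges$id2)
  expect_identical(g1$edges$direction_class == 1L,
                   g2$edges$direction_class == 1L)
  m <- table(g1$edges$direction_class, g2$edges$direction_class)
  expect_equal(sum(m > 0 & m < max(m) * 0.01), 0) # one-to-one class mapping
  expect_true(all(colSums(m > 0) == 1) && all(rowSums(m > 0) == 1))
})

test_that("vacancy neighbours are detected with perfect precision and recall", {
  ps <- cached("tube900", tube_lattice(cell_length = 900))
  psd <- add_defects(ps, 5, seed = 3)
  g <- build_graph(psd, 15)
  flagged <- detect_defects(g)
  truth <- psd$particle_id[psd$truth_near_vacancy]
  interior <- g$nodes$particle_id[!g$nodes$is_boundary]
  truth_interior <- intersect(truth, interior)
  expect_true(all(flagged$particle_id %in% truth))       # precision 1
  expect_true(all(truth_interior %in% flagged$particle_id)) # recall 1
  expect_true(all(flagged$coordination != 6))
  # a single vacancy leaves exactly its 6 neighbours at coordination 5
  d1 <- detect_defects(build_graph(add_defects(ps, 1, seed = 11), 15))
  expect_equal(nrow(d1), 6)
  expect_true(all(d1$coordination == 5))
})

test_that("defect-free lattices yield no flags, even under noise", {
  ps <- cached("tube900", tube_lattice(cell_length = 900))
  expect_equal(nrow(detect_defects(cached("graph900", build_graph(ps, 15)))), 0)
  psn <- cached("tube900n", tube_lattice(cell_length = 900, noise_sigma = 0.5,
                                         seed = 21))
  gn <- cached("graph900n", build_graph(psn, 15))
  fpr <- nrow(detect_defects(gn)) / sum(!gn$nodes$is_boundary)
  expect_lt(fpr, 0.01)
})
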