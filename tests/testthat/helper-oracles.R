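# Independent oracles the implementation is checked against. These stay
# deliberately naive: brute-force enumeration, closed forms, O(n^2) scans.

# All unordered pairs with distance in [lo, hi], by full distance matrix.
brute_force_pairs <- function(pos, lo, hi) {
  d <- as.matrix(dist(pos))
  idx <- which(d >= lo & d <= hi & upper.tri(d), arr.ind = TRUE)
  out <- data.frame(i = pmin(idx[, 1], idx[, 2]),
                    j = pmax(idx[, 1], idx[, 2]),
                    d = d[idx])
  out[order(out$i, out$j), ]
}

# Brute-force count of distinct pores on an nx x ny toroidal triangular
# lattice of hexamer tiles. Every tile's surrounding interfaces are
# enumerated locally (6 trimeric vertices as triangles with its 6 cyclic
# neighbour pairs, alternating between the two vertex classes; 6 dimeric
# edges), then deduplicated globally, so the sharing factors (3 tiles per
# vertex, 2 per edge) emerge from the enumeration instead of being
# assumed. Returns the total distinct pore count on the torus.
toroidal_pore_total <- function(nx, ny, spec) {
  wrap_id <- function(i, j) paste(((i - 1) %% nx) + 1, ((j - 1) %% ny) + 1)
  offs <- list(c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1))
  tri_keys <- character(0)
  edge_keys <- character(0)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    for (k in 1:6) {
      o1 <- offs[[k]]; o2 <- offs[[(k %% 6) + 1]]
      ids <- sort(c(wrap_id(i, j), wrap_id(i + o1[1], j + o1[2]),
                    wrap_id(i + o2[1], j + o2[2])))
      orient <- if (k %% 2 == 1) "A" else "B"
      tri_keys <- c(tri_keys, paste(c(ids, orient), collapse = "|"))
      edge_keys <- c(edge_keys,
                     paste(sort(c(wrap_id(i, j), wrap_id(i + o1[1], j + o1[2]))),
                           collapse = "|"))
    }
  }
  tri_tab <- table(tri_keys)
  edge_tab <- table(edge_keys)
  stopifnot(all(tri_tab == 3), all(edge_tab == 2)) # sharing, by enumeration
  n_A <- sum(grepl("\\|A$", names(tri_tab)))
  n_B <- sum(grepl("\\|B$", names(tri_tab)))
  nx * ny * (spec$intrinsic_central + spec$intrinsic_peripheral) +
    n_A * spec$trimeric_types[[1]] + n_B * spec$trimeric_types[[2]] +
    length(edge_tab) * spec$dimeric_per_edge
}

# Numeric perimeter of an axis-aligned ellipse (independent quadrature).
ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-10)$value
}

# Points on a sphere cap around the +z pole (for curvature oracles).
sphere_cap_points <- function(r, polar_angles, n_azimuth = 12) {
  do.call(rbind, lapply(seq_along(polar_angles), function(k) {
    th <- seq(0, 2 * pi, length.out = n_azimuth + 1)[-1] + 0.1 * k
    cbind(r * sin(polar_angles[k]) * cos(th),
          r * sin(polar_angles[k]) * sin(th),
          r * cos(polar_angles[k]))
  }))
}

# Random rigid motion (seeded by caller).
random_rigid_motion <- function() {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 50))
}

apply_rigid <- function(particles, motion) {
  pos <- positions(particles) %*% t(motion$R)
  pos <- sweep(pos, 2, motion$t, "+")
  particles$x <- pos[, 1]; particles$y <- pos[, 2]; particles$z <- pos[, 3]
  # rotate orientations accordingly
  for (i in seq_len(nrow(particles))) {
    M <- rotmat_from_euler(particles$rot[i], particles$tilt[i], particles$psi[i])
    e <- euler_from_rotmat(motion$R %*% M)
    particles$rot[i] <- e[1]; particles$tilt[i] <- e[2]; particles$psi[i] <- e[3]
  }
  particles
}
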