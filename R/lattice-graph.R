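# Reconstruction of the hexagonal tiling as a neighbour graph: unit-distance
# estimation, edge building, tiling-direction classification via the
# 6-fold (hexatic) bond-orientational order parameter, and coordination-
# defect detection.

#' Estimate the lattice unit distance from particle positions
#'
#' Collects first-shell inter-particle distances (all pairs below 1.6x a
#' rough nearest-neighbour scale) and returns the peak of their
#' kernel-smoothed distribution. Pooled over all cell groups with at least
#' 10 particles. The estimate is scale-equivariant.
#'
#' @param particles A [particle_set()].
#' @return The estimated unit distance (nm).
#' @export
estimate_unit_distance <- function(particles) {
  assert_particle_set(particles)
  cells <- split(seq_len(nrow(particles)), particles$cell_id)
  cells <- cells[lengths(cells) >= 10]
  if (!length(cells))
    stop("unit-distance estimation needs at least 10 particles in one cell group")
  dists <- unlist(lapply(cells, function(idx) {
    pos <- positions(particles)[idx, , drop = FALSE]
    # rough scale from a subsample's nearest-neighbour distances
    smp <- if (nrow(pos) > 200) sample_deterministic(nrow(pos), 200) else seq_len(nrow(pos))
    d0 <- stats::median(vapply(smp, function(i) {
      d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2 +
        (pos[, 3] - pos[i, 3])^2
      sqrt(min(d2[-i]))
    }, numeric(1)))
    pr <- pairs_within(pos, 1.6 * d0)
    pr$d
  }))
  if (!length(dists)) stop("no first-shell distances found")
  if (stats::sd(dists) < 1e-9 * mean(dists)) return(stats::median(dists))
  dens <- stats::density(dists, n = 1024)
  dens$x[which.max(dens$y)]
}

# Deterministic evenly-spaced subsample (no RNG use).
sample_deterministic <- function(n, k) unique(round(seq(1, n, length.out = k)))

#' Build the lattice neighbour graph
#'
#' Connects particle pairs (within the same cell group) whose distance lies
#' in `a_est * (1 - tol, 1 + tol)`. Also computes per-node tangent frames
#' (local surface normal and an in-plane reference axis), coordination
#' numbers, and a boundary flag: a node is boundary when its tangent-plane
#' neighbour directions leave an angular gap larger than 90 degrees (this
#' captures lattice seams and cell ends, which would otherwise flood
#' defect lists).
#'
#' Tangent frames come from PCA of each node's graph neighbourhood
#' (normal = smallest-variance axis), with signs made consistent across
#' the graph and oriented outward by aggregate surface convexity; set
#' `use_pose_normals = TRUE` to trust the Euler-encoded normals instead.
#'
#' @param particles A [particle_set()].
#' @param a_est Unit distance (nm); estimated with
#'   [estimate_unit_distance()] when omitted.
#' @param tol_fraction Half-width of the accepted distance window as a
#'   fraction of `a_est` (default 0.2: generous for 0.5-nm positional noise
#'   and mild flattening, yet excluding the second shell at `a * sqrt(3)`).
#' @param use_pose_normals Logical; use Euler-encoded normals for the
#'   tangent frames.
#' @return A list of class `lattice_graph`: `nodes` (particle_id, cell_id,
#'   coordination, is_boundary), `edges` (id1, id2, length_nm,
#'   direction_class, angle_to_axis), `normals`/`positions` matrices
#'   indexed like `nodes`, per-cell `axes`, and `a_est`.
#' @export
build_graph <- function(particles, a_est = NULL, tol_fraction = 0.2,
                        use_pose_normals = FALSE) {
  assert_particle_set(particles)
  stopifnot(is.null(a_est) || a_est > 0)
  if (!(tol_fraction > 0 && tol_fraction < 0.5))
    stop("tol_fraction must lie in (0, 0.5)")
  if (is.null(a_est)) a_est <- estimate_unit_distance(particles)

  pos <- positions(particles)
  n <- nrow(particles)
  edge_list <- list()
  normals <- matrix(NA_real_, n, 3)
  coordination <- integer(n)
  is_boundary <- rep(TRUE, n)
  axes <- list()

  for (cell in unique(particles$cell_id)) {
    idx <- which(particles$cell_id == cell)
    cpos <- pos[idx, , drop = FALSE]
    pr <- pairs_within(cpos, a_est * (1 + tol_fraction))
    pr <- pr[pr$d >= a_est * (1 - tol_fraction), ]
    adj <- pairs_to_adjacency(pr, nrow(cpos))
    coordination[idx] <- lengths(adj)

    # cell principal axis (for outward normal orientation and direction-1)
    ctr <- colMeans(cpos)
    centred <- sweep(cpos, 2, ctr)
    ax <- eigen(crossprod(centred) / nrow(cpos), symmetric = TRUE)$vectors[, 1]
    if (ax[which.max(abs(ax))] < 0) ax <- -ax
    axes[[cell]] <- list(point = ctr, direction = ax)

    nrm <- if (use_pose_normals) {
      pose_normals(particles)[idx, , drop = FALSE]
    } else {
      ln <- local_normals(cpos, adj)
      orient_normals(ln$nrm, ln$convexity, adj)
    }
    normals[idx, ] <- nrm
    pr_ext <- pairs_within(cpos, 2.6 * a_est)
    pr_ext <- pr_ext[pr_ext$d > 1.3 * a_est, ]
    adj_ext <- pairs_to_adjacency(pr_ext, nrow(cpos))
    is_boundary[idx] <- boundary_flags(cpos, adj, nrm, adj_ext)

    if (nrow(pr)) {
      edge_list[[cell]] <- data.table::data.table(
        id1 = particles$particle_id[idx[pr$i]],
        id2 = particles$particle_id[idx[pr$j]],
        cell_id = cell, length_nm = pr$d)
    }
  }
  edges <- if (length(edge_list)) {
    e <- data.table::rbindlist(edge_list)
    tibble::as_tibble(e)
  } else {
    tibble::tibble(id1 = integer(), id2 = integer(), cell_id = character(),
                   length_nm = numeric())
  }
  edges$direction_class <- NA_integer_
  edges$angle_to_axis <- NA_real_
  structure(list(
    nodes = tibble::tibble(particle_id = particles$particle_id,
                           cell_id = particles$cell_id,
                           coordination = coordination,
                           is_boundary = is_boundary),
    edges = edges,
    positions = pos,
    normals = normals,
    axes = axes,
    a_est = a_est,
    tol_fraction = tol_fraction
  ), class = "lattice_graph")
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat(sprintf(paste0("<lattice_graph> %d nodes, %d edges, a = %.3f nm, ",
                     "%d interior defect candidate(s)\n"),
              nrow(x$nodes), nrow(x$edges), x$a_est,
              sum(!x$nodes$is_boundary & x$nodes$coordination != 6)))
  invisible(x)
}

# PCA surface normals per node over its graph neighbourhood (self + graph
# neighbours; nearest points as fallback for under-connected nodes).
# Returns the (sign-arbitrary) normals plus each node's convexity score:
# the component of (node - neighbourhood centroid) along the normal, which
# is positive on the outward side of a convex surface.
local_normals <- function(cpos, adj) {
  n <- nrow(cpos)
  nrm <- matrix(NA_real_, n, 3)
  convexity <- numeric(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) < 3) {
      d2 <- (cpos[, 1] - cpos[i, 1])^2 + (cpos[, 2] - cpos[i, 2])^2 +
        (cpos[, 3] - cpos[i, 3])^2
      nb <- order(d2)[2:min(9, n)]
    }
    pts <- cpos[c(i, nb), , drop = FALSE]
    cen <- sweep(pts, 2, colMeans(pts))
    ev <- eigen(crossprod(cen), symmetric = TRUE)$vectors
    v <- ev[, 3]
    dip <- cpos[i, ] - colMeans(cpos[nb, , drop = FALSE])
    nrm[i, ] <- v
    convexity[i] <- sum(v * dip)
  }
  list(nrm = nrm, convexity = convexity)
}

# Globally consistent outward orientation of the normal field: signs are
# propagated over the neighbour graph so adjacent normals agree, then each
# connected component is flipped outward as a whole when its summed
# convexity score is negative. Per-node convexity is too noisy a sign cue
# at realistic positional noise; the component aggregate is not.
orient_normals <- function(nrm, convexity, adj) {
  n <- nrow(nrm)
  sign_of <- rep(NA_real_, n)
  for (start in seq_len(n)) {
    if (!is.na(sign_of[start])) next
    comp <- integer(0)
    sign_of[start] <- 1
    queue <- start
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      comp <- c(comp, i)
      for (j in adj[[i]]) {
        if (!is.na(sign_of[j])) next
        agree <- sum(nrm[i, ] * nrm[j, ])
        sign_of[j] <- sign_of[i] * if (agree >= 0) 1 else -1
        queue <- c(queue, j)
      }
    }
    if (sum(sign_of[comp] * convexity[comp]) < 0)
      sign_of[comp] <- -sign_of[comp]
  }
  nrm * sign_of
}

# Boundary flag from tangent-plane neighbour directions. A node whose
# largest angular gap between first-shell neighbours exceeds 150 degrees
# (neighbours close to a half-plane, as at lattice seams and cell ends)
# is boundary outright. A gap in (100, 150] degrees is ambiguous: a
# vacancy neighbour (coordination 5) shows a 120-degree gap but the
# lattice continues behind the hole, whereas an end-row node's gap looks
# out of the lattice. Such nodes are boundary only when no second-shell
# particle (distance 1.3-2.6 unit distances) lies strictly inside the gap
# arc (15-degree margin from the flanking neighbours). Nodes with < 3
# neighbours are boundary.
boundary_flags <- function(cpos, adj, nrm, adj_ext) {
  n <- nrow(cpos)
  flag <- rep(TRUE, n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) < 3) next
    nv <- nrm[i, ]
    ref <- pick_inplane_ref(nv)
    bv <- cross3(nv, ref)
    off <- sweep(cpos[nb, , drop = FALSE], 2, cpos[i, ])
    ang <- sort(atan2(off %*% bv, off %*% ref))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    mx <- which.max(gaps)
    gap <- gaps[mx]
    if (gap <= deg2rad(100)) { flag[i] <- FALSE; next }
    if (gap > deg2rad(150)) next
    ext <- adj_ext[[i]]
    if (!length(ext)) next
    off2 <- sweep(cpos[ext, , drop = FALSE], 2, cpos[i, ])
    ang2 <- atan2(off2 %*% bv, off2 %*% ref)
    lo <- ang[mx] + deg2rad(15)
    rel <- (ang2 - lo) %% (2 * pi)
    flag[i] <- !any(rel < gap - deg2rad(30))
  }
  flag
}

# Any unit vector orthogonal to v.
pick_inplane_ref <- function(v) {
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(ref - sum(ref * v) * v)
}

#' Classify edges into the three tiling directions
#'
#' Projects each edge into the local tangent plane and measures its angle
#' from the cell axis reference (the cylinder-fit axis when supplied,
#' otherwise the cell's principal axis), then clusters edge orientations
#' with the 6-fold bond-orientational order parameter: the mean of
#' `exp(6i * phi)` over edges fixes a base axis, and the three class axes
#' sit 60 degrees apart. Class 1 is the axis closest to the cell axis;
#' classes 2 and 3 follow in increasing axis angle. Edges farther than 15
#' degrees from every class axis — or all edges of a cell whose hexatic
#' order is too weak — stay unassigned.
#'
#' @param graph A [build_graph()] result.
#' @param fit Optional [fit_cylinder()] result (or named list of fits per
#'   cell) supplying the axis reference.
#' @param max_axis_dev Assignment window around each class axis (degrees).
#' @param min_order Minimum modulus of the hexatic order parameter; below
#'   it the cell's edges stay unassigned with a warning.
#' @return The graph with `edges$direction_class` in {1, 2, 3, NA} and
#'   `edges$angle_to_axis` (tangent-plane angle to the cell axis, degrees
#'   in [0, 180)).
#' @export
assign_edge_directions <- function(graph, fit = NULL, max_axis_dev = 15,
                                   min_order = 0.4) {
  stopifnot(inherits(graph, "lattice_graph"))
  edges <- graph$edges
  if (!nrow(edges)) return(graph)
  idx_of <- match(edges$id1, graph$nodes$particle_id)
  idx2 <- match(edges$id2, graph$nodes$particle_id)
  for (cell in unique(edges$cell_id)) {
    sel <- which(edges$cell_id == cell)
    ax <- axis_for_cell(graph, fit, cell)
    phi <- numeric(length(sel))
    for (k in seq_along(sel)) {
      e <- sel[k]
      i <- idx_of[e]
      nv <- graph$normals[i, ]
      r <- ax - sum(ax * nv) * nv
      if (sqrt(sum(r^2)) < 1e-8) { phi[k] <- NA; next }
      r <- unit(r)
      b <- cross3(nv, r)
      ev <- graph$positions[idx2[e], ] - graph$positions[i, ]
      ev <- ev - sum(ev * nv) * nv
      phi[k] <- rad2deg(atan2(sum(ev * b), sum(ev * r))) %% 180
    }
    ok <- !is.na(phi)
    z <- mean(exp(1i * 6 * deg2rad(phi[ok])))
    if (Mod(z) < min_order) {
      warning(sprintf(paste0("cell %s: hexatic order %.2f below %.2f; ",
                             "edges left unassigned"), cell, Mod(z), min_order))
      edges$angle_to_axis[sel] <- phi
      next
    }
    theta0 <- rad2deg(Arg(z)) / 6
    axes_deg <- (theta0 + c(0, 60, 120)) %% 180
    # class 1 = axis closest to the cell axis (angle 0 by construction)
    dev0 <- pmin(axes_deg, 180 - axes_deg)
    ord <- order(dev0, abs(fold_hex_angle_signed(axes_deg)), seq_along(axes_deg))
    class_of_axis <- integer(3)
    class_of_axis[ord[1]] <- 1L
    rest <- setdiff(seq_len(3), ord[1])
    rest <- rest[order(axes_deg[rest])]
    class_of_axis[rest] <- c(2L, 3L)
    dev <- vapply(seq_len(3), function(k) {
      m <- (phi - axes_deg[k]) %% 180
      pmin(m, 180 - m)
    }, numeric(length(sel)))
    dev <- matrix(dev, ncol = 3)
    best <- max.col(-dev, ties.method = "first")
    cls <- class_of_axis[best]
    cls[is.na(phi) | dev[cbind(seq_along(best), best)] > max_axis_dev] <- NA_integer_
    edges$direction_class[sel] <- cls
    edges$angle_to_axis[sel] <- phi
  }
  graph$edges <- edges
  graph
}

axis_for_cell <- function(graph, fit, cell) {
  if (is.null(fit)) return(graph$axes[[cell]]$direction)
  if (inherits(fit, "cylinder_fit")) return(fit$axis_direction)
  if (!is.null(fit[[cell]])) return(fit[[cell]]$axis_direction)
  graph$axes[[cell]]$direction
}

#' Detect coordination defects
#'
#' Interior lattice nodes (non-boundary under the tangent-plane angular-gap
#' criterion) whose coordination differs from the hexagonal value of 6 —
#' vacancy neighbours, pentamer-like sites, or picking errors.
#'
#' @param graph A [build_graph()] result.
#' @return A tibble (particle_id, cell_id, coordination) of flagged nodes.
#' @export
detect_defects <- function(graph) {
  stopifnot(inherits(graph, "lattice_graph"))
  nd <- graph$nodes
  out <- nd[!nd$is_boundary & nd$coordination != 6,
            c("particle_id", "cell_id", "coordination")]
  tibble::as_tibble(out)
}
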