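# Cylinder-axis fitting and the angle between tiling direction-1 and the
# cell axis.

#' Fit a cylinder axis and radius to particle positions
#'
#' Initialises the axis from the principal component of the positions and
#' refines axis orientation, axis offset and radius by Levenberg-Marquardt
#' least squares on the radial residuals (radius profiled out as the mean
#' radial distance at each step).
#'
#' @param particles A [particle_set()] (single cell) or an n x 3 position
#'   matrix.
#' @param max_iter Iteration cap for the refinement.
#' @return A list of class `cylinder_fit`: `axis_point` (3-vector, nm),
#'   `axis_direction` (unit 3-vector), `radius` (nm), `rms_residual` (nm),
#'   `n_points`, `converged`.
#' @export
fit_cylinder <- function(particles, max_iter = 100) {
  pos <- if (inherits(particles, "particle_set")) positions(particles)
         else as.matrix(particles)
  n <- nrow(pos)
  if (n < 50) stop("cylinder fitting needs at least 50 particles")
  ctr <- colMeans(pos)
  cen <- sweep(pos, 2, ctr)
  ev <- eigen(crossprod(cen) / n, symmetric = TRUE)$vectors
  v0 <- ev[, 1]; u1 <- ev[, 2]; u2 <- ev[, 3]
  span <- diff(range(cen %*% v0))
  r0 <- stats::median(sqrt(rowSums((cen - (cen %*% v0) %*% t(v0))^2)))
  if (span <= 2 * (2 * r0))
    stop(sprintf(paste0("particles span %.0f nm along the long axis; more than ",
                        "2 diameters (%.0f nm) are required for a stable fit"),
                 span, 4 * r0))

  radial_resid <- function(par) {
    p <- ctr + par[1] * u1 + par[2] * u2
    v <- unit(v0 + par[3] * u1 + par[4] * u2)
    rel <- sweep(pos, 2, p)
    ax <- rel %*% v
    rad <- sqrt(rowSums((rel - ax %*% t(v))^2))
    rad - mean(rad)
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0, 0), fn = radial_resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-14, ptol = 1e-14))
  if (!(fit$info %in% 1:4)) {
    stop(sprintf(paste0("cylinder refinement did not converge (%s); ",
                        "initial axis (%.4f, %.4f, %.4f), radius %.2f nm"),
                 fit$message, v0[1], v0[2], v0[3], r0))
  }
  par <- fit$par
  p <- ctr + par[1] * u1 + par[2] * u2
  v <- unit(v0 + par[3] * u1 + par[4] * u2)
  if (v[which.max(abs(v))] < 0) v <- -v
  rel <- sweep(pos, 2, p)
  rad <- sqrt(rowSums((rel - (rel %*% v) %*% t(v))^2))
  structure(list(axis_point = as.numeric(p), axis_direction = as.numeric(v),
                 radius = mean(rad),
                 rms_residual = sqrt(mean((rad - mean(rad))^2)),
                 n_points = n, converged = TRUE),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf(paste0("<cylinder_fit> radius %.2f nm, rms residual %.3f nm, ",
                     "axis (%.4f, %.4f, %.4f), %d points\n"),
              x$radius, x$rms_residual, x$axis_direction[1],
              x$axis_direction[2], x$axis_direction[3], x$n_points))
  invisible(x)
}

#' Angle between tiling direction-1 and the cell axis
#'
#' For every class-1 edge of each cell, projects the edge vector and the
#' axis direction into the local tangent plane and measures the angle
#' between them; the per-cell angle is the circular mean (period 60
#' degrees, the hexagonal symmetry) folded into [0, 30] degrees —
#' or signed in (-30, 30], exposing the lattice chirality, with
#' `signed = TRUE`.
#'
#' @param graph A [build_graph()] result with direction classes assigned.
#' @param fit Optional cylinder fit (or per-cell named list of fits)
#'   giving the axis; defaults to the axis used at assignment time.
#' @param min_edges Cells with fewer class-1 edges are skipped with a
#'   warning.
#' @param signed Logical; report the signed angle.
#' @return A tibble (cell_id, angle_deg, n_edges_used).
#' @export
direction1_angle <- function(graph, fit = NULL, min_edges = 10, signed = FALSE) {
  stopifnot(inherits(graph, "lattice_graph"))
  edges <- graph$edges
  res <- list()
  for (cell in unique(edges$cell_id)) {
    sel <- which(edges$cell_id == cell & !is.na(edges$direction_class) &
                   edges$direction_class == 1L)
    if (length(sel) < min_edges) {
      warning(sprintf("cell %s: only %d class-1 edges (< %d); skipped",
                      cell, length(sel), min_edges))
      next
    }
    phi <- edge_axis_angles(graph, fit, cell, sel)
    theta <- fold_hex_angle_signed(phi)
    m <- rad2deg(Arg(mean(exp(1i * 6 * deg2rad(theta))))) / 6
    if (!signed) m <- abs(m)
    res[[cell]] <- tibble::tibble(cell_id = cell, angle_deg = m,
                                  n_edges_used = length(sel))
  }
  if (!length(res))
    return(tibble::tibble(cell_id = character(), angle_deg = numeric(),
                          n_edges_used = integer()))
  do.call(rbind, res)
}

# Tangent-plane angles (degrees, mod 180) of the given edges to the cell
# axis; recomputed against `fit` when supplied, otherwise the stored
# assignment-time angles are reused.
edge_axis_angles <- function(graph, fit, cell, sel) {
  if (is.null(fit)) return(graph$edges$angle_to_axis[sel])
  ax <- axis_for_cell(graph, fit, cell)
  idx1 <- match(graph$edges$id1[sel], graph$nodes$particle_id)
  idx2 <- match(graph$edges$id2[sel], graph$nodes$particle_id)
  phi <- numeric(length(sel))
  for (k in seq_along(sel)) {
    nv <- graph$normals[idx1[k], ]
    r <- ax - sum(ax * nv) * nv
    if (sqrt(sum(r^2)) < 1e-8) { phi[k] <- NA; next }
    r <- unit(r)
    b <- cross3(nv, r)
    ev <- graph$positions[idx2[k], ] - graph$positions[idx1[k], ]
    ev <- ev - sum(ev * nv) * nv
    phi[k] <- rad2deg(atan2(sum(ev * b), sum(ev * r))) %% 180
  }
  phi
}

#' Aggregate per-cell direction-1 angles into a report
#'
#' @param per_cell Tibble from [direction1_angle()] (one row per cell).
#' @param bins Histogram bin edges (degrees); default 1-degree bins over
#'   [0, 30].
#' @return A list of class `angle_report`: `per_cell`, `mean_angle`
#'   (arithmetic mean over cells), `histogram` (bin edges and counts),
#'   `n_cells`.
#' @export
aggregate_angles <- function(per_cell, bins = seq(0, 30, by = 1)) {
  stopifnot(is.data.frame(per_cell))
  if (nrow(per_cell) < 1) stop("no valid cells to aggregate")
  h <- graphics::hist(abs(per_cell$angle_deg), breaks = bins, plot = FALSE)
  structure(list(per_cell = per_cell,
                 mean_angle = mean(per_cell$angle_deg),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 n_cells = nrow(per_cell)),
            class = "angle_report")
}

#' @export
print.angle_report <- function(x, ...) {
  cat(sprintf("<angle_report> %d cell(s), mean direction-1/axis angle %.2f deg\n",
              x$n_cells, x$mean_angle))
  invisible(x)
}
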