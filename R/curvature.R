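# Per-particle local surface curvature by least-squares quadric fitting,
# and the flat/curved partition used to select particles for symmetry
# relaxation.

#' Fit a local quadric and report principal curvatures
#'
#' Fits the height field
#' \code{z = c0 + c1 x + c2 y + (A x^2 + 2 B x y + C y^2) / 2}
#' to a particle's neighbourhood in its local tangent frame and derives the
#' principal curvatures from the shape operator (second fundamental form
#' corrected for the fitted slope). Curvature is positive where the surface
#' bends away from the outward normal, i.e. towards the cell interior, so a
#' cylinder of radius R seen from outside has k1 = +1/R, k2 = 0 and a
#' sphere of radius r has k1 = k2 = +1/r.
#'
#' @param center Position (3-vector, nm) of the particle.
#' @param neighborhood Matrix (m x 3) of neighbour positions (nm),
#'   excluding the centre.
#' @param outward Optional outward direction hint used to orient the
#'   fitted normal; defaults to the PCA normal's own sign.
#' @return A list (class `curvature_record`): `k1 >= k2` (1/nm),
#'   `mean_curvature`, `normal` (unit 3-vector, outward), `n_neighbors_used`,
#'   `fit_rms` (nm), `valid`.
#' @export
fit_local_quadric <- function(center, neighborhood, outward = NULL) {
  neighborhood <- as.matrix(neighborhood)
  rec <- list(k1 = NA_real_, k2 = NA_real_, mean_curvature = NA_real_,
              normal = c(NA_real_, NA_real_, NA_real_),
              n_neighbors_used = nrow(neighborhood), fit_rms = NA_real_,
              valid = FALSE)
  class(rec) <- "curvature_record"
  if (nrow(neighborhood) < 6) return(rec)
  pts <- rbind(center, neighborhood)
  cen <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) return(rec) # rank < 2
  nrm <- ev$vectors[, 3]
  if (!is.null(outward) && sum(nrm * outward) < 0) nrm <- -nrm
  e1 <- ev$vectors[, 1]; e2 <- cross3(nrm, e1)
  loc <- sweep(pts, 2, center) %*% cbind(e1, e2, nrm)
  X <- cbind(1, loc[, 1], loc[, 2], loc[, 1]^2 / 2, loc[, 1] * loc[, 2],
             loc[, 2]^2 / 2)
  qrX <- qr(X)
  if (qrX$rank < 6) return(rec)
  beta <- qr.coef(qrX, loc[, 3])
  res <- loc[, 3] - X %*% beta
  p <- beta[2]; q <- beta[3]
  A <- beta[4]; B <- beta[5]; C <- beta[6]
  w <- sqrt(1 + p^2 + q^2)
  I1 <- matrix(c(1 + p^2, p * q, p * q, 1 + q^2), 2, 2)
  II <- matrix(c(A, B, B, C), 2, 2) / w
  S <- solve(I1, II)
  # principal curvatures relative to the outward normal: negate because the
  # height axis nrm points outward and the surface curves away from it
  k <- -sort(Re(eigen(S, only.values = TRUE)$values))
  rec$k1 <- max(k); rec$k2 <- min(k)
  rec$mean_curvature <- (rec$k1 + rec$k2) / 2
  rec$normal <- nrm
  rec$fit_rms <- sqrt(mean(res^2))
  rec$valid <- TRUE
  rec
}

#' Estimate local curvature for every particle
#'
#' Applies [fit_local_quadric()] to each particle's neighbourhood within
#' `radius` (default 2.2 unit distances, covering the first and second
#' lattice rings). Normals are sign-aligned to the locally convex side
#' (away from the neighbourhood centroid), the outward direction on a
#' closed tube. Records with fewer than 6 neighbours or a degenerate
#' tangent plane are marked invalid.
#'
#' @param particles A [particle_set()].
#' @param a_est Lattice unit distance (nm); estimated when omitted.
#' @param radius Neighbourhood radius (nm); default `2.2 * a_est`.
#' @return A tibble: particle_id, cell_id, k1, k2, mean_curvature, fit_rms,
#'   n_neighbors_used, valid.
#' @export
estimate_curvature <- function(particles, a_est = NULL, radius = NULL) {
  assert_particle_set(particles)
  if (is.null(a_est) && is.null(radius)) a_est <- estimate_unit_distance(particles)
  radius <- radius %||% (2.2 * a_est)
  pos <- positions(particles)
  n <- nrow(particles)
  out <- tibble::tibble(
    particle_id = particles$particle_id, cell_id = particles$cell_id,
    k1 = NA_real_, k2 = NA_real_, mean_curvature = NA_real_,
    fit_rms = NA_real_, n_neighbors_used = 0L, valid = FALSE)
  for (cell in unique(particles$cell_id)) {
    idx <- which(particles$cell_id == cell)
    cpos <- pos[idx, , drop = FALSE]
    pr <- pairs_within(cpos, radius)
    adj <- pairs_to_adjacency(pr, nrow(cpos))
    for (k in seq_along(idx)) {
      nb <- adj[[k]]
      if (length(nb) < 6) { out$n_neighbors_used[idx[k]] <- length(nb); next }
      # outward hint: away from the neighbourhood centroid (convex side)
      outward <- cpos[k, ] - colMeans(cpos[nb, , drop = FALSE])
      rec <- fit_local_quadric(cpos[k, ], cpos[nb, , drop = FALSE],
                               outward = if (sum(outward^2) > 1e-12) outward else NULL)
      out$k1[idx[k]] <- rec$k1
      out$k2[idx[k]] <- rec$k2
      out$mean_curvature[idx[k]] <- rec$mean_curvature
      out$fit_rms[idx[k]] <- rec$fit_rms
      out$n_neighbors_used[idx[k]] <- rec$n_neighbors_used
      out$valid[idx[k]] <- rec$valid
    }
  }
  out
}

#' Partition particles into flat and curved subsets
#'
#' A particle is `curved` when the absolute mean curvature of its valid
#' record reaches the threshold; otherwise `flat`. Invalid records are
#' excluded from the partition and counted separately. The default
#' threshold, half the mean curvature of the fitted cylinder
#' (`0.5 / (2 * R)`), separates the flattened top/bottom of a
#' vitrification-compressed cell from its tightly curved flanks.
#'
#' @param records Output of [estimate_curvature()].
#' @param threshold Curvature threshold (1/nm).
#' @return A list (class `curvature_partition`): `assignment` tibble
#'   (particle_id, class), counts `n_flat`, `n_curved`, `n_invalid`, and
#'   the `threshold`.
#' @export
classify_particles <- function(records, threshold) {
  stopifnot(is.data.frame(records), threshold >= 0)
  valid <- records$valid & is.finite(records$mean_curvature)
  cls <- rep(NA_character_, nrow(records))
  cls[valid] <- ifelse(abs(records$mean_curvature[valid]) >= threshold,
                       "curved", "flat")
  structure(list(
    assignment = tibble::tibble(particle_id = records$particle_id, class = cls),
    n_flat = sum(cls == "flat", na.rm = TRUE),
    n_curved = sum(cls == "curved", na.rm = TRUE),
    n_invalid = sum(!valid),
    threshold = threshold
  ), class = "curvature_partition")
}

#' Default curvature threshold from a cylinder fit
#' @param fit A [fit_cylinder()] result.
#' @return `0.5 * 1 / (2 * radius)` (1/nm).
#' @export
curvature_threshold <- function(fit) {
  stopifnot(inherits(fit, "cylinder_fit"))
  0.5 / (2 * fit$radius)
}

#' Export the flat or curved particle subset
#'
#' Returns the sub-`particle_set` of one partition class, with poses and
#' grouping preserved — STAR-writable as input for symmetry-relaxed
#' subtomogram averaging in external software.
#'
#' @param particles A [particle_set()].
#' @param partition A [classify_particles()] result.
#' @param which `"curved"` or `"flat"`.
#' @return A `particle_set` subset.
#' @export
export_subset <- function(particles, partition, which = c("curved", "flat")) {
  assert_particle_set(particles)
  stopifnot(inherits(partition, "curvature_partition"))
  which <- match.arg(which)
  ids <- partition$assignment$particle_id[
    !is.na(partition$assignment$class) & partition$assignment$class == which]
  out <- particles[particles$particle_id %in% ids, ]
  class(out) <- c("particle_set", setdiff(class(out), "particle_set"))
  attr(out, "lattice_spec") <- attr(particles, "lattice_spec")
  if (nrow(out) == 0)
    warning(sprintf("'%s' subset is empty", which))
  out
}
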