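#' Particle pose tables
#'
#' A `particle_set` is a tibble with one row per subtomogram particle,
#' carrying a 3D position (nm), an intrinsic-ZYZ Euler orientation (degrees,
#' RELION convention: rot, tilt, psi) and a cell/tomogram grouping label.
#' Optional `truth_*` columns carry ground-truth annotations from the
#' synthetic generator (lattice indices, seam membership, local curvature,
#' vacancy neighbourhood) and survive STAR round-trips via a sidecar table.
#'
#' @param particle_id Integer vector, unique within the set.
#' @param cell_id Character vector naming the cell/tomogram of each particle.
#' @param position Numeric n x 3 matrix of positions in nm.
#' @param euler Numeric n x 3 matrix of (rot, tilt, psi) in degrees.
#' @param truth Optional data frame of `truth_*` columns (prefix added if
#'   missing), one row per particle.
#' @return A tibble of class `particle_set` with columns `particle_id`,
#'   `cell_id`, `x`, `y`, `z`, `rot`, `tilt`, `psi` and any truth columns.
#' @export
particle_set <- function(particle_id, cell_id, position, euler, truth = NULL) {
  position <- as.matrix(position)
  euler <- as.matrix(euler)
  n <- length(particle_id)
  stopifnot(nrow(position) == n, ncol(position) == 3,
            nrow(euler) == n, ncol(euler) == 3,
            length(cell_id) == n)
  particle_id <- as.integer(particle_id)
  if (anyDuplicated(particle_id)) stop("particle_id values must be unique")
  if (n > 0 && !all(is.finite(position))) stop("particle positions must be finite")
  out <- tibble::tibble(
    particle_id = particle_id,
    cell_id = as.character(cell_id),
    x = position[, 1], y = position[, 2], z = position[, 3],
    rot = wrap180(euler[, 1]),
    tilt = euler[, 2],
    psi = wrap180(euler[, 3])
  )
  if (n > 0 && (any(out$tilt < 0) || any(out$tilt > 180)))
    stop("tilt angles must lie in [0, 180] degrees")
  if (!is.null(truth)) {
    truth <- tibble::as_tibble(truth)
    stopifnot(nrow(truth) == n)
    names(truth) <- ifelse(startsWith(names(truth), "truth_"),
                           names(truth), paste0("truth_", names(truth)))
    out <- tibble::as_tibble(cbind(out, truth))
  }
  class(out) <- c("particle_set", class(out))
  out
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles in %d cell(s)\n",
              nrow(x), length(unique(x$cell_id))))
  NextMethod()
}

#' Extract particle positions as a matrix
#' @param particles A `particle_set`.
#' @return An n x 3 numeric matrix (nm).
#' @export
positions <- function(particles) {
  as.matrix(particles[, c("x", "y", "z")])
}

#' Extract particle normals encoded in the Euler orientations
#'
#' The particle normal is the third column of the ZYZ rotation matrix,
#' i.e. the direction \code{(cos(rot) sin(tilt), sin(rot) sin(tilt),
#' cos(tilt))}.
#'
#' @param particles A `particle_set`.
#' @return An n x 3 matrix of unit vectors.
#' @export
pose_normals <- function(particles) {
  r <- deg2rad(particles$rot)
  t <- deg2rad(particles$tilt)
  cbind(cos(r) * sin(t), sin(r) * sin(t), cos(t))
}

# In-plane direction-1 vector of each particle (first frame column).
pose_inplane <- function(particles) {
  t(vapply(seq_len(nrow(particles)), function(i) {
    rotmat_from_euler(particles$rot[i], particles$tilt[i], particles$psi[i])[, 1]
  }, numeric(3)))
}

assert_particle_set <- function(particles) {
  if (!inherits(particles, "particle_set"))
    stop("expected a particle_set (see particle_set(), generate_cylinder_lattice(), read_particles())")
  invisible(particles)
}
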