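# Internal geometry and angle utilities shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Wrap angles (degrees) into [-180, 180).
wrap180 <- function(x) ((x + 180) %% 360) - 180

# Fold an angle (degrees) into [0, 30] using the 60-degree symmetry of the
# hexagonal tiling: directions are only defined modulo 60 degrees, and an
# undirected axis at +x is the same as one at -x.
fold_hex_angle <- function(x) {
  m <- x %% 60
  pmin(m, 60 - m)
}

# Signed fold into (-30, 30]: the angle modulo 60 degrees, centred on zero.
fold_hex_angle_signed <- function(x) {
  m <- x %% 60
  ifelse(m > 30, m - 60, m)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from intrinsic ZYZ Euler angles
#'
#' Builds the rotation matrix \code{Rz(rot) Ry(tilt) Rz(psi)} from Euler
#' angles in degrees, following the RELION intrinsic ZYZ convention. The
#' columns of the returned matrix are the particle frame axes expressed in
#' lab coordinates; the third column is the particle's normal direction and
#' the first column its in-plane reference (tiling direction-1 for lattice
#' particles).
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotmat_from_euler <- function(rot, tilt, psi) {
  a <- deg2rad(rot); b <- deg2rad(tilt); g <- deg2rad(psi)
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(
    ca * cb * cg - sa * sg,  -ca * cb * sg - sa * cg,  ca * sb,
    sa * cb * cg + ca * sg,  -sa * cb * sg + ca * cg,  sa * sb,
    -sb * cg,                 sb * sg,                  cb
  ), nrow = 3, byrow = TRUE)
}

#' Intrinsic ZYZ Euler angles from a rotation matrix
#'
#' Inverse of [rotmat_from_euler()]. Angles are returned in canonical ranges:
#' rot and psi in [-180, 180), tilt in [0, 180].
#'
#' @param M A 3x3 rotation matrix.
#' @return Named numeric vector \code{c(rot, tilt, psi)} in degrees.
#' @export
euler_from_rotmat <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  ct <- clamp(M[3, 3], -1, 1)
  tilt <- rad2deg(acos(ct))
  if (abs(ct) < 1 - 1e-12) {
    rot <- rad2deg(atan2(M[2, 3], M[1, 3]))
    psi <- rad2deg(atan2(M[3, 2], -M[3, 1]))
  } else if (ct > 0) {
    # tilt ~ 0: only rot + psi is defined; put it all in rot
    rot <- rad2deg(atan2(M[2, 1], M[1, 1]))
    psi <- 0
  } else {
    # tilt ~ 180: only rot - psi is defined
    rot <- rad2deg(atan2(-M[2, 1], -M[1, 1]))
    psi <- 0
  }
  c(rot = wrap180(rot), tilt = tilt, psi = wrap180(psi))
}

# Vectorised frame -> Euler conversion. `normals` and `inplane` are n x 3
# matrices; inplane is re-orthogonalised against the normal. Returns an
# n x 3 matrix of (rot, tilt, psi) in degrees.
eulers_from_frames <- function(normals, inplane) {
  n <- nrow(normals)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("rot", "tilt", "psi")))
  for (i in seq_len(n)) {
    z <- unit(normals[i, ])
    x <- inplane[i, ] - sum(inplane[i, ] * z) * z
    x <- unit(x)
    y <- cross3(z, x)
    out[i, ] <- euler_from_rotmat(cbind(x, y, z))
  }
  out
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
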