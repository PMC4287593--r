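# Rigid-body transform algebra.  A transform acts on column points as
# p' = R %*% p + t; composition is therefore matrix-product order:
# rt_compose(T1, T2) applies T2 first.

#' Construct a rigid transform
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) together with a translation in Angstroms. Transforms act
#' on column points as `p' = R p + t`.
#'
#' @param rotation 3x3 orthonormal matrix, determinant +1.
#' @param translation numeric length-3 translation (Angstrom).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
#' @examples
#' rt_new(diag(3), c(1, 0, 0))
rt_new <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  out <- structure(list(R = rotation, t = translation), class = "rigid_transform")
  rt_validate(out)
  out
}

rt_validate <- function(T, tol = 1e-9) {
  if (!is.matrix(T$R) || !identical(dim(T$R), c(3L, 3L)) || !all(is.finite(T$R)))
    stop("invalid transform: rotation must be a finite 3x3 matrix", call. = FALSE)
  if (length(T$t) != 3L || !all(is.finite(T$t)))
    stop("invalid transform: translation must be a finite 3-vector", call. = FALSE)
  if (max(abs(crossprod(T$R) - diag(3))) > tol)
    stop("invalid transform: rotation is not orthonormal", call. = FALSE)
  if (abs(det(T$R) - 1) > tol)
    stop("invalid transform: rotation determinant is not +1", call. = FALSE)
  invisible(T)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid transform>\n")
  cat("rotation:\n")
  print(round(x$R, 6))
  cat("translation:", paste(signif(x$t, 7), collapse = " "), "\n")
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rt_new(diag(3), c(0, 0, 0))

#' Pure translation
#' @param x,y,z translation components (Angstrom); `x` may also be a 3-vector.
#' @return A `rigid_transform`.
#' @export
rt_translation <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  rt_new(diag(3), v)
}

#' Rotation about an axis through a point
#'
#' @param axis direction of the rotation axis (any nonzero length).
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @param point a point on the axis; default the origin.
#' @return A `rigid_transform`.
#' @export
rt_rotation <- function(axis, angle, point = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("rotation axis must be nonzero", call. = FALSE)
  R <- axis_angle_matrix(axis / nrm, angle)
  point <- as.numeric(point)
  rt_new(R, point - R %*% point)
}

# Rodrigues' formula
axis_angle_matrix <- function(a, angle) {
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `rt_compose(T1, T2)` applies `T2` first and then `T1`:
#' `rt_apply(rt_compose(T1, T2), p)` equals `rt_apply(T1, rt_apply(T2, p))`.
#'
#' @param T1,T2 `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(T1, T2) {
  rt_validate(T1); rt_validate(T2)
  rt_new(T1$R %*% T2$R, as.numeric(T1$R %*% T2$t) + T1$t)
}

#' Invert a rigid transform
#' @param T a `rigid_transform`.
#' @return The inverse transform: `rt_compose(T, rt_invert(T))` is the identity.
#' @export
rt_invert <- function(T) {
  rt_validate(T)
  Rt <- t(T$R)
  rt_new(Rt, as.numeric(-Rt %*% T$t))
}

#' Relative transform between two poses
#'
#' Returns the transform `T_AB` such that `rt_compose(TA, T_AB) == TB`,
#' i.e. the pose of B expressed in A's local frame. This is the quantity a
#' placed example pair of monomers defines for chain replication.
#'
#' @param TA,TB `rigid_transform` poses in world coordinates.
#' @return A `rigid_transform`.
#' @export
rt_relative <- function(TA, TB) {
  rt_compose(rt_invert(TA), TB)
}

#' Integer power of a rigid transform
#'
#' @param T a `rigid_transform`.
#' @param k non-negative integer; `rt_power(T, 0)` is the identity.
#' @return The k-fold composition of `T` with itself.
#' @export
rt_power <- function(T, k) {
  if (length(k) != 1L || is.na(k) || k < 0 || k != round(k))
    stop("k must be a non-negative integer", call. = FALSE)
  rt_validate(T)
  out <- rt_identity()
  base <- T
  k <- as.integer(k)
  # binary exponentiation keeps round-off growth logarithmic in k
  while (k > 0L) {
    if (k %% 2L == 1L) out <- rt_compose(out, base)
    k <- k %/% 2L
    if (k > 0L) base <- rt_compose(base, base)
  }
  out
}

#' Apply a rigid transform to points
#' @param T a `rigid_transform`.
#' @param points numeric 3-vector or n x 3 matrix of points.
#' @return Transformed points in the same shape.
#' @export
rt_apply <- function(T, points) {
  if (is.null(dim(points))) {
    as.numeric(T$R %*% as.numeric(points)) + T$t
  } else {
    sweep(points %*% t(T$R), 2, T$t, "+")
  }
}

#' Convert to / from a 4x4 homogeneous matrix
#' @param T a `rigid_transform`.
#' @return `rt_to_matrix`: a 4x4 matrix; `rt_from_matrix`: a `rigid_transform`.
#' @export
rt_to_matrix <- function(T) {
  M <- diag(4)
  M[1:3, 1:3] <- T$R
  M[1:3, 4] <- T$t
  M
}

#' @rdname rt_to_matrix
#' @param M a 4x4 homogeneous matrix with last row (0,0,0,1).
#' @export
rt_from_matrix <- function(M) {
  M <- as.matrix(M)
  if (!identical(dim(M), c(4L, 4L)) || max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("not a rigid homogeneous matrix", call. = FALSE)
  rt_new(M[1:3, 1:3], M[1:3, 4])
}

# max entrywise difference between two transforms, used throughout the tests
rt_distance <- function(T1, T2) {
  max(max(abs(T1$R - T2$R)), max(abs(T1$t - T2$t)))
}

#' Screw-axis decomposition of a rigid transform
#'
#' Every rigid motion is a rotation about an axis combined with a
#' translation along that axis (a screw motion). For a helical repeat this
#' returns the familiar twist (angle per subunit) and rise (translation per
#' subunit along the helix axis).
#'
#' @param T a `rigid_transform`.
#' @return A list of class `screw_parameters` with `axis_direction` (unit
#'   3-vector), `axis_point` (a point on the axis, Angstrom), `angle`
#'   (radians, in (-pi, pi]) and `rise` (signed Angstrom along the axis).
#' @export
#' @examples
#' screw_decompose(rt_rotation(c(0, 0, 1), pi / 2))
screw_decompose <- function(T) {
  rt_validate(T)
  R <- T$R; tr <- T$t
  cos_theta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(cos_theta)

  if (theta < 1e-9) {
    # pure translation (or identity): axis along the translation, through origin
    nrm <- sqrt(sum(tr^2))
    a <- if (nrm > 0) tr / nrm else c(0, 0, 1)
    return(new_screw(a, c(0, 0, 0), 0, nrm))
  }

  if (pi - theta < 1e-7) {
    # angle pi: R + I has rank 1 with columns parallel to the axis
    M <- R + diag(3)
    cn <- sqrt(colSums(M^2))
    a <- M[, which.max(cn)]
    a <- a / sqrt(sum(a^2))
    # sign convention: first nonzero component positive
    nz <- which(abs(a) > 1e-9)[1]
    if (a[nz] < 0) a <- -a
    theta <- pi
  } else {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    a <- v / (2 * sin(theta))
    a <- a / sqrt(sum(a^2))
  }

  rise <- sum(a * tr)
  t_perp <- tr - rise * a
  # point on the axis: solve (I - R) p = t_perp in the plane normal to a
  half <- theta / 2
  p <- 0.5 * (t_perp + pracma_cross(a, t_perp) / tan(half))
  new_screw(a, p, theta, rise)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_screw <- function(axis_direction, axis_point, angle, rise) {
  structure(list(axis_direction = as.numeric(axis_direction),
                 axis_point = as.numeric(axis_point),
                 angle = as.numeric(angle),
                 rise = as.numeric(rise)),
            class = "screw_parameters")
}

#' @export
print.screw_parameters <- function(x, ...) {
  cat(sprintf("<screw> twist %.4f rad (%.2f deg), rise %.4f A\n",
              x$angle, x$angle * 180 / pi, x$rise))
  cat("axis direction:", paste(signif(x$axis_direction, 6), collapse = " "), "\n")
  cat("axis point:    ", paste(signif(x$axis_point, 6), collapse = " "), "\n")
  invisible(x)
}

#' Rebuild a rigid transform from screw parameters
#'
#' Inverse of [screw_decompose()]: rotation by `angle` about the axis through
#' `axis_point` along `axis_direction`, plus a translation of `rise` along
#' the axis.
#'
#' @param params a `screw_parameters` object (or list with the same fields).
#' @return A `rigid_transform`.
#' @export
screw_transform <- function(params) {
  a <- as.numeric(params$axis_direction)
  a <- a / sqrt(sum(a^2))
  Trot <- rt_rotation(a, params$angle, params$axis_point)
  rt_new(Trot$R, Trot$t + params$rise * a)
}

#' Project points onto a ground plane along a light direction
#'
#' Models a light infinitely far away along `up`: each point drops to the
#' plane `{p : sum(p * up) == ground_height}`, with components orthogonal to
#' `up` unchanged. This is the drop-shadow used as a depth cue.
#'
#' @param points 3-vector or n x 3 matrix.
#' @param ground_height plane offset along `up` (Angstrom).
#' @param up unit direction of the light / plane normal.
#' @return Projected points in the same shape as `points`.
#' @export
project_to_ground <- function(points, ground_height = 0, up = c(0, 1, 0)) {
  up <- as.numeric(up)
  nrm <- sqrt(sum(up^2))
  if (nrm == 0) stop("up direction must be nonzero", call. = FALSE)
  if (abs(nrm - 1) > 1e-9) stop("up direction must be unit length", call. = FALSE)
  proj1 <- function(p) p + (ground_height - sum(p * up)) * up
  if (is.null(dim(points))) {
    proj1(as.numeric(points))
  } else {
    h <- points %*% up
    points + outer(as.numeric(ground_height - h), up)
  }
}
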