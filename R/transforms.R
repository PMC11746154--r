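#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation plus a translation, applied as
#' `x' = R x + t`.  Transforms compose with [rt_compose()] (or `%o%`) and
#' invert with [rt_inverse()]; the rotation angle/axis is recovered with
#' [rotation_angle()].
#'
#' @param rotation 3x3 proper rotation matrix (`det = +1`, orthonormal).
#' @param translation length-3 numeric translation, in Angstrom.
#' @return An object of class `rigid_xform`.
#' @examples
#' t1 <- rt_rotation_z(90) %o% rt_translation(c(1, 0, 0))
#' rotation_angle(t1)$angle
#' @export
rigid_xform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1); got det = ", det(rotation))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation columns must be orthonormal")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_xform")
}

#' @rdname rigid_xform
#' @export
rt_identity <- function() rigid_xform()

#' @param axis length-3 axis (need not be unit length).
#' @param angle rotation angle in degrees.
#' @param center point the rotation axis passes through (default origin).
#' @rdname rigid_xform
#' @export
rt_rotation <- function(axis, angle, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  rigid_xform(R, as.numeric(center - R %*% center))
}

#' @rdname rigid_xform
#' @export
rt_rotation_z <- function(angle) rt_rotation(c(0, 0, 1), angle)

#' @param v length-3 translation vector.
#' @rdname rigid_xform
#' @export
rt_translation <- function(v) rigid_xform(diag(3), v)

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform that applies `b` first, then `a`
#' (function composition `a` after `b`).
#'
#' @param a,b `rigid_xform` objects.
#' @return A `rigid_xform`.
#' @export
rt_compose <- function(a, b) {
  rigid_xform(a$rotation %*% b$rotation,
              as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rt_compose
#' @export
`%o%` <- function(a, b) rt_compose(a, b)

#' @param t a `rigid_xform`.
#' @rdname rt_compose
#' @export
rt_inverse <- function(t) {
  Rt <- t(t$rotation)
  rigid_xform(Rt, as.numeric(-Rt %*% t$translation))
}

#' Apply a rigid transform to coordinates
#'
#' @param t a `rigid_xform`.
#' @param xyz numeric n x 3 matrix (or length-3 vector) of coordinates.
#' @return Transformed coordinates, same shape as input.
#' @export
rt_apply <- function(t, xyz) {
  if (is.null(dim(xyz))) return(as.numeric(t$rotation %*% xyz + t$translation))
  sweep(xyz %*% t(t$rotation), 2, t$translation, `+`)
}

#' Rotation angle and axis of a rigid transform
#'
#' The angle is extracted from the trace of the rotation matrix and folded
#' to `[0, 180]` degrees; the axis is the unit eigenvector of the rotation
#' (undefined for the identity, returned as `c(0, 0, 1)` by convention).
#'
#' @param t a `rigid_xform`.
#' @return List with `angle` (degrees) and `axis` (unit 3-vector).
#' @export
rotation_angle <- function(t) {
  R <- t$rotation
  cs <- (sum(diag(R)) - 1) / 2
  angle <- acos(max(-1, min(1, cs))) * 180 / pi
  if (angle < 1e-9) return(list(angle = 0, axis = c(0, 0, 1)))
  if (angle > 180 - 1e-7) {
    # R ~ symmetric: axis from largest diagonal of (R + I)/2
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    k <- which.max(ax)
    if (ax[k] > 0) {
      ax <- B[, k] / ax[k]
    }
  } else {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle * pi / 180))
  }
  list(angle = angle, axis = ax / sqrt(sum(ax^2)))
}

#' @export
print.rigid_xform <- function(x, ...) {
  ra <- rotation_angle(x)
  cat(sprintf("rigid transform: rotation %.2f deg about [%s], translation [%s] A\n",
              ra$angle, paste(sprintf("%.3f", ra$axis), collapse = ", "),
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  invisible(x)
}

# fold an angle in degrees to [0, 180]
fold180 <- function(a) {
  a <- a %% 360
  ifelse(a > 180, 360 - a, a)
}
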