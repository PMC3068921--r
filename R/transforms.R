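#' Build a 2x2 visuomotor transformation matrix
#'
#' A visuomotor transformation maps the hand position `h` to the displayed
#' cursor position `v = T h` about an origin (by default the centre of the
#' start circle). Coordinates are in centimetres, x rightward and y forward
#' (away from the chest).
#'
#' @param a,b,c,d Matrix elements: `v_x = a h_x + b h_y`,
#'   `v_y = c h_x + d h_y`.
#' @return A 2x2 numeric matrix.
#' @examples
#' transform_matrix(1, 0, 0, 1)       # identity (veridical feedback)
#' rotation_scaling_matrix(pi / 6)    # 30 degree rotation
#' @export
transform_matrix <- function(a, b, c, d) {
  matrix(c(a, b, c, d), nrow = 2, ncol = 2, byrow = TRUE)
}

#' Vectorize / unvectorize a transformation matrix
#'
#' The vectorization order is row-major `(a, b, c, d)`; all pairwise
#' statistics in the package are symmetric in the pair so only internal
#' consistency matters.
#'
#' @param T A 2x2 transformation matrix.
#' @return `vec_transform` returns a length-4 numeric vector;
#'   `unvec_transform` its inverse.
#' @export
vec_transform <- function(T) {
  stopifnot(is.matrix(T), all(dim(T) == 2L))
  c(T[1, 1], T[1, 2], T[2, 1], T[2, 2])
}

#' @rdname vec_transform
#' @param t Length-4 numeric vector in order `(a, b, c, d)`.
#' @export
unvec_transform <- function(t) {
  stopifnot(length(t) == 4L)
  transform_matrix(t[1], t[2], t[3], t[4])
}

#' Apply a transformation to a hand position
#'
#' Returns `origin + T (h - origin)`. The default origin is the start-circle
#' centre `(0, 0)`, the coordinate frame in which all transformations are
#' defined unless an alternative origin is being probed (see
#' [origin_sweep()]).
#'
#' @param T 2x2 transformation matrix.
#' @param h Length-2 hand position (cm).
#' @param origin Length-2 origin of the transformation (cm).
#' @return Length-2 cursor position (cm).
#' @export
apply_transform <- function(T, h, origin = c(0, 0)) {
  drop(T %*% (h - origin)) + origin
}

#' Invert a transformation
#'
#' @param T 2x2 transformation matrix with `|det(T)| > 1e-10`.
#' @return The inverse 2x2 matrix.
#' @export
invert_transform <- function(T) {
  dt <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  if (abs(dt) <= 1e-10) {
    stop("singular transformation: |det| = ", format(abs(dt)), " <= 1e-10")
  }
  matrix(c(T[2, 2], -T[1, 2], -T[2, 1], T[1, 1]), 2, 2, byrow = TRUE) / dt
}

#' Observation design matrix for a hand position
#'
#' Returns the 2x4 matrix `A(h)` such that `A(h) %*% vec_transform(T)`
#' equals `T %*% h` for every transformation `T`. This expresses the cursor
#' observation as a linear function of the vectorized transformation, which
#' is what makes the Gaussian belief update conjugate.
#'
#' @param h Length-2 hand position (cm).
#' @return A 2x4 numeric matrix.
#' @export
design_matrix <- function(h) {
  matrix(c(h[1], h[2], 0, 0,
           0, 0, h[1], h[2]), nrow = 2, byrow = TRUE)
}

#' Rotation-and-scaling transformation
#'
#' A rotation by `theta` (counter-clockwise positive, measured from the +x
#' axis) combined with a uniform scaling by `gain`. Such matrices satisfy
#' `a = d` and `b = -c`, the structure that a prior favouring rotations
#' concentrates on.
#'
#' @param theta Rotation angle in radians.
#' @param gain Positive uniform scaling factor.
#' @return A 2x2 transformation matrix.
#' @export
rotation_scaling_matrix <- function(theta, gain = 1) {
  stopifnot(gain > 0)
  gain * matrix(c(cos(theta), -sin(theta),
                  sin(theta),  cos(theta)), 2, 2, byrow = TRUE)
}
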