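# Rigid transforms in 2D (in-plane section motion) and 3D (stack-to-reference).
#
# Conventions used throughout the package: a 2D point is (x, y) with
# x = (col - 1) * spacing_x and y = (row - 1) * spacing_y in millimetres;
# angles are in degrees, measured counterclockwise in the (x, y) plane.

#' In-plane rigid transform
#'
#' A rotation about `center_mm` followed by a translation. Used both for the
#' perturbations applied during simulated sectioning and for the per-section
#' corrections recovered by the alignment fit.
#'
#' @param rotation_deg Rotation angle in degrees, counterclockwise.
#' @param translation_mm Numeric length-2 translation (x, y) in mm.
#' @param center_mm Numeric length-2 center of rotation (x, y) in mm.
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(rotation_deg = 0, translation_mm = c(0, 0),
                    center_mm = c(0, 0)) {
  stopifnot(is.numeric(rotation_deg), length(rotation_deg) == 1L,
            is.numeric(translation_mm), length(translation_mm) == 2L,
            is.numeric(center_mm), length(center_mm) == 2L)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid2d")
}

rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a 2D rigid transform to points
#'
#' @param transform A [rigid2d()] object.
#' @param points An n x 2 matrix of (x, y) coordinates in mm (a length-2
#'   vector is treated as a single point).
#' @return An n x 2 matrix of transformed coordinates.
#' @export
rigid2d_apply <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  R <- rot2(transform$rotation_deg)
  ctr <- transform$center_mm
  out <- sweep(points, 2, ctr) %*% t(R)
  sweep(out, 2, ctr + transform$translation_mm, `+`)
}

# Reduce to canonical form: rotation about the origin plus translation.
rigid2d_canonical <- function(transform) {
  R <- rot2(transform$rotation_deg)
  ctr <- transform$center_mm
  t0 <- ctr + transform$translation_mm - R %*% ctr
  list(R = R, t = as.numeric(t0), deg = transform$rotation_deg)
}

#' Compose two 2D rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#'
#' @param a,b [rigid2d()] objects.
#' @return A [rigid2d()] object with center at the origin.
#' @export
rigid2d_compose <- function(a, b) {
  ca <- rigid2d_canonical(a)
  cb <- rigid2d_canonical(b)
  deg <- ca$deg + cb$deg
  t0 <- as.numeric(ca$R %*% cb$t) + ca$t
  rigid2d(wrap_angle(deg, 360), t0, c(0, 0))
}

#' Invert a 2D rigid transform
#'
#' @param transform A [rigid2d()] object.
#' @return The inverse transform, with center at the origin.
#' @export
rigid2d_invert <- function(transform) {
  cc <- rigid2d_canonical(transform)
  Rinv <- t(cc$R)
  rigid2d(-cc$deg, as.numeric(-Rinv %*% cc$t), c(0, 0))
}

# Wrap an angle into (-period/2, period/2].
wrap_angle <- function(deg, period = 360) {
  w <- deg - period * round(deg / period)
  ifelse(w <= -period / 2, w + period, w)
}

#' Rigid transform in 3D
#'
#' A proper rotation (orthonormal, determinant +1) plus a translation,
#' mapping stack coordinates into reference-volume coordinates.
#'
#' @param rotation A 3 x 3 proper rotation matrix.
#' @param translation_mm Numeric length-3 translation in mm.
#' @return An object of class `rigid3d`.
#' @export
rigid3d <- function(rotation = diag(3), translation_mm = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            is.numeric(translation_mm), length(translation_mm) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation matrix is a reflection (determinant < 0)")
  structure(list(rotation = rotation,
                 translation_mm = as.numeric(translation_mm)),
            class = "rigid3d")
}

#' Apply a 3D rigid transform to points
#'
#' @param transform A [rigid3d()] object.
#' @param points An n x 3 matrix of coordinates in mm.
#' @return An n x 3 matrix of transformed coordinates.
#' @export
rigid3d_apply <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points %*% t(transform$rotation), 2, transform$translation_mm, `+`)
}

#' Homogeneous 4 x 4 matrix of a 3D rigid transform
#'
#' @param transform A [rigid3d()] object.
#' @return A 4 x 4 matrix.
#' @export
rigid3d_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation_mm
  m
}
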