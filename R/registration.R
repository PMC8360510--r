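# Rigid 3D landmark registration of the assembled stack to the tomographic
# reference volume. The cannulas (sampled along their fitted lines) and the
# grooves serve as matched landmarks; the closed-form least-squares fit is
# the SVD solution of the cross-covariance between the centered point sets,
# sign-corrected so that a proper rotation (never a reflection) is
# returned.

#' Closed-form rigid landmark registration
#'
#' Finds the proper rigid transform minimizing the sum of squared distances
#' `sum ||R m_i + t - f_i||^2` between matched landmark sets, and reports
#' the fiducial registration error (FRE), the RMS of the post-transform
#' distances.
#'
#' @param moving n x 3 matrix of moving landmarks (n >= 3, not collinear).
#' @param fixed n x 3 matrix of the matched fixed landmarks.
#' @return List with `transform` (a [rigid3d()]) and `fre_mm`.
#' @export
register_landmarks <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("landmark sets differ in size: ", nrow(moving), " vs ",
         nrow(fixed))
  if (nrow(moving) < 3)
    stop("need at least three landmark pairs")
  mm <- colMeans(moving)
  mf <- colMeans(fixed)
  cm <- sweep(moving, 2, mm)
  cf <- sweep(fixed, 2, mf)
  check_not_collinear(cm, "moving")
  check_not_collinear(cf, "fixed")
  H <- crossprod(cm, cf)   # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t0 <- mf - as.numeric(R %*% mm)
  tf <- rigid3d(R, t0)
  resid <- rigid3d_apply(tf, moving) - fixed
  list(transform = tf, fre_mm = sqrt(mean(rowSums(resid^2))))
}

check_not_collinear <- function(centered, what) {
  sv <- svd(centered, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop("collinear ", what,
         " landmarks: rotation about the line is unidentifiable")
  invisible(TRUE)
}

#' Extract 3D landmarks from an aligned stack
#'
#' Samples each fitted fiducial line at the first, middle and last section
#' plane (nine points for three cannulas), optionally appending groove
#' landmarks.
#'
#' @param aligned An `aligned_stack` with fitted lines.
#' @param z_samples z positions to sample; defaults to first, middle and
#'   last section z.
#' @param groove_points_mm Optional k x 3 matrix of groove landmark
#'   positions to append.
#' @return An m x 3 matrix of landmark coordinates (mm), row names
#'   identifying each landmark.
#' @export
extract_stack_landmarks <- function(aligned, z_samples = NULL,
                                    groove_points_mm = NULL) {
  if (is.null(aligned$lines) || length(aligned$lines) == 0)
    stop("aligned stack has no fitted fiducial lines")
  if (is.null(z_samples)) {
    z <- aligned$z_mm
    z_samples <- c(min(z), z[which.min(abs(z - stats::median(z)))], max(z))
  }
  pts <- do.call(rbind, lapply(names(aligned$lines), function(nm) {
    xy <- line_at_z(aligned$lines[[nm]], z_samples)
    out <- cbind(xy, z_samples)
    rownames(out) <- paste0(nm, "_z", signif(z_samples, 6))
    out
  }))
  if (!is.null(groove_points_mm)) {
    gp <- as.matrix(groove_points_mm)
    rownames(gp) <- paste0("groove", seq_len(nrow(gp)))
    pts <- rbind(pts, gp)
  }
  colnames(pts) <- c("x_mm", "y_mm", "z_mm")
  pts
}

#' Ground-truth fiducial landmarks of a phantom
#'
#' Samples the phantom's true needle lines at the given z positions; used as
#' the reference-side landmark set when validating the registration against
#' the tomography surrogate.
#'
#' @param phantom An [build_phantom()] result (or its `truth` element).
#' @param z_samples z positions to sample.
#' @return An m x 3 matrix of landmark coordinates (mm).
#' @export
reference_landmarks <- function(phantom, z_samples) {
  truth <- if (inherits(phantom, "et_phantom")) phantom$truth else phantom
  pts <- do.call(rbind, lapply(seq_along(truth$fiducials), function(i) {
    fid <- truth$fiducials[[i]]
    xy <- t(vapply(z_samples, function(z) fiducial_at_z(fid, z),
                   numeric(2)))
    out <- cbind(xy, z_samples)
    rownames(out) <- paste0("fid", i, "_z", signif(z_samples, 6))
    out
  }))
  colnames(pts) <- c("x_mm", "y_mm", "z_mm")
  pts
}

#' Register an aligned stack to a reference via its fiducial lines
#'
#' The track ids assigned during correspondence are arbitrary, so the
#' identity of each cannula relative to the reference volume is itself
#' unknown. This samples both line sets at the same z positions, tries
#' every permutation of the three line identities and keeps the rigid
#' registration with the smallest FRE.
#'
#' @param aligned An `aligned_stack` with fitted lines.
#' @param reference An `et_phantom` (or its `truth`) providing the true
#'   needle lines.
#' @param z_samples z positions to sample; defaults to first, middle and
#'   last section z.
#' @return As [register_landmarks()], plus `permutation` (the line
#'   identity mapping used).
#' @export
register_to_reference <- function(aligned, reference, z_samples = NULL) {
  if (is.null(z_samples)) {
    z <- aligned$z_mm
    z_samples <- c(min(z), z[which.min(abs(z - stats::median(z)))], max(z))
  }
  moving <- extract_stack_landmarks(aligned, z_samples)
  fixed <- reference_landmarks(reference, z_samples)
  nlines <- length(aligned$lines)
  k <- length(z_samples)
  perms <- all_injections(nlines, nlines)
  best <- NULL
  for (p in perms) {
    ord <- unlist(lapply(p, function(j) (j - 1) * k + seq_len(k)))
    reg <- register_landmarks(moving, fixed[ord, , drop = FALSE])
    if (is.null(best) || reg$fre_mm < best$fre_mm) {
      best <- reg
      best$permutation <- p
    }
  }
  best
}

#' Write a 3D rigid transform as a JSON sidecar
#'
#' Stores the homogeneous 4 x 4 matrix together with the FRE.
#'
#' @param registration Result of [register_landmarks()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(registration, path) {
  jsonlite::write_json(list(matrix = rigid3d_matrix(registration$transform),
                            fre_mm = registration$fre_mm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
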