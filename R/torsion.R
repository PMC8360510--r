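# Helical torsion of the tube cartilage: per-section orientation of the
# cartilage mask's major principal axis (second central moments), unwrapped
# over the 180-degree-periodic orientation circle, with the total torsion
# taken as the endpoint difference of the unwrapped angles and a robust
# (least-absolute-deviations) line fit reported alongside.

#' Principal-axis orientation of a binary mask
#'
#' Orientation of the major principal axis from the second central moments
#' of the mask, in degrees, counterclockwise in the physical (x, y) frame,
#' reported in (-90, 90]. The anisotropy ratio sqrt(lambda1 / lambda2) of
#' the moment eigenvalues indicates how well-defined the orientation is;
#' below `min_anisotropy` the estimate is flagged unreliable (near-isotropic
#' cross-section).
#'
#' @param mask Logical or 0/1 matrix (rows = y, cols = x).
#' @param spacing_mm Pixel spacing (y, x) in mm.
#' @param min_anisotropy Reliability threshold on the anisotropy ratio.
#' @return List with `theta_deg`, `anisotropy_ratio`, `reliable`.
#' @export
slice_orientation <- function(mask, spacing_mm = c(1, 1),
                              min_anisotropy = 1.05) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot orient an empty mask")
  x <- (idx[, 2] - 1) * spacing_mm[2]
  y <- (idx[, 1] - 1) * spacing_mm[1]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  theta <- wrap_angle(theta, 180)
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2),
              symmetric = TRUE, only.values = TRUE)$values
  ratio <- sqrt(max(ev[1], 0) / max(ev[2], .Machine$double.eps))
  list(theta_deg = theta, anisotropy_ratio = ratio,
       reliable = ratio >= min_anisotropy)
}

#' Unwrap a sequence of 180-degree-periodic orientations
#'
#' Adjusts successive values by multiples of 180 degrees so every step has
#' the smallest possible magnitude. A forced step of exactly 90 degrees is
#' ambiguous and raises an error naming the section pair.
#'
#' @param theta_deg Raw orientations in (-90, 90].
#' @param labels Optional labels (e.g. section indices) used in error
#'   messages.
#' @return The unwrapped sequence (first element unchanged).
#' @export
unwrap_orientations <- function(theta_deg, labels = NULL) {
  n <- length(theta_deg)
  if (n == 0) return(numeric(0))
  if (is.null(labels)) labels <- seq_len(n) - 1L
  out <- numeric(n)
  out[1] <- theta_deg[1]
  for (i in seq_len(n - 1L)) {
    step <- wrap_angle(theta_deg[i + 1L] - out[i], 180)
    if (abs(abs(step) - 90) < 1e-9)
      stop(sprintf("ambiguous 90-degree orientation step between sections %s and %s",
                   labels[i], labels[i + 1L]))
    out[i + 1L] <- out[i] + step
  }
  out
}

# Least-absolute-deviations line fit by iteratively reweighted least
# squares.
lad_fit <- function(x, y, max_iter = 50, eps = 1e-8) {
  w <- rep(1, length(x))
  for (k in seq_len(max_iter)) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    r <- as.numeric(y - cbind(1, x) %*% fit$coefficients)
    w_new <- 1 / pmax(abs(r), eps)
    if (max(abs(w_new - w)) < 1e-6 * max(w)) break
    w <- w_new
  }
  coef <- fit$coefficients
  pred <- cbind(1, x) %*% coef
  r2 <- 1 - sum((y - pred)^2) / max(sum((y - mean(y))^2),
                                    .Machine$double.eps)
  list(intercept = coef[1], slope = coef[2], r2 = r2)
}

#' Total helical torsion of a compartment along the stack
#'
#' Measures the per-section principal-axis orientation of the compartment on
#' the original section images, adds each section's recovered in-plane
#' rotation (a rigid rotation shifts the orientation exactly, so no
#' resampling is involved), unwraps the 180-degree-periodic sequence over
#' reliable sections, and reports the endpoint difference as the total
#' torsion together with a robust least-absolute-deviations line fit of
#' angle versus axial position. Sections with a near-isotropic cross-section
#' are excluded from the fit and interpolated in the unwrapped sequence.
#'
#' @param sections A `section_series`.
#' @param aligned Optional `aligned_stack`; if `NULL`, orientations are
#'   taken from the raw sections (valid only for unperturbed stacks).
#' @param label Compartment to orient (default `"cartilage"`).
#' @param min_reliable Minimum number of sections with a reliable
#'   orientation.
#' @param min_anisotropy Reliability threshold (see [slice_orientation()]).
#' @return An object of class `torsion_estimate`: list with `per_section`
#'   (data.frame of `section_index`, `z_mm`, `theta_deg`,
#'   `theta_unwrapped_deg`, `anisotropy_ratio`, `reliable`),
#'   `total_torsion_deg`, `fit_slope_deg_per_mm`, `r2`.
#' @export
total_torsion <- function(sections, aligned = NULL, label = "cartilage",
                          min_reliable = 5, min_anisotropy = 1.05) {
  lv <- resolve_label(label)
  idx <- vapply(sections, function(s) s$section_index, 1L)
  if (!is.null(aligned)) {
    pos <- match(idx, aligned$section_indices)
    z <- aligned$z_mm[pos]
    rot <- vapply(aligned$transforms[pos],
                  function(t) t$rotation_deg, 0)
  } else {
    z <- vapply(sections, function(s) {
      if (is.null(s$nominal_z_mm)) stop("sections carry no z metadata")
      s$nominal_z_mm
    }, 0)
    rot <- rep(0, length(sections))
  }
  ori <- lapply(seq_along(sections), function(i) {
    mask <- sections[[i]]$labels == lv
    if (!any(mask))
      return(list(theta_deg = NA_real_, anisotropy_ratio = NA_real_,
                  reliable = FALSE))
    slice_orientation(mask, sections[[i]]$spacing_mm,
                      min_anisotropy = min_anisotropy)
  })
  theta_raw <- vapply(ori, function(o) o$theta_deg, 0)
  aniso <- vapply(ori, function(o) o$anisotropy_ratio, 0)
  reliable <- vapply(ori, function(o) o$reliable, TRUE)
  # orientation in the aligned frame: recovered rotation adds exactly
  theta_aligned <- wrap_angle(theta_raw + rot, 180)
  if (sum(reliable) < min_reliable)
    stop(sprintf("only %d sections have a reliable orientation (need %d)",
                 sum(reliable), min_reliable))
  rel_idx <- which(reliable)
  unwrapped_rel <- unwrap_orientations(theta_aligned[rel_idx],
                                       labels = idx[rel_idx])
  unwrapped <- rep(NA_real_, length(sections))
  unwrapped[rel_idx] <- unwrapped_rel
  if (any(!reliable) && sum(reliable) >= 2) {
    unwrapped[!reliable] <- stats::approx(z[rel_idx], unwrapped_rel,
                                          z[!reliable], rule = 2)$y
  }
  total <- unwrapped_rel[length(unwrapped_rel)] - unwrapped_rel[1]
  fit <- lad_fit(z[rel_idx], unwrapped_rel)
  per_section <- data.frame(section_index = idx, z_mm = z,
                            theta_deg = theta_aligned,
                            theta_unwrapped_deg = unwrapped,
                            anisotropy_ratio = aniso,
                            reliable = reliable)
  structure(list(per_section = per_section,
                 total_torsion_deg = total,
                 fit_slope_deg_per_mm = fit$slope,
                 r2 = fit$r2),
            class = "torsion_estimate")
}

#' @export
print.torsion_estimate <- function(x, ...) {
  cat(sprintf("torsion_estimate: total %.2f deg over %d sections\n",
              x$total_torsion_deg, nrow(x$per_section)))
  cat(sprintf("  robust slope %.3f deg/mm (R^2 = %.4f); %d reliable sections\n",
              x$fit_slope_deg_per_mm, x$r2, sum(x$per_section$reliable)))
  invisible(x)
}
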