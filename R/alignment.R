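# Slice-to-slice alignment from needle fiducials. The three cannulas are
# straight in the specimen, so their per-section traces must be colinear in
# z once each section's rigid perturbation is undone. The fit jointly
# estimates three straight 3D lines and one in-plane rigid transform per
# section by minimizing the sum of squared in-plane distances between
# transformed detections and the lines' intersections with the section
# planes (block coordinate descent: 2D Procrustes per section given the
# lines, total-least-squares 3D line fit per fiducial given the
# transforms). The criterion is invariant to one common rigid motion of all
# sections; that gauge is fixed by forcing the mean rotation and mean
# translation across sections to zero.

#' Detect needle fiducials in a section
#'
#' Finds connected components of the fiducial label whose area lies within
#' `area_range` times the expected needle cross-section (pi * r^2) and
#' returns their center-of-mass centroids in mm. Sections with zero or more
#' than three plausible components are flagged unalignable.
#'
#' @param section A [section_image()].
#' @param expected_radius_mm Needle radius (default 0.45 mm for a 0.9 mm
#'   needle).
#' @param area_range Acceptable area range as multiples of the expected
#'   cross-section (default 0.25 to 4, allowing for section obliquity).
#' @return A data.frame with columns `x_mm`, `y_mm`, `area_mm2`; attribute
#'   `unalignable` is `TRUE` when detection failed.
#' @export
detect_fiducials <- function(section, expected_radius_mm = 0.45,
                             area_range = c(0.25, 4)) {
  sc <- et_labels()
  mask <- section$labels == sc[["fiducial"]]
  sp <- section$spacing_mm
  empty <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      area_mm2 = numeric(0))
  if (!any(mask)) {
    attr(empty, "unalignable") <- TRUE
    return(empty)
  }
  lab <- EBImage::bwlabel(mask)
  ids <- seq_len(max(lab))
  px_area <- sp[1] * sp[2]
  expected <- pi * expected_radius_mm^2
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[idx]
  areas <- tabulate(comp, nbins = max(lab)) * px_area
  keep <- which(areas >= area_range[1] * expected &
                areas <= area_range[2] * expected)
  if (length(keep) == 0L || length(keep) > 3L) {
    attr(empty, "unalignable") <- TRUE
    return(empty)
  }
  cx <- tapply((idx[, 2] - 1) * sp[2], comp, mean)
  cy <- tapply((idx[, 1] - 1) * sp[1], comp, mean)
  out <- data.frame(x_mm = as.numeric(cx[as.character(keep)]),
                    y_mm = as.numeric(cy[as.character(keep)]),
                    area_mm2 = areas[keep])
  attr(out, "unalignable") <- FALSE
  out
}

# Best injective assignment of detections to reference positions; both are
# matrices with columns x, y. Returns the reference index for each
# detection. Warns on near-ties (cost difference below tol_mm^2) and breaks
# them deterministically toward the lexicographically smallest assignment.
assign_detections <- function(det, ref, tol_mm = 1e-3) {
  nd <- nrow(det)
  nr <- nrow(ref)
  perms <- all_injections(nr, nd)
  costs <- vapply(perms, function(p)
    sum((det - ref[p, , drop = FALSE])^2), 0)
  o <- order(costs)
  if (length(costs) > 1 && costs[o[2]] - costs[o[1]] < tol_mm^2)
    warning("ambiguous fiducial correspondence (near-equal costs); ",
            "using deterministic tie-break")
  best <- which(costs == costs[o[1]])
  perms[[min(best)]]  # perms generated in lexicographic order
}

# All ordered selections of k out of n indices, lexicographic.
all_injections <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (r in remaining) rec(c(prefix, r), setdiff(remaining, r))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Track fiducial correspondence across sections
#'
#' Assigns a consistent fiducial id (1-3) to every detection. The reference
#' frame is the first section with three detections; ids there are ordered
#' by angle about the detection centroid (deterministic and invariant to
#' the input order of detections). Ids are then propagated frame to frame
#' by the least total squared displacement assignment.
#'
#' @param detections List of detection data.frames (from
#'   [detect_fiducials()]).
#' @param section_indices Integer section index per element of `detections`.
#' @return A data.frame (`fiducial_tracks`) with columns `section_index`,
#'   `fid`, `x_mm`, `y_mm`.
#' @export
correspond_tracks <- function(detections, section_indices) {
  stopifnot(length(detections) == length(section_indices))
  n3 <- vapply(detections, nrow, 1L)
  if (sum(n3 >= 2) < 2)
    stop("need at least two sections with two or more detections")
  ref_i <- which(n3 == 3)[1]
  if (is.na(ref_i)) stop("no section with three detections to anchor ids")
  ref <- detections[[ref_i]]
  ctr <- c(mean(ref$x_mm), mean(ref$y_mm))
  ang <- atan2(ref$y_mm - ctr[2], ref$x_mm - ctr[1])
  ref_order <- order(ang, (ref$x_mm - ctr[1])^2 + (ref$y_mm - ctr[2])^2)
  known <- as.matrix(ref[ref_order, c("x_mm", "y_mm")])
  rows <- list()
  add_rows <- function(i, ids) {
    d <- detections[[i]]
    rows[[length(rows) + 1L]] <<- data.frame(
      section_index = section_indices[i], fid = ids,
      x_mm = d$x_mm, y_mm = d$y_mm)
  }
  rows[[1]] <- data.frame(section_index = section_indices[ref_i],
                          fid = seq_len(3),
                          x_mm = ref$x_mm[ref_order],
                          y_mm = ref$y_mm[ref_order])
  propagate <- function(order_i) {
    last <- known
    for (i in order_i) {
      d <- detections[[i]]
      if (nrow(d) == 0) next
      ids <- assign_detections(as.matrix(d[, c("x_mm", "y_mm")]), last)
      add_rows(i, ids)
      last[ids, ] <- as.matrix(d[, c("x_mm", "y_mm")])
    }
  }
  idx <- seq_along(detections)
  propagate(idx[idx > ref_i][order(section_indices[idx[idx > ref_i]])])
  propagate(idx[idx < ref_i][order(-section_indices[idx[idx < ref_i]])])
  out <- do.call(rbind, rows)
  out <- out[order(out$section_index, out$fid), ]
  rownames(out) <- NULL
  class(out) <- c("fiducial_tracks", "data.frame")
  out
}

# 2D Procrustes: rotation + translation mapping src to dst (n x 2 each),
# least squares.
procrustes2d <- function(src, dst) {
  ms <- colMeans(src)
  md <- colMeans(dst)
  sa <- sweep(src, 2, ms)
  da <- sweep(dst, 2, md)
  num <- sum(sa[, 1] * da[, 2] - sa[, 2] * da[, 1])
  den <- sum(sa[, 1] * da[, 1] + sa[, 2] * da[, 2])
  theta <- atan2(num, den)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t0 <- md - as.numeric(R %*% ms)
  rigid2d(theta * 180 / pi, t0, c(0, 0))
}

# 3D line through per-section points (n x 3 with exact z): x and y are
# regressed on z, which minimizes exactly the sum of squared *in-plane*
# distances between the points and the line -- the same criterion the
# alignment cost uses, so the block update is an exact minimizer.
fit_line3d <- function(pts) {
  z <- pts[, 3]
  zc <- z - mean(z)
  den <- sum(zc^2)
  if (den < 1e-12)
    stop("cannot fit a fiducial line: all detections in one plane")
  bx <- sum(zc * pts[, 1]) / den
  by <- sum(zc * pts[, 2]) / den
  ax <- mean(pts[, 1]) - bx * mean(z)
  ay <- mean(pts[, 2]) - by * mean(z)
  d <- c(bx, by, 1)
  d <- d / sqrt(sum(d^2))
  list(point = c(ax, ay, 0), direction = d)
}

line_at_z <- function(line, z) {
  tt <- (z - line$point[3]) / line$direction[3]
  cbind(line$point[1] + tt * line$direction[1],
        line$point[2] + tt * line$direction[2])
}

# Project the gauge and quasi-gauge freedoms out of a list of transforms.
# The constant rigid motion and the translation shear (linear in z) are
# exact invariances of the colinearity cost: they move or tilt the
# straight lines without bending them, so they are fixed to zero by
# detrending. A rotation drift linear in z (a global twist of the stack)
# is *almost* invariant -- it is identifiable only through the needles'
# small deviation from parallelism -- which makes it a pathologically slow
# direction for coordinate descent. It is therefore pinned to `rot_trend`
# during the descent and optimized separately by an exact one-dimensional
# search (see trend_cost below).
fix_gauge <- function(transforms, z_mm, rot_trend = 0) {
  degs <- vapply(transforms, function(t) t$rotation_deg, 0)
  zc <- z_mm - mean(z_mm)
  den <- max(sum(zc^2), 1e-12)
  deg_slope <- sum(zc * degs) / den
  degs <- degs - mean(degs) - (deg_slope - rot_trend) * zc
  mean_deg <- mean(vapply(transforms, function(t) t$rotation_deg, 0))
  Rg <- rot2(-mean_deg)
  trans <- t(vapply(transforms, function(t) rigid2d_canonical(t)$t,
                    numeric(2)))
  trans <- trans %*% t(Rg)
  for (comp in 1:2) {
    slope <- sum(zc * trans[, comp]) / den
    trans[, comp] <- trans[, comp] - mean(trans[, comp]) - slope * zc
  }
  out <- vector("list", length(transforms))
  for (i in seq_along(transforms))
    out[[i]] <- rigid2d(degs[i], trans[i, ], c(0, 0))
  out
}

# Exact cost of the alignment as a function of the rotation-trend
# coefficient (degrees per mm about the mean z). Given the per-section
# rotations (base rotations plus trend), the cost is linear in the
# remaining unknowns -- per-section translations and per-fiducial line
# parameters -- so they are eliminated in closed form: translations drop
# out by centering within each section, and the line parameters solve a
# small linear least-squares problem per coordinate.
trend_design <- function(det, z_mm, fids) {
  nf <- length(fids)
  rows <- list()
  for (i in seq_along(det)) {
    jj <- match(det[[i]]$fid, fids)
    m <- length(jj)
    if (m < 2) next
    for (r in seq_len(m)) {
      row_a <- -(seq_len(nf) %in% jj) / m
      row_a[jj[r]] <- row_a[jj[r]] + 1
      rows[[length(rows) + 1L]] <- c(row_a, row_a * z_mm[i])
    }
  }
  do.call(rbind, rows)
}

trend_rhs <- function(c_trend, base_deg, det, zc) {
  rhs_x <- c()
  rhs_y <- c()
  for (i in seq_along(det)) {
    m <- nrow(det[[i]]$xy)
    if (m < 2) next
    R <- rot2(base_deg[i] + c_trend * zc[i])
    y <- det[[i]]$xy %*% t(R)
    y <- sweep(y, 2, colMeans(y))
    rhs_x <- c(rhs_x, y[, 1])
    rhs_y <- c(rhs_y, y[, 2])
  }
  cbind(rhs_x, rhs_y)
}

trend_cost <- function(c_trend, base_deg, det, z_mm, fids,
                       design_qr = NULL) {
  zc <- z_mm - mean(z_mm)
  if (is.null(design_qr))
    design_qr <- qr(trend_design(det, z_mm, fids))
  rhs <- trend_rhs(c_trend, base_deg, det, zc)
  res <- qr.resid(design_qr, rhs)
  coef <- qr.coef(design_qr, rhs)
  list(cost = sum(res^2),
       coef_x = coef[, 1], coef_y = coef[, 2])
}

#' Fit the stack alignment from fiducial tracks
#'
#' Block coordinate descent on transforms and lines as described above,
#' iterated until the relative cost change falls below `tol` (default
#' 1e-10) or `max_iter` iterations. The colinearity criterion cannot
#' identify a common rigid motion of all sections, nor a translation shear
#' linear in z (both merely move or tilt the straight fiducial lines);
#' this gauge is fixed by constraining the mean rotation to zero and the
#' translations to have no constant or linear-in-z component. Sections
#' with fewer than two usable detections receive transforms interpolated
#' linearly in z from their neighbours and are flagged.
#'
#' @param tracks A `fiducial_tracks` data.frame from [correspond_tracks()].
#' @param z_mm Named or ordered numeric vector: one z position per section
#'   index appearing in `tracks` (and possibly more, for flagged sections).
#' @param section_indices Section indices matching `z_mm`.
#' @param tol Relative cost-change convergence tolerance.
#' @param max_iter Maximum iterations (error on non-convergence).
#' @param min_fiducial_fraction Minimum fraction of sections with two or
#'   more detections (default 0.8).
#' @return An object of class `aligned_stack`: list with `transforms` (one
#'   [rigid2d()] per section), `z_mm`, `section_indices`, `lines` (three
#'   fitted fiducial lines), `residuals` (per detection), `rms_residual_mm`,
#'   `dof_rms_residual_mm` (degrees-of-freedom-deflated), `cost_history` and
#'   `interpolated` flags.
#' @export
fit_stack_alignment <- function(tracks, z_mm, section_indices = NULL,
                                tol = 1e-10, max_iter = 200,
                                min_fiducial_fraction = 0.8) {
  if (is.null(section_indices)) section_indices <- sort(unique(tracks$section_index))
  stopifnot(length(z_mm) == length(section_indices))
  ns <- length(section_indices)
  if (ns < 3) stop("need at least three sections")
  counts <- table(factor(tracks$section_index, levels = section_indices))
  usable <- counts >= 2
  if (mean(usable) < min_fiducial_fraction)
    stop(sprintf("only %.0f%% of sections have >= 2 fiducials (need >= %.0f%%)",
                 100 * mean(usable), 100 * min_fiducial_fraction))
  fids <- sort(unique(tracks$fid))
  # per-section detection matrices in section order
  det <- lapply(section_indices, function(si) {
    tr <- tracks[tracks$section_index == si, ]
    list(xy = as.matrix(tr[, c("x_mm", "y_mm")]), fid = tr$fid)
  })
  # initialize by chaining each usable section to its predecessor, which
  # puts the block coordinate descent close to the optimum
  transforms <- rep(list(rigid2d()), ns)
  prev <- NULL
  for (i in seq_len(ns)) {
    if (!usable[i]) next
    if (!is.null(prev)) {
      common <- intersect(det[[i]]$fid, prev$fid)
      if (length(common) >= 2) {
        src <- det[[i]]$xy[match(common, det[[i]]$fid), , drop = FALSE]
        dst <- prev$xy[match(common, prev$fid), , drop = FALSE]
        transforms[[i]] <- procrustes2d(src, dst)
      }
    }
    prev <- list(fid = det[[i]]$fid,
                 xy = rigid2d_apply(transforms[[i]], det[[i]]$xy))
  }
  # start inside the pinned-gauge space so every later step is monotone
  transforms[usable] <- fix_gauge(transforms[usable], z_mm[usable])
  cost <- Inf
  cost_history <- numeric(0)
  lines <- NULL
  rot_trend <- 0
  zc_use <- z_mm[usable] - mean(z_mm[usable])
  bcd_pass <- function() {
    for (iter in seq_len(max_iter)) {
      # lines given transforms (exact block minimizer: per-axis OLS on z)
      pts3 <- do.call(rbind, lapply(seq_len(ns), function(i) {
        if (!usable[i] || nrow(det[[i]]$xy) == 0) return(NULL)
        xy <- rigid2d_apply(transforms[[i]], det[[i]]$xy)
        cbind(xy, z_mm[i], det[[i]]$fid)
      }))
      lines <<- lapply(fids, function(f)
        fit_line3d(pts3[pts3[, 4] == f, 1:3, drop = FALSE]))
      names(lines) <<- paste0("fid", fids)
      # transforms given lines (2D Procrustes per section)
      new_cost <- 0
      for (i in seq_len(ns)) {
        if (!usable[i]) next
        targets <- do.call(rbind, lapply(seq_along(fids), function(j) {
          if (!fids[j] %in% det[[i]]$fid) return(NULL)
          line_at_z(lines[[j]], z_mm[i])
        }))
        src <- det[[i]]$xy[order(det[[i]]$fid), , drop = FALSE]
        transforms[[i]] <<- procrustes2d(src, targets)
        new_cost <- new_cost +
          sum((rigid2d_apply(transforms[[i]], src) - targets)^2)
      }
      # keep the descent out of the flat gauge directions and off the
      # pathologically slow rotation-trend direction (handled exactly by
      # the trend search below)
      transforms[usable] <<- fix_gauge(transforms[usable], z_mm[usable],
                                       rot_trend)
      cost_history <<- c(cost_history, new_cost)
      # converged when the relative change is below tol, or when the cost
      # itself reaches the numerical floor (exactly consistent data)
      if (is.finite(cost) &&
          (abs(cost - new_cost) <= tol * max(cost, .Machine$double.eps) ||
           new_cost <= 1e-16 * nrow(tracks))) {
        cost <<- new_cost
        return(invisible())
      }
      cost <<- new_cost
      if (iter == max_iter)
        stop(sprintf("alignment did not converge in %d iterations (final cost %.3e)",
                     max_iter, new_cost))
    }
  }
  det_use <- det[usable]
  design_qr <- qr(trend_design(det_use, z_mm[usable], fids))
  for (round in seq_len(50)) {
    cost_before_round <- cost
    bcd_pass()
    # exact 1D minimization over the rotation-trend coefficient, the one
    # direction block coordinate descent cannot traverse efficiently
    base_deg <- vapply(transforms[usable], function(t) t$rotation_deg, 0) -
      rot_trend * zc_use
    cfun <- function(cc) trend_cost(cc, base_deg, det_use, z_mm[usable],
                                    fids, design_qr)$cost
    opt <- stats::optimize(cfun, interval = rot_trend + c(-1, 1),
                           tol = 1e-12)
    if (opt$objective < cost) {
      rot_trend <- opt$minimum
      sol <- trend_cost(rot_trend, base_deg, det_use, z_mm[usable], fids,
                        design_qr)
      coef_x <- ifelse(is.na(sol$coef_x), 0, sol$coef_x)
      coef_y <- ifelse(is.na(sol$coef_y), 0, sol$coef_y)
      nf <- length(fids)
      lines <- lapply(seq_len(nf), function(j) {
        d <- c(coef_x[nf + j], coef_y[nf + j], 1)
        list(point = c(coef_x[j], coef_y[j], 0), direction = d / sqrt(sum(d^2)))
      })
      names(lines) <- paste0("fid", fids)
      ui <- which(usable)
      for (k in seq_along(ui)) {
        i <- ui[k]
        deg <- base_deg[k] + rot_trend * zc_use[k]
        R <- rot2(deg)
        targets <- do.call(rbind, lapply(seq_along(fids), function(j) {
          if (!fids[j] %in% det[[i]]$fid) return(NULL)
          line_at_z(lines[[j]], z_mm[i])
        }))
        src <- det[[i]]$xy[order(det[[i]]$fid), , drop = FALSE]
        t0 <- colMeans(targets) - colMeans(src %*% t(R))
        transforms[[i]] <- rigid2d(deg, t0, c(0, 0))
      }
      cost <- opt$objective
      cost_history <- c(cost_history, cost)
    }
    if (is.finite(cost_before_round) &&
        abs(cost_before_round - cost) <=
          tol * max(cost_before_round, .Machine$double.eps))
      break
  }
  # normalize the exact gauge of the final solution (mean rotation, mean
  # and shear of translation); the fitted rotation trend is retained
  transforms[usable] <- fix_gauge(transforms[usable], z_mm[usable],
                                  rot_trend)
  # interpolate transforms for unusable sections
  if (any(!usable)) {
    zi <- z_mm[usable]
    di <- vapply(transforms[usable], function(t) t$rotation_deg, 0)
    ti <- t(vapply(transforms[usable],
                   function(t) rigid2d_canonical(t)$t, numeric(2)))
    for (i in which(!usable)) {
      transforms[[i]] <- rigid2d(
        stats::approx(zi, di, z_mm[i], rule = 2)$y,
        c(stats::approx(zi, ti[, 1], z_mm[i], rule = 2)$y,
          stats::approx(zi, ti[, 2], z_mm[i], rule = 2)$y),
        c(0, 0))
    }
  }
  # refit lines and residuals under the fixed gauge
  pts3 <- do.call(rbind, lapply(seq_len(ns), function(i) {
    if (!usable[i] || nrow(det[[i]]$xy) == 0) return(NULL)
    xy <- rigid2d_apply(transforms[[i]], det[[i]]$xy)
    cbind(xy, z_mm[i], det[[i]]$fid, section_indices[i])
  }))
  lines <- lapply(fids, function(f)
    fit_line3d(pts3[pts3[, 4] == f, 1:3, drop = FALSE]))
  names(lines) <- paste0("fid", fids)
  res <- do.call(rbind, lapply(seq_along(fids), function(j) {
    p <- pts3[pts3[, 4] == fids[j], , drop = FALSE]
    q <- line_at_z(lines[[j]], p[, 3])
    data.frame(section_index = p[, 5], fid = fids[j],
               dx = p[, 1] - q[, 1], dy = p[, 2] - q[, 2])
  }))
  res$norm <- sqrt(res$dx^2 + res$dy^2)
  res <- res[order(res$section_index, res$fid), ]
  rownames(res) <- NULL
  n_obs <- 2 * nrow(res)
  n_par <- 3 * sum(usable) + 4 * length(fids) - 3  # transforms + lines - gauge
  dof <- max(n_obs - n_par, 1)
  ss <- sum(res$dx^2 + res$dy^2)
  structure(list(transforms = transforms,
                 z_mm = z_mm,
                 section_indices = section_indices,
                 lines = lines,
                 residuals = res,
                 rms_residual_mm = sqrt(ss / n_obs),
                 dof_rms_residual_mm = sqrt(ss / dof),
                 cost = cost,
                 cost_history = cost_history,
                 interpolated = !usable),
            class = "aligned_stack")
}

#' @export
print.aligned_stack <- function(x, ...) {
  cat(sprintf("aligned_stack: %d sections, %d fiducial lines\n",
              length(x$transforms), length(x$lines)))
  cat(sprintf("  final cost %.4e after %d iterations; RMS residual %.4f mm (dof-deflated %.4f mm)\n",
              x$cost, length(x$cost_history), x$rms_residual_mm,
              x$dof_rms_residual_mm))
  if (any(x$interpolated))
    cat("  interpolated sections:",
        paste(x$section_indices[x$interpolated], collapse = ", "), "\n")
  invisible(x)
}

#' Corrected z positions and per-section tilt from groove measurements
#'
#' The section z position is recovered from the mean remaining block
#' thickness via the exact plane through the three groove read-outs: its
#' value at the block center gives the cut depth, and its slopes give the
#' section's tilt. When the three read-outs disagree by more than an
#' outlier threshold (3x the groove noise plus the plausible tilt spread),
#' the median read-out is used instead and the tilt is reported as `NA`.
#'
#' @param groove_mm n x 3 matrix of remaining thicknesses.
#' @param proto The [protocol_spec()] used.
#' @param groove_xy_mm 3 x 2 groove positions.
#' @param block_height_mm Per-block height (n_sections_per_block x period).
#' @param block_center_mm In-plane block center.
#' @param block_id Length-n block id per section (for the z offset of later
#'   blocks).
#' @return List with `z_mm`, `tilt_deg` (n x 2), `fallback` flags.
#' @export
assign_z <- function(groove_mm, proto, groove_xy_mm, block_height_mm,
                     block_center_mm, block_id = NULL) {
  groove_mm <- as.matrix(groove_mm)
  stopifnot(ncol(groove_mm) == 3)
  n <- nrow(groove_mm)
  if (is.null(block_id)) block_id <- rep(1L, n)
  period <- section_period_mm(proto)
  lever <- sweep(as.matrix(groove_xy_mm), 2, block_center_mm)
  A <- cbind(1, lever)
  Ainv <- solve(A)
  noise <- proto$groove_noise_um / 1000
  tilt_allow <- tan(3 * proto$perturbation$tilt_sd_deg * pi / 180) *
    max(stats::dist(lever))
  thresh <- 3 * noise + tilt_allow
  z <- numeric(n)
  tilt <- matrix(NA_real_, n, 2)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    r <- groove_mm[i, ]
    if (max(stats::dist(r)) > thresh) {
      fallback[i] <- TRUE
      depth <- stats::median(r)
    } else {
      coef <- Ainv %*% r
      depth <- coef[1]
      tilt[i, ] <- atan(coef[2:3]) * 180 / pi
    }
    z[i] <- block_height_mm - depth - period
  }
  z <- z + (block_id - 1L) * block_height_mm
  ord <- order(seq_len(n))
  if (any(diff(z[ord]) <= 0)) {
    bad <- which(diff(z[ord]) <= 0)
    stop("non-monotone corrected z sequence at section positions: ",
         paste(bad, collapse = ", "))
  }
  list(z_mm = z, tilt_deg = tilt, fallback = fallback)
}

#' Assemble aligned sections into a 3D label volume
#'
#' Resamples every section into the common grid under its recovered
#' transform (nearest neighbour; labels are categorical) with the section
#' period as z spacing. Lost sections remain background planes and are
#' flagged in the metadata.
#'
#' @param sections A `section_series`.
#' @param aligned An `aligned_stack` from [fit_stack_alignment()].
#' @param period_mm z spacing; defaults to the series' protocol period.
#' @param max_voxels Guard against runaway output sizes.
#' @return A [label_volume()] with attributes `lost_planes` and
#'   `plane_section_index`.
#' @export
assemble <- function(sections, aligned, period_mm = NULL,
                     max_voxels = 2e8) {
  proto <- attr(sections, "proto")
  if (is.null(period_mm)) {
    if (is.null(proto)) stop("period_mm required when the series carries no protocol")
    period_mm <- section_period_mm(proto)
  }
  idx <- vapply(sections, function(s) s$section_index, 1L)
  nz <- max(idx) + 1L
  ny <- nrow(sections[[1]]$labels)
  nx <- ncol(sections[[1]]$labels)
  if (as.numeric(ny) * nx * nz > max_voxels)
    stop(sprintf("assembled volume would need %d voxels (budget %g)",
                 as.numeric(ny) * nx * nz, max_voxels))
  vox <- array(0L, dim = c(ny, nx, nz))
  sp <- sections[[1]]$spacing_mm
  pos <- match(idx, aligned$section_indices)
  if (anyNA(pos)) stop("aligned stack lacks transforms for some sections")
  for (i in seq_along(sections)) {
    tr <- aligned$transforms[[pos[i]]]
    # warp_labels(labels, sp, T) samples labels at T^-1(p): passing the
    # forward observed-to-aligned transform places content correctly
    vox[, , idx[i] + 1L] <- warp_labels(sections[[i]]$labels, sp, tr)
  }
  out <- label_volume(vox, spacing_mm = c(sp, period_mm))
  attr(out, "lost_planes") <- setdiff(seq_len(nz) - 1L, idx)
  attr(out, "plane_section_index") <- seq_len(nz) - 1L
  out
}

#' Full alignment of a section series
#'
#' Convenience wrapper: detect fiducials, establish correspondence, recover
#' z from the groove measurements, and fit the stack alignment.
#'
#' @param sections A `section_series`.
#' @param ... Passed to [fit_stack_alignment()].
#' @return An `aligned_stack` with the corrected z and tilt attached.
#' @export
align_series <- function(sections, ...) {
  proto <- attr(sections, "proto")
  detections <- lapply(sections, detect_fiducials)
  idx <- vapply(sections, function(s) s$section_index, 1L)
  tracks <- correspond_tracks(detections, idx)
  groove <- t(vapply(sections, function(s) s$groove_remaining_mm,
                     numeric(3)))
  block_id <- vapply(sections, function(s) s$block_id, 1L)
  zc <- assign_z(groove, proto, attr(sections, "groove_xy_mm"),
                 attr(sections, "block_height_mm"),
                 attr(sections, "block_center_mm"), block_id)
  aligned <- fit_stack_alignment(tracks, zc$z_mm, idx, ...)
  aligned$tilt_deg <- zc$tilt_deg
  aligned$z_fallback <- zc$fallback
  aligned
}

#' Per-section recovery error against ground-truth perturbations
#'
#' The recovered transform of a perfectly aligned section equals the inverse
#' of the applied perturbation up to one common rigid motion (the gauge).
#' This composes each recovered transform with the true perturbation,
#' removes the mean rotation and mean translation of the compositions, and
#' reports the per-section deviations.
#'
#' @param recovered List of [rigid2d()] (the fit).
#' @param truth List of [rigid2d()] (the applied perturbations), same
#'   length/order.
#' @param z_mm Optional per-section z positions. When given, the
#'   linear-in-z components of translation (a shear that tilts the fiducial
#'   lines without bending them) and rotation (a global twist, only weakly
#'   identifiable from near-parallel needles) are removed along with the
#'   means, matching the estimator's gauge; otherwise only the means are
#'   removed.
#' @return A data.frame with `rotation_err_deg` and `translation_err_mm`
#'   per section, with RMS values as attributes.
#' @export
transform_recovery_error <- function(recovered, truth, z_mm = NULL) {
  stopifnot(length(recovered) == length(truth))
  comp <- mapply(function(r, p) rigid2d_compose(r, p),
                 recovered, truth, SIMPLIFY = FALSE)
  degs <- vapply(comp, function(t) t$rotation_deg, 0)
  mean_deg <- mean(degs)
  Rg <- rot2(-mean_deg)
  trans <- t(vapply(comp, function(t) rigid2d_canonical(t)$t, numeric(2)))
  trans <- trans %*% t(Rg)
  trans <- sweep(trans, 2, colMeans(trans))
  rot_err <- wrap_angle(degs - mean_deg, 360)
  if (!is.null(z_mm)) {
    zc <- z_mm - mean(z_mm)
    den <- sum(zc^2)
    for (k in 1:2)
      trans[, k] <- trans[, k] - sum(zc * trans[, k]) / den * zc
    rot_err <- rot_err - sum(zc * rot_err) / den * zc
  }
  trans_err <- sqrt(rowSums(trans^2))
  out <- data.frame(rotation_err_deg = rot_err,
                    translation_err_mm = trans_err)
  attr(out, "rms_rotation_deg") <- sqrt(mean(rot_err^2))
  attr(out, "rms_translation_mm") <- sqrt(mean(trans_err^2))
  out
}
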