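# Ground-truth phantom: a helically twisted, J-shaped cartilaginous tube with
# its neighbouring compartments (lumen, mucosa, TVPM, LVPM, Ostmann fat pad,
# bone), three near-axial needle fiducials and three reference grooves, all
# embedded in a rectangular block. The phantom provides known geometry
# (twist per axial position, fiducial lines, groove positions) against which
# the reconstruction pipeline is validated.

#' Label scheme of the phantom and of reconstructed stacks
#'
#' @return A named integer vector mapping compartment names to label values.
#' @export
et_labels <- function() {
  c(background = 0L, cartilage = 1L, lumen = 2L, mucosa = 3L,
    TVPM = 4L, LVPM = 5L, OFP = 6L, bone = 7L,
    fiducial = 8L, groove = 9L)
}

resolve_label <- function(label, scheme = et_labels()) {
  if (is.character(label)) {
    if (!label %in% names(scheme))
      stop("unknown label name: ", label)
    return(unname(scheme[label]))
  }
  label <- as.integer(label)
  if (!label %in% scheme)
    stop("unknown label value: ", label)
  label
}

#' Labelled 3D volume
#'
#' Container for an integer label map with anisotropic spacing. Voxel
#' (i, j, k) has its center at `origin_mm + (c(i, j, k) - 0.5) * spacing_mm`
#' with i indexing y (rows), j indexing x (columns), k indexing z (planes).
#'
#' @param voxels 3D integer array of label values.
#' @param spacing_mm Numeric length-3 voxel spacing (y, x, z) in mm.
#' @param origin_mm Numeric length-3 position of the block corner in mm.
#' @param scheme Named integer label scheme; every voxel value must occur in
#'   it.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                         scheme = et_labels()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("voxels must be a non-empty 3D array")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be three strictly positive values")
  storage.mode(voxels) <- "integer"
  bad <- setdiff(unique(as.vector(voxels)), scheme)
  if (length(bad) > 0)
    stop("voxel values outside the label scheme: ",
         paste(bad, collapse = ", "))
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm), scheme = scheme),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x ")))
  tab <- table(factor(as.vector(x$voxels), levels = x$scheme,
                      labels = names(x$scheme)))
  print(tab[tab > 0])
  invisible(x)
}

#' Phantom specification
#'
#' All geometric and protocol constants of the synthetic specimen. The
#' defaults describe the fixture used throughout the package: a 20 x 20 x
#' 38 mm embedding block holding a gently bowed tube whose J-shaped cartilage
#' cross-section (long medial lamina, short lateral lamina) rotates helically
#' by `twist_total_deg` from the pharyngeal to the middle-ear end, flanked by
#' the tensor and levator veli palatini muscles (TVPM, LVPM), the Ostmann fat
#' pad (OFP), a mucosa-lined lumen that is open only near the pharyngeal
#' orifice, and bone near the isthmus end. Three 0.9 mm needle fiducials run
#' near-parallel to the tube axis and three grooves are milled into the block
#' faces.
#'
#' @param block_size_mm Block extents (x, y, z) in mm.
#' @param voxel_mm Voxel spacing (x, y, z) in mm.
#' @param twist_total_deg Total helical rotation of the cross-section from
#'   the first to the last axis point, in degrees (interpolated linearly in
#'   arc length).
#' @param axis_z_range_mm z-range spanned by the tube axis.
#' @param axis_bow_mm Amplitude of the in-plane (x) bow of the axis.
#' @param n_axis_points Number of polyline points used for the axis.
#' @param tube_axis Optional n x 3 polyline overriding the default axis.
#' @param cartilage_profile List with `medial_mm`, `lateral_mm`,
#'   `thickness_mm`, `taper` (relative shortening of the laminae toward the
#'   isthmus) and `thickness_exponent` (thickness grows as
#'   `f^-thickness_exponent` where `f` is the lamina scale, keeping the
#'   cross-sectional area nearly constant).
#' @param lumen_gap_mm Lumen opening width at the pharyngeal orifice.
#' @param lumen_open_fraction Fraction of the axis (from the pharyngeal end)
#'   over which the lumen gap tapers from `lumen_gap_mm` to zero.
#' @param mucosa_thickness_mm Thickness of the mucosal lining.
#' @param compartment_offsets Placement of TVPM, LVPM, OFP and bone in the
#'   local (rotating) cross-section frame; see the default for the format.
#' @param fiducials List of three needles, each
#'   `list(entry_mm = c(x, y, z), direction = c(dx, dy, dz), radius_mm)`.
#' @param grooves List of three grooves, each `list(face, pos_mm)` with
#'   `face` one of `"x-"`, `"x+"`, `"y-"`, `"y+"`; plus `depth_mm`/`width_mm`
#'   entries applying to all grooves.
#' @param fiducial_max_angle_deg Maximum allowed angle between each needle
#'   and the mean axis direction.
#' @param roughness_mm Standard deviation of seeded per-plane jitter added to
#'   the structure half-widths (0 disables it; geometry is then fully
#'   deterministic).
#' @param seed Integer seed for the optional surface roughness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(block_size_mm = c(20, 20, 38),
                         voxel_mm = c(0.1, 0.1, 0.1815),
                         twist_total_deg = 38,
                         axis_z_range_mm = c(0.0908, 36.0278),
                         axis_bow_mm = 1.2,
                         n_axis_points = 81,
                         tube_axis = NULL,
                         cartilage_profile = list(medial_mm = 6,
                                                  lateral_mm = 2.5,
                                                  thickness_mm = 0.9,
                                                  taper = 0.35,
                                                  thickness_exponent = 0.8),
                         lumen_gap_mm = 0.5,
                         lumen_open_fraction = 0.15,
                         mucosa_thickness_mm = 0.25,
                         compartment_offsets = list(
                           TVPM = list(from = c(0.5, -1.8), to = c(3.5, -2.4),
                                       halfwidth_mm = 0.8),
                           LVPM = list(from = c(-2.0, -2.6), to = c(-0.2, -3.4),
                                       halfwidth_mm = 0.9),
                           OFP = list(center = c(3.2, -0.8), radius_mm = 1.3,
                                      taper = 0.6),
                           bone = list(center = c(-2.8, 1.2), radius_mm = 1.1,
                                       from_fraction = 0.85)),
                         fiducials = NULL,
                         grooves = NULL,
                         fiducial_max_angle_deg = 5,
                         roughness_mm = 0,
                         seed = 0L) {
  ctr <- block_size_mm[1:2] / 2
  if (is.null(fiducials)) {
    polar <- function(r, ang_deg) ctr + r * c(cos(ang_deg * pi / 180),
                                              sin(ang_deg * pi / 180))
    unitv <- function(v) v / sqrt(sum(v^2))
    fiducials <- list(
      list(entry_mm = c(polar(6.3, 25), 0),
           direction = unitv(c(0.020, -0.012, 1)), radius_mm = 0.45),
      list(entry_mm = c(polar(6.8, 140), 0),
           direction = unitv(c(-0.018, 0.015, 1)), radius_mm = 0.45),
      list(entry_mm = c(polar(6.0, 262), 0),
           direction = unitv(c(0.010, 0.022, 1)), radius_mm = 0.45))
  }
  if (is.null(grooves)) {
    grooves <- list(list(face = "x-", pos_mm = 7),
                    list(face = "x+", pos_mm = 13),
                    list(face = "y-", pos_mm = 10))
  }
  if (is.null(tube_axis)) {
    s <- seq(0, 1, length.out = n_axis_points)
    tube_axis <- cbind(x = ctr[1] + axis_bow_mm * sin(pi * s),
                       y = rep(ctr[2], n_axis_points),
                       z = axis_z_range_mm[1] +
                         s * diff(axis_z_range_mm))
  }
  structure(list(block_size_mm = as.numeric(block_size_mm),
                 voxel_mm = as.numeric(voxel_mm),
                 twist_total_deg = as.numeric(twist_total_deg),
                 tube_axis = tube_axis,
                 cartilage_profile = cartilage_profile,
                 lumen_gap_mm = lumen_gap_mm,
                 lumen_open_fraction = lumen_open_fraction,
                 mucosa_thickness_mm = mucosa_thickness_mm,
                 compartment_offsets = compartment_offsets,
                 fiducials = fiducials,
                 grooves = grooves,
                 groove_depth_mm = 0.5,
                 groove_width_mm = 0.6,
                 fiducial_max_angle_deg = fiducial_max_angle_deg,
                 roughness_mm = roughness_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Distance from points (px, py) to the segment (ax, ay)-(bx, by); vectorized
# over points.
segment_distance <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax
  aby <- by - ay
  len2 <- abx^2 + aby^2
  tt <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - ax) * abx + (py - ay) * aby) / len2))
  sqrt((px - (ax + tt * abx))^2 + (py - (ay + tt * aby))^2)
}

# Cross-section geometry at taper fraction s in [0, 1]: lamina lengths and
# thickness in mm.
cartilage_dims <- function(profile, s) {
  f <- 1 - profile$taper * s
  list(medial = profile$medial_mm * f,
       lateral = profile$lateral_mm * f,
       thickness = profile$thickness_mm / f^profile$thickness_exponent)
}

# Per-structure masks at local (rotating) coordinates u, v. Returns a list of
# logical vectors. s is the arc-length fraction along the axis.
cross_section_masks <- function(u, v, spec, s, jitter = 0) {
  pr <- spec$cartilage_profile
  dm <- cartilage_dims(pr, s)
  hw <- dm$thickness / 2 + jitter
  cart <- (segment_distance(u, v, -dm$medial / 2, 0, dm$medial / 2, 0) <= hw) |
    (segment_distance(u, v, -dm$medial / 2, 0,
                      -dm$medial / 2, -dm$lateral) <= hw)
  gap <- spec$lumen_gap_mm *
    max(0, 1 - s / max(spec$lumen_open_fraction, 1e-9))
  mu_t <- spec$mucosa_thickness_mm
  v_seam <- -(dm$thickness / 2 + mu_t + gap / 2)
  d_seam <- segment_distance(u, v, -dm$medial / 2 + 1.0, v_seam,
                             dm$medial / 2 - 0.8, v_seam)
  lumen <- if (gap > 0) d_seam <= gap / 2 else rep(FALSE, length(u))
  mucosa <- d_seam <= gap / 2 + mu_t & !lumen
  off <- spec$compartment_offsets
  tv <- off$TVPM
  lv <- off$LVPM
  tvpm <- segment_distance(u, v, tv$from[1], tv$from[2],
                           tv$to[1], tv$to[2]) <= tv$halfwidth_mm + jitter
  lvpm <- segment_distance(u, v, lv$from[1], lv$from[2],
                           lv$to[1], lv$to[2]) <= lv$halfwidth_mm + jitter
  ofr <- off$OFP$radius_mm * (1 - off$OFP$taper * s)
  ofp <- (u - off$OFP$center[1])^2 + (v - off$OFP$center[2])^2 <= ofr^2
  bone <- if (s >= off$bone$from_fraction) {
    (u - off$bone$center[1])^2 + (v - off$bone$center[2])^2 <=
      off$bone$radius_mm^2
  } else rep(FALSE, length(u))
  list(cartilage = cart, lumen = lumen, mucosa = mucosa,
       TVPM = tvpm, LVPM = lvpm, OFP = ofp, bone = bone)
}

# Axis geometry helpers: arc-length fraction and interpolated (x, y) position
# as functions of z. Axis z must be strictly increasing.
axis_geometry <- function(tube_axis) {
  z <- tube_axis[, 3]
  if (any(diff(z) <= 0))
    stop("degenerate axis: z-coordinates must be strictly increasing ",
         "(repeated or reordered points)")
  seglen <- sqrt(rowSums(diff(tube_axis)^2))
  arc <- c(0, cumsum(seglen))
  list(z = z, x = tube_axis[, 1], y = tube_axis[, 2],
       arc_fraction = arc / arc[length(arc)])
}

# Interpolate axis position and arc fraction at height z_mm; NULL outside the
# axis range.
axis_at_z <- function(geom, z_mm) {
  if (z_mm < geom$z[1] || z_mm > geom$z[length(geom$z)]) return(NULL)
  list(x = stats::approx(geom$z, geom$x, z_mm)$y,
       y = stats::approx(geom$z, geom$y, z_mm)$y,
       s = stats::approx(geom$z, geom$arc_fraction, z_mm)$y)
}

# Intersection of fiducial line f with the plane at z_mm.
fiducial_at_z <- function(fid, z_mm) {
  d <- fid$direction
  if (abs(d[3]) < 1e-9) stop("fiducial direction has no z component")
  tt <- (z_mm - fid$entry_mm[3]) / d[3]
  fid$entry_mm[1:2] + tt * d[1:2]
}

check_fiducial_angles <- function(spec) {
  geom <- axis_geometry(spec$tube_axis)
  n <- nrow(spec$tube_axis)
  mean_dir <- spec$tube_axis[n, ] - spec$tube_axis[1, ]
  mean_dir <- mean_dir / sqrt(sum(mean_dir^2))
  for (i in seq_along(spec$fiducials)) {
    d <- spec$fiducials[[i]]$direction
    ang <- acos(min(1, abs(sum(d * mean_dir)))) * 180 / pi
    if (ang > spec$fiducial_max_angle_deg)
      stop(sprintf("fiducial %d deviates %.2f deg from the mean axis ",
                   i, ang),
           sprintf("direction (limit %.2f deg)", spec$fiducial_max_angle_deg))
  }
  invisible(TRUE)
}

#' Rasterize the phantom into a labelled volume
#'
#' Builds the ground-truth specimen voxel by voxel: each z-plane takes the
#' cross-section of every structure in the local frame rotated by the
#' interpolated twist angle, paints it with a fixed precedence (cartilage
#' over lumen over mucosa over muscles/fat/bone), then adds the needle
#' fiducials and block-face grooves. Needle voxels intersecting cartilage or
#' lumen abort with an error naming the needle. The returned object carries
#' ground-truth metadata: the twist angle and cartilage centroid of every
#' plane, the fiducial line parameters, and the groove positions.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `et_phantom`: a list with elements `volume`
#'   (a [label_volume()]), `truth` (ground-truth metadata) and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$voxel_mm <= 0)) stop("voxel_mm must be strictly positive")
  check_fiducial_angles(spec)
  geom <- axis_geometry(spec$tube_axis)
  sc <- et_labels()
  nx <- round(spec$block_size_mm[1] / spec$voxel_mm[1])
  ny <- round(spec$block_size_mm[2] / spec$voxel_mm[2])
  nz <- round(spec$block_size_mm[3] / spec$voxel_mm[3])
  xs <- (seq_len(nx) - 0.5) * spec$voxel_mm[1]
  ys <- (seq_len(ny) - 0.5) * spec$voxel_mm[2]
  X <- rep(xs, each = ny)   # column-major over (row = y, col = x)
  Y <- rep(ys, times = nx)
  vox <- array(0L, dim = c(ny, nx, nz))
  zc <- (seq_len(nz) - 0.5) * spec$voxel_mm[3]
  jitter <- if (spec$roughness_mm > 0) {
    with_local_seed(spec$seed, stats::rnorm(nz, 0, spec$roughness_mm))
  } else rep(0, nz)
  twist <- rep(NA_real_, nz)
  centroid <- matrix(NA_real_, nz, 2)
  paint_order <- c("OFP", "TVPM", "LVPM", "bone", "mucosa", "lumen",
                   "cartilage")
  for (k in seq_len(nz)) {
    ax <- axis_at_z(geom, zc[k])
    plane <- matrix(0L, ny, nx)
    if (!is.null(ax)) {
      th <- spec$twist_total_deg * ax$s
      twist[k] <- th
      a <- th * pi / 180
      dx <- X - ax$x
      dy <- Y - ax$y
      u <- cos(a) * dx + sin(a) * dy
      v <- -sin(a) * dx + cos(a) * dy
      masks <- cross_section_masks(u, v, spec, ax$s, jitter[k])
      lab <- integer(length(u))
      for (nm in paint_order) lab[masks[[nm]]] <- sc[[nm]]
      forbidden <- masks$cartilage | masks$lumen
      for (i in seq_along(spec$fiducials)) {
        fid <- spec$fiducials[[i]]
        p <- fiducial_at_z(fid, zc[k])
        fm <- (X - p[1])^2 + (Y - p[2])^2 <= fid$radius_mm^2
        if (any(fm & forbidden))
          stop(sprintf("fiducial %d intersects cartilage or lumen at z = %.2f mm",
                       i, zc[k]))
        lab[fm] <- sc[["fiducial"]]
      }
      plane <- matrix(lab, ny, nx)
      cm <- masks$cartilage
      if (any(cm))
        centroid[k, ] <- c(mean(X[cm]), mean(Y[cm]))
    } else {
      for (i in seq_along(spec$fiducials)) {
        fid <- spec$fiducials[[i]]
        p <- fiducial_at_z(fid, zc[k])
        fm <- (X - p[1])^2 + (Y - p[2])^2 <= fid$radius_mm^2
        plane[matrix(fm, ny, nx)] <- sc[["fiducial"]]
      }
    }
    plane <- paint_grooves(plane, spec, xs, ys, sc)
    vox[, , k] <- plane
  }
  volume <- label_volume(vox, spacing_mm = c(spec$voxel_mm[2],
                                             spec$voxel_mm[1],
                                             spec$voxel_mm[3]))
  truth <- list(z_mm = zc,
                twist_deg = twist,
                cartilage_centroid_mm = centroid,
                fiducials = spec$fiducials,
                groove_xy_mm = groove_positions(spec),
                axis = spec$tube_axis,
                twist_total_deg = spec$twist_total_deg)
  structure(list(volume = volume, truth = truth, spec = spec),
            class = "et_phantom")
}

# Paint grooves into a single plane; grooves run the full z-extent along the
# block faces and only replace background.
paint_grooves <- function(plane, spec, xs, ys, sc) {
  d <- spec$groove_depth_mm
  w <- spec$groove_width_mm / 2
  bx <- spec$block_size_mm[1]
  by <- spec$block_size_mm[2]
  for (g in spec$grooves) {
    gm <- switch(g$face,
      "x-" = outer(abs(ys - g$pos_mm) <= w, xs <= d),
      "x+" = outer(abs(ys - g$pos_mm) <= w, xs >= bx - d),
      "y-" = outer(ys <= d, abs(xs - g$pos_mm) <= w),
      "y+" = outer(ys >= by - d, abs(xs - g$pos_mm) <= w),
      stop("unknown groove face: ", g$face))
    plane[gm & plane == 0L] <- sc[["groove"]]
  }
  plane
}

# In-plane (x, y) positions of the grooves, used as measurement points and
# registration landmarks.
groove_positions <- function(spec) {
  t(vapply(spec$grooves, function(g) {
    switch(g$face,
           "x-" = c(0, g$pos_mm),
           "x+" = c(spec$block_size_mm[1], g$pos_mm),
           "y-" = c(g$pos_mm, 0),
           "y+" = c(g$pos_mm, spec$block_size_mm[2]))
  }, numeric(2)))
}

#' @export
print.et_phantom <- function(x, ...) {
  cat("et_phantom: twisted-tube specimen phantom\n")
  cat(sprintf("  twist: %.1f deg over axis z in [%.2f, %.2f] mm\n",
              x$spec$twist_total_deg,
              min(x$spec$tube_axis[, 3]), max(x$spec$tube_axis[, 3])))
  print(x$volume)
  invisible(x)
}

#' Density reference volume (tomography surrogate)
#'
#' Maps the phantom labels to densities (bone and steel needles high, soft
#' tissue intermediate, embedding block low, grooves carved out as air) and
#' box-averages the result down to the requested isotropic resolution,
#' emulating the cone-beam CT scan of the embedded block that serves as the
#' registration reference.
#'
#' @param phantom An [build_phantom()] result or a [label_volume()].
#' @param resolution_mm Target voxel size; must be at least the largest
#'   source spacing. Default 0.3 mm.
#' @return An object of class `density_volume`: list with `values` (3D
#'   array), `spacing_mm` and `origin_mm`.
#' @export
make_reference_volume <- function(phantom, resolution_mm = 0.3) {
  vol <- if (inherits(phantom, "et_phantom")) phantom$volume else phantom
  stopifnot(inherits(vol, "label_volume"))
  if (resolution_mm < max(vol$spacing_mm))
    stop(sprintf("resolution (%g mm) must be >= the largest source spacing (%g mm)",
                 resolution_mm, max(vol$spacing_mm)))
  density_map <- c(background = 0.05, cartilage = 0.55, lumen = 0.10,
                   mucosa = 0.35, TVPM = 0.35, LVPM = 0.35, OFP = 0.30,
                   bone = 0.90, fiducial = 1.00, groove = 0.00)
  lut <- numeric(max(vol$scheme) + 1L)
  lut[vol$scheme + 1L] <- density_map[names(vol$scheme)]
  dens <- array(lut[vol$voxels + 1L], dim = dim(vol$voxels))
  f <- pmax(1L, round(resolution_mm / vol$spacing_mm))
  out <- box_downsample(dens, f)
  structure(list(values = out, spacing_mm = vol$spacing_mm * f,
                 origin_mm = vol$origin_mm),
            class = "density_volume")
}

# Box-average downsampling by integer factors; trailing partial blocks are
# averaged over the voxels they actually contain.
box_downsample <- function(a, f) {
  d <- dim(a)
  nd <- as.integer(ceiling(d / f))
  grp <- lapply(1:3, function(i) rep(seq_len(nd[i]), each = f[i])[seq_len(d[i])])
  cnt <- lapply(1:3, function(i) tabulate(grp[[i]], nd[i]))
  sum_along_first <- function(arr, g, n1) {
    dd <- dim(arr)
    m <- rowsum(matrix(arr, dd[1]), g, reorder = TRUE)
    array(m, dim = c(n1, dd[2], dd[3]))
  }
  s <- sum_along_first(a, grp[[1]], nd[1])
  s <- aperm(sum_along_first(aperm(s, c(2, 1, 3)), grp[[2]], nd[2]),
             c(2, 1, 3))
  s <- aperm(sum_along_first(aperm(s, c(3, 2, 1)), grp[[3]], nd[3]),
             c(3, 2, 1))
  w <- outer(outer(cnt[[1]], cnt[[2]]), cnt[[3]])
  s / w
}
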