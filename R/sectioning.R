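# Simulation of the cutting and digitization protocol: the embedded block is
# divided into blocks of equal height, cut into thin sections separated by
# the blade thickness, and each section is digitized as a single 2D image.
# Every section suffers a small in-plane rigid perturbation (mounting on the
# sample holder) and a slight tilt (imperfect parallelism of the cut), and
# the thickness remaining at the three block grooves is measured after each
# cut.

#' Sectioning protocol specification
#'
#' @param section_thickness_um Thickness of each section in micrometres
#'   (default 33).
#' @param blade_thickness_um Thickness of the saw blade, i.e. the material
#'   lost between consecutive sections, in micrometres (default 330). The
#'   section period is the sum of the two (default 363 um).
#' @param n_sections Number of sections cut (default 100).
#' @param lost_section_indices 0-based indices of sections lost during
#'   mounting; defaults to the first section of each block.
#' @param split_into_blocks Number of blocks the specimen is divided into
#'   before cutting (default 2).
#' @param perturbation List with `translation_sd_mm`, `rotation_sd_deg` and
#'   `tilt_sd_deg`: standard deviations of the per-section rigid perturbation
#'   and tilt.
#' @param groove_noise_um Standard deviation of the groove thickness
#'   measurement noise, in micrometres.
#' @param seed Integer seed for all random draws of the protocol.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(section_thickness_um = 33,
                          blade_thickness_um = 330,
                          n_sections = 100,
                          lost_section_indices = NULL,
                          split_into_blocks = 2,
                          perturbation = list(translation_sd_mm = 0.3,
                                              rotation_sd_deg = 2,
                                              tilt_sd_deg = 0.2),
                          groove_noise_um = 5,
                          seed = 0L) {
  if (section_thickness_um <= 0 || blade_thickness_um <= 0)
    stop("section and blade thickness must be > 0")
  n_sections <- as.integer(n_sections)
  if (split_into_blocks < 1 || n_sections %% split_into_blocks != 0)
    stop("n_sections must be a multiple of split_into_blocks")
  if (is.null(lost_section_indices)) {
    per_block <- n_sections %/% split_into_blocks
    lost_section_indices <- (seq_len(split_into_blocks) - 1L) * per_block
  }
  lost_section_indices <- as.integer(lost_section_indices)
  if (any(lost_section_indices < 0 | lost_section_indices >= n_sections))
    stop("lost_section_indices must lie in [0, n_sections)")
  structure(list(section_thickness_um = section_thickness_um,
                 blade_thickness_um = blade_thickness_um,
                 n_sections = n_sections,
                 lost_section_indices = lost_section_indices,
                 split_into_blocks = as.integer(split_into_blocks),
                 perturbation = perturbation,
                 groove_noise_um = groove_noise_um,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Section period in millimetres
#'
#' The axial distance between consecutive section planes: section thickness
#' plus blade thickness.
#'
#' @param proto A [protocol_spec()].
#' @return Scalar period in mm.
#' @export
section_period_mm <- function(proto) {
  (proto$section_thickness_um + proto$blade_thickness_um) / 1000
}

#' One digitized section
#'
#' @param labels Integer matrix of label values (rows = y, cols = x).
#' @param spacing_mm Length-2 pixel spacing (y, x) in mm.
#' @param section_index 0-based index, 0 at the pharyngeal end.
#' @param block_id 1-based block number.
#' @param nominal_z_mm Section index times the period.
#' @param groove_remaining_mm Length-3 remaining block thickness at the
#'   grooves.
#' @param true_transform Ground-truth [rigid2d()] perturbation (synthetic
#'   data only), mapping true in-plane positions to observed ones.
#' @param true_tilt_deg Ground-truth tilt angles (about x and y), degrees.
#' @param rgb Optional rows x cols x 3 array in `[0, 1]`.
#' @return An object of class `section_image`.
#' @export
section_image <- function(labels, spacing_mm, section_index, block_id = 1L,
                          nominal_z_mm = NULL, groove_remaining_mm = NULL,
                          true_transform = NULL, true_tilt_deg = NULL,
                          rgb = NULL) {
  stopifnot(is.matrix(labels), length(spacing_mm) == 2L,
            all(spacing_mm > 0))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing_mm = as.numeric(spacing_mm),
                 section_index = as.integer(section_index),
                 block_id = as.integer(block_id),
                 nominal_z_mm = nominal_z_mm,
                 groove_remaining_mm = groove_remaining_mm,
                 true_transform = true_transform,
                 true_tilt_deg = true_tilt_deg,
                 rgb = rgb),
            class = "section_image")
}

# Resample a label plane under the inverse of a rigid transform:
# out(p) = plane(transform^-1(p)), nearest-neighbour, background outside.
warp_labels <- function(labels, spacing_mm, transform) {
  ny <- nrow(labels)
  nx <- ncol(labels)
  xs <- (seq_len(nx) - 1) * spacing_mm[2]
  ys <- (seq_len(ny) - 1) * spacing_mm[1]
  pts <- cbind(rep(xs, each = ny), rep(ys, times = nx))
  src <- rigid2d_apply(rigid2d_invert(transform), pts)
  ci <- round(src[, 1] / spacing_mm[2]) + 1
  ri <- round(src[, 2] / spacing_mm[1]) + 1
  ok <- ri >= 1 & ri <= ny & ci >= 1 & ci <= nx
  out <- integer(length(ri))
  out[ok] <- labels[cbind(ri[ok], ci[ok])]
  matrix(out, ny, nx)
}

#' Simulate sectioning and digitization of the phantom
#'
#' Cuts the phantom into `n_sections` sections of the protocol's thickness at
#' the protocol's period. Each kept section is the nearest voxel plane to the
#' mid-plane of its slab, perturbed by a seeded random in-plane rigid
#' transform (drawn from the protocol's standard deviations) and annotated
#' with the groove thickness measurements taken after the cut. Lost sections
#' are absent from the output, but z book-keeping is preserved through the
#' section indices.
#'
#' @param phantom An [build_phantom()] result.
#' @param proto A [protocol_spec()].
#' @param make_rgb If `TRUE`, also render a stain-like RGB image per section
#'   with a random per-section illumination tint (exercises white
#'   balancing).
#' @return A list of [section_image()] objects (class `section_series`) with
#'   attributes `proto` and `phantom_truth`.
#' @export
simulate_sectioning <- function(phantom, proto, make_rgb = FALSE) {
  stopifnot(inherits(phantom, "et_phantom"), inherits(proto, "protocol_spec"))
  vol <- phantom$volume
  period <- section_period_mm(proto)
  thick <- proto$section_thickness_um / 1000
  z_extent <- dim(vol$voxels)[3] * vol$spacing_mm[3]
  if (z_extent < proto$n_sections * period - 1e-9)
    stop(sprintf("block too shallow: %d sections x %.3f mm period needs %.2f mm, volume has %.2f mm",
                 proto$n_sections, period, proto$n_sections * period,
                 z_extent))
  per_block <- proto$n_sections %/% proto$split_into_blocks
  block_height <- per_block * period
  ny <- dim(vol$voxels)[1]
  nx <- dim(vol$voxels)[2]
  ctr <- c((nx - 1) * vol$spacing_mm[2] / 2, (ny - 1) * vol$spacing_mm[1] / 2)
  draws <- with_local_seed(derive_seed(proto$seed, 1), {
    n <- proto$n_sections
    list(tx = stats::rnorm(n, 0, proto$perturbation$translation_sd_mm),
         ty = stats::rnorm(n, 0, proto$perturbation$translation_sd_mm),
         rot = stats::rnorm(n, 0, proto$perturbation$rotation_sd_deg),
         tilt_x = stats::rnorm(n, 0, proto$perturbation$tilt_sd_deg),
         tilt_y = stats::rnorm(n, 0, proto$perturbation$tilt_sd_deg))
  })
  groove_noise <- with_local_seed(derive_seed(proto$seed, 2),
    matrix(stats::rnorm(3 * proto$n_sections, 0,
                        proto$groove_noise_um / 1000),
           proto$n_sections, 3))
  tint <- if (make_rgb) {
    with_local_seed(derive_seed(proto$seed, 3),
      matrix(exp(stats::rnorm(3 * proto$n_sections, 0, 0.15)),
             proto$n_sections, 3))
  } else NULL
  groove_xy <- phantom$truth$groove_xy_mm
  block_center <- phantom$spec$block_size_mm[1:2] / 2
  sections <- list()
  for (k in seq_len(proto$n_sections) - 1L) {
    if (k %in% proto$lost_section_indices) next
    z_mid <- k * period + thick / 2
    plane_idx <- max(1L, min(dim(vol$voxels)[3],
                             round(z_mid / vol$spacing_mm[3] + 0.5)))
    plane <- vol$voxels[, , plane_idx]
    tr <- rigid2d(draws$rot[k + 1], c(draws$tx[k + 1], draws$ty[k + 1]),
                  center_mm = ctr)
    warped <- warp_labels(plane, vol$spacing_mm[1:2], tr)
    block_id <- k %/% per_block + 1L
    tilt <- c(draws$tilt_x[k + 1], draws$tilt_y[k + 1])
    grooves <- simulate_groove_measurements(
      proto, k %% per_block, groove_xy, block_height, block_center,
      tilt_deg = tilt, noise_mm = groove_noise[k + 1, ])
    rgb <- if (make_rgb) render_rgb(warped, tint[k + 1, ]) else NULL
    sections[[length(sections) + 1L]] <- section_image(
      labels = warped, spacing_mm = vol$spacing_mm[1:2],
      section_index = k, block_id = block_id,
      nominal_z_mm = k * period, groove_remaining_mm = grooves,
      true_transform = tr, true_tilt_deg = tilt, rgb = rgb)
  }
  structure(sections, class = "section_series",
            proto = proto,
            phantom_truth = phantom$truth,
            block_height_mm = block_height,
            groove_xy_mm = groove_xy,
            block_center_mm = block_center)
}

#' Simulated groove thickness measurements for one section
#'
#' After cutting section `section_index` (0-based within its block), the
#' remaining block thickness is `block_height - (index + 1) * period`; each
#' groove reads this value offset by the section's tilt plane evaluated at
#' the groove position, plus measurement noise.
#'
#' @param proto A [protocol_spec()].
#' @param section_index 0-based section index within the block.
#' @param groove_xy_mm 3 x 2 matrix of in-plane groove positions.
#' @param block_height_mm Height of the block being cut.
#' @param block_center_mm In-plane block center (x, y), the tilt pivot.
#' @param tilt_deg Length-2 tilt angles (slope about the x and y lever arms),
#'   degrees.
#' @param noise_mm Optional length-3 pre-drawn noise; if `NULL`, drawn from
#'   the protocol's `groove_noise_um` using its seed and the section index.
#' @return Numeric length-3 remaining thickness at the three grooves, mm.
#' @export
simulate_groove_measurements <- function(proto, section_index,
                                         groove_xy_mm, block_height_mm,
                                         block_center_mm,
                                         tilt_deg = c(0, 0),
                                         noise_mm = NULL) {
  period <- section_period_mm(proto)
  base <- block_height_mm - (section_index + 1) * period
  lever_x <- groove_xy_mm[, 1] - block_center_mm[1]
  lever_y <- groove_xy_mm[, 2] - block_center_mm[2]
  offset <- tan(tilt_deg[1] * pi / 180) * lever_x +
    tan(tilt_deg[2] * pi / 180) * lever_y
  if (is.null(noise_mm)) {
    noise_mm <- with_local_seed(derive_seed(proto$seed, 100 + section_index),
                                stats::rnorm(3, 0,
                                             proto$groove_noise_um / 1000))
  }
  base + offset + noise_mm
}

# Map labels to stain-like colours and apply a per-section illumination
# tint.
render_rgb <- function(labels, tint) {
  palette <- rbind(background = c(0.92, 0.90, 0.86),
                   cartilage = c(0.20, 0.25, 0.60),
                   lumen = c(0.95, 0.93, 0.90),
                   mucosa = c(0.75, 0.45, 0.55),
                   TVPM = c(0.55, 0.20, 0.25),
                   LVPM = c(0.60, 0.25, 0.30),
                   OFP = c(0.90, 0.85, 0.55),
                   bone = c(0.85, 0.30, 0.25),
                   fiducial = c(0.10, 0.10, 0.10),
                   groove = c(0.50, 0.50, 0.50))
  sc <- et_labels()
  lut <- matrix(0, max(sc) + 1L, 3)
  lut[sc + 1L, ] <- palette[names(sc), ]
  flat <- lut[labels + 1L, ]
  flat <- sweep(flat, 2, tint, `*`)
  flat[flat > 1] <- 1
  array(flat, dim = c(nrow(labels), ncol(labels), 3))
}

#' Gray-world white balance
#'
#' Scales each channel so that all channel means equal their joint mean, then
#' clips to `[0, 1]`. Idempotent up to clipping.
#'
#' @param rgb A rows x cols x 3 array with values in `[0, 1]`.
#' @return The balanced array.
#' @export
white_balance <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be a rows x cols x 3 array")
  mu <- apply(rgb, 3, mean)
  if (any(mu == 0))
    stop("cannot white-balance: a channel mean is zero")
  target <- mean(mu)
  out <- sweep(rgb, 3, target / mu, `*`)
  out[out > 1] <- 1
  out[out < 0] <- 0
  out
}
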