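# Helper: render a synthetic section with fiducial disks at given centers.
disk_section <- function(centers_mm, spacing = c(0.1, 0.1), n = 140,
                         radius_mm = 0.45, index = 0L) {
  lab <- matrix(0L, n, n)
  xs <- (seq_len(n) - 1) * spacing[2]
  ys <- (seq_len(n) - 1) * spacing[1]
  for (r in seq_len(nrow(centers_mm))) {
    mask <- outer(ys, xs, function(y, x)
      (x - centers_mm[r, 1])^2 + (y - centers_mm[r, 2])^2 <= radius_mm^2)
    lab[mask] <- et_labels()[["fiducial"]]
  }
  section_image(lab, spacing, section_index = index)
}

test_that("fiducial centroids are recovered to sub-pixel accuracy", {
  ctrs <- rbind(c(3.21, 4.87), c(9.53, 3.02), c(6.44, 10.11))
  s <- disk_section(ctrs)
  det <- detect_fiducials(s)
  expect_false(attr(det, "unalignable"))
  expect_equal(nrow(det), 3L)
  got <- as.matrix(det[order(det$x_mm), c("x_mm", "y_mm")])
  want <- ctrs[order(ctrs[, 1]), ]
  expect_lt(max(abs(got - want)), 0.25 * 0.1)  # 0.25 px at 0.1 mm
})

test_that("detected disk areas match the analytic cross-section", {
  for (r in c(0.35, 0.45, 0.6)) {
    s <- disk_section(rbind(c(7.03, 6.97)), radius_mm = r)
    det <- detect_fiducials(s, expected_radius_mm = r)
    expect_equal(det$area_mm2, pi * r^2, tolerance = 0.05)
  }
})

test_that("sections without plausible fiducials are flagged unalignable", {
  s <- section_image(matrix(0L, 50, 50), c(0.1, 0.1), 0L)
  det <- detect_fiducials(s)
  expect_true(attr(det, "unalignable"))
  expect_equal(nrow(det), 0L)
  # a blob far larger than a needle is not plausible either
  big <- matrix(0L, 80, 80)
  big[10:70, 10:70] <- et_labels()[["fiducial"]]
  det2 <- detect_fiducials(section_image(big, c(0.1, 0.1), 0L))
  expect_true(attr(det2, "unalignable"))
})

straight_tracks <- function(ns = 12, jitter = 0, seed = 1) {
  base <- rbind(c(3, 4), c(10, 3.5), c(6.5, 10))
  with_seed_local <- function(code) {
    set.seed(seed)
    code
  }
  set.seed(seed)
  lapply(seq_len(ns), function(i) {
    pts <- base + matrix(stats::rnorm(6, 0, jitter), 3, 2)
    data.frame(x_mm = pts[, 1], y_mm = pts[, 2], area_mm2 = 0.6)
  })
}

test_that("correspondence is identity for straight tracks and is order-invariant", {
  dets <- straight_tracks(10)
  tracks <- correspond_tracks(dets, 0:9)
  expect_equal(nrow(tracks), 30L)
  for (f in 1:3) {
    tr <- tracks[tracks$fid == f, ]
    expect_lt(max(abs(tr$x_mm - tr$x_mm[1])), 1e-12)
  }
  # permute detection rows in some sections: same correspondence
  dets2 <- dets
  dets2[[3]] <- dets2[[3]][c(3, 1, 2), ]
  dets2[[7]] <- dets2[[7]][c(2, 3, 1), ]
  tracks2 <- correspond_tracks(dets2, 0:9)
  expect_equal(tracks2[order(tracks2$section_index, tracks2$fid),
                       c("fid", "x_mm", "y_mm")],
               tracks[order(tracks$section_index, tracks$fid),
                      c("fid", "x_mm", "y_mm")],
               tolerance = 1e-12)
})

test_that("correspondence survives jitter below half the fiducial spacing", {
  dets <- straight_tracks(20, jitter = 0.8, seed = 5)  # min spacing ~6.5 mm
  tracks <- correspond_tracks(dets, 0:19)
  # each fiducial id must stay near its base position throughout
  base <- rbind(c(3, 4), c(10, 3.5), c(6.5, 10))
  for (f in 1:3) {
    tr <- tracks[tracks$fid == f, ]
    d <- sqrt((tr$x_mm - mean(tr$x_mm))^2 + (tr$y_mm - mean(tr$y_mm))^2)
    expect_lt(max(d), 3)  # never jumps to another track
  }
})

test_that("already-colinear tracks give identity transforms at zero cost", {
  dets <- straight_tracks(8)
  tracks <- correspond_tracks(dets, 0:7)
  al <- fit_stack_alignment(tracks, (0:7) * 0.363, 0:7)
  for (tr in al$transforms) {
    expect_lt(abs(tr$rotation_deg), 1e-9)
    expect_lt(max(abs(tr$translation_mm)), 1e-9)
  }
  expect_lt(al$cost, 1e-18)
})

# Build exact noiseless tracks from tilted 3D lines, perturbed per section.
perturbed_line_tracks <- function(ns, trans_sd = 0.3, rot_sd = 2,
                                  noise_mm = 0, seed = 1) {
  set.seed(seed)
  z <- (seq_len(ns) - 1) * 0.363
  p0 <- rbind(c(3, 4), c(10, 3.5), c(6.5, 10))
  slope <- rbind(c(0.02, -0.01), c(-0.015, 0.012), c(0.008, 0.02))
  truth <- list()
  dets <- list()
  for (i in seq_len(ns)) {
    pts <- p0 + slope * z[i]
    tr <- rigid2d(stats::rnorm(1, 0, rot_sd),
                  c(stats::rnorm(1, 0, trans_sd),
                    stats::rnorm(1, 0, trans_sd)),
                  center_mm = c(7, 7))
    obs <- rigid2d_apply(tr, pts) +
      matrix(stats::rnorm(6, 0, noise_mm), 3, 2)
    truth[[i]] <- tr
    dets[[i]] <- data.frame(x_mm = obs[, 1], y_mm = obs[, 2],
                            area_mm2 = 0.6)
  }
  list(dets = dets, truth = truth, z = z)
}

test_that("known noiseless perturbations are recovered to numerical precision", {
  sim <- perturbed_line_tracks(20, seed = 2)
  tracks <- correspond_tracks(sim$dets, seq_len(20) - 1L)
  al <- fit_stack_alignment(tracks, sim$z, seq_len(20) - 1L)
  err <- transform_recovery_error(al$transforms, sim$truth, z_mm = sim$z)
  expect_lt(attr(err, "rms_rotation_deg"), 1e-6)
  expect_lt(attr(err, "rms_translation_mm"), 1e-6)
  expect_lt(al$rms_residual_mm, 1e-9)
})

test_that("the BCD cost never increases across iterations", {
  sim <- perturbed_line_tracks(15, noise_mm = 0.02, seed = 3)
  tracks <- correspond_tracks(sim$dets, seq_len(15) - 1L)
  al <- fit_stack_alignment(tracks, sim$z, seq_len(15) - 1L)
  ch <- al$cost_history
  expect_true(all(diff(ch) <= 1e-6 * pmax(ch[-length(ch)], 1e-30)))
})

test_that("post-fit residuals reflect the injected detection noise", {
  sigma <- 0.010
  rms <- vapply(1:20, function(s) {
    sim <- perturbed_line_tracks(25, noise_mm = sigma, seed = 100 + s)
    tracks <- correspond_tracks(sim$dets, seq_len(25) - 1L)
    fit_stack_alignment(tracks, sim$z,
                        seq_len(25) - 1L)$dof_rms_residual_mm
  }, 0)
  expect_gt(mean(rms), 0.7 * sigma)
  expect_lt(mean(rms), 1.3 * sigma)
})

test_that("the fit is gauge invariant", {
  sim <- perturbed_line_tracks(12, noise_mm = 0.02, seed = 4)
  tracks <- correspond_tracks(sim$dets, seq_len(12) - 1L)
  al1 <- fit_stack_alignment(tracks, sim$z, seq_len(12) - 1L)
  common <- rigid2d(13, c(0.7, -0.4), c(5, 5))
  tracks2 <- tracks
  moved <- rigid2d_apply(common, as.matrix(tracks[, c("x_mm", "y_mm")]))
  tracks2$x_mm <- moved[, 1]
  tracks2$y_mm <- moved[, 2]
  al2 <- fit_stack_alignment(tracks2, sim$z, seq_len(12) - 1L)
  expect_equal(al2$rms_residual_mm, al1$rms_residual_mm,
               tolerance = 1e-8)
  expect_equal(sort(abs(al2$residuals$norm)),
               sort(abs(al1$residuals$norm)), tolerance = 1e-8)
})

test_that("sections with too few fiducials get interpolated transforms", {
  sim <- perturbed_line_tracks(10, seed = 6)
  tracks <- correspond_tracks(sim$dets, seq_len(10) - 1L)
  tracks <- tracks[!(tracks$section_index == 4), ]  # no detections there
  al <- fit_stack_alignment(tracks, sim$z, seq_len(10) - 1L)
  expect_true(al$interpolated[5])
  expect_equal(sum(al$interpolated), 1L)
  # interpolated rotation lies between its neighbours
  r <- vapply(al$transforms, function(t) t$rotation_deg, 0)
  expect_true(r[5] >= min(r[4], r[6]) && r[5] <= max(r[4], r[6]))
})

test_that("alignment refuses stacks with too few usable sections", {
  sim <- perturbed_line_tracks(10, seed = 7)
  tracks <- correspond_tracks(sim$dets, seq_len(10) - 1L)
  thin <- tracks[tracks$section_index %in% c(0, 3, 9) |
                 tracks$fid == 1, ]
  thin <- thin[!(thin$fid == 1 & !(thin$section_index %in% c(0, 3, 9))), ]
  expect_error(fit_stack_alignment(thin, sim$z, seq_len(10) - 1L),
               "2 fiducials")
})

test_that("noiseless groove z assignment reproduces the cutting grid exactly", {
  proto <- protocol_spec(groove_noise_um = 0,
                         perturbation = list(translation_sd_mm = 0,
                                             rotation_sd_deg = 0,
                                             tilt_sd_deg = 0))
  gxy <- matrix(c(0, 7, 20, 13, 10, 0), 3, 2, byrow = TRUE)
  h <- 50 * section_period_mm(proto)
  groove <- t(vapply(0:49, function(k)
    simulate_groove_measurements(proto, k, gxy, h, c(10, 10),
                                 noise_mm = c(0, 0, 0)), numeric(3)))
  zc <- assign_z(groove, proto, gxy, h, c(10, 10))
  expect_equal(zc$z_mm, (0:49) * 0.363, tolerance = 1e-12)
  expect_true(all(abs(zc$tilt_deg) < 1e-9))
})

test_that("a constant groove offset shifts z uniformly with zero tilt", {
  proto <- protocol_spec(groove_noise_um = 0)
  gxy <- matrix(c(0, 7, 20, 13, 10, 0), 3, 2, byrow = TRUE)
  h <- 50 * section_period_mm(proto)
  groove <- t(vapply(0:9, function(k)
    simulate_groove_measurements(proto, k, gxy, h, c(10, 10),
                                 noise_mm = c(0, 0, 0)), numeric(3)))
  zc0 <- assign_z(groove, proto, gxy, h, c(10, 10))
  zc1 <- assign_z(groove + 0.05, proto, gxy, h, c(10, 10))
  expect_equal(zc1$z_mm, zc0$z_mm - 0.05, tolerance = 1e-12)
  expect_true(all(abs(zc1$tilt_deg) < 1e-9))
})

test_that("a synthetic tilt of half a degree is recovered closely", {
  proto <- protocol_spec(groove_noise_um = 0)
  gxy <- matrix(c(0, 7, 20, 13, 10, 0), 3, 2, byrow = TRUE)
  h <- 50 * section_period_mm(proto)
  groove <- t(vapply(0:9, function(k)
    simulate_groove_measurements(proto, k, gxy, h, c(10, 10),
                                 tilt_deg = c(0.5, -0.2),
                                 noise_mm = c(0, 0, 0)), numeric(3)))
  zc <- assign_z(groove, proto, gxy, h, c(10, 10))
  expect_lt(max(abs(zc$tilt_deg[, 1] - 0.5)), 0.05)
  expect_lt(max(abs(zc$tilt_deg[, 2] + 0.2)), 0.05)
})

test_that("an outlier groove readout falls back to the median", {
  proto <- protocol_spec(groove_noise_um = 5)
  gxy <- matrix(c(0, 7, 20, 13, 10, 0), 3, 2, byrow = TRUE)
  h <- 50 * section_period_mm(proto)
  g <- simulate_groove_measurements(proto, 3, gxy, h, c(10, 10),
                                    noise_mm = c(0, 0, 0))
  g[2] <- g[2] + 2  # gross outlier
  zc <- assign_z(rbind(g), proto, gxy, h, c(10, 10))
  expect_true(zc$fallback[1])
  expect_true(all(is.na(zc$tilt_deg[1, ])))
  expect_equal(zc$z_mm[1], 3 * 0.363, tolerance = 1e-9)
})

test_that("non-monotone corrected z is rejected with the offending indices", {
  proto <- protocol_spec(groove_noise_um = 0)
  gxy <- matrix(c(0, 7, 20, 13, 10, 0), 3, 2, byrow = TRUE)
  h <- 50 * section_period_mm(proto)
  groove <- t(vapply(c(0, 1, 1, 3), function(k)
    simulate_groove_measurements(proto, k, gxy, h, c(10, 10),
                                 noise_mm = c(0, 0, 0)), numeric(3)))
  expect_error(assign_z(groove, proto, gxy, h, c(10, 10)), "non-monotone")
})

# Exact fiducial tracks taken from the phantom's true needle lines,
# optionally perturbed per section by known transforms.
exact_tracks <- function(ph, sections, perturb = NULL) {
  idx <- vapply(sections, function(s) s$section_index, 1L)
  z <- vapply(sections, function(s) s$nominal_z_mm, 0) + 0.0165
  dets <- lapply(seq_along(sections), function(i) {
    pts <- t(vapply(ph$spec$fiducials, function(f)
      tuberecon:::fiducial_at_z(f, z[i]), numeric(2)))
    if (!is.null(perturb)) pts <- rigid2d_apply(perturb[[i]], pts)
    data.frame(x_mm = pts[, 1], y_mm = pts[, 2], area_mm2 = 0.6)
  })
  list(tracks = correspond_tracks(dets, idx), idx = idx, z = z)
}

test_that("assembly with identity transforms equals plain stacking", {
  ph <- tiny_phantom()
  proto <- tiny_protocol(
    perturbation = list(translation_sd_mm = 0, rotation_sd_deg = 0,
                        tilt_sd_deg = 0),
    groove_noise_um = 0, lost_section_indices = integer(0))
  sec <- simulate_sectioning(ph, proto)
  et <- exact_tracks(ph, sec)
  al <- fit_stack_alignment(et$tracks, et$z, et$idx)
  for (tr in al$transforms) {
    expect_lt(abs(tr$rotation_deg), 1e-9)
    expect_lt(max(abs(tr$translation_mm)), 1e-9)
  }
  vol <- assemble(sec, al)
  for (i in seq_along(sec))
    expect_identical(vol$voxels[, , sec[[i]]$section_index + 1L],
                     sec[[i]]$labels)
  expect_equal(vol$spacing_mm[3], 0.363)
})

test_that("full realignment reproduces the phantom planes after perturbation", {
  ph <- tiny_phantom()
  proto0 <- tiny_protocol(
    perturbation = list(translation_sd_mm = 0, rotation_sd_deg = 0,
                        tilt_sd_deg = 0),
    groove_noise_um = 0, lost_section_indices = integer(0))
  sec <- simulate_sectioning(ph, proto0)
  # exact one-pixel translations (alternating sign, so they are not a pure
  # gauge motion) applied to both the images and the exact tracks are
  # recovered and inverted exactly
  perturb <- lapply(seq_along(sec), function(i)
    rigid2d(0, c(0.1 * (-1)^i, 0)))
  sec_shift <- lapply(seq_along(sec), function(i) {
    s <- sec[[i]]
    s$labels <- tuberecon:::warp_labels(s$labels, s$spacing_mm,
                                        perturb[[i]])
    s
  })
  attributes(sec_shift) <- attributes(sec)
  et <- exact_tracks(ph, sec_shift, perturb = perturb)
  al <- fit_stack_alignment(et$tracks, et$z, et$idx)
  vol <- assemble(sec_shift, al)
  d <- dim(vol$voxels)
  # compare away from the border that scrolls out of view
  for (i in seq_along(sec))
    expect_identical(
      vol$voxels[3:(d[1] - 3), 3:(d[2] - 3), sec[[i]]$section_index + 1L],
      sec[[i]]$labels[3:(d[1] - 3), 3:(d[2] - 3)])
})

test_that("assembly enforces the voxel budget", {
  ph <- tiny_phantom()
  sec <- simulate_sectioning(ph, tiny_protocol(seed = 1))
  al <- align_series(sec)
  expect_error(assemble(sec, al, max_voxels = 1000), "budget")
})
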