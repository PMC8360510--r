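test_that("zero-twist, zero-taper phantom has identical end cross-sections", {
  spec <- tiny_phantom_spec(twist_total_deg = 0, taper = 0,
                            lumen_gap_mm = 0, axis_bow_mm = 0,
                            ofp_taper = 0)
  spec$compartment_offsets$bone$from_fraction <- 2  # no bone anywhere
  ph <- build_phantom(spec)
  zs <- which(!is.na(ph$truth$twist_deg))
  first <- ph$volume$voxels[, , zs[1]] == 1L
  last <- ph$volume$voxels[, , zs[length(zs)]] == 1L
  expect_identical(first, last)
})

test_that("38-degree twist shows as a 38-degree principal-axis rotation", {
  ph <- default_phantom()
  v <- ph$volume$voxels
  sp <- ph$volume$spacing_mm[1:2]
  zs <- which(!is.na(ph$truth$twist_deg))
  o1 <- slice_orientation(v[, , zs[1]] == 1L, sp)
  o2 <- slice_orientation(v[, , zs[length(zs)]] == 1L, sp)
  expect_equal(o2$theta_deg - o1$theta_deg, 38, tolerance = 2 / 38)
})

test_that("rasterization agrees with an independent point-in-shape oracle", {
  ph <- tiny_phantom()
  spec <- ph$spec
  sc <- et_labels()
  d <- dim(ph$volume$voxels)
  for (k in c(8, 15, 22)) {  # three tube planes
    z <- (k - 0.5) * spec$voxel_mm[3]
    plane <- ph$volume$voxels[, , k]
    xs <- (seq_len(d[2]) - 0.5) * spec$voxel_mm[1]
    ys <- (seq_len(d[1]) - 0.5) * spec$voxel_mm[2]
    # oracle over a subgrid (full plane is slow in scalar code)
    grid <- expand.grid(i = seq(1, d[1], by = 3), j = seq(1, d[2], by = 3))
    got <- plane[cbind(grid$i, grid$j)]
    keep <- !(got %in% sc[c("fiducial", "groove")])
    want <- mapply(function(i, j) oracle_classify_point(spec, xs[j], ys[i], z),
                   grid$i[keep], grid$j[keep])
    expect_identical(names(sc)[match(got[keep], sc)], unname(want))
  }
})

test_that("phantom compartment voxel counts match the oracle counts", {
  ph <- tiny_phantom()
  spec <- ph$spec
  sc <- et_labels()
  k <- 15
  z <- (k - 0.5) * spec$voxel_mm[3]
  plane <- ph$volume$voxels[, , k]
  d <- dim(plane)
  xs <- (seq_len(d[2]) - 0.5) * spec$voxel_mm[1]
  ys <- (seq_len(d[1]) - 0.5) * spec$voxel_mm[2]
  # count only where no fiducial/groove was painted on top
  keep <- !(plane %in% sc[c("fiducial", "groove")])
  oracle_labels <- vapply(which(keep), function(lin) {
    i <- (lin - 1) %% d[1] + 1
    j <- (lin - 1) %/% d[1] + 1
    oracle_classify_point(spec, xs[j], ys[i], z)
  }, "")
  for (nm in c("cartilage", "lumen", "mucosa", "TVPM", "LVPM", "OFP")) {
    expect_identical(sum(plane[keep] == sc[[nm]]),
                     sum(oracle_labels == nm))
  }
})

test_that("a needle through the cartilage aborts naming the fiducial", {
  spec <- tiny_phantom_spec()
  # put fiducial 2 on the tube axis
  spec$fiducials[[2]]$entry_mm <- c(7, 7, 0)
  spec$fiducials[[2]]$direction <- c(0, 0, 1)
  expect_error(build_phantom(spec), "fiducial 2 intersects")
})

test_that("degenerate axes and bad fiducial angles are rejected", {
  spec <- tiny_phantom_spec()
  spec$tube_axis[3, 3] <- spec$tube_axis[2, 3]
  expect_error(build_phantom(spec), "degenerate axis")
  spec2 <- tiny_phantom_spec()
  spec2$fiducials[[1]]$direction <- c(sin(10 * pi / 180), 0,
                                      cos(10 * pi / 180))
  expect_error(build_phantom(spec2), "fiducial 1 deviates")
})

test_that("phantom generation is deterministic", {
  a <- build_phantom(tiny_phantom_spec(roughness_mm = 0.02, seed = 5))
  b <- build_phantom(tiny_phantom_spec(roughness_mm = 0.02, seed = 5))
  expect_identical(a$volume$voxels, b$volume$voxels)
  c3 <- build_phantom(tiny_phantom_spec(roughness_mm = 0.02, seed = 6))
  expect_false(identical(a$volume$voxels, c3$volume$voxels))
})

test_that("ground-truth twist is affine in axial position", {
  ph <- tiny_phantom()
  ok <- !is.na(ph$truth$twist_deg)
  fit <- stats::lm(ph$truth$twist_deg[ok] ~ ph$truth$z_mm[ok])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("voxelized fiducial centerlines stay within a voxel of the line", {
  ph <- tiny_phantom()
  sc <- et_labels()
  v <- ph$volume$voxels
  sp <- ph$volume$spacing_mm
  for (f in seq_len(3)) {
    devs <- c()
    for (k in seq_len(dim(v)[3])) {
      z <- (k - 0.5) * sp[3]
      truth <- tuberecon:::fiducial_at_z(ph$spec$fiducials[[f]], z)
      mask <- v[, , k] == sc[["fiducial"]]
      idx <- which(mask, arr.ind = TRUE)
      pos <- cbind((idx[, 2] - 0.5) * sp[2], (idx[, 1] - 0.5) * sp[1])
      dist <- sqrt(rowSums(sweep(pos, 2, truth)^2))
      near <- dist < 2 * ph$spec$fiducials[[f]]$radius_mm
      if (!any(near)) next
      ctr <- colMeans(pos[near, , drop = FALSE])
      devs <- c(devs, sqrt(sum((ctr - truth)^2)))
    }
    expect_lt(sqrt(mean(devs^2)), sp[1])  # < 1 voxel RMS
  }
})

test_that("reference volume maps labels to densities and conserves the mean", {
  arr <- array(sample(c(0L, 1L, 7L), 12 * 12 * 6, replace = TRUE),
               dim = c(12, 12, 6))
  vol <- label_volume(arr, spacing_mm = c(0.1, 0.1, 0.15))
  ref <- make_reference_volume(vol, resolution_mm = 0.3)
  expect_equal(dim(ref$values), c(4, 4, 3))
  # box averaging over exactly divisible dims conserves the mean
  lut <- c("0" = 0.05, "1" = 0.55, "7" = 0.90)
  mapped <- array(lut[as.character(arr)], dim = dim(arr))
  expect_equal(mean(ref$values), mean(mapped), tolerance = 1e-6)
})

test_that("identity-resolution reference volume is a pure density lookup", {
  arr <- array(0L, dim = c(4, 4, 4))
  arr[2, 3, 1] <- 7L
  vol <- label_volume(arr, spacing_mm = c(0.3, 0.3, 0.3))
  ref <- make_reference_volume(vol, resolution_mm = 0.3)
  expect_equal(dim(ref$values), dim(arr))
  expect_equal(ref$values[2, 3, 1], 0.90)
  expect_true(all(ref$values[arr == 0L] == 0.05))
})

test_that("reference volume rejects finer-than-source resolution", {
  vol <- label_volume(array(0L, dim = c(4, 4, 4)),
                      spacing_mm = c(0.3, 0.3, 0.3))
  expect_error(make_reference_volume(vol, resolution_mm = 0.1),
               "resolution")
  expect_true(all(make_reference_volume(vol, 0.3)$values == 0.05))
})
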