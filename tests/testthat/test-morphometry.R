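test_that("areas are exact pixel sums", {
  m <- matrix(0L, 6, 6)
  m[2:3, 2:3] <- 1L
  expect_equal(compartment_area(m, "cartilage", c(0.1, 0.1)), 0.04)
  expect_equal(compartment_area(matrix(0L, 5, 5), "lumen", c(0.1, 0.1)), 0)
  set.seed(10)
  for (i in 1:10) {
    r <- matrix(sample(0:2, 400, replace = TRUE), 20, 20)
    sp <- stats::runif(2, 0.05, 0.4)
    # brute-force per-pixel summation oracle
    want <- 0
    for (a in 1:20) for (b in 1:20)
      if (r[a, b] == 1L) want <- want + sp[1] * sp[2]
    expect_equal(compartment_area(r, 1L, sp), want)
  }
  expect_error(compartment_area(m, "nope", c(1, 1)), "unknown label")
  expect_error(compartment_area(m, 42L, c(1, 1)), "unknown label")
})

test_that("disk perimeters approach the analytic circumference", {
  for (r in c(20, 30, 50)) {
    p <- compartment_perimeter(disk_mask(r) * 1L, 1L, c(1, 1))
    expect_equal(p, 2 * pi * r, tolerance = 0.02)
  }
})

test_that("perimeters equal the independent marching-squares oracle", {
  expect_equal(compartment_perimeter(matrix(0L, 5, 5), 1L, c(1, 1)), 0)
  set.seed(11)
  for (i in 1:15) {
    m <- matrix(as.integer(stats::runif(144) < 0.4), 12, 12)
    sp <- stats::runif(2, 0.5, 1.5)
    got <- compartment_perimeter(m, 1L, sp)
    want <- oracle_perimeter(m == 1L, sp)
    expect_equal(got, want, tolerance = 1e-9)
    # raw (unsmoothed) contour lengths agree as well
    expect_equal(compartment_perimeter(m, 1L, sp, smooth_window = 1),
                 oracle_perimeter(m == 1L, sp, 1), tolerance = 1e-9)
  }
})

test_that("any nonempty mask has positive perimeter", {
  px <- matrix(0L, 5, 5)
  px[3, 3] <- 1L
  expect_gt(compartment_perimeter(px, 1L, c(1, 1)), 0)
  line <- matrix(0L, 8, 8)
  line[4, 2:7] <- 1L
  expect_gt(compartment_perimeter(line, 1L, c(1, 1)), 0)
})

test_that("holes count toward the total but not the outer perimeter", {
  m <- matrix(0L, 20, 20)
  m[4:16, 4:16] <- 1L
  m[8:12, 8:12] <- 0L
  total <- compartment_perimeter(m, 1L, c(1, 1))
  outer_only <- compartment_perimeter(m, 1L, c(1, 1), outer_only = TRUE)
  full <- m
  full[8:12, 8:12] <- 1L
  expect_equal(outer_only, compartment_perimeter(full, 1L, c(1, 1)),
               tolerance = 1e-12)
  expect_gt(total, outer_only)
})

test_that("area is additive over disjoint masks and perimeter obeys the isoperimetric bound", {
  set.seed(12)
  a <- matrix(0L, 15, 15)
  a[2:6, 2:6] <- 1L
  b <- matrix(0L, 15, 15)
  b[9:13, 8:14] <- 1L
  expect_equal(compartment_area(a + b, 1L, c(0.2, 0.3)),
               compartment_area(a, 1L, c(0.2, 0.3)) +
                 compartment_area(b, 1L, c(0.2, 0.3)))
  for (r in c(8, 15)) {
    m <- disk_mask(r) * 1L
    per <- compartment_perimeter(m, 1L, c(1, 1))
    area <- compartment_area(m, 1L, c(1, 1))
    expect_gte(per^2, 4 * pi * area * 0.98)
  }
})

test_that("in-plane islands joined through the adjacent section form one unit", {
  arr <- array(0L, dim = c(3, 3, 3))
  arr[1, 1, 1] <- 1L
  arr[3, 3, 1] <- 1L   # two islands in plane 1, far apart
  arr[2, 2, 2] <- 1L   # bridge in plane 2, corner-adjacent to both
  merged <- merge_perforated(arr, 1L)
  expect_equal(merged$n_units, 1L)
  expect_equal(merged$merge_log$islands_2d, c(2L, 1L, 0L))
  expect_equal(merged$merge_log$units_3d, c(1L, 1L, 0L))
})

test_that("islands never adjacent in 3D stay separate units", {
  arr <- array(0L, dim = c(5, 5, 3))
  arr[1, 1, 1] <- 1L
  arr[5, 5, 3] <- 1L
  merged <- merge_perforated(arr, 1L)
  expect_equal(merged$n_units, 2L)
})

test_that("3D component labelling matches the union-find oracle", {
  set.seed(13)
  for (i in 1:6) {
    d <- sample(8:20, 3, replace = TRUE)
    arr <- array(as.integer(stats::runif(prod(d)) < 0.25), dim = d)
    got <- merge_perforated(arr, 1L)
    want <- oracle_components_26(arr == 1L)
    expect_equal(got$n_units, max(want))
    expect_true(same_partition(got$component_map, want))
  }
})

test_that("profiles follow the constructed specimen geometry", {
  ph <- default_phantom()
  sec <- simulate_sectioning(ph, protocol_spec(seed = 5))
  al <- align_series(sec)
  prof <- profile_stack(sec, al)
  expect_s3_class(prof, "morphometry_profile")
  expect_equal(nrow(prof), 98L * 5L)
  expect_true(all(prof$area_mm2 >= 0))
  expect_true(all(prof$perimeter_mm >= 0))
  expect_true(all((prof$perimeter_mm == 0) == (prof$area_mm2 == 0)))
  cart <- prof[prof$compartment == "cartilage", ]
  # near-constant cartilage cross-section
  expect_lt(stats::sd(cart$area_mm2) / mean(cart$area_mm2), 0.10)
  # circumference decreases toward the isthmus
  fit <- stats::lm(perimeter_mm ~ z_mm, data = cart)
  expect_lt(stats::coef(fit)[2], 0)
  expect_lt(stats::cor(cart$z_mm, cart$perimeter_mm), -0.9)
  # lumen open only near the pharyngeal orifice
  lum <- prof[prof$compartment == "lumen", ]
  zmax <- max(lum$z_mm)
  expect_gt(sum(lum$area_mm2[lum$z_mm < 0.15 * zmax]), 0)
  expect_true(all(lum$area_mm2[lum$z_mm > 0.25 * zmax] == 0))
  # fat pad shrinks monotonically toward the isthmus
  ofp <- prof[prof$compartment == "OFP", ]
  expect_lt(stats::cor(ofp$z_mm, ofp$area_mm2), -0.95)
  sm <- stats::filter(ofp$area_mm2, rep(1 / 5, 5), sides = 2)
  expect_true(all(diff(sm[3:95]) <= 0.05 * max(ofp$area_mm2)))
  expect_gt(min(ofp$area_mm2[1:10]), max(ofp$area_mm2[89:98]))
})

test_that("a single-section stack profiles to one row per compartment", {
  ph <- tiny_phantom()
  sec <- simulate_sectioning(ph, tiny_protocol(
    perturbation = list(translation_sd_mm = 0, rotation_sd_deg = 0,
                        tilt_sd_deg = 0),
    groove_noise_um = 0, lost_section_indices = integer(0)))[8]
  prof <- profile_stack(sec)
  expect_equal(nrow(prof), 5L)
  expect_equal(sort(unique(prof$compartment)),
               sort(c("cartilage", "lumen", "OFP", "TVPM", "LVPM")))
})

test_that("mucosa is profiled only on request", {
  ph <- tiny_phantom()
  sec <- simulate_sectioning(ph, tiny_protocol(
    perturbation = list(translation_sd_mm = 0, rotation_sd_deg = 0,
                        tilt_sd_deg = 0),
    groove_noise_um = 0, lost_section_indices = integer(0)))[5:8]
  prof <- profile_stack(sec, compartments = c("cartilage", "mucosa"))
  expect_true("mucosa" %in% prof$compartment)
  expect_gt(sum(prof$area_mm2[prof$compartment == "mucosa"]), 0)
})
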