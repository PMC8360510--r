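# Shared fixtures: a small fast phantom for unit tests and the full-size
# fixture phantom (built once per session) for the end-to-end checks.

tiny_phantom_spec <- function(twist_total_deg = 20, taper = 0.35,
                              lumen_gap_mm = 0.25, axis_bow_mm = 0.4,
                              ofp_taper = 0.6, ...) {
  unitv <- function(v) v / sqrt(sum(v^2))
  phantom_spec(
    block_size_mm = c(14, 14, 6), voxel_mm = c(0.1, 0.1, 0.2),
    axis_z_range_mm = c(0.5, 5.5), twist_total_deg = twist_total_deg,
    axis_bow_mm = axis_bow_mm,
    fiducials = list(
      list(entry_mm = c(11.5, 7, 0), direction = unitv(c(0.01, -0.01, 1)),
           radius_mm = 0.45),
      list(entry_mm = c(4, 11, 0), direction = unitv(c(-0.01, 0.01, 1)),
           radius_mm = 0.45),
      list(entry_mm = c(4.5, 3.5, 0), direction = unitv(c(0.005, 0.01, 1)),
           radius_mm = 0.45)),
    grooves = list(list(face = "x-", pos_mm = 4),
                   list(face = "x+", pos_mm = 10),
                   list(face = "y-", pos_mm = 7)),
    cartilage_profile = list(medial_mm = 3, lateral_mm = 1.3,
                             thickness_mm = 0.5, taper = taper,
                             thickness_exponent = 0.8),
    compartment_offsets = list(
      TVPM = list(from = c(0.3, -0.9), to = c(1.8, -1.2),
                  halfwidth_mm = 0.4),
      LVPM = list(from = c(-1.0, -1.3), to = c(-0.1, -1.7),
                  halfwidth_mm = 0.45),
      OFP = list(center = c(1.6, -0.4), radius_mm = 0.65,
                 taper = ofp_taper),
      bone = list(center = c(-1.4, 0.6), radius_mm = 0.55,
                  from_fraction = 0.85)),
    lumen_gap_mm = lumen_gap_mm, mucosa_thickness_mm = 0.15, ...)
}

# Protocol matching the tiny phantom's 6 mm depth: 16 sections.
tiny_protocol <- function(...) {
  protocol_spec(n_sections = 16, split_into_blocks = 2, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_phantom <- function() cached("tiny", build_phantom(tiny_phantom_spec()))

default_phantom <- function() cached("default", build_phantom(phantom_spec()))

disk_mask <- function(r, n = 2 * r + 11, center = (n + 1) / 2) {
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  matrix((ij$i - center)^2 + (ij$j - center)^2 <= r^2, n, n)
}

ellipse_mask <- function(a, b, theta_deg = 0, n = 2 * max(a, b) + 11) {
  ctr <- (n + 1) / 2
  th <- theta_deg * pi / 180
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  # x along columns, y along rows; rotate by -theta to test +theta
  x <- ij$j - ctr
  y <- ij$i - ctr
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}

sphere_volume_fixture <- function(r = 10, spacing = c(1, 1, 1)) {
  n <- 2 * r + 5
  ctr <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  arr <- array(as.integer((g$i - ctr)^2 + (g$j - ctr)^2 +
                            (g$k - ctr)^2 <= r^2), dim = c(n, n, n))
  label_volume(arr, spacing_mm = spacing)
}

random_proper_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
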