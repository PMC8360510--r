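# Independent oracles, deliberately implemented on different code paths
# from the package: a scalar point-in-shape rasterizer, a hand-rolled
# marching-squares contour tracer, and a union-find 3D component labeller.

# --- point-in-shape oracle for the phantom cross-section -------------------

oracle_point_distance_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

# Classify one physical point (x, y) at plane z of a phantom spec into a
# label name, mirroring the paint precedence scalar-by-scalar.
oracle_classify_point <- function(spec, x, y, z) {
  ax <- spec$tube_axis
  if (z < min(ax[, 3]) || z > max(ax[, 3])) return("background")
  seglen <- sqrt(rowSums(diff(ax)^2))
  arc <- c(0, cumsum(seglen))
  s <- stats::approx(ax[, 3], arc / max(arc), z)$y
  cx <- stats::approx(ax[, 3], ax[, 1], z)$y
  cy <- stats::approx(ax[, 3], ax[, 2], z)$y
  th <- spec$twist_total_deg * s * pi / 180
  dx <- x - cx
  dy <- y - cy
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  pr <- spec$cartilage_profile
  f <- 1 - pr$taper * s
  Lm <- pr$medial_mm * f
  Ll <- pr$lateral_mm * f
  tt <- pr$thickness_mm / f^pr$thickness_exponent
  p <- c(u, v)
  lab <- "background"
  off <- spec$compartment_offsets
  ofr <- off$OFP$radius_mm * (1 - off$OFP$taper * s)
  if (sum((p - off$OFP$center)^2) <= ofr^2) lab <- "OFP"
  if (oracle_point_distance_to_segment(p, off$TVPM$from, off$TVPM$to) <=
      off$TVPM$halfwidth_mm) lab <- "TVPM"
  if (oracle_point_distance_to_segment(p, off$LVPM$from, off$LVPM$to) <=
      off$LVPM$halfwidth_mm) lab <- "LVPM"
  if (s >= off$bone$from_fraction &&
      sum((p - off$bone$center)^2) <= off$bone$radius_mm^2) lab <- "bone"
  gap <- spec$lumen_gap_mm * max(0, 1 - s / spec$lumen_open_fraction)
  v_seam <- -(tt / 2 + spec$mucosa_thickness_mm + gap / 2)
  dseam <- oracle_point_distance_to_segment(
    p, c(-Lm / 2 + 1.0, v_seam), c(Lm / 2 - 0.8, v_seam))
  if (dseam <= gap / 2 + spec$mucosa_thickness_mm) lab <- "mucosa"
  if (gap > 0 && dseam <= gap / 2) lab <- "lumen"
  if (oracle_point_distance_to_segment(p, c(-Lm / 2, 0), c(Lm / 2, 0)) <=
      tt / 2 ||
      oracle_point_distance_to_segment(p, c(-Lm / 2, 0),
                                       c(-Lm / 2, -Ll)) <= tt / 2)
    lab <- "cartilage"
  lab
}

# --- independent marching squares ------------------------------------------

# Trace all 0.5-level contours of a zero-padded binary mask by walking cell
# edges. Returns a list of closed polygons (x, y in physical units with the
# same coordinate convention as the package: x = (col-1)*sx, y =
# (row-1)*sy). Standard 16-case marching squares with midpoint
# interpolation; both saddle cases use the fixed (W,N)+(E,S) pairing,
# which leaves every edge midpoint incident to exactly two segments so the
# loop linking is unique.
oracle_marching_squares <- function(mask, spacing_mm) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  m <- matrix(0, ny + 2, nx + 2)
  m[2:(ny + 1), 2:(nx + 1)] <- mask
  # cell (i, j) has corners m[i, j] (top-left in row space), m[i, j+1],
  # m[i+1, j+1], m[i+1, j]. Edges: N between (i,j)-(i,j+1), E between
  # (i,j+1)-(i+1,j+1), S between (i+1,j)-(i+1,j+1), W between (i,j)-(i+1,j).
  # Midpoint coordinates in (row, col) units relative to padded indices.
  edge_mid <- function(i, j, e) {
    switch(e,
           N = c(i, j + 0.5),
           S = c(i + 1, j + 0.5),
           W = c(i + 0.5, j),
           E = c(i + 0.5, j + 1))
  }
  segs <- list()
  for (i in seq_len(ny + 1)) {
    for (j in seq_len(nx + 1)) {
      tl <- m[i, j] > 0.5
      tr <- m[i, j + 1] > 0.5
      br <- m[i + 1, j + 1] > 0.5
      bl <- m[i + 1, j] > 0.5
      code <- tl + 2 * tr + 4 * br + 8 * bl
      ee <- switch(code + 1,
        NULL,                       # 0
        list(c("W", "N")),          # 1: tl
        list(c("N", "E")),          # 2: tr
        list(c("W", "E")),          # 3: tl+tr
        list(c("E", "S")),          # 4: br
        list(c("W", "N"), c("E", "S")), # 5: saddle tl+br
        list(c("N", "S")),          # 6: tr+br
        list(c("W", "S")),          # 7: all but bl
        list(c("S", "W")),          # 8: bl
        list(c("S", "N")),          # 9: tl+bl
        list(c("W", "N"), c("E", "S")), # 10: saddle tr+bl
        list(c("S", "E")),          # 11: all but br
        list(c("E", "W")),          # 12: bl+br
        list(c("E", "N")),          # 13: all but tr
        list(c("N", "W")),          # 14: all but tl
        NULL)                       # 15
      if (is.null(ee)) next
      for (p in ee)
        segs[[length(segs) + 1L]] <- rbind(edge_mid(i, j, p[1]),
                                           edge_mid(i, j, p[2]))
    }
  }
  if (length(segs) == 0) return(list())
  # link segments into closed loops by matching endpoints
  key <- function(pt) paste(round(pt[1] * 2), round(pt[2] * 2))
  ends <- new.env(parent = emptyenv())
  for (k in seq_along(segs)) {
    for (e in 1:2) {
      kk <- key(segs[[k]][e, ])
      ends[[kk]] <- c(if (!is.null(ends[[kk]])) ends[[kk]], k)
    }
  }
  used <- logical(length(segs))
  loops <- list()
  for (k in seq_along(segs)) {
    if (used[k]) next
    used[k] <- TRUE
    loop <- list(segs[[k]][1, ], segs[[k]][2, ])
    repeat {
      cur <- loop[[length(loop)]]
      cand <- setdiff(ends[[key(cur)]], which(used))
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      nk <- cand[1]
      used[nk] <- TRUE
      nxt <- if (key(segs[[nk]][1, ]) == key(cur)) segs[[nk]][2, ]
             else segs[[nk]][1, ]
      loop[[length(loop) + 1L]] <- nxt
    }
    pts <- do.call(rbind, loop)
    loops[[length(loops) + 1L]] <- list(
      x = (pts[, 2] - 2) * spacing_mm[2],
      y = (pts[, 1] - 2) * spacing_mm[1])
  }
  loops
}

# Perimeter from the oracle contours with the same closed-polygon smoothing
# definition as the package estimator.
oracle_perimeter <- function(mask, spacing_mm, smooth_window = 5) {
  loops <- oracle_marching_squares(mask, spacing_mm)
  total <- 0
  for (lp in loops) {
    x <- lp$x
    y <- lp$y
    n <- length(x) - 1L
    w <- min(smooth_window, if (n %% 2L == 0L) n - 1L else n)
    h <- (w - 1L) %/% 2L
    if (h >= 1L) {
      xs <- numeric(n)
      ys <- numeric(n)
      for (i in seq_len(n)) {
        sel <- ((i - 1 + (-h:h)) %% n) + 1
        xs[i] <- mean(x[sel])
        ys[i] <- mean(y[sel])
      }
      x <- c(xs, xs[1])
      y <- c(ys, ys[1])
    }
    total <- total + sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  total
}

# --- union-find 3D connected components ------------------------------------

oracle_components_26 <- function(mask) {
  d <- dim(mask)
  parent <- seq_len(prod(d))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (mask[ii, jj, kk]) union(lin(i, j, k), lin(ii, jj, kk))
    }
  }
  roots <- vapply(which(mask), function(i) as.integer(find(i)), 1L)
  out <- array(0L, dim = d)
  out[which(mask)] <- as.integer(factor(roots))
  out
}

# Compare two component labelings up to renaming of ids.
same_partition <- function(a, b) {
  fa <- a[a > 0 | b > 0]
  fb <- b[a > 0 | b > 0]
  if (any((fa == 0) != (fb == 0))) return(FALSE)
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}
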