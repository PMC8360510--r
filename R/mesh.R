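# Surface extraction from label volumes and binary STL input/output. The
# isosurface of the 0.5 level of a binary mask is extracted by marching
# tetrahedra on the Freudenthal decomposition of the voxel grid (each cell
# between eight voxel centers is split into six tetrahedra sharing the main
# diagonal; every tetrahedron crossed by the level set contributes one or
# two triangles with vertices at the crossing-edge midpoints). Using the
# same decomposition in every cell makes adjacent cells agree on their
# shared-face triangulation, so the resulting surface is watertight
# whenever the structure does not touch the volume boundary (the mask is
# padded with background to guarantee this).

# The six tetrahedra: corner offsets within a unit cell, each sharing the
# main diagonal (0,0,0)-(1,1,1).
freudenthal_tets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    e <- diag(3)
    rbind(c(0, 0, 0), e[p[1], ], e[p[1], ] + e[p[2], ], c(1, 1, 1))
  })
}

# For one tetrahedron (4 x 3 corner offsets) and one inside/outside code
# (bit i set = corner i inside), the triangles as a list of 3 x 3 matrices
# of vertex positions in doubled cell units (so all values are integers).
tet_triangles <- function(corners, code) {
  inside <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
  outside <- setdiff(1:4, inside)
  if (length(inside) == 0L || length(inside) == 4L) return(list())
  mid <- function(a, b) corners[a, ] + corners[b, ]  # doubled units
  tris <- if (length(inside) == 1L) {
    a <- inside
    b <- outside
    list(rbind(mid(a, b[1]), mid(a, b[2]), mid(a, b[3])))
  } else if (length(inside) == 3L) {
    b <- outside
    a <- inside
    list(rbind(mid(a[1], b), mid(a[2], b), mid(a[3], b)))
  } else {
    a <- inside
    b <- outside
    q <- rbind(mid(a[1], b[1]), mid(a[1], b[2]),
               mid(a[2], b[2]), mid(a[2], b[1]))
    list(q[c(1, 2, 3), ], q[c(1, 3, 4), ])
  }
  # orient outward: normal away from the inside corners
  ref <- colMeans(corners[inside, , drop = FALSE]) * 2
  lapply(tris, function(tri) {
    n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * (colMeans(tri) - ref)) < 0) tri[c(1, 3, 2), ] else tri
  })
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Precomputed triangle tables: tri_table[[tet]][[code + 1]] is a list of
# 3 x 3 integer matrices in doubled cell units.
tri_tables <- local({
  tets <- freudenthal_tets()
  lapply(tets, function(corners)
    lapply(0:15, function(code) tet_triangles(corners, code)))
})

#' Extract a compartment surface mesh
#'
#' Marching tetrahedra at the 0.5 level of the compartment's binary mask,
#' with the anisotropic voxel spacing applied, followed by optional
#' Laplacian smoothing guarded against volume shrinkage.
#'
#' @param volume A [label_volume()] (or 3D array with `spacing_mm` given).
#' @param label Compartment name or label value; must be present.
#' @param smoothing_iterations Laplacian smoothing passes (default 0: the
#'   raw isosurface).
#' @param spacing_mm Voxel spacing, taken from the volume when omitted.
#' @param max_volume_change Relative enclosed-volume change above which
#'   smoothing stops early (default 0.05).
#' @return An object of class `surface_mesh`: list with `vertices` (n x 3,
#'   mm), `faces` (m x 3, 1-based) and `compartment`.
#' @export
label_to_mesh <- function(volume, label, smoothing_iterations = 0,
                          spacing_mm = NULL, max_volume_change = 0.05) {
  arr <- if (inherits(volume, "label_volume")) volume$voxels else volume
  if (is.null(spacing_mm))
    spacing_mm <- volume$spacing_mm
  origin <- if (inherits(volume, "label_volume")) volume$origin_mm else c(0, 0, 0)
  lv <- resolve_label(label)
  mask <- arr == lv
  if (!any(mask))
    stop("label ", label, " is absent from the volume")
  d <- dim(mask)
  P <- array(0L, dim = d + 2L)
  P[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  dp <- dim(P)
  # active cells: any corner differs
  sub <- function(di, dj, dk)
    P[(1:(dp[1] - 1L)) + di, (1:(dp[2] - 1L)) + dj, (1:(dp[3] - 1L)) + dk]
  tot <- sub(0L, 0L, 0L)
  for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                 c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)))
    tot <- tot + sub(o[1], o[2], o[3])
  active <- which(tot > 0L & tot < 8L)
  base <- arrayInd(active, dp - 1L)   # cell corner (0,0,0) in padded indices
  lin0 <- base[, 1] + (base[, 2] - 1L) * dp[1] +
    (base[, 3] - 1L) * dp[1] * dp[2]
  off_lin <- function(o) o[1] + o[2] * dp[1] + o[3] * dp[1] * dp[2]
  tets <- freudenthal_tets()
  verts2 <- list()   # doubled padded-index coordinates per triangle corner
  for (tt in seq_along(tets)) {
    corners <- tets[[tt]]
    vals <- sapply(1:4, function(ci) P[lin0 + off_lin(corners[ci, ])])
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = 4)
    code <- vals[, 1] + 2L * vals[, 2] + 4L * vals[, 3] + 8L * vals[, 4]
    for (cd in setdiff(sort(unique(code)), c(0L, 15L))) {
      tris <- tri_tables[[tt]][[cd + 1L]]
      sel <- which(code == cd)
      b2 <- 2L * base[sel, , drop = FALSE]
      for (tri in tris) {
        # three corners, each n x 3
        verts2[[length(verts2) + 1L]] <- list(
          sweep(b2, 2, tri[1, ], `+`),
          sweep(b2, 2, tri[2, ], `+`),
          sweep(b2, 2, tri[3, ], `+`))
      }
    }
  }
  if (length(verts2) == 0L)
    stop("no surface extracted (mask touches no background?)")
  v1 <- do.call(rbind, lapply(verts2, `[[`, 1))
  v2 <- do.call(rbind, lapply(verts2, `[[`, 2))
  v3 <- do.call(rbind, lapply(verts2, `[[`, 3))
  allv <- rbind(v1, v2, v3)
  key <- paste(allv[, 1], allv[, 2], allv[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  nf <- nrow(v1)
  faces <- cbind(vid[seq_len(nf)], vid[nf + seq_len(nf)],
                 vid[2L * nf + seq_len(nf)])
  # doubled padded index -> mm: index p maps to (p/2 - 1.5) * spacing
  uv <- allv[uk, , drop = FALSE]
  vertices <- sweep(sweep(uv / 2 - 1.5, 2, spacing_mm, `*`), 2, origin, `+`)
  mesh <- structure(list(vertices = vertices, faces = faces,
                         compartment = if (is.character(label)) label else
                           names(et_labels())[match(lv, et_labels())]),
                    class = "surface_mesh")
  if (smoothing_iterations > 0)
    mesh <- laplacian_smooth(mesh, smoothing_iterations,
                             max_volume_change = max_volume_change)
  mesh
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume from the divergence theorem; positive for outward-oriented
#' watertight meshes.
#'
#' @param mesh A `surface_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Check mesh watertightness
#'
#' A closed, consistently oriented surface has every undirected edge shared
#' by exactly two faces, once in each direction.
#'
#' @param mesh A `surface_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  directed <- paste(ed[, 1], ed[, 2])
  undirected <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(undirected) == 2L) && !anyDuplicated(directed)
}

#' Laplacian mesh smoothing with a volume guard
#'
#' Moves each vertex toward the mean of its neighbours
#' (`lambda` per iteration). Smoothing stops early if the enclosed volume
#' would change by more than `max_volume_change` relative to the input.
#'
#' @param mesh A `surface_mesh`.
#' @param iterations Number of passes.
#' @param lambda Step size in (0, 1].
#' @param max_volume_change Relative volume-change guard (default 0.05).
#' @return The smoothed `surface_mesh`.
#' @export
laplacian_smooth <- function(mesh, iterations, lambda = 0.5,
                             max_volume_change = 0.05) {
  v0 <- mesh_volume(mesh)
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  v <- mesh$vertices
  n <- nrow(v)
  deg <- tabulate(ed[, 1], n)
  for (it in seq_len(iterations)) {
    nb <- rowsum(v[ed[, 2], , drop = FALSE], ed[, 1], reorder = TRUE)
    vnew <- v + lambda * (nb / deg - v)
    trial <- mesh
    trial$vertices <- vnew
    if (abs(mesh_volume(trial) - v0) > max_volume_change * abs(v0))
      break
    v <- vnew
  }
  mesh$vertices <- v
  mesh
}

#' Write a mesh as binary STL
#'
#' Little-endian binary STL: 80-byte header, unsigned 32-bit triangle
#' count, then 50 bytes per triangle (normal, three vertices as float32,
#' attribute byte count 0). Normals are computed from the vertex winding
#' (right-hand rule).
#'
#' @param mesh A `surface_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", paste0("tuberecon ",
                                              mesh$compartment)))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  block <- t(cbind(nrm, a, b, cc))   # 12 floats per triangle
  floats <- writeBin(as.numeric(block), raw(), size = 4L,
                     endian = "little")
  # interleave the 48 float bytes of each triangle with its 2-byte
  # attribute count
  out <- matrix(as.raw(0), 50L, nrow(f))
  out[1:48, ] <- matrix(floats, 48L)
  writeBin(as.vector(out), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices are merged by exact float32 coordinate equality, recovering the
#' face topology. Malformed files raise an error reporting the byte offset
#' at which the data ended prematurely.
#'
#' @param path STL file.
#' @return A `surface_mesh` (with an additional `normals` element holding
#'   the stored per-facet normals).
#' @export
read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 84)
    stop("malformed STL: file ends at byte ", sz,
         " before the 84-byte header")
  header <- readBin(con, raw(), n = 80L)
  nf <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  need <- 84 + 50 * as.numeric(nf)
  if (sz < need)
    stop("malformed STL: ", nf, " triangles declared but file ends at byte ",
         sz, " (need ", need, ")")
  body <- readBin(con, raw(), n = 50L * as.numeric(nf))
  bm <- matrix(body, 50L)
  tri <- matrix(readBin(as.vector(bm[1:48, ]), numeric(),
                        n = 12L * nf, size = 4L, endian = "little"),
                nf, 12, byrow = TRUE)
  pts <- rbind(tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE],
               tri[, 10:12, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  faces <- cbind(vid[seq_len(nf)], vid[nf + seq_len(nf)],
                 vid[2L * nf + seq_len(nf)])
  structure(list(vertices = pts[uk, , drop = FALSE], faces = faces,
                 compartment = trimws(rawToChar(header[header != as.raw(0)])),
                 normals = tri[, 1:3, drop = FALSE]),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s': %d vertices, %d faces, volume %.2f mm^3\n",
              x$compartment, nrow(x$vertices), nrow(x$faces),
              mesh_volume(x)))
  invisible(x)
}
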