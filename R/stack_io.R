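# Reading and writing section series (one 16-bit TIFF per section plus a
# JSON manifest that is the single source of z and groove metadata) and 3D
# volumes (NRRD with anisotropic spacing encoded in the space directions).

#' Write a section series to disk
#'
#' Writes one TIFF per section, named `sec_0000.tif` etc., and a
#' `manifest.json` holding spacing, period, label scheme, per-section z and
#' groove metadata, and (for synthetic data) the ground-truth transforms
#' under a `truth` key.
#'
#' @param sections A `section_series` (or plain list of [section_image()]).
#' @param path Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
write_stack <- function(sections, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  proto <- attr(sections, "proto")
  entries <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    fn <- sprintf("sec_%04d.tif", s$section_index)
    tiff::writeTIFF(s$labels / 65535, file.path(path, fn),
                    bits.per.sample = 16)
    if (!is.null(s$rgb))
      tiff::writeTIFF(s$rgb, file.path(path,
                                       sprintf("sec_%04d_rgb.tif",
                                               s$section_index)),
                      bits.per.sample = 8)
    entry <- list(index = s$section_index, filename = fn,
                  block_id = s$block_id, nominal_z_mm = s$nominal_z_mm,
                  groove_remaining_mm = s$groove_remaining_mm)
    if (!is.null(s$true_transform)) {
      entry$truth <- list(rotation_deg = s$true_transform$rotation_deg,
                          translation_mm = s$true_transform$translation_mm,
                          center_mm = s$true_transform$center_mm,
                          tilt_deg = s$true_tilt_deg)
    }
    entries[[i]] <- entry
  }
  manifest <- list(
    format = "tuberecon-stack-1",
    spacing_mm = sections[[1]]$spacing_mm,
    period_mm = if (!is.null(proto)) section_period_mm(proto) else NULL,
    label_scheme = as.list(et_labels()),
    block_height_mm = attr(sections, "block_height_mm"),
    groove_xy_mm = attr(sections, "groove_xy_mm"),
    block_center_mm = attr(sections, "block_center_mm"),
    protocol = if (!is.null(proto)) {
      list(section_thickness_um = proto$section_thickness_um,
           blade_thickness_um = proto$blade_thickness_um,
           n_sections = proto$n_sections,
           lost_section_indices = proto$lost_section_indices,
           split_into_blocks = proto$split_into_blocks,
           groove_noise_um = proto$groove_noise_um,
           tilt_sd_deg = proto$perturbation$tilt_sd_deg)
    } else NULL,
    sections = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a section series from disk
#'
#' Validates the manifest (unique indices, files present, positive spacing)
#' and every section image (integer labels, values inside the label scheme)
#' before returning; corrupt inputs raise descriptive errors rather than
#' being coerced.
#'
#' @param path Directory containing `manifest.json`, or the manifest path
#'   itself.
#' @return A `section_series` list of [section_image()] objects.
#' @export
read_stack <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json")
                   else path
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  dirn <- dirname(manifest_path)
  spacing <- as.numeric(man$spacing_mm)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("manifest spacing_mm must be two positive numbers")
  scheme <- unlist(man$label_scheme)
  if (is.null(scheme["background"]) || scheme[["background"]] != 0L)
    stop("label scheme must contain background = 0")
  idx <- vapply(man$sections, function(e) as.integer(e$index), 1L)
  if (anyDuplicated(idx))
    stop("duplicate section indices in manifest: ",
         paste(idx[duplicated(idx)], collapse = ", "))
  fns <- vapply(man$sections, function(e) e$filename, "")
  if (anyDuplicated(fns))
    stop("duplicate filenames in manifest")
  sections <- vector("list", length(man$sections))
  for (i in seq_along(man$sections)) {
    e <- man$sections[[i]]
    fp <- file.path(dirn, e$filename)
    if (!file.exists(fp))
      stop("section file missing: ", e$filename)
    img <- tiff::readTIFF(fp, as.is = TRUE)
    if (!is.matrix(img))
      stop("section ", e$filename, " is not a single-channel label image")
    bad <- setdiff(unique(as.vector(img)), scheme)
    if (length(bad) > 0)
      stop("section ", e$filename,
           " contains label values outside the scheme: ",
           paste(sort(bad), collapse = ", "))
    tr <- NULL
    tilt <- NULL
    if (!is.null(e$truth)) {
      tr <- rigid2d(e$truth$rotation_deg,
                    as.numeric(e$truth$translation_mm),
                    as.numeric(e$truth$center_mm))
      tilt <- as.numeric(e$truth$tilt_deg)
    }
    sections[[i]] <- section_image(
      labels = img, spacing_mm = spacing,
      section_index = e$index, block_id = e$block_id,
      nominal_z_mm = e$nominal_z_mm,
      groove_remaining_mm = as.numeric(e$groove_remaining_mm),
      true_transform = tr, true_tilt_deg = tilt)
  }
  structure(sections, class = "section_series",
            manifest = man,
            period_mm = man$period_mm,
            block_height_mm = man$block_height_mm,
            groove_xy_mm = man$groove_xy_mm,
            block_center_mm = man$block_center_mm)
}

#' Write a volume as NRRD
#'
#' Writes a minimal NRRD0004 file (attached header, little-endian, gzip or
#' raw encoding) with the anisotropic spacing in the space directions and
#' the origin in the space origin field.
#'
#' @param volume A [label_volume()] or `density_volume`.
#' @param path Output file path.
#' @param encoding `"gzip"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(volume, path, encoding = c("gzip", "raw")) {
  encoding <- match.arg(encoding)
  if (inherits(volume, "label_volume")) {
    data <- volume$voxels
    type <- "int32"
  } else if (inherits(volume, "density_volume")) {
    data <- volume$values
    type <- "double"
  } else stop("volume must be a label_volume or density_volume")
  d <- dim(data)
  sp <- volume$spacing_mm
  hdr <- c("NRRD0004",
           "# written by tuberecon",
           paste0("type: ", type),
           "dimension: 3",
           "space: left-posterior-superior",
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("space directions: (", sp[1], ",0,0) (0,", sp[2],
                  ",0) (0,0,", sp[3], ")"),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", encoding),
           paste0("space origin: (",
                  paste(volume$origin_mm, collapse = ","), ")"),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  raw_data <- if (type == "int32") {
    writeBin(as.integer(data), raw(), size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(data), raw(), size = 8L, endian = "little")
  }
  if (encoding == "gzip")
    raw_data <- memCompress(raw_data, type = "gzip")
  writeBin(raw_data, con)
  invisible(path)
}

#' Read an NRRD volume
#'
#' Supports the subset written by [write_nrrd()]: 3D, little-endian,
#' `int32`/`double`, raw or gzip encoding, diagonal space directions.
#' Malformed headers, unknown types and non-positive spacings raise errors.
#'
#' @param path NRRD file path.
#' @return A [label_volume()] (for `int32` data whose values fit the label
#'   scheme) or a `density_volume`.
#' @export
read_nrrd <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  # header ends at the first blank line (\n\n)
  nl <- which(bytes == as.raw(10L))
  sep <- nl[which(diff(nl) == 1L)[1]]
  if (is.na(sep)) stop("truncated NRRD header (no blank line found)")
  header <- strsplit(rawToChar(bytes[seq_len(sep - 1L)]), "\n",
                     fixed = TRUE)[[1]]
  payload <- bytes[(sep + 2L):length(bytes)]
  if (!startsWith(header[1], "NRRD"))
    stop("not an NRRD file: ", path)
  fields <- list()
  for (line in header[-1]) {
    if (line == "" || startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed NRRD header line: ", line)
    fields[[kv[1]]] <- kv[2]
  }
  if (is.null(fields$sizes) || is.null(fields$type) ||
      is.null(fields$encoding))
    stop("NRRD header missing required fields")
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  if (length(sizes) != 3L || any(sizes <= 0))
    stop("only 3D NRRD volumes are supported")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    spacing <- unname(sqrt(rowSums(m^2)))
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD space directions give non-positive spacing")
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]),
                                  ",")[[1]])
  n <- prod(sizes)
  if (fields$encoding == "gzip") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (fields$encoding != "raw") {
    stop("unsupported NRRD encoding: ", fields$encoding)
  }
  data <- switch(fields$type,
    int32 = readBin(payload, integer(), n = n, size = 4L,
                    endian = "little"),
    double = readBin(payload, numeric(), n = n, size = 8L,
                     endian = "little"),
    stop("unsupported NRRD type: ", fields$type))
  if (length(data) != n)
    stop("NRRD payload shorter than the declared sizes")
  arr <- array(data, dim = sizes)
  if (fields$type == "int32" &&
      all(unique(as.vector(arr)) %in% et_labels())) {
    label_volume(arr, spacing_mm = spacing, origin_mm = origin)
  } else {
    structure(list(values = arr, spacing_mm = spacing, origin_mm = origin),
              class = "density_volume")
  }
}
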