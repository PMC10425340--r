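#' Multi-channel 3D image stack
#'
#' Container for a multi-channel 3D intensity grid with physical voxel size.
#' Channels are stored as arrays with dim = (z, y, x); all geometry is
#' reported in physical (x, y, z) micrometres. The center of voxel
#' (i, j, k) (1-based, storage order z, y, x) lies at physical position
#' `origin_um + ((k-1)*dx, (j-1)*dy, (i-1)*dz)`.
#'
#' @param channels named list of 3D numeric arrays of identical dim (z, y, x).
#' @param voxel_size_um physical voxel size, (x, y, z) um, all > 0.
#' @param origin_um physical position of the first voxel center, (x, y, z) um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um, origin_um = c(0, 0, 0)) {
  if (!is.list(channels) || length(channels) == 0)
    stop("format error: 'channels' must be a non-empty list of 3D arrays")
  if (is.null(names(channels)) || any(names(channels) == ""))
    names(channels) <- paste0("ch", seq_along(channels) - 1)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stop("format error: each channel must be a 3D array (z, y, x)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("format error: all channels must share the same shape")
  voxel_size_um <- vec3(voxel_size_um, "voxel_size_um")
  if (any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("metadata error: voxel sizes must be positive")
  structure(list(channels = channels,
                 voxel_size_um = voxel_size_um,
                 origin_um = vec3(origin_um, "origin_um")),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d x %d voxels (z,y,x), voxel %s um\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], paste(x$voxel_size_um, collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Convert voxel indices to physical coordinates and back
#'
#' `voxel_to_um` maps 1-based storage indices (i, j, k) = (z, y, x) to
#' physical (x, y, z) um; `um_to_voxel` is its inverse (nearest voxel).
#'
#' @param stack an [image_stack()].
#' @param idx integer matrix with columns (i, j, k), 1-based.
#' @param xyz numeric matrix with columns (x, y, z) um.
#' @return a numeric (resp. integer) matrix.
#' @export
voxel_to_um <- function(stack, idx) {
  idx <- matrix(idx, ncol = 3)
  v <- stack$voxel_size_um
  cbind(x = stack$origin_um[1] + (idx[, 3] - 1) * v[1],
        y = stack$origin_um[2] + (idx[, 2] - 1) * v[2],
        z = stack$origin_um[3] + (idx[, 1] - 1) * v[3])
}

#' @rdname voxel_to_um
#' @export
um_to_voxel <- function(stack, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  v <- stack$voxel_size_um
  cbind(i = as.integer(round((xyz[, 3] - stack$origin_um[3]) / v[3])) + 1L,
        j = as.integer(round((xyz[, 2] - stack$origin_um[2]) / v[2])) + 1L,
        k = as.integer(round((xyz[, 1] - stack$origin_um[1]) / v[1])) + 1L)
}

ome_xml <- function(stack, scale = 1) {
  d <- dim(stack$channels[[1]])
  ch <- paste0(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                       seq_along(stack$channels) - 1, names(stack$channels)),
               collapse = "")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="float"',
    sprintf(' SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="%d" SizeT="1"',
            d[3], d[2], length(stack$channels), d[1]),
    sprintf(' PhysicalSizeX="%g" PhysicalSizeY="%g" PhysicalSizeZ="%g"',
            stack$voxel_size_um[1], stack$voxel_size_um[2], stack$voxel_size_um[3]),
    ' PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm" PhysicalSizeZUnit="µm"',
    sprintf(' IntensityScale="%.17g">', scale),
    ch, '<TiffData/></Pixels></Image></OME>')
}

# tiff::writeTIFF cannot set the ImageDescription tag, which is where OME-XML
# lives. This relocates the first IFD of a (little-endian, as written by
# libtiff) TIFF to the end of the file with an added tag 270 entry pointing at
# the appended XML. Offsets of all existing tag payloads are unchanged.
embed_tiff_description <- function(path, text) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)))
    stop("format error: expected a little-endian TIFF")
  u16 <- function(at) readBin(raw[at + 0:1], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) {
    b <- as.integer(raw[at + 0:3])
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }
  w16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  w32 <- function(x) {
    b <- as.integer(c(x %% 256, (x %/% 256) %% 256,
                      (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
    as.raw(b)
  }
  ifd_off <- u32(5)
  n_entries <- u16(ifd_off + 1)
  entries_raw <- raw[(ifd_off + 3):(ifd_off + 2 + 12 * n_entries)]
  next_ptr <- u32(ifd_off + 3 + 12 * n_entries)

  xml_raw <- c(charToRaw(enc2utf8(text)), as.raw(0))
  n_value <- length(xml_raw)                  # text + terminating NUL
  if (n_value %% 2 == 1) xml_raw <- c(xml_raw, as.raw(0))  # word-align pad

  file_len <- length(raw)
  if (file_len %% 2 == 1) { raw <- c(raw, as.raw(0)); file_len <- file_len + 1 }
  xml_off <- file_len
  new_ifd_off <- xml_off + length(xml_raw)

  desc <- c(w16(270L), w16(2L), w32(n_value), w32(xml_off))
  # keep entries sorted by tag id; 270 goes after any tag < 270
  tags <- vapply(seq_len(n_entries) - 1L, function(e)
    u16(ifd_off + 3 + 12 * e), 0)
  pos <- sum(tags < 270)
  before <- if (pos > 0) entries_raw[seq_len(12 * pos)] else raw(0)
  after <- if (pos < n_entries) entries_raw[(12 * pos + 1):length(entries_raw)] else raw(0)
  new_ifd <- c(w16(n_entries + 1L), before, desc, after, w32(next_ptr))

  raw[5:8] <- w32(new_ifd_off)
  writeBin(c(raw, xml_raw, new_ifd), path)
  invisible(path)
}

#' Write an image stack as OME-TIFF
#'
#' Planes are written channel-fastest within z (OME DimensionOrder `XYCZT`) as
#' 32-bit float, with an OME-XML ImageDescription carrying channel names and
#' `PhysicalSizeX/Y/Z` in micrometres. Because the TIFF container stores
#' values in `[0, 1]`, intensities are divided by a power-of-two
#' `IntensityScale` (recorded in the OME-XML and undone on read), so the
#' round trip is exact up to one float32 quantization. Negative intensities
#' are clipped at zero.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1]])
  vmax <- max(vapply(stack$channels, max, 0), 0)
  scale <- if (vmax > 1) 2^ceiling(log2(vmax * (1 + 1e-7))) else 1
  planes <- vector("list", d[1] * length(stack$channels))
  p <- 0L
  for (i in seq_len(d[1])) {
    for (c in seq_along(stack$channels)) {
      p <- p + 1L
      planes[[p]] <- pmax(stack$channels[[c]][i, , ], 0) / scale
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  embed_tiff_description(path, ome_xml(stack, scale))
  invisible(path)
}

parse_ome_description <- function(desc) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  at <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  chn <- xml2::xml_find_all(doc, ".//*[local-name()='Channel']")
  sc <- at("IntensityScale")
  list(
    physical = c(at("PhysicalSizeX"), at("PhysicalSizeY"), at("PhysicalSizeZ")),
    size_c = at("SizeC"), size_z = at("SizeZ"),
    dim_order = xml2::xml_attr(px, "DimensionOrder"),
    channel_names = xml2::xml_attr(chn, "Name"),
    scale = if (is.finite(sc)) sc else 1
  )
}

#' Read a TIFF / OME-TIFF stack
#'
#' Voxel size and channel layout are taken from the OME-XML ImageDescription
#' when present. Plain TIFFs are read as a single-channel z-stack and require
#' `voxel_size_override`.
#'
#' @param path TIFF file path.
#' @param voxel_size_override optional (x, y, z) um voxel size, required when
#'   the file carries no OME physical-size metadata.
#' @param channel_names optional channel names overriding the metadata.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size_override = NULL, channel_names = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE,
                                   as.is = FALSE),
                    error = function(e) stop("format error: ", conditionMessage(e),
                                             call. = FALSE))
  if (length(pages) == 0) stop("format error: TIFF contains no images")
  if (length(dim(pages[[1]])) != 2)
    stop("format error: expected single-sample (grayscale) planes")
  meta <- NULL
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc)) meta <- parse_ome_description(desc)

  n_pages <- length(pages)
  if (!is.null(meta) && is.finite(meta$size_c) && is.finite(meta$size_z)) {
    nc <- as.integer(meta$size_c); nz <- as.integer(meta$size_z)
    if (nc * nz != n_pages)
      stop("format error: OME SizeC*SizeZ does not match page count")
    c_fastest <- !identical(meta$dim_order, "XYZCT")
  } else {
    nc <- 1L; nz <- n_pages; c_fastest <- TRUE
  }
  vox <- NULL
  if (!is.null(meta) && all(is.finite(meta$physical))) vox <- meta$physical
  if (!is.null(voxel_size_override)) vox <- vec3(voxel_size_override, "voxel_size_override")
  if (is.null(vox))
    stop("metadata error: no physical voxel size in file; supply voxel_size_override")

  scale <- if (!is.null(meta)) meta$scale else 1
  d2 <- dim(pages[[1]])
  channels <- vector("list", nc)
  for (c in seq_len(nc)) {
    arr <- array(0, c(nz, d2[1], d2[2]))
    for (i in seq_len(nz)) {
      p <- if (c_fastest) (i - 1L) * nc + c else (c - 1L) * nz + i
      arr[i, , ] <- pages[[p]] * scale
    }
    channels[[c]] <- arr
  }
  nm <- channel_names
  if (is.null(nm) && !is.null(meta) && length(meta$channel_names) == nc &&
      !anyNA(meta$channel_names)) nm <- meta$channel_names
  if (is.null(nm)) nm <- paste0("ch", seq_len(nc) - 1)
  names(channels) <- nm
  image_stack(channels, vox)
}

#' Crop a stack by a physical bounding box
#'
#' Returns the voxel-aligned crop formed by all voxels whose centers lie in
#' the half-open physical box `[center - size/2, center + size/2)`. The crop
#' is clipped to the stack with a warning; an empty intersection is an error.
#' The returned stack's origin records the physical offset so coordinates
#' remain absolute.
#'
#' @param stack an [image_stack()].
#' @param center_um physical center of the box, (x, y, z) um.
#' @param size_um physical box size, (x, y, z) um.
#' @return an [image_stack()].
#' @export
crop_um <- function(stack, center_um, size_um) {
  stopifnot(inherits(stack, "image_stack"))
  center_um <- vec3(center_um, "center_um")
  size_um <- vec3(size_um, "size_um")
  v <- stack$voxel_size_um
  d <- dim(stack$channels[[1]])                       # (z, y, x)
  n_xyz <- c(d[3], d[2], d[1])
  eps <- 1e-9
  lo_um <- center_um - size_um / 2
  hi_um <- center_um + size_um / 2
  lo <- ceiling((lo_um - stack$origin_um) / v - eps) + 1  # first center >= lo
  hi <- ceiling((hi_um - stack$origin_um) / v - eps)      # last center < hi
  lo_cl <- pmax(1, lo); hi_cl <- pmin(n_xyz, hi)
  if (any(hi_cl < lo_cl))
    stop("bounds error: crop does not intersect the stack")
  if (any(lo < 1) || any(hi > n_xyz))
    warning("crop clipped to stack bounds")
  channels <- lapply(stack$channels, function(a)
    a[lo_cl[3]:hi_cl[3], lo_cl[2]:hi_cl[2], lo_cl[1]:hi_cl[1], drop = FALSE])
  image_stack(channels, v,
              origin_um = stack$origin_um + (lo_cl - 1) * v)
}

MORPH_SCHEMA <- c("measure", "value_um", "mouse_id", "node_id", "group",
                  "batch", "axon_type")
MORPH_HEADER <- "# ranvier3d morphometry v1"

#' Read / write morphometry record tables
#'
#' CSV round-trip of `MorphRecord` tables (one row per measured paranode or
#' node). The column schema is versioned in a header comment; reading a file
#' with missing schema columns is a format error, and writing non-finite
#' measurement values is rejected.
#'
#' @param records a morphometry record `data.frame`.
#' @param path CSV path.
#' @return `read_morphometry` returns the records `data.frame`.
#' @export
write_morphometry <- function(records, path) {
  missing_cols <- setdiff(MORPH_SCHEMA, names(records))
  if (length(missing_cols))
    stop("format error: missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) && any(!is.finite(records$value_um)))
    stop("non-finite measurement values cannot be written")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(MORPH_HEADER, con)
  write.csv(records[, union(MORPH_SCHEMA, names(records))], con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_morphometry
#' @export
read_morphometry <- function(path) {
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(MORPH_SCHEMA, names(out))
  if (length(missing_cols))
    stop("format error: missing columns: ", paste(missing_cols, collapse = ", "))
  out$value_um <- as.numeric(out$value_um)
  out
}
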