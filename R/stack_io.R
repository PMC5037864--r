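#' Physical voxel spacing
#'
#' Voxel spacing in micrometres per voxel. The pipeline assumes isotropic
#' lateral sampling, so `dx` and `dy` must be equal; violating inputs are
#' rejected rather than silently resampled.
#'
#' @param dx,dy Lateral spacing in um/voxel (must be equal).
#' @param dz Axial spacing in um/voxel.
#' @return An object of class `voxel_spacing` with fields `dx`, `dy`, `dz`.
#' @examples
#' voxel_spacing(0.06, 0.06, 0.2)
#' @export
voxel_spacing <- function(dx = 0.06, dy = dx, dz = 0.2) {
  s <- c(dx = dx, dy = dy, dz = dz)
  if (!all(is.finite(s)) || any(s <= 0))
    stop("voxel spacing must be strictly positive and finite")
  if (abs(dx - dy) > 1e-12 * max(dx, dy))
    stop("anisotropic lateral spacing (dx != dy) is not supported")
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx = dy = %g um, dz = %g um\n", x$dx, x$dz))
  invisible(x)
}

#' Single-channel 3D image stack
#'
#' The unit every pipeline stage consumes and produces: a non-negative 3D
#' intensity grid indexed `[z, y, x]` with physical voxel spacing. The axial
#' index increases from the apical (coverslip-distal) side toward the basal
#' side; this convention is fixed here, once, and all downstream code is
#' agnostic to it. Penetration past the apical surface is therefore a
#' negative axial distance.
#'
#' @param data Numeric 3D array, dim `c(nz, ny, nx)`, finite and >= 0.
#' @param spacing A [voxel_spacing()].
#' @param channel Optional channel label.
#' @param check Validate the minimum analyzable size (at least 8 z-planes
#'   and 32 pixels laterally). Internal helpers set this to `FALSE` for
#'   small scratch grids.
#' @return An object of class `voxel_stack` with fields `data`, `spacing`,
#'   `channel`.
#' @export
voxel_stack <- function(data, spacing = voxel_spacing(), channel = "",
                        check = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array indexed [z, y, x]")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  if (check) {
    d <- dim(data)
    if (d[1] < 8L || d[2] < 32L || d[3] < 32L)
      stop("minimum analyzable stack is 8 z-planes and 32x32 pixels")
  }
  if (!inherits(spacing, "voxel_spacing"))
    spacing <- do.call(voxel_spacing, as.list(spacing))
  structure(list(data = data, spacing = spacing, channel = as.character(channel)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_stack%s: %d x %d x %d (z,y,x), dx = %g um, dz = %g um, range [%g, %g]\n",
              if (nzchar(x$channel)) paste0(" [", x$channel, "]") else "",
              d[1], d[2], d[3], x$spacing$dx, x$spacing$dz,
              min(x$data), max(x$data)))
  invisible(x)
}

# Accept either a voxel_stack or a bare 3D array in the operations below.
stack_data <- function(x) {
  if (inherits(x, "voxel_stack")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a voxel_stack or a 3D array")
}

stack_spacing <- function(x, spacing = NULL) {
  if (!is.null(spacing)) {
    if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
    return(spacing)
  }
  if (inherits(x, "voxel_stack")) return(x$spacing)
  stop("voxel spacing required: pass a voxel_stack or an explicit spacing")
}

with_data <- function(stack, data) {
  if (inherits(stack, "voxel_stack")) { stack$data <- data; stack } else data
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to TIFF
#'
#' Writes z-planes as TIFF pages. Integer-valued stacks within the 16-bit
#' range are stored as 16-bit pages and round-trip bit-exactly; other stacks
#' are stored as 32-bit float pages scaled into `[0, 1]`. The voxel spacing,
#' channel layout, data type and intensity scale are recorded in a JSON
#' sidecar (`<path>.json`) because the installed TIFF codec exposes no
#' description-tag writer; [read_stack()] also understands ImageJ-style
#' description metadata in files produced elsewhere.
#'
#' @param stack A [voxel_stack()] (or a list of them sharing spacing and
#'   shape, written as an interleaved multi-channel file, channel-fastest).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stacks <- if (inherits(stack, "voxel_stack")) list(stack) else stack
  if (!length(stacks) || !all(vapply(stacks, inherits, TRUE, "voxel_stack")))
    stop("expected a voxel_stack or a list of voxel_stack")
  d <- dim(stacks[[1]]$data)
  sp <- stacks[[1]]$spacing
  for (s in stacks) {
    if (!identical(dim(s$data), d)) stop("all channels must share the same shape")
    if (!isTRUE(all.equal(unlist(s$spacing), unlist(sp)))) stop("all channels must share spacing")
  }
  nc <- length(stacks)
  nz <- d[1]
  is_int <- vapply(stacks, function(s)
    max(s$data) <= 65535 && all(s$data == round(s$data)), TRUE)
  dtype <- if (all(is_int)) "uint16" else "float32"
  scale <- vapply(stacks, function(s) {
    m <- max(s$data)
    if (dtype == "uint16") 65535 else if (m > 0) m else 1
  }, 1.0)
  pages <- vector("list", nz * nc)
  for (z in seq_len(nz)) for (ch in seq_len(nc))
    pages[[(z - 1L) * nc + ch]] <- stacks[[ch]]$data[z, , ] / scale[ch]
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (dtype == "uint16") 16L else 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(
    format = "qdepth-stack", version = 1L,
    dx_um = sp$dx, dy_um = sp$dy, dz_um = sp$dz,
    slices = nz, channels = nc, page_order = "channel-fastest",
    dtype = dtype, scale = as.numeric(scale),
    channel_names = vapply(stacks, function(s) s$channel, "")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

parse_imagej_meta <- function(pages) {
  at <- attributes(pages[[1]])
  out <- list(dx = NA_real_, dz = NA_real_, channels = NA_integer_, slices = NA_integer_)
  desc <- at$description
  if (!is.null(desc)) {
    get_field <- function(key) {
      m <- regmatches(desc, regexec(paste0(key, "=([0-9.eE+-]+)"), desc))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else NA_real_
    }
    out$dz <- get_field("spacing")
    out$channels <- as.integer(get_field("channels"))
    out$slices <- as.integer(get_field("slices"))
  }
  if (!is.null(at$x.resolution) && at$x.resolution > 0) {
    # ImageJ stores pixels per unit; with unit=micron this is 1/dx
    out$dx <- 1 / at$x.resolution
  }
  out
}

#' Read an image stack from TIFF
#'
#' Reads one channel of a TIFF/OME-style z-stack. Voxel spacing is taken
#' from the JSON sidecar written by [write_stack()], else from ImageJ-style
#' metadata in the file, else from the `spacing` argument; if none is
#' available the read is refused (distances in physical units would be
#' meaningless). Integer pages are returned bit-exactly.
#'
#' @param path TIFF file path.
#' @param channel 1-based channel index.
#' @param spacing Optional [voxel_spacing()] override; wins over file
#'   metadata when given.
#' @param channel_name Optional label for the returned stack.
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, channel = 1L, spacing = NULL, channel_name = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!identical(meta$format, "qdepth-stack")) meta <- NULL
  }
  # integer pages are read unscaled (bit-exact); float pages must be read
  # in the codec's native [0, 1] scaling and multiplied back
  raw_ints <- is.null(meta) || identical(meta$dtype, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = raw_ints, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)
  ij <- parse_imagej_meta(pages)
  nc <- if (!is.null(meta)) as.integer(meta$channels)
        else if (!is.na(ij$channels)) ij$channels else 1L
  if (npages %% nc != 0) stop("page count is not a multiple of the channel count")
  nz <- npages %/% nc
  if (channel < 1 || channel > nc)
    stop(sprintf("channel %d requested but file has %d channel(s)", channel, nc))
  if (!is.null(spacing)) {
    sp <- if (inherits(spacing, "voxel_spacing")) spacing else do.call(voxel_spacing, as.list(spacing))
  } else if (!is.null(meta)) {
    sp <- voxel_spacing(meta$dx_um, meta$dy_um, meta$dz_um)
  } else if (!is.na(ij$dx) && !is.na(ij$dz)) {
    sp <- voxel_spacing(ij$dx, ij$dx, ij$dz)
  } else {
    stop("no voxel spacing in file metadata and none supplied; ",
         "refusing to guess physical units")
  }
  p1 <- pages[[channel]]
  d2 <- dim(p1)
  data <- array(0, dim = c(nz, d2[1], d2[2]))
  for (z in seq_len(nz)) data[z, , ] <- pages[[(z - 1L) * nc + channel]]
  if (!is.null(meta)) {
    scale <- meta$scale[channel]
    if (identical(meta$dtype, "uint16")) {
      data <- round(data) # as.is returns stored integers already
    } else {
      data <- data * scale
    }
    if (channel_name == "" && length(meta$channel_names) >= channel)
      channel_name <- meta$channel_names[channel]
  }
  voxel_stack(data, sp, channel = channel_name, check = FALSE)
}

record_columns <- c("stack_id", "object_id", "axial_distance_um",
                    "volume_voxels", "com_z_um")

#' Write penetration records to a CSV table
#'
#' One row per particle object with its signed axial distance to the apical
#' membrane surface. Numeric columns are written with 17 significant digits
#' so distances round-trip to full double precision; an empty record set
#' produces a header-only file.
#'
#' @param records Data frame of penetration records (see
#'   [measure_distance()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    cols <- record_columns
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  stopifnot(all(record_columns %in% names(records)))
  extra <- setdiff(names(records), record_columns)
  out <- records[, c(record_columns, extra), drop = FALSE]
  fmt <- vapply(out, function(col) {
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else as.character(col)
  }, FUN.VALUE = character(nrow(out)))
  fmt <- matrix(fmt, nrow = nrow(out), dimnames = list(NULL, names(out)))
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a penetration record table written by [write_records()]
#' @param path CSV path.
#' @return Data frame of records (zero rows for a header-only file).
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(names(df), c("axial_distance_um", "volume_voxels",
                                     "com_z_um", "nearest_z_um", "nearest_y_um",
                                     "nearest_x_um", "com_y_um", "com_x_um")))
    df[[col]] <- as.numeric(df[[col]])
  df
}
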