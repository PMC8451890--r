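#' Voxel volume container
#'
#' A `voxel_volume` wraps a 3D array of scalars with isotropic voxel spacing
#' (micrometers) and a grid origin (the world position, in micrometers, of
#' the center of voxel \[1,1,1\]). Binary masks are `voxel_volume`s whose
#' values are logical; masks additionally carry a `provenance` attribute, an
#' append-only list of the operations (with parameters) that produced them.
#'
#' @param values 3D numeric or logical array.
#' @param spacing Isotropic voxel edge length in micrometers (single positive
#'   number).
#' @param origin World coordinates (micrometers) of the first voxel center;
#'   length-3 numeric. Default `c(0, 0, 0)`.
#' @param provenance Optional list of provenance records.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0),
                         provenance = list()) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("`spacing` must be a single positive number (micrometers)")
  }
  if (any(dim(values) < 1L)) stop("grid must be non-empty")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    provenance = provenance,
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing %.4g um, %s\n",
              d[1], d[2], d[3], x$spacing,
              if (is.logical(x$values))
                sprintf("binary (%d foreground)", sum(x$values))
              else sprintf("range [%.3g, %.3g]", min(x$values),
                           max(x$values))))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

is_binary_volume <- function(vol) is.logical(vol$values)

#' Provenance trail of a mask
#'
#' @param vol A `voxel_volume`.
#' @return List of provenance records (operation name + parameters), oldest
#'   first.
#' @export
provenance <- function(vol) {
  attr(vol, "provenance") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_provenance <- function(vol, op, params = list()) {
  p <- c(provenance(vol), list(c(list(op = op), params)))
  attr(vol, "provenance") <- p
  vol
}

# World (mm) <-> continuous voxel coordinates (1-based voxel centers).
# Positions throughout the network/morphometry layers are in mm; volumes
# store spacing/origin in um.
voxel_to_world <- function(vox, spacing_um, origin_um = c(0, 0, 0)) {
  t((t(vox) - 1) * (spacing_um / 1000) + origin_um / 1000)
}

world_to_voxel <- function(mm, spacing_um, origin_um = c(0, 0, 0)) {
  t((t(mm) - origin_um / 1000) / (spacing_um / 1000) + 1)
}

#' Read a volume from NRRD, MetaImage or TIFF stack
#'
#' Supported: `.nrrd` (attached raw/ascii encoding), `.mhd`/`.mha`
#' (MET_UCHAR/MET_SHORT/MET_FLOAT/MET_DOUBLE, uncompressed), and multi-page
#' `.tif`/`.tiff` stacks (spacing must then be supplied).
#'
#' @param path File path.
#' @param spacing Spacing override in micrometers (required for TIFF).
#' @return A `voxel_volume`.
#' @export
read_volume <- function(path, spacing = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = read_nrrd(path, spacing),
    mhd = read_metaimage(path, spacing),
    mha = read_metaimage(path, spacing),
    tif = ,
    tiff = read_tiff_stack(path, spacing),
    stop("unsupported volume format: .", ext)
  )
}

#' Write a volume to NRRD, MetaImage or TIFF stack
#'
#' Spacing (micrometers) is recorded in the NRRD/MetaImage header. A JSON
#' sidecar `<path>.provenance.json` records the mask's provenance trail when
#' present.
#'
#' @param vol A `voxel_volume`.
#' @param path Output path; format chosen by extension.
#' @param sidecar Write the provenance JSON sidecar (default TRUE when the
#'   volume has provenance).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = length(provenance(vol)) > 0) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = write_nrrd(vol, path),
    mhd = write_metaimage(vol, path),
    mha = write_metaimage(vol, path),
    tif = ,
    tiff = write_tiff_stack(vol, path),
    stop("unsupported volume format: .", ext)
  )
  if (sidecar) {
    jsonlite::write_json(provenance(vol), paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# -- NRRD ---------------------------------------------------------------

read_nrrd <- function(path, spacing = NULL) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) {
      hdr_end <- p
      break
    }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD header: ", path)
  hlines <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\n")[[1]]
  if (!grepl("^NRRD", hlines[1])) stop("not an NRRD file: ", path)
  hdr <- list()
  for (line in hlines[-1]) {
    if (!nzchar(line) || grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*")[[1]]
    hdr[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  dims <- as.integer(strsplit(trimws(hdr[["sizes"]]), "\\s+")[[1]])
  type <- hdr[["type"]]
  enc <- hdr[["encoding"]]
  n <- prod(dims)
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  vals <- if (identical(enc, "raw")) {
    switch(type,
      "unsigned char" = , "uchar" = , "uint8" =
        as.numeric(readBin(payload, "integer", n, size = 1, signed = FALSE)),
      "short" = , "int16" =
        as.numeric(readBin(payload, "integer", n, size = 2,
                           endian = "little")),
      "int" = , "int32" =
        as.numeric(readBin(payload, "integer", n, size = 4,
                           endian = "little")),
      "float" = readBin(payload, "numeric", n, size = 4, endian = "little"),
      "double" = readBin(payload, "numeric", n, size = 8,
                         endian = "little"),
      stop("unsupported NRRD type: ", type)
    )
  } else if (enc %in% c("ascii", "txt", "text")) {
    scan(text = rawToChar(payload), what = double(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  sp <- spacing
  if (is.null(sp) && !is.null(hdr[["spacings"]])) {
    sp <- as.numeric(strsplit(trimws(hdr[["spacings"]]), "\\s+")[[1]])[1]
  }
  if (is.null(sp)) sp <- 1
  org <- c(0, 0, 0)
  if (!is.null(hdr[["space origin"]])) {
    org <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]),
                               ",")[[1]])
  }
  binary <- all(vals %in% c(0, 1))
  arr <- if (binary) array(vals > 0.5, dims) else array(vals, dims)
  voxel_volume(arr, sp, org)
}

write_nrrd <- function(vol, path) {
  v <- vol$values
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))
  type <- if (is.logical(v)) "unsigned char" else "double"
  hdr <- c(
    "NRRD0004",
    "# airway cast volume",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("spacings: ", paste(rep(vol$spacing, 3), collapse = " ")),
    paste0("space origin: (", paste(vol$origin, collapse = ","), ")"),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (is.logical(v)) {
    writeBin(as.integer(v), con, size = 1)
  } else {
    writeBin(as.numeric(v), con, size = 8, endian = "little")
  }
  invisible(path)
}

# -- MetaImage ----------------------------------------------------------

read_metaimage <- function(path, spacing = NULL) {
  lines <- readLines(path, n = 50, warn = FALSE)
  hdr <- list()
  data_offset <- NULL
  # .mha keeps data after "ElementDataFile = LOCAL"
  raw_all <- readBin(path, "raw", file.info(path)$size)
  hdr_end <- 0
  txt <- rawToChar(raw_all[seq_len(min(length(raw_all), 4096))])
  hlines <- strsplit(txt, "\n")[[1]]
  for (line in hlines) {
    if (!grepl("=", line)) next
    kv <- strsplit(line, "\\s*=\\s*")[[1]]
    hdr[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    hdr_end <- hdr_end + nchar(line, type = "bytes") + 1
    if (trimws(kv[1]) == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  et <- hdr[["ElementType"]]
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw_data <- raw_all[(hdr_end + 1):length(raw_all)]
  } else {
    raw_data <- readBin(file.path(dirname(path), datafile), "raw",
                        file.info(file.path(dirname(path), datafile))$size)
  }
  vals <- switch(et,
    MET_UCHAR = as.numeric(readBin(raw_data, "integer", n, size = 1,
                                   signed = FALSE)),
    MET_SHORT = as.numeric(readBin(raw_data, "integer", n, size = 2,
                                   endian = "little")),
    MET_FLOAT = readBin(raw_data, "numeric", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(raw_data, "numeric", n, size = 8, endian = "little"),
    stop("unsupported MetaImage element type: ", et)
  )
  sp <- spacing
  if (is.null(sp) && !is.null(hdr[["ElementSpacing"]])) {
    sp <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])[1]
  }
  if (is.null(sp)) sp <- 1
  org <- c(0, 0, 0)
  if (!is.null(hdr[["Offset"]])) {
    org <- as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  }
  binary <- all(vals %in% c(0, 1))
  arr <- if (binary) array(vals > 0.5, dims) else array(vals, dims)
  voxel_volume(arr, sp, org)
}

write_metaimage <- function(vol, path) {
  v <- vol$values
  d <- dim(v)
  et <- if (is.logical(v)) "MET_UCHAR" else "MET_DOUBLE"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste0("DimSize = ", paste(d, collapse = " ")),
    paste0("ElementSpacing = ", paste(rep(vol$spacing, 3), collapse = " ")),
    paste0("Offset = ", paste(vol$origin, collapse = " ")),
    paste0("ElementType = ", et),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (is.logical(v)) {
    writeBin(as.integer(v), con, size = 1)
  } else {
    writeBin(as.numeric(v), con, size = 8, endian = "little")
  }
  invisible(path)
}

# -- TIFF stack ---------------------------------------------------------

read_tiff_stack <- function(path, spacing = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF I/O")
  }
  if (is.null(spacing)) {
    stop("TIFF stacks carry no spacing; supply `spacing` (micrometers)")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(d[2], d[1], length(pages)))  # (x, y, z)
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  # TIFF stores samples with finite precision; 0/1 masks come back as
  # values within rounding of 0 or 1
  binary <- all(abs(arr) < 1e-6 | abs(arr - 1) < 1e-6)
  voxel_volume(if (binary) array(arr > 0.5, dim(arr)) else arr, spacing)
}

write_tiff_stack <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF I/O")
  }
  v <- vol$values
  d <- dim(v)
  pages <- lapply(seq_len(d[3]), function(z) t(v[, , z]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
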