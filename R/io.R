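# MetaImage (MHD/RAW) volume I/O, CSV slice export and YAML sidecars.
# MHD is the interchange format the medical-imaging toolchains (ITK and
# friends) read; the writer here covers only what this package emits:
# 2D/3D double-precision scalar volumes on regular grids.

#' Write / read a scalar volume as MetaImage (MHD + RAW)
#'
#' `write_mhd()` stores a numeric matrix or 3D array as a two-file
#' MetaImage volume: a text header `<path>.mhd` and little-endian
#' double-precision voxel data `<path>.raw`. `read_mhd()` reads it back.
#'
#' @param x Numeric matrix or 3D array.
#' @param path Output path without extension (or with `.mhd`, which is
#'   stripped).
#' @param spacing Voxel spacing per axis (m). Recycled to the array rank.
#' @return `write_mhd()` invisibly returns the header path; `read_mhd()`
#'   returns the array with a `spacing` attribute.
#' @export
write_mhd <- function(x, path, spacing = 1) {
  stopifnot(is.numeric(x), length(dim(x)) %in% c(2L, 3L))
  path <- sub("\\.mhd$", "", path)
  nd <- length(dim(x))
  spacing <- rep_len(spacing, nd)
  rawfile <- paste0(basename(path), ".raw")
  header <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", nd),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dim(x), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(spacing, collapse = " ")),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", rawfile))
  writeLines(header, paste0(path, ".mhd"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8L, endian = "little")
  invisible(paste0(path, ".mhd"))
}

#' @rdname write_mhd
#' @export
read_mhd <- function(path) {
  path <- sub("\\.mhd$", "", path)
  lines <- readLines(paste0(path, ".mhd"))
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (length(ln) == 0L) stop("missing MHD header field: ", key)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  if (get("ElementType") != "MET_DOUBLE")
    stop("only MET_DOUBLE volumes are supported")
  dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  rawfile <- file.path(dirname(paste0(path, ".mhd")), get("ElementDataFile"))
  con <- file(rawfile, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
  structure(array(v, dim = dims), spacing = spacing)
}

#' Export a 2D map as CSV
#'
#' Long-format export of a matrix-valued map with physical coordinates:
#' one row per node, columns `y_m`, `z_m`, `value`.
#'
#' @param x Numeric matrix (a 2D map, indexed y then z).
#' @param path Output CSV path.
#' @param extent_m Length-2 physical extents (m), centered on 0.
#' @param value_name Name for the value column.
#' @return Invisibly, the data.frame written.
#' @export
write_map_csv <- function(x, path, extent_m, value_name = "value") {
  stopifnot(is.matrix(x), length(extent_m) == 2L)
  ys <- axis_coords(extent_m[1], nrow(x))
  zs <- axis_coords(extent_m[2], ncol(x))
  df <- data.frame(y_m = rep(ys, times = ncol(x)),
                   z_m = rep(zs, each = nrow(x)),
                   value = as.vector(x))
  names(df)[3] <- value_name
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a YAML sidecar with a run's resolved parameters
#'
#' Records the full parameter set of a simulation or experiment next to its
#' outputs, so any result can be regenerated from its sidecar alone.
#'
#' @param params Named list of parameters.
#' @param path Output path (YAML).
#' @return Invisibly, `path`.
#' @export
write_sidecar <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
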