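## Minimal NRRD reader/writer. Only what the package emits is supported:
## raw little-endian encoding, types float/double/uint8/uint16/int32,
## 2-D or 3-D arrays, "spacings" metadata carrying the voxel size in um.

.nrrd_types <- list(
  float    = list(what = "numeric", size = 4),
  double   = list(what = "numeric", size = 8),
  uint8    = list(what = "integer", size = 1, signed = FALSE),
  uint16   = list(what = "integer", size = 2, signed = FALSE),
  int32    = list(what = "integer", size = 4, signed = TRUE)
)

#' Write an array as a NRRD file
#'
#' Raw little-endian encoding with the voxel size recorded in the
#' `spacings` field. This is the package's native volume format.
#'
#' @param x numeric or integer array (2-D or 3-D).
#' @param path output file path.
#' @param type one of `"float"`, `"double"`, `"uint8"`, `"uint16"`, `"int32"`.
#' @param spacing voxel edge length(s), um; recycled to the array rank.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, type = "float", spacing = 1) {
  spec <- .nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  spacing <- rep_len(spacing, length(dims))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# calciscan volume",
    paste0("type: ", type),
    paste0("dimension: ", length(dims)),
    paste0("sizes: ", paste(dims, collapse = " ")),
    paste0("spacings: ", paste(format(spacing, scientific = FALSE),
                               collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  vals <- as.vector(x)
  if (spec$what == "integer") {
    writeBin(as.integer(vals), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

#' Read a NRRD file written by this package
#'
#' @param path file path.
#' @return list with `values` (array) and `spacing` (numeric vector, um).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[[tolower(kv[1])]] <- kv[2]
  }
  type <- fields[["type"]]
  spec <- .nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], " +")[[1]]) else rep(1, length(sizes))
  n <- prod(sizes)
  vals <- if (spec$what == "integer") {
    readBin(con, "integer", n = n, size = spec$size,
            signed = if (is.null(spec$signed)) TRUE else spec$signed,
            endian = "little")
  } else {
    readBin(con, "numeric", n = n, size = spec$size, endian = "little")
  }
  list(values = array(vals, dim = sizes), spacing = spacing)
}

## Binary PPM (P6) writer for color slice export; no PNG encoder is assumed
## to be installed, and P6 is universally readable.
write_ppm <- function(rgb, path) {
  # rgb: integer array [nx, ny, 3] in 0..255
  d <- dim(rgb)
  stopifnot(length(d) == 3, d[3] == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(d[1], d[2]), "255"), con, sep = "\n")
  # PPM is row-major top-to-bottom; emit y rows of (r,g,b) triples
  px <- aperm(rgb, c(3, 1, 2))
  writeBin(as.integer(px), con, size = 1)
  invisible(path)
}
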