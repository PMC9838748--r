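#' Write a spectral cube as ENVI header + BSQ binary
#'
#' Writes `path` (raw binary, band-sequential, little-endian) and
#' `path.hdr` (ENVI text header carrying dimensions, the full-precision
#' wavelength list and the cube kind). Values are stored as 64-bit IEEE
#' doubles (ENVI data type 5) so that a write/read round trip reproduces
#' the raster bit-exactly for both DN and reflectance cubes.
#'
#' @param cube A [spectral_cube()].
#' @param path Destination path of the binary data file; the header is
#'   written alongside as `<path>.hdr`.
#' @return `path`, invisibly.
#' @seealso [read_envi()]
#' @export
write_envi <- function(cube, path) {
  if (!inherits(cube, "spectral_cube")) stop("cube must be a spectral_cube")
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {dyespec spectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("cube kind = %s", cube$kind),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.17g", cube$grid$band_centers), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band outermost, then line, sample fastest -> samples-first array
  writeBin(as.vector(aperm(cube$values, c(2, 1, 3))), con,
           size = 8, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^ENVI", lines[1])) {
    stop(sprintf("%s is not an ENVI header (missing ENVI magic)", hdr_path))
  }
  txt <- paste(lines[-1], collapse = "\n")
  # re-join multi-line { ... } blocks before splitting into key = value pairs
  fields <- list()
  pos <- 1L
  for (piece in strsplit(txt, "\n", fixed = TRUE)[[1]]) {
    if (length(fields) > 0 && isTRUE(attr(fields, "open"))) {
      fields[[length(fields)]] <- paste(fields[[length(fields)]], piece)
    } else if (grepl("=", piece, fixed = TRUE)) {
      fields[[length(fields) + 1L]] <- piece
    } else {
      next
    }
    open_brace <- grepl("\\{", fields[[length(fields)]]) &&
      !grepl("\\}", fields[[length(fields)]])
    attr(fields, "open") <- open_brace
  }
  out <- list()
  for (f in fields) {
    kv <- regmatches(f, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", f))[[1]]
    if (length(kv) == 3) out[[tolower(kv[2])]] <- trimws(kv[3])
  }
  out
}

header_num <- function(h, key) {
  if (is.null(h[[key]])) stop(sprintf("ENVI header is missing '%s'", key))
  v <- suppressWarnings(as.numeric(h[[key]]))
  if (is.na(v)) stop(sprintf("ENVI header field '%s' is not numeric", key))
  v
}

#' Read an ENVI cube
#'
#' Accepts the data-file path (with `<path>.hdr` alongside) or the header
#' path itself. Supported: BSQ interleave, little-endian, data types 1
#' (uint8), 2 (int16), 4 (float32), 5 (float64) and 12 (uint16). The
#' wavelength list must be present, strictly increasing and of length
#' `bands`; the data file size must match the declared dimensions exactly.
#'
#' @param path Data file or `.hdr` file path.
#' @return A [spectral_cube()].
#' @export
read_envi <- function(path) {
  if (grepl("\\.hdr$", path)) {
    hdr_path <- path
    data_path <- sub("\\.hdr$", "", path)
  } else {
    hdr_path <- paste0(path, ".hdr")
    data_path <- path
  }
  if (!file.exists(hdr_path)) stop(sprintf("missing ENVI header %s", hdr_path))
  if (!file.exists(data_path)) stop(sprintf("missing ENVI data file %s", data_path))
  h <- parse_envi_header(hdr_path)

  samples <- as.integer(header_num(h, "samples"))
  lines_n <- as.integer(header_num(h, "lines"))
  bands <- as.integer(header_num(h, "bands"))
  if (samples < 1 || lines_n < 1 || bands < 1) {
    stop("ENVI header declares non-positive dimensions")
  }
  interleave <- tolower(h[["interleave"]] %||% "bsq")
  if (interleave != "bsq") {
    stop(sprintf("unsupported interleave '%s' (only bsq is supported)", interleave))
  }
  byte_order <- as.integer(header_num(h, "byte order"))
  if (byte_order != 0L) stop("unsupported byte order (only little-endian)")
  dtype <- as.integer(header_num(h, "data type"))
  spec <- switch(as.character(dtype),
    "1"  = list(what = integer(),  size = 1L, signed = FALSE),
    "2"  = list(what = integer(),  size = 2L, signed = TRUE),
    "4"  = list(what = numeric(),  size = 4L, signed = TRUE),
    "5"  = list(what = numeric(),  size = 8L, signed = TRUE),
    "12" = list(what = integer(),  size = 2L, signed = FALSE),
    stop(sprintf("unsupported ENVI data type %d", dtype))
  )

  n_values <- as.double(samples) * lines_n * bands
  expected_bytes <- n_values * spec$size + header_num(h, "header offset")
  actual_bytes <- file.size(data_path)
  if (actual_bytes != expected_bytes) {
    stop(sprintf(
      "ENVI data file %s has %d bytes; header declares %d x %d x %d values of %d bytes (%d expected) - truncated or mismatched dimensions",
      data_path, actual_bytes, lines_n, samples, bands, spec$size, expected_bytes))
  }

  if (is.null(h[["wavelength"]])) stop("ENVI header is missing 'wavelength'")
  wl_txt <- gsub("[{}]", "", h[["wavelength"]])
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  if (length(wl) != bands) {
    stop(sprintf("header lists %d wavelengths for %d bands", length(wl), bands))
  }
  grid <- wavelength_grid(wl)  # rejects non-increasing lists

  con <- file(data_path, "rb")
  on.exit(close(con))
  seek(con, header_num(h, "header offset"))
  v <- readBin(con, spec$what, n = n_values, size = spec$size,
               signed = spec$signed, endian = "little")
  arr <- aperm(array(as.numeric(v), dim = c(samples, lines_n, bands)), c(2, 1, 3))

  kind <- h[["cube kind"]] %||% "raw"
  if (!kind %in% c("raw", "reflectance")) kind <- "raw"
  spectral_cube(arr, grid, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
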