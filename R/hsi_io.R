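#' Read a hyperspectral cube from disk
#'
#' Two interchange formats are supported: `"envi"` — the de-facto
#' hyperspectral standard, an ASCII header (`.hdr`) next to a flat binary
#' image file with band-sequential (BSQ) interleave and the wavelength list
#' in the header — and `"portable_array"`, a self-contained gzip-compressed
#' JSON container convenient for fixtures and cross-language exchange.
#'
#' @param path File path. For ENVI, the data file (`.img`); the header is
#'   looked up by swapping the extension for `.hdr`.
#' @param format `"envi"` or `"portable_array"`.
#' @return An [hsi_cube].
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format = c("envi", "portable_array")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         envi = read_cube_envi(path),
         portable_array = read_cube_portable(path))
}

#' Write a hyperspectral cube to disk
#'
#' ENVI output stores raw integer-valued cubes as unsigned 16-bit integers
#' (bit-exact round trip) and everything else as 64-bit floats. The
#' portable-array container always stores full-precision doubles.
#'
#' @param cube An [hsi_cube].
#' @param path Output path (for ENVI, the `.img` data file).
#' @param format `"envi"` or `"portable_array"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "portable_array")) {
  format <- match.arg(format)
  if (!inherits(cube, "hsi_cube")) stop("`cube` must be an hsi_cube",
                                        call. = FALSE)
  switch(format,
         envi = write_cube_envi(cube, path),
         portable_array = write_cube_portable(cube, path))
  invisible(path)
}

envi_header_path <- function(path) {
  if (grepl("\\.img$", path)) sub("\\.img$", ".hdr", path)
  else paste0(path, ".hdr")
}

write_cube_envi <- function(cube, path) {
  d <- dim(cube$data)
  vals <- as.vector(cube$data)
  use_u16 <- cube$value_kind == "raw" &&
    all(vals == round(vals)) && all(vals >= 0) && all(vals <= 65535)
  dtype <- if (use_u16) 12L else 5L
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    sprintf("data type = %d", dtype),
    "interleave = bsq",
    "byte order = 0",
    sprintf("value kind = %s", cube$value_kind),
    sprintf("bit depth = %d", cube$bit_depth),
    "wavelength units = nm",
    paste0("wavelength = {",
           paste(sprintf("%.17g", cube$wavelengths), collapse = ", "), "}"))
  writeLines(hdr, envi_header_path(path))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major, each band row-major (lines of samples)
  for (b in seq_len(d[3L])) {
    band <- as.vector(t(cube$data[, , b]))
    if (use_u16) writeBin(as.integer(band), con, size = 2L, endian = "little")
    else writeBin(as.double(band), con, size = 8L, endian = "little")
  }
}

parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path))
    stop("ENVI header not found: ", hdr_path, call. = FALSE)
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  # fold multi-line { ... } blocks onto one line
  txt <- gsub("\\{([^}]*)\\}", "{\\1}", txt)
  fields <- list()
  pat <- "(?ms)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1L] != -1L) {
    starts <- m; lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
      key <- trimws(sub("=.*", "", piece))
      val <- trimws(sub("^[^=]*=", "", piece))
      key <- tolower(key)
      if (!is.null(fields[[key]]))
        stop("duplicate ENVI header field: ", key, call. = FALSE)
      fields[[key]] <- val
    }
  }
  fields
}

read_cube_envi <- function(path) {
  f <- parse_envi_header(envi_header_path(path))
  need <- c("samples", "lines", "bands", "data type", "wavelength")
  miss <- setdiff(need, names(f))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- as.integer(f$samples); lines <- as.integer(f$lines)
  bands <- as.integer(f$bands); dtype <- as.integer(f[["data type"]])
  wl <- as.numeric(strsplit(gsub("[{}]", "", f$wavelength), ",")[[1]])
  if (anyNA(wl)) stop("unparseable wavelength list in ENVI header",
                      call. = FALSE)
  if (length(wl) != bands)
    stop("ENVI header lists ", length(wl), " wavelengths for ", bands,
         " bands", call. = FALSE)
  interleave <- tolower(f$interleave %||% "bsq")
  if (interleave != "bsq")
    stop("only BSQ interleave is supported (got ", interleave, ")",
         call. = FALSE)
  n <- samples * lines * bands
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- switch(as.character(dtype),
    "12" = readBin(con, integer(), n, size = 2L, signed = FALSE,
                   endian = "little"),
    "5"  = readBin(con, double(), n, size = 8L, endian = "little"),
    "4"  = readBin(con, double(), n, size = 4L, endian = "little"),
    "2"  = readBin(con, integer(), n, size = 2L, signed = TRUE,
                   endian = "little"),
    stop("unsupported ENVI data type: ", dtype, call. = FALSE))
  if (length(vals) != n)
    stop("ENVI data file shorter than header-declared shape", call. = FALSE)
  data <- array(NA_real_, c(lines, samples, bands))
  for (b in seq_len(bands)) {
    off <- (b - 1L) * samples * lines
    data[, , b] <- t(matrix(vals[off + seq_len(samples * lines)],
                            nrow = samples))
  }
  vk <- f[["value kind"]] %||% "raw"
  bd <- as.integer(f[["bit depth"]] %||% 14L)
  hsi_cube(data, wl, value_kind = vk, bit_depth = bd)
}

write_cube_portable <- function(cube, path) {
  obj <- list(format = "nirhsi-cube", dims = dim(cube$data),
              wavelengths = cube$wavelengths, value_kind = cube$value_kind,
              bit_depth = cube$bit_depth, data = as.vector(cube$data))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), con)
}

read_cube_portable <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(gzfile(path), warn = FALSE),
                                  collapse = ""))
  if (!identical(obj$format, "nirhsi-cube"))
    stop("not a portable-array cube container: ", path, call. = FALSE)
  if (length(obj$data) != prod(obj$dims))
    stop("portable-array data length does not match declared dims",
         call. = FALSE)
  hsi_cube(array(obj$data, obj$dims), obj$wavelengths,
           value_kind = obj$value_kind, bit_depth = obj$bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a specimen annotation map
#'
#' The on-disk layout is plain text: `<base>_labels.txt` (the integer label
#' raster), `<base>_thickness.txt` (the tumor-thickness raster, mm) and
#' `<base>_meta.json` (label vocabulary and the boundary-line coordinates).
#'
#' @param path Base path (no extension); the three component files are
#'   derived from it.
#' @return [read_annotation()] returns an [annotation_map];
#'   [write_annotation()] returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  meta_path <- paste0(path, "_meta.json")
  if (!file.exists(meta_path))
    stop("annotation metadata not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  labels <- as.matrix(utils::read.table(paste0(path, "_labels.txt")))
  dimnames(labels) <- NULL
  thick <- as.matrix(utils::read.table(paste0(path, "_thickness.txt")))
  dimnames(thick) <- NULL
  as_mat <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    if (is.matrix(x)) return(x)
    matrix(as.integer(unlist(x)), ncol = 2L, byrow = TRUE)
  }
  annotation_map(labels,
                 tumor_boundary = as_mat(meta$tumor_boundary),
                 exposure_boundary = as_mat(meta$exposure_boundary),
                 thickness_mm = thick)
}

#' @rdname read_annotation
#' @param map An [annotation_map].
#' @export
write_annotation <- function(map, path) {
  if (!inherits(map, "annotation_map"))
    stop("`map` must be an annotation_map", call. = FALSE)
  utils::write.table(map$labels, paste0(path, "_labels.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(sprintf("%.17g", map$thickness_mm),
                            nrow(map$thickness_mm)),
                     paste0(path, "_thickness.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(vocabulary = as.list(LABELS),
               dims = dim(map$labels),
               tumor_boundary = unname(map$tumor_boundary),
               exposure_boundary = unname(map$exposure_boundary))
  jsonlite::write_json(meta, paste0(path, "_meta.json"), digits = NA)
  invisible(path)
}
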