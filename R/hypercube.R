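#' Hyperspectral reflectance cube
#'
#' Container for a calibrated reflectance image: a rows x cols x bands array
#' of dimensionless reflectance values (0-1 scale) together with the per-band
#' center wavelengths in nanometres. All spectral trait extraction starts from
#' this object.
#'
#' @param reflectance numeric 3-D array, rows x cols x bands, finite values.
#' @param wavelengths numeric vector of per-band center wavelengths (nm),
#'   strictly increasing, one per band.
#' @return An object of class `hyper_cube` with elements `reflectance` and
#'   `wavelengths`.
#' @export
#' @examples
#' cube <- hyper_cube(array(0.5, c(1, 1, 2)), c(550, 750))
#' dim(cube$reflectance)
hyper_cube <- function(reflectance, wavelengths) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3L)
    stop("`reflectance` must be a 3-D array (rows x cols x bands)")
  storage.mode(reflectance) <- "double"
  d <- dim(reflectance)
  if (any(d[1:2] < 1L))
    stop("spatial dimensions must be positive")
  if (!all(is.finite(reflectance)))
    stop("reflectance values must be finite")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != d[3L])
    stop("length(wavelengths) must equal the number of bands (",
         d[3L], "), got ", length(wavelengths))
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  structure(list(reflectance = reflectance, wavelengths = wavelengths),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# ---- ENVI I/O --------------------------------------------------------------
# Minimal ENVI support: text .hdr + flat binary. Read handles data types
# 2 (int16), 4 (float32), 5 (float64), 12 (uint16) and bsq/bil/bip
# interleave; write emits float64 bsq so cubes round-trip exactly.

.parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  if (!length(txt) || !grepl("ENVI", txt[[1]], ignore.case = TRUE))
    stop("not an ENVI header (missing 'ENVI' magic): ", hdr_path)
  joined <- paste(txt[-1], collapse = "\n")
  fields <- list()
  # scan key = value, where a {...} value may span lines
  pat <- "(?mi)^\\s*([a-z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  ms <- gregexpr(pat, joined, perl = TRUE)[[1]]
  if (ms[1] != -1) {
    starts <- ms
    lens <- attr(ms, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(joined, starts[i], starts[i] + lens[i] - 1L)
      key <- tolower(trimws(sub("(?si)^\\s*([a-z ]+?)\\s*=.*$", "\\1",
                                piece, perl = TRUE)))
      val <- trimws(sub("(?si)^\\s*[a-z ]+?\\s*=\\s*(.*)$", "\\1",
                        piece, perl = TRUE))
      fields[[key]] <- val
    }
  }
  fields
}

.envi_num_list <- function(v) {
  v <- gsub("[{}]", "", v)
  out <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
  out[!is.na(out)]
}

#' Read an ENVI hyperspectral image
#'
#' @param path path to the binary image file or to its `.hdr` header; the
#'   companion file is located automatically (`file.hdr` or `file` +
#'   `file.hdr` side-by-side conventions).
#' @return A [hyper_cube].
#' @export
read_envi <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) {
    hdr <- path
    img <- sub("\\.hdr$", "", path, ignore.case = TRUE)
    if (!file.exists(img)) img <- paste0(img, ".img")
  } else {
    img <- path
    hdr <- paste0(path, ".hdr")
    if (!file.exists(hdr))
      hdr <- paste0(sub("\\.[^.]*$", "", path), ".hdr")
  }
  if (!file.exists(img)) stop("ENVI image file not found: ", img)
  if (!file.exists(hdr)) stop("ENVI header not found for: ", path)
  f <- .parse_envi_header(hdr)
  need <- c("samples", "lines", "bands", "data type")
  miss <- need[!need %in% names(f)]
  if (length(miss))
    stop("ENVI header ", hdr, " is missing field(s): ",
         paste(miss, collapse = ", "))
  ns <- as.integer(f[["samples"]]); nl <- as.integer(f[["lines"]])
  nb <- as.integer(f[["bands"]]);   dt <- as.integer(f[["data type"]])
  interleave <- tolower(if (is.null(f[["interleave"]])) "bsq"
                        else f[["interleave"]])
  byte_order <- as.integer(if (is.null(f[["byte order"]])) 0L
                           else f[["byte order"]])
  if (is.null(f[["wavelength"]]))
    stop("ENVI header ", hdr,
         " has no 'wavelength' field; cannot resolve band wavelengths")
  wl <- .envi_num_list(f[["wavelength"]])
  if (length(wl) != nb)
    stop("ENVI header ", hdr, ": 'wavelength' lists ", length(wl),
         " values for ", nb, " bands")
  sz <- switch(as.character(dt), "2" = 2L, "12" = 2L, "4" = 4L, "5" = 8L,
               stop("unsupported ENVI data type ", dt, " in ", hdr))
  what <- if (dt %in% c(2L, 12L)) "integer" else "double"
  signed <- dt != 12L
  endian <- if (byte_order == 0L) "little" else "big"
  n <- ns * nl * nb
  con <- file(img, "rb"); on.exit(close(con))
  raw <- readBin(con, what = what, n = n, size = sz,
                 signed = signed, endian = endian)
  if (length(raw) != n)
    stop("ENVI image ", img, " truncated: expected ", n, " values, read ",
         length(raw))
  raw <- as.double(raw)
  # ENVI stores row-major within a band; R arrays are column-major
  arr <- switch(interleave,
    bsq = aperm(array(raw, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, c(nb, ns, nl)), c(3L, 2L, 1L)),
    stop("unsupported interleave '", interleave, "' in ", hdr))
  hyper_cube(arr, wl)
}

#' Write a cube as an ENVI image
#'
#' Emits a float64 band-sequential binary plus a text header carrying the
#' wavelengths, so [read_envi()] round-trips the cube exactly.
#'
#' @param cube a [hyper_cube].
#' @param path output binary path; `<path>.hdr` is written alongside.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$reflectance)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           paste0("wavelength units = Nanometers"),
           paste0("wavelength = {",
                  paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.vector(aperm(cube$reflectance, c(2L, 1L, 3L))), con,
           size = 8L, endian = "little")
  invisible(path)
}

#' Load a hyperspectral cube from disk
#'
#' @param path file path (ENVI binary or `.hdr`).
#' @param format input format; only `"envi"` is supported in this build
#'   (`"geotiff"` is recognised but rejected: no GeoTIFF reader is available
#'   in the supported dependency set).
#' @return A [hyper_cube].
#' @export
load_cube <- function(path, format = c("envi", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF input is not supported in this build; ",
         "convert to ENVI (.hdr + binary) or use read_envi()")
  if (!file.exists(path) && !file.exists(paste0(path, ".hdr")) &&
      !grepl("\\.hdr$", path))
    stop("file not found: ", path)
  read_envi(path)
}
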