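#' Canopy point cloud
#'
#' @param points numeric matrix with columns x, y, z, coordinates in cm.
#' @param sample_id sample identifier.
#' @return An object of class `point_cloud` with elements `points`
#'   (n x 3 matrix, columns `x`, `y`, `z`) and `sample_id`.
#' @export
point_cloud <- function(points, sample_id = "") {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("point coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, sample_id = as.character(sample_id)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  r <- apply(x$points, 2, range)
  cat(sprintf(paste0("<point_cloud> %d points%s  x[%.2f,%.2f] ",
                     "y[%.2f,%.2f] z[%.2f,%.2f] cm\n"),
              nrow(x$points),
              if (nzchar(x$sample_id)) paste0(" (", x$sample_id, ")") else "",
              r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  invisible(x)
}

#' Read whitespace-delimited XYZ text
#'
#' @param path file with one `x y z` row per point; extra columns ignored.
#' @param sample_id identifier attached to the cloud.
#' @return A [point_cloud].
#' @export
read_xyz <- function(path, sample_id = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tryCatch(as.matrix(utils::read.table(path)),
                error = function(e) stop("cannot parse XYZ file ", path,
                                         ": ", conditionMessage(e)))
  if (!nrow(m)) stop("empty point file: ", path)
  if (ncol(m) < 3L) stop("XYZ file ", path, " has fewer than 3 columns")
  point_cloud(m[, 1:3, drop = FALSE], sample_id)
}

#' Write a cloud as XYZ text
#' @param cloud a [point_cloud].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  utils::write.table(format(cloud$points, trim = TRUE, digits = 15),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a PLY point cloud
#'
#' Supports ascii and binary_little_endian PLY with float/double vertex
#' properties; only the x, y, z properties are used.
#'
#' @param path PLY file.
#' @param sample_id identifier attached to the cloud.
#' @return A [point_cloud].
#' @export
read_ply <- function(path, sample_id = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!length(magic) || trimws(magic) != "ply")
    stop("not a PLY file: ", path)
  fmt <- NULL; n_vertex <- NULL
  props <- character(); sizes <- integer(); in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated PLY header: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      props <- c(props, tok[3])
      sizes <- c(sizes, switch(tok[2],
        float = 4L, float32 = 4L, double = 8L, float64 = 8L,
        uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
        short = 2L, ushort = 2L, int = 4L, uint = 4L,
        stop("unsupported PLY property type '", tok[2], "' in ", path)))
    } else if (tok[1] == "end_header") break
  }
  if (is.null(n_vertex) || n_vertex < 1L)
    stop("PLY file ", path, " has no vertex element")
  ij <- match(c("x", "y", "z"), props)
  if (anyNA(ij)) stop("PLY file ", path, " lacks x/y/z vertex properties")
  if (identical(fmt, "ascii")) {
    rows <- readLines(con, n = n_vertex, warn = FALSE)
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    pts <- m[, ij, drop = FALSE]
  } else if (identical(fmt, "binary_little_endian")) {
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = stride * n_vertex)
    if (length(raw) < stride * n_vertex)
      stop("truncated PLY body: ", path)
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    pts <- sapply(ij, function(j) {
      idx <- as.vector(outer(seq_len(sizes[j]),
                             (seq_len(n_vertex) - 1L) * stride + offs[j],
                             `+`))
      readBin(raw[idx], "double", n = n_vertex, size = sizes[j],
              endian = "little")
    })
    pts <- matrix(pts, ncol = 3L)
  } else stop("unsupported PLY format '", fmt, "' in ", path)
  point_cloud(pts, sample_id)
}

#' Write a cloud as ascii PLY
#' @param cloud a [point_cloud].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(cloud$points)),
               "property double x", "property double y", "property double z",
               "end_header"), con)
  writeLines(apply(format(cloud$points, trim = TRUE, digits = 15), 1,
                   paste, collapse = " "), con)
  invisible(path)
}

#' Load a point cloud from disk
#'
#' @param path input file.
#' @param format `"ply"` or `"xyz"` (guessed from the extension by default);
#'   `"las"` is recognised but rejected: no LAS reader is available in the
#'   supported dependency set.
#' @param sample_id identifier attached to the cloud.
#' @return A [point_cloud] with at least 4 points.
#' @export
load_points <- function(path, format = c("auto", "ply", "xyz", "las"),
                        sample_id = "") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (format == "las")
    stop("LAS/LAZ input is not supported in this build; ",
         "convert to PLY or XYZ text")
  cloud <- switch(format, ply = read_ply(path, sample_id),
                  xyz = read_xyz(path, sample_id))
  if (nrow(cloud$points) < 4L)
    stop("point cloud ", path, " has fewer than 4 points")
  cloud
}
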