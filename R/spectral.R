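#' Built-in narrow-band vegetation index definitions
#'
#' The 16 indices used as spectral phenotypic traits. Each definition names
#' the center wavelengths it needs and a formula over the reflectances at
#' those wavelengths (`R550` is the reflectance of the band nearest 550 nm,
#' and so on). Categories group the indices by the physiological property
#' they track.
#'
#' The index set: SR680, PSSRb, Datt, mNDVI, BN (chlorophyll); ARI
#' (anthocyanin); CRI (carotenol); Srapa, TVI (leaf area index); WI, SWSI
#' (water); SRVI, CTR, NDVIlut, NDRI (stress); NDVI (biomass). BN uses the
#' natural log; any positive log base gives the same standardized trait.
#'
#' @return A named list of index definitions, each a list with elements
#'   `name`, `category`, `required_wavelengths` (nm) and `formula`
#'   (an R expression over `R<nm>` symbols).
#' @export
#' @examples
#' names(index_definitions())
index_definitions <- function() {
  def <- function(name, category, formula_chr) {
    e <- str2lang(formula_chr)
    wl <- sort(unique(as.numeric(sub("^R", "",
           grep("^R[0-9]+$", all.names(e), value = TRUE)))))
    list(name = name, category = category,
         required_wavelengths = wl, formula = e)
  }
  defs <- list(
    def("SR680",   "chlorophyll", "R800 / R680"),
    def("PSSRb",   "chlorophyll", "R800 / R635"),
    def("Datt",    "chlorophyll", "(R850 - R710) / (R850 - R680)"),
    def("mNDVI",   "chlorophyll", "(R750 - R705) / (R750 + R705 - 2 * R445)"),
    def("BN",      "chlorophyll", "log(R800 / R550)"),
    def("ARI",     "anthocyanin", "1 / R550 - 1 / R700"),
    def("CRI",     "carotenol",   "(1 / R510) - (1 / R550)"),
    def("Srapa",   "LAI",         "R900 / R680"),
    def("TVI",     "LAI",
        "0.5 * (120 * (R750 - R550) - 200 * (R670 - R550))"),
    def("WI",      "water",       "R900 / R970"),
    def("SWSI",    "water",       "(R803 - R681) / sqrt(R905 + R972)"),
    def("SRVI",    "stress",      "R830 / R660"),
    def("CTR",     "stress",      "R695 / R420"),
    def("NDVIlut", "stress",      "(R913 - R711) / (R913 + R711)"),
    def("NDRI",    "stress",      "(R790 - R720) / (R790 + R720)"),
    def("NDVI",    "biomass",     "(R800 - R670) / (R800 + R670)")
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Find the band nearest a requested wavelength
#'
#' Index formulas name wavelengths; real sensors sample a grid (the reference
#' imager's spectral resolution is 4.6875 nm), so each request is resolved to
#' the band whose center wavelength is closest. Ties go to the shorter
#' wavelength.
#'
#' @param cube a [hyper_cube].
#' @param wavelength requested wavelength, nm.
#' @param tolerance maximum allowed |center - request| in nm (default 10).
#' @return Integer band index.
#' @export
nearest_band <- function(cube, wavelength, tolerance = 10) {
  stopifnot(inherits(cube, "hyper_cube"), tolerance > 0)
  d <- abs(cube$wavelengths - wavelength)
  i <- which.min(d)  # which.min takes the first minimum = shorter wavelength
  if (d[i] > tolerance)
    stop(sprintf(
      "no band within %g nm of %g nm (nearest center: %g nm)",
      tolerance, wavelength, cube$wavelengths[i]))
  i
}

#' Compute a vegetation index image
#'
#' Evaluates one index formula per pixel. Division by zero yields NaN at the
#' affected pixel rather than aborting the scene; masked means later skip
#' NaNs.
#'
#' @param cube a [hyper_cube].
#' @param definition one element of [index_definitions()] (or a compatible
#'   list), or the name of a built-in index.
#' @param tolerance band-matching tolerance passed to [nearest_band()].
#' @return A rows x cols numeric matrix of index values.
#' @export
#' @examples
#' cube <- hyper_cube(array(c(0.1, 0.05, 0.5), c(1, 1, 3)),
#'                    c(550, 670, 750))
#' compute_index(cube, "TVI")   # 29
compute_index <- function(cube, definition, tolerance = 10) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (is.character(definition)) {
    defs <- index_definitions()
    if (!definition %in% names(defs))
      stop("unknown index '", definition, "'")
    definition <- defs[[definition]]
  }
  env <- new.env(parent = baseenv())
  for (wl in definition$required_wavelengths) {
    b <- nearest_band(cube, wl, tolerance)
    assign(paste0("R", format(wl, scientific = FALSE)),
           cube$reflectance[, , b, drop = TRUE], envir = env)
  }
  vals <- eval(definition$formula, env)
  d <- dim(cube$reflectance)
  vals <- matrix(as.numeric(vals), d[1L], d[2L])
  vals[is.infinite(vals)] <- NaN
  vals
}

#' Segment vegetation by TVI thresholding
#'
#' Pixels with TVI strictly greater than the threshold are vegetation;
#' boundary pixels are background. 10.6 is the operating threshold on the
#' 0-1 reflectance scale, where canopy TVI typically falls in the 10-30
#' range.
#'
#' @param tvi_grid numeric matrix of TVI values (from
#'   `compute_index(cube, "TVI")`).
#' @param threshold TVI cut (default 10.6).
#' @return An object of class `vegetation_mask`: list with `mask` (logical
#'   matrix) and `threshold_used`.
#' @export
segment_vegetation <- function(tvi_grid, threshold = 10.6) {
  if (!is.matrix(tvi_grid) || !is.numeric(tvi_grid))
    stop("`tvi_grid` must be a numeric matrix")
  if (!all(is.finite(tvi_grid)))
    stop("`tvi_grid` must be finite")
  mask <- tvi_grid > threshold
  if (!any(mask))
    stop("no vegetation pixels: no TVI value exceeds ", threshold)
  structure(list(mask = mask, threshold_used = threshold),
            class = "vegetation_mask")
}

#' @export
print.vegetation_mask <- function(x, ...) {
  cat(sprintf("<vegetation_mask> %d / %d pixels vegetation (TVI > %g)\n",
              sum(x$mask), length(x$mask), x$threshold_used))
  invisible(x)
}

#' Extract the 16 spectral traits of a sample
#'
#' Each index image is reduced to the arithmetic mean over vegetation pixels
#' (NaN pixels excluded), giving one trait value per index.
#'
#' @param cube a [hyper_cube].
#' @param mask a `vegetation_mask` (or a logical matrix) matching the cube's
#'   spatial dimensions with at least one `TRUE` pixel.
#' @param sample_id sample identifier stored with the trait vector.
#' @param tolerance band-matching tolerance, nm.
#' @return An object of class `spectral_traits`: list with `sample_id` and
#'   `values`, a named numeric vector over the 16 index names.
#' @export
extract_spectral_traits <- function(cube, mask, sample_id,
                                    tolerance = 10) {
  stopifnot(inherits(cube, "hyper_cube"))
  m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
  d <- dim(cube$reflectance)
  if (!is.logical(m) || !identical(dim(m), d[1:2]))
    stop("mask must be a logical matrix matching the cube's spatial grid")
  if (!any(m)) stop("mask has no vegetation pixels")
  defs <- index_definitions()
  values <- vapply(defs, function(def) {
    v <- compute_index(cube, def, tolerance)[m]
    v <- v[!is.nan(v)]
    if (!length(v))
      stop("index ", def$name, " is NaN at every vegetation pixel")
    mean(v)
  }, numeric(1))
  structure(list(sample_id = as.character(sample_id), values = values),
            class = "spectral_traits")
}

#' @export
print.spectral_traits <- function(x, ...) {
  cat("<spectral_traits> sample", x$sample_id, "\n")
  print(round(x$values, 4))
  invisible(x)
}
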