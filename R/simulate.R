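# Seeded generators for hyperspectral scenes, canopy point clouds and trait
# cohorts with known ground truth. All generators are pure functions of
# their spec (seed included): the RNG state is saved and restored.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Parametric canopy reflectance: visible floor that rises with stress, a
# green peak at 550 nm, a logistic red edge up to a NIR plateau that drops
# with stress, and a 970 nm water dip that shallows with stress. Not a
# radiative-transfer model; just enough structure to exercise every index.
.veg_reflectance <- function(wl, stress) {
  0.04 + 0.08 * stress +
    0.08 * exp(-(wl - 550)^2 / (2 * 25^2)) +
    (0.46 - 0.28 * stress) * stats::plogis((wl - 710) / 12) -
    0.12 * (1 - 0.5 * stress) * exp(-(wl - 970)^2 / (2 * 22^2))
}

# Smooth soil-like background ramp; its TVI sits near 0 on this scale.
.soil_reflectance <- function(wl) 0.08 + 0.00025 * (wl - 400)

#' Hyperspectral scene specification
#'
#' @param rows,cols scene size in pixels.
#' @param band_start,band_end,band_step spectral grid, nm (defaults
#'   400-1000 nm in 5 nm steps, covering every built-in index).
#' @param stress stress severity in [0, 1]; raises red reflectance, lowers
#'   the NIR plateau and shallows the water dip.
#' @param vegetation_blobs list of `list(center = c(row, col), radius)` in
#'   pixels; default one centered blob of radius `min(rows, cols) / 3`.
#' @param noise_sd per-pixel Gaussian reflectance noise sd.
#' @param seed RNG seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(rows = 40, cols = 40, band_start = 400,
                       band_end = 1000, band_step = 5, stress = 0,
                       vegetation_blobs = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, band_step > 0, band_start < band_end,
            stress >= 0, stress <= 1, noise_sd >= 0)
  if (is.null(vegetation_blobs))
    vegetation_blobs <- list(list(center = c(rows, cols) / 2,
                                  radius = min(rows, cols) / 3))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 band_start = band_start, band_end = band_end,
                 band_step = band_step, stress = stress,
                 vegetation_blobs = vegetation_blobs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic hyperspectral scene
#'
#' Vegetation blobs carry the parametric canopy spectrum at the requested
#' stress severity; everything else is the soil ramp. The true vegetation
#' mask is returned alongside the cube.
#'
#' @param spec a [scene_spec()].
#' @return List with `cube` (a [hyper_cube]), `mask` (logical matrix, the
#'   true vegetation footprint) and `spec`.
#' @export
make_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  wl <- seq(spec$band_start, spec$band_end, by = spec$band_step)
  mask <- matrix(FALSE, spec$rows, spec$cols)
  rr <- row(mask); cc <- col(mask)
  for (blob in spec$vegetation_blobs)
    mask <- mask | ((rr - blob$center[1])^2 + (cc - blob$center[2])^2 <=
                      blob$radius^2)
  veg <- .veg_reflectance(wl, spec$stress)
  soil <- .soil_reflectance(wl)
  arr <- array(0, c(spec$rows, spec$cols, length(wl)))
  for (b in seq_along(wl))
    arr[, , b] <- ifelse(mask, veg[b], soil[b])
  if (spec$noise_sd > 0)
    arr <- arr + .with_seed(spec$seed,
      array(stats::rnorm(length(arr), 0, spec$noise_sd), dim(arr)))
  list(cube = hyper_cube(arr, wl), mask = mask, spec = spec)
}

#' Canopy point-cloud specification
#'
#' @param shape `"box"`, `"hemisphere"` or `"ellipsoid"` (half-ellipsoid
#'   dome on a flat base).
#' @param dimensions cm: box `c(width, depth, height)`; hemisphere `radius`;
#'   ellipsoid semi-axes `c(a, b, c)`.
#' @param point_density surface sampling density, points/cm^2; points are
#'   laid on a regular raster (scanner-like) with spacing
#'   `1/sqrt(point_density)`.
#' @param outlier_count planted far outliers, uniform in the 2x inflated
#'   bounding box and kept clear of the surface so the default statistical
#'   filter can remove exactly them.
#' @param jitter_sd Gaussian coordinate jitter, cm.
#' @param seed RNG seed.
#' @return A `canopy_spec` list.
#' @export
canopy_spec <- function(shape = c("box", "hemisphere", "ellipsoid"),
                        dimensions = c(20, 20, 15), point_density = 8,
                        outlier_count = 0L, jitter_sd = 0.02, seed = 1L) {
  shape <- match.arg(shape)
  dimensions <- as.numeric(dimensions)
  nd <- switch(shape, box = 3L, hemisphere = 1L, ellipsoid = 3L)
  if (length(dimensions) != nd)
    stop("shape '", shape, "' needs ", nd, " dimension(s)")
  stopifnot(all(dimensions > 0), point_density > 0, outlier_count >= 0,
            jitter_sd >= 0)
  structure(list(shape = shape, dimensions = dimensions,
                 point_density = point_density,
                 outlier_count = as.integer(outlier_count),
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "canopy_spec")
}

.face_grid <- function(len, h) {
  n <- max(2L, ceiling(len / h) + 1L)
  seq(0, len, length.out = n)
}

# Box surfaces are rastered inset by half a laser-spot diameter (1 mm spot):
# a scanner measures patch centers, never the exact mathematical edge. This
# keeps the sampled footprint strictly inside the nominal one, so the
# occupied-cell area is not inflated by boundary-cell quantization.
.sample_box <- function(dim3, h, inset = 0.05) {
  dim3 <- pmax(dim3 - 2 * min(inset, min(dim3) / 4), dim3 / 2)
  w <- dim3[1]; d <- dim3[2]; ht <- dim3[3]
  gx <- .face_grid(w, h); gy <- .face_grid(d, h); gz <- .face_grid(ht, h)
  rbind(
    cbind(expand.grid(x = gx, y = gy), z = ht),     # top
    cbind(expand.grid(x = gx, y = gy), z = 0),      # bottom
    cbind(expand.grid(x = gx, z = gz), y = 0)[, c("x", "y", "z")],
    cbind(expand.grid(x = gx, z = gz), y = d)[, c("x", "y", "z")],
    cbind(expand.grid(y = gy, z = gz), x = 0)[, c("x", "y", "z")],
    cbind(expand.grid(y = gy, z = gz), x = w)[, c("x", "y", "z")]
  )
}

# dome of a half-ellipsoid (a, b, c): rings of constant polar angle, arc
# spacing ~h (scaled by the largest semi-axis), plus base rings and rim
.sample_dome <- function(abc, h) {
  a <- abc[1]; b <- abc[2]; c3 <- abc[3]
  R <- max(abc)
  n_theta <- max(3L, ceiling((pi / 2) * R / h))
  theta <- (seq_len(n_theta) - 0.5) * (pi / 2) / n_theta
  dome <- do.call(rbind, lapply(theta, function(th) {
    circ <- 2 * pi * max(a, b) * sin(th)
    m <- max(6L, ceiling(circ / h))
    phi <- (seq_len(m) - 0.5) * 2 * pi / m
    cbind(a * sin(th) * cos(phi), b * sin(th) * sin(phi),
          c3 * cos(th))
  }))
  rimm <- max(6L, ceiling(2 * pi * max(a, b) / h))
  phi <- (seq_len(rimm) - 0.5) * 2 * pi / rimm
  rim <- cbind(a * cos(phi), b * sin(phi), 0)
  n_r <- max(2L, ceiling(max(a, b) / h))
  base <- do.call(rbind, lapply(seq_len(n_r) - 0.5, function(k) {
    f <- k / n_r
    m <- max(6L, ceiling(2 * pi * max(a, b) * f / h))
    phi <- (seq_len(m) - 0.5) * 2 * pi / m
    cbind(a * f * cos(phi), b * f * sin(phi), 0)
  }))
  rbind(dome, rim, base)
}

# Analytic grid truth for domes: per-cell maximum of
# z = c * sqrt(1 - (x/a)^2 - (y/b)^2) with the grid anchored at (-a, -b);
# the minimized normalized radius over a cell is separable (clamp to 0).
.dome_grid_truth <- function(abc, cell) {
  a <- abc[1]; b <- abc[2]; c3 <- abc[3]
  nx <- ceiling(2 * a / cell); ny <- ceiling(2 * b / cell)
  x0 <- -a + (seq_len(nx) - 1) * cell
  y0 <- -b + (seq_len(ny) - 1) * cell
  cx <- pmax(0, pmax(x0, -(x0 + cell)))  # |x| closest to 0 within the cell
  cy <- pmax(0, pmax(y0, -(y0 + cell)))
  q <- outer((cx / a)^2, (cy / b)^2, `+`)
  occ <- q < 1
  list(height = mean(c3 * sqrt(1 - q[occ])), occupied = sum(occ))
}

#' Generate a synthetic canopy point cloud
#'
#' Surface-samples the named shape on a scanner-like regular raster, adds
#' Gaussian jitter, and appends labelled far outliers. Ground truth traits
#' come in closed form: box height/footprint/volume are exact; for domes the
#' height truth is the analytic mean of per-cell surface maxima on the
#' 0.5 cm grid, the footprint is pi*a*b, and the volume is (2/3)*pi*a*b*c.
#'
#' @param spec a [canopy_spec()].
#' @param sample_id identifier for the generated cloud.
#' @return List with `cloud` (a [point_cloud], outliers appended last),
#'   `truth` (list: `height`, `canopy_leaf_area`, `volume`, cm units),
#'   `outliers` (indices into the cloud of the planted outliers) and `spec`.
#' @export
make_canopy <- function(spec = canopy_spec(), sample_id = "synthetic") {
  stopifnot(inherits(spec, "canopy_spec"))
  h <- 1 / sqrt(spec$point_density)
  dims <- spec$dimensions
  surf <- switch(spec$shape,
    box = as.matrix(.sample_box(dims, h)),
    hemisphere = .sample_dome(rep(dims[1], 3), h),
    ellipsoid = .sample_dome(dims, h))
  truth <- switch(spec$shape,
    box = list(height = dims[3], canopy_leaf_area = dims[1] * dims[2],
               volume = prod(dims)),
    hemisphere = list(
      height = .dome_grid_truth(rep(dims[1], 3), 0.5)$height,
      canopy_leaf_area = pi * dims[1]^2,
      volume = 2 / 3 * pi * dims[1]^3),
    ellipsoid = list(
      height = .dome_grid_truth(dims, 0.5)$height,
      canopy_leaf_area = pi * dims[1] * dims[2],
      volume = 2 / 3 * pi * prod(dims)))
  .with_seed(spec$seed, {
    if (spec$jitter_sd > 0)
      surf <- surf + stats::rnorm(length(surf), 0, spec$jitter_sd)
    out_idx <- integer()
    if (spec$outlier_count > 0) {
      lo <- apply(surf, 2, min); hi <- apply(surf, 2, max)
      ctr <- (lo + hi) / 2; half <- pmax(hi - ctr, 1)
      clear <- max(10 * h, 2)  # keep outliers detectable by the knn filter
      outs <- matrix(NA_real_, spec$outlier_count, 3)
      k <- 0L; tries <- 0L
      while (k < spec$outlier_count && tries < 10000L) {
        tries <- tries + 1L
        cand <- ctr + stats::runif(3, -2, 2) * half
        d2 <- min((surf[, 1] - cand[1])^2 + (surf[, 2] - cand[2])^2 +
                    (surf[, 3] - cand[3])^2)
        if (d2 >= clear^2) { k <- k + 1L; outs[k, ] <- cand }
      }
      if (k < spec$outlier_count)
        stop("could not place ", spec$outlier_count, " clear outliers")
      out_idx <- nrow(surf) + seq_len(spec$outlier_count)
      surf <- rbind(surf, outs)
    }
    list(cloud = point_cloud(surf, sample_id), truth = truth,
         outliers = out_idx, spec = spec)
  })
}

#' Trait-cohort specification
#'
#' Trait j of sample i is `a_j + b_j * tolerance_i + noise`; the sign of the
#' effect `b_j` defines the trait's declared polarity.
#'
#' @param n_samples,m_traits cohort size (defaults 12 samples, 19 traits:
#'   the computing-phenotypic-trait layout of 3 structural + 16 spectral
#'   traits).
#' @param latent_tolerance per-sample latent tolerance; default equally
#'   spaced on [0, 1].
#' @param loadings signed per-trait effect sizes `b_j`; default 1 for all
#'   traits except three (negative-polarity stress-pigment slots) at -1.
#' @param noise_sd trait-unit Gaussian noise sd (default 0.1).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 12L, m_traits = 19L,
                        latent_tolerance = NULL, loadings = NULL,
                        noise_sd = 0.1, seed = 1L) {
  stopifnot(n_samples >= 2, m_traits >= 1, noise_sd >= 0)
  if (is.null(latent_tolerance))
    latent_tolerance <- seq(0, 1, length.out = n_samples)
  if (length(latent_tolerance) != n_samples)
    stop("need one latent tolerance per sample")
  if (is.null(loadings)) {
    loadings <- rep(1, m_traits)
    # default CPT layout: slots 9, 10, 16 are ARI, CRI, CTR (negative sense)
    neg <- intersect(c(9L, 10L, 16L), seq_len(m_traits))
    loadings[neg] <- -1
  }
  if (length(loadings) != m_traits) stop("need one loading per trait")
  if (any(loadings == 0)) stop("loadings must be nonzero")
  structure(list(n_samples = as.integer(n_samples),
                 m_traits = as.integer(m_traits),
                 latent_tolerance = as.numeric(latent_tolerance),
                 loadings = as.numeric(loadings),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

.cpt_trait_names <- function(m) {
  full <- c("Height", "Leaf-area", "Volume", names(index_definitions()))
  if (m == length(full)) full else paste0("T", seq_len(m))
}

#' Generate a synthetic trait cohort
#'
#' @param spec a [cohort_spec()].
#' @return List with `matrix` (a [trait_matrix] whose polarities match the
#'   loading signs) and `latent_tolerance` (the recovery target).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples; m <- spec$m_traits
  vals <- .with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m)
    outer(rep(1, n), seq_len(m)) +            # intercept a_j = j
      outer(spec$latent_tolerance, spec$loadings) + noise
  })
  colnames(vals) <- .cpt_trait_names(m)
  tm <- trait_matrix(vals,
                     sample_ids = paste0("S", seq_len(n)),
                     polarity = ifelse(spec$loadings > 0,
                                       "positive", "negative"))
  list(matrix = tm, latent_tolerance = spec$latent_tolerance)
}
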