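make_flat_cube <- function(refl, wl) {
  # 2 x 2 spatially constant cube from a named reflectance spectrum
  hyper_cube(array(rep(refl, each = 4), c(2, 2, length(wl))), wl)
}

test_that("hyper_cube validates its invariants", {
  expect_error(hyper_cube(array(1, c(2, 2, 3)), c(500, 400, 600)),
               "strictly increasing")
  expect_error(hyper_cube(array(1, c(2, 2, 3)), c(500, 600)),
               "equal the number of bands")
  expect_error(hyper_cube(array(c(1, NA), c(1, 1, 2)), c(500, 600)),
               "finite")
  cube <- hyper_cube(array(0.5, c(1, 1, 2)), c(550, 750))
  expect_identical(dim(cube$reflectance)[3], 2L)
})

test_that("ENVI round-trips exactly and rejects bad headers", {
  sc <- make_scene(scene_spec(rows = 7, cols = 9, band_step = 50,
                              noise_sd = 0.01, seed = 11))
  img <- file.path(tempdir(), "rt.img")
  write_envi(sc$cube, img)
  back <- read_envi(img)
  expect_identical(back$reflectance, sc$cube$reflectance)
  expect_identical(back$wavelengths, sc$cube$wavelengths)
  expect_identical(load_cube(img)$wavelengths, sc$cube$wavelengths)

  # header without wavelengths must fail naming the file
  hdr <- readLines(paste0(img, ".hdr"))
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(img, ".hdr"))
  expect_error(read_envi(img), "wavelength")
  expect_error(load_cube("no/such/file.img"), "not found")
  expect_error(load_cube(img, format = "geotiff"), "not supported")
})

test_that("nearest_band resolves wavelengths, ties to shorter, errors out of tolerance", {
  cube2 <- hyper_cube(array(1, c(1, 1, 2)), c(548, 552))
  expect_identical(nearest_band(cube2, 550), 1L)  # tie -> shorter
  grid <- seq(400, 1000, by = 5)
  cube <- hyper_cube(array(1, c(1, 1, length(grid))), grid)
  expect_identical(grid[nearest_band(cube, 673)], 675)
  expect_error(nearest_band(cube, 1200, tolerance = 10), "1200")
})

test_that("built-in definitions reproduce the published formulas", {
  defs <- index_definitions()
  expect_length(defs, 16L)
  expect_setequal(vapply(defs, `[[`, "", "category"),
                  c("chlorophyll", "anthocyanin", "carotenol", "LAI",
                    "water", "stress", "biomass"))
  # every formula symbol is declared
  for (d in defs) {
    syms <- as.numeric(sub("^R", "",
      grep("^R[0-9]+$", all.names(d$formula), value = TRUE)))
    expect_true(all(syms %in% d$required_wavelengths), info = d$name)
  }

  # hand evaluations at a spot spectrum
  wl <- c(420, 445, 510, 550, 635, 660, 670, 680, 681, 695, 700, 705,
          710, 711, 720, 750, 790, 800, 803, 830, 850, 900, 905, 913,
          970, 972)
  refl <- seq(0.05, 0.55, length.out = length(wl))
  names(refl) <- paste0("R", wl)
  cube <- make_flat_cube(refl, wl)
  px <- function(nm) refl[[paste0("R", nm)]]
  expect_equal(compute_index(cube, "TVI")[1, 1],
               0.5 * (120 * (px(750) - px(550)) - 200 * (px(670) - px(550))))
  expect_equal(compute_index(cube, "SWSI")[1, 1],
               (px(803) - px(681)) / sqrt(px(905) + px(972)))
  expect_equal(compute_index(cube, "mNDVI")[1, 1],
               (px(750) - px(705)) / (px(750) + px(705) - 2 * px(445)))
  expect_equal(compute_index(cube, "BN")[1, 1], log(px(800) / px(550)))
  expect_equal(compute_index(cube, "CRI")[1, 1],
               1 / px(510) - 1 / px(550))
})

test_that("compute_index hand values and NaN handling", {
  cube <- hyper_cube(array(c(0.1, 0.05, 0.5), c(1, 1, 3)),
                     c(550, 670, 750))
  expect_equal(compute_index(cube, "TVI")[1, 1], 29)

  # R800 = R670 -> NDVI exactly 0; R550 = R510 -> CRI exactly 0
  wl <- c(510, 550, 670, 800)
  cube2 <- make_flat_cube(c(0.2, 0.2, 0.3, 0.3), wl)
  expect_equal(compute_index(cube2, "NDVI")[1, 1], 0)
  expect_equal(compute_index(cube2, "CRI")[1, 1], 0)

  # zero denominator -> NaN, not an error
  cube3 <- make_flat_cube(c(0.2, 0.2, 0, 0), wl)
  expect_true(is.nan(compute_index(cube3, "NDVI")[1, 1]))
})

test_that("segment_vegetation is strict at the boundary and monotone", {
  grid <- matrix(c(5, 10.6, 15, 30), 2, 2, byrow = TRUE)
  m <- segment_vegetation(grid, 10.6)
  expect_identical(m$mask, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2,
                                  byrow = TRUE))
  expect_identical(m$threshold_used, 10.6)
  expect_error(segment_vegetation(matrix(5, 2, 2), 10.6), "no vegetation")

  # monotone: raising the threshold never adds pixels
  set.seed(3)
  g <- matrix(runif(400, 0, 30), 20, 20)
  prev <- segment_vegetation(g, 1)$mask
  for (thr in c(5, 12, 20)) {
    cur <- segment_vegetation(g, thr)$mask
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("segmentation recovers the true mask on fixture scenes", {
  sc <- make_scene(scene_spec(rows = 30, cols = 30, noise_sd = 0, seed = 4))
  m <- segment_vegetation(compute_index(sc$cube, "TVI"))
  expect_identical(m$mask, sc$mask)  # IoU 1 in the noiseless scene

  scn <- make_scene(scene_spec(rows = 30, cols = 30, noise_sd = 0.01,
                               seed = 4))
  mn <- segment_vegetation(compute_index(scn$cube, "TVI"))
  iou <- sum(mn$mask & scn$mask) / sum(mn$mask | scn$mask)
  expect_gte(iou, 0.95)
})

test_that("masked means behave like per-pixel arithmetic", {
  sc <- make_scene(scene_spec(rows = 12, cols = 12, noise_sd = 0.005,
                              seed = 8))
  cube <- sc$cube
  mask <- sc$mask

  # mask-then-average equals averaging the per-pixel index over the mask
  tr <- extract_spectral_traits(cube, mask, "s")
  expect_named(tr$values, names(index_definitions()))
  ndvi <- compute_index(cube, "NDVI")
  expect_equal(unname(tr$values["NDVI"]), mean(ndvi[mask]))

  # single-pixel mask reproduces that pixel's values
  one <- mask & FALSE
  px <- which(mask, arr.ind = TRUE)[1, ]
  one[px[1], px[2]] <- TRUE
  tr1 <- extract_spectral_traits(cube, one, "s")
  expect_equal(unname(tr1$values["TVI"]), compute_index(cube, "TVI")[px[1], px[2]])

  # dimension mismatch / empty mask
  expect_error(extract_spectral_traits(cube, mask[1:5, 1:5], "s"), "match")
  expect_error(extract_spectral_traits(cube, mask & FALSE, "s"),
               "no vegetation")
})

test_that("stress monotonically depresses the masked NDVI mean", {
  ndvi_at <- function(s) {
    sc <- make_scene(scene_spec(rows = 16, cols = 16, stress = s,
                                noise_sd = 0.002, seed = 5))
    m <- segment_vegetation(compute_index(sc$cube, "TVI"))
    unname(extract_spectral_traits(sc$cube, m, "s")$values["NDVI"])
  }
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), ndvi_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})
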