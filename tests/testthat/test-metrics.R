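test_that("band integrals follow trapezoidal geometry", {
  s <- as_spectra(data.frame(wavenumber = seq(2400, 2700, 2), absorbance = 1))
  expect_equal(band_integral(s, 2460, 2620)$value, 160)

  # local linear baseline annihilates any straight-line window
  line <- as_spectra(data.frame(wavenumber = seq(2400, 2700, 2),
                                absorbance = 0.5 + 0.001 * seq(2400, 2700, 2)))
  expect_equal(band_integral(line, 2460, 2620, "local_linear")$value, 0,
               tolerance = 1e-10)
  expect_error(band_integral(s, 2620, 2460), "lo < hi")
})

test_that("band integral matches dense quadrature of an analytic Gaussian", {
  wn <- seq(2400, 2700, 2)
  s <- as_spectra(data.frame(wavenumber = wn,
                             absorbance = gauss(wn, 2550, 10, 1)))
  v <- band_integral(s, 2420, 2680)$value
  # oracle: dense quadrature at 0.01 cm^-1
  xx <- seq(2420, 2680, 0.01)
  dense <- pracma::trapz(xx, gauss(xx, 2550, 10, 1))
  expect_equal(v, dense, tolerance = 0.005 * dense)
  expect_equal(v, 10 * sqrt(2 * pi), tolerance = 0.05)
})

test_that("band integrals are additive over adjacent windows", {
  wn <- seq(1000, 1400, 2)
  set.seed(5)
  s <- tiny_spectrum(wn, abs(rnorm(length(wn))) + gauss(wn, 1200, 30, 2))
  whole <- band_integral(s, 1000, 1400)$value
  parts <- band_integral(s, 1000, 1200)$value +
    band_integral(s, 1200, 1400)$value
  expect_equal(whole, parts, tolerance = 1e-10)
})

test_that("metrics are invariant to stored grid direction", {
  m <- synthetic_model(seed = 19)
  s <- generate_population(m, 2, groups = list(c("GIC7", "2mM")))
  path <- withr::local_tempfile(fileext = ".csv")
  sm <- spc_matrix(s)
  hdr <- paste(c("wavenumber", paste(sm$labels$cell_line, sm$labels$treatment,
                                     sm$labels$sample_id, sep = "/")),
               collapse = ",")
  rows <- vapply(rev(seq_along(sm$wn)), function(i)
    paste(c(sm$wn[i], sm$A[, i]), collapse = ","), character(1))
  writeLines(c(hdr, rows), path)                       # stored descending
  s_desc <- read_spectra(path)
  expect_equal(spectral_metrics(s_desc)[, -1],
               spectral_metrics(s)[, -1], tolerance = 1e-9)
})

test_that("unsaturation index recovers the generating area ratio", {
  # the two indexed bands share sigma, so the finite +/-10 windows clip the
  # same area fraction of each and their ratio equals the analytic area
  # ratio of the generating Gaussians
  wn <- seq(2780, 3050, 2)
  lipid <- function(olefinic_h) {
    gauss(wn, 2850, 6, 0.5) + gauss(wn, 2922, 9, 0.8) +
      gauss(wn, 2960, 8, 0.45) + gauss(wn, 3010, 6, olefinic_h)
  }
  # oracle: analytic areas of the generating bands; pick the olefinic height
  # so that area(3010) / area(2850) = 0.2 (equal sigmas: height ratio 0.2)
  h_ole <- 0.2 * 0.5
  s <- as_spectra(data.frame(wavenumber = wn, absorbance = lipid(h_ole)))
  u <- unsaturation_index(s)
  expect_equal(u$value, 0.2, tolerance = 0.01)

  # no olefinic band: fully saturated lipids read 0
  s0 <- as_spectra(data.frame(wavenumber = wn, absorbance = lipid(0)))
  expect_equal(unsaturation_index(s0)$value, 0, tolerance = 5e-3)

  # halving the olefinic amplitude halves the index
  sh <- as_spectra(data.frame(wavenumber = wn, absorbance = lipid(h_ole / 2)))
  expect_equal(unsaturation_index(sh)$value, u$value / 2, tolerance = 0.005)
})

test_that("CH3/CH2 peak ratio follows band heights", {
  wn <- seq(2880, 3000, 2)
  mk <- function(h3, h2) as_spectra(data.frame(
    wavenumber = wn,
    absorbance = gauss(wn, 2960, 7, h3) + gauss(wn, 2921, 7, h2)))
  expect_equal(peak_ratio(mk(0.4, 0.4))$value, 1, tolerance = 0.02)
  expect_equal(peak_ratio(mk(0.3, 0.6))$value, 0.5, tolerance = 0.02)

  # invariant under constant offset followed by rubber-band correction
  s <- mk(0.3, 0.6)
  s_off <- dplyr::mutate(s, absorbance = absorbance + 0.25)
  corrected <- rubber_band_correct(s_off)
  # oracle: subtracting the offset by hand gives the same ratio
  manual <- dplyr::mutate(s_off, absorbance = absorbance - 0.25)
  expect_equal(peak_ratio(corrected)$value, peak_ratio(manual)$value,
               tolerance = 0.02)

  flat <- as_spectra(data.frame(wavenumber = wn, absorbance = 0))
  expect_true(peak_ratio(flat)$undefined)
})

test_that("bh_index separates drug-treated from control cells", {
  m <- clean_model()
  ctrl <- bh_index(group_template(m, "GIC7", "control"))
  expect_equal(ctrl$value, 0)
  expect_true(ctrl$below_detection)

  # treated doublet: integral within 3% of the analytic area sum
  wn <- seq(2400, 2700, 2)
  s <- as_spectra(data.frame(
    wavenumber = wn,
    absorbance = gauss(wn, 2557, 8, 0.02) + gauss(wn, 2537, 8, 0.01)))
  v <- bh_index(s)
  oracle <- (0.02 + 0.01) * 8 * sqrt(2 * pi)
  expect_equal(v$value, oracle, tolerance = 0.03 * oracle)
  expect_false(v$below_detection)

  # dose monotonicity of the group means, mirroring the stronger 2 mM band
  t200 <- bh_index(group_template(m, "GIC7", "200uM"))$value
  t2mm <- bh_index(group_template(m, "GIC7", "2mM"))$value
  expect_gt(t2mm, t200)
})

test_that("map band integration localizes the programmed blob", {
  m <- clean_model()
  mp <- generate_map(m, nx = 9, ny = 9, step_um = 1.5,
                     nucleus_center = c(5, 5), nucleus_radius_um = 3)
  ms <- integrate_map_band(mp$map, mask = mp$mask)
  expect_equal(ms$hotspot, c(5, 5))
  expect_gt(ms$mask_fraction, 0.8)
  expect_true(all(ms$intensity >= 0))

  # repeated integration of the same map is bit-identical
  ms2 <- integrate_map_band(mp$map, mask = mp$mask)
  expect_identical(ms$intensity, ms2$intensity)
})

test_that("uniform maps flag the hotspot tie and centre the centroid", {
  wn <- seq(2400, 2700, 2)
  cube <- matrix(rep(gauss(wn, 2557, 8, 0.1), 25), nrow = 25, byrow = TRUE)
  mp <- hypermap(wn, cube, 5, 5, 1.5)
  ms <- integrate_map_band(mp)
  expect_true("hotspot_tie" %in% ms$flags)
  expect_equal(ms$hotspot, c(1, 1))          # row-major first occurrence
  expect_equal(ms$centroid, c(3, 3))

  zero <- hypermap(wn, matrix(0, 25, length(wn)), 5, 5, 1.5)
  mz <- integrate_map_band(zero)
  expect_true("hotspot_undefined" %in% mz$flags)
  expect_true(all(is.na(mz$hotspot)))
})
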