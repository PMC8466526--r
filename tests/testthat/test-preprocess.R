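test_that("EMSC recovers programmed offset, gain and drift", {
  wn <- seq(1000, 1800, 2)
  ref <- gauss(wn, 1650, 30, 1) + gauss(wn, 1550, 25, 0.6)
  raw <- dplyr::bind_rows(
    tiny_spectrum(wn, ref, "r0"),
    tiny_spectrum(wn, 0.5 + 2 * ref, "r1"),
    tiny_spectrum(wn, ref + 0.001 * wn, "r2"))
  out <- emsc_correct(raw, poly_order = 1, reference = ref, models = TRUE)
  cf <- out$coefficients
  A <- spc_matrix(out$spectra)$A

  # raw = reference: identity model
  expect_equal(cf$a[cf$sample_id == "r0"], 0, tolerance = 1e-10)
  expect_equal(cf$b[cf$sample_id == "r0"], 1, tolerance = 1e-10)
  expect_lt(max(abs(A["r0", ] - ref)), 1e-10)
  # exact affine case
  expect_equal(cf$a[cf$sample_id == "r1"], 0.5, tolerance = 1e-8)
  expect_equal(cf$b[cf$sample_id == "r1"], 2, tolerance = 1e-8)
  expect_lt(max(abs(A["r1", ] - ref)), 1e-10)

  # linear drift: oracle = explicit least squares on the 3-column design
  nu <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  X <- cbind(1, ref, nu)
  beta <- solve(crossprod(X), crossprod(X, ref + 0.001 * wn))
  corrected_oracle <- (ref + 0.001 * wn - beta[1] - beta[3] * nu) / beta[2]
  expect_lt(max(abs(A["r2", ] - corrected_oracle)), 1e-10)
  expect_lt(max(abs(A["r2", ] - ref)), 1e-8)
})

test_that("EMSC is idempotent and rejects a singular design", {
  m <- synthetic_model(seed = 5)
  s <- generate_population(m, 6, groups = list(c("GIC7", "control")))
  ref <- colMeans(spc_matrix(s)$A)
  once <- emsc_correct(s, reference = ref)
  again <- emsc_correct(once, reference = ref)
  expect_lt(max(abs(spc_matrix(again)$A - spc_matrix(once)$A)), 1e-8)

  const <- dplyr::bind_rows(tiny_spectrum(seq(1000, 1100, 2), rep(1, 51), "a"),
                            tiny_spectrum(seq(1000, 1100, 2), rep(1, 51), "b"))
  expect_error(emsc_correct(const, poly_order = 1), "collinear")
})

test_that("SNV satisfies its mean-0 / sample-sd-1 contract", {
  s <- tiny_spectrum(c(1000, 1001, 1002), c(1, 2, 3))
  out <- snv_normalize(s)
  expect_equal(out$absorbance, c(-1, 0, 1))   # sample sd (n-1) is exactly 1

  set.seed(11)
  for (i in 1:5) {
    r <- tiny_spectrum(seq(1000, 1198, 2), rnorm(100))
    o <- snv_normalize(r)
    expect_lt(abs(mean(o$absorbance)), 1e-12)
    expect_lt(abs(sd(o$absorbance) - 1), 1e-12)
  }
  expect_error(snv_normalize(tiny_spectrum(c(1000, 1001, 1002), c(5, 5, 5))),
               "zero variance")
})

test_that("unit-vector normalization is scale invariant with norm 1", {
  s <- tiny_spectrum(c(1000, 1001), c(3, 4))
  expect_equal(unit_vector_normalize(s)$absorbance, c(0.6, 0.8))
  expect_equal(unit_vector_normalize(unit_vector_normalize(s)),
               unit_vector_normalize(s))
  s7 <- dplyr::mutate(s, absorbance = 7 * absorbance)
  expect_equal(unit_vector_normalize(s7)$absorbance,
               unit_vector_normalize(s)$absorbance)
  expect_error(unit_vector_normalize(tiny_spectrum(c(1, 2) + 1000, c(0, 0))),
               "all-zero")
})

# brute-force lower-hull baseline: at each x, the highest line through two
# points that stays on or below every point
brute_hull_baseline <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sl <- (y[j] - y[i]) / (x[j] - x[i])
    line <- y[i] + sl * (x - x[i])
    if (all(line <= y + 1e-12)) base <- pmax(base, line)
  }
  base
}

test_that("rubber-band correction equals the brute-force lower hull", {
  set.seed(21)
  x <- sort(runif(50, 1000, 1800))
  y <- gauss(x, 1400, 60, 1) + 0.3 * sin(x / 90) + 0.001 * x
  s <- tiny_spectrum(x, y)
  out <- rubber_band_correct(s)
  expect_equal(out$absorbance, y - brute_hull_baseline(x, y),
               tolerance = 1e-10)
  expect_true(all(out$absorbance >= 0))
  expect_equal(out$absorbance[c(1, 50)], c(0, 0))
})

test_that("rubber-band correction removes lines and preserves peak height", {
  wn <- seq(1000, 1800, 2)
  line <- tiny_spectrum(wn, 0.2 + 0.001 * wn)
  expect_lt(max(abs(rubber_band_correct(line)$absorbance)), 1e-12)

  y <- gauss(wn, 1400, 30, 0.8) + 0.001 * wn
  out <- rubber_band_correct(tiny_spectrum(wn, y))
  expect_lt(abs(max(out$absorbance) - 0.8), 1e-3)
})

test_that("linear baseline correction zeroes the anchors", {
  wn <- seq(1580, 1720, 2)
  y <- gauss(wn, 1652, 10, 0.5) + 0.3 - 0.0002 * wn
  out <- linear_baseline_correct(tiny_spectrum(wn, y), 1600, 1700)
  expect_equal(out$absorbance[out$wavenumber %in% c(1600, 1700)], c(0, 0),
               tolerance = 1e-12)

  pure <- linear_baseline_correct(tiny_spectrum(wn, 1 + 0.002 * wn),
                                  1600, 1700)
  expect_lt(max(abs(pure$absorbance)), 1e-12)

  # oracle: analytic line subtraction leaves only the (tiny) band tails
  # outside the core
  yl <- gauss(wn, 1652, 10, 0.5)
  base <- yl[wn == 1600] + (yl[wn == 1700] - yl[wn == 1600]) *
    (wn - 1600) / 100
  o2 <- linear_baseline_correct(tiny_spectrum(wn, yl + 0.3 - 0.0002 * wn),
                                1600, 1700)
  expect_equal(o2$absorbance, yl - base, tolerance = 1e-10)

  expect_error(linear_baseline_correct(tiny_spectrum(wn, y), 1650, 1650),
               "anchors must differ")
})

test_that("Savitzky-Golay derivatives are exact for low-degree polynomials", {
  wn <- seq(1000, 1100, 2)
  # second derivative of nu^2 is exactly 2 at interior points
  d2 <- savgol_derivative(tiny_spectrum(wn, wn^2), deriv = 2)
  expect_equal(d2$absorbance, rep(2, length(wn) - 8), tolerance = 1e-8)
  # edge points are excluded, not padded
  expect_equal(range(d2$wavenumber), c(wn[5], wn[length(wn) - 4]))

  # smoothing (order 0) reproduces a cubic exactly at interior points
  y3 <- (wn - 1050)^3 / 1e4
  d0 <- savgol_derivative(tiny_spectrum(wn, y3), deriv = 0)
  expect_equal(d0$absorbance, y3[5:(length(wn) - 4)], tolerance = 1e-8)
})

test_that("SG second derivative tracks the analytic Gaussian derivative", {
  # the 9-point cubic filter's truncation error for a sigma = 10 band is
  # ~4% of the derivative extreme at 1 cm^-1 sampling and shrinks
  # quadratically with the spacing (~1% at 0.5 cm^-1)
  for (cfg in list(list(sp = 1, bound = 0.045), list(sp = 0.5, bound = 0.012))) {
    wn <- seq(1600, 1700, cfg$sp)
    y <- gauss(wn, 1652, 10, 1)
    d2 <- savgol_derivative(tiny_spectrum(wn, y), deriv = 2)
    analytic <- ((wn - 1652)^2 / 10^4 - 1 / 10^2) * gauss(wn, 1652, 10, 1)
    analytic <- analytic[wn %in% d2$wavenumber]
    expect_lt(max(abs(d2$absorbance - analytic)),
              cfg$bound * max(abs(analytic)))
  }
})

test_that("SG refuses unevenly spaced grids", {
  s <- tiny_spectrum(c(seq(1000, 1018, 2), 1021, seq(1024, 1040, 2)), 1:20)
  expect_error(savgol_derivative(s), "not equally spaced")
})
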