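# fixtures built in code: analytic Gaussian band sums and tidy wrappers

gauss <- function(wn, mu, sigma, h) h * exp(-(wn - mu)^2 / (2 * sigma^2))

# one-cell spectra tibble without ingestion validation (for tiny grids)
tiny_spectrum <- function(wn, a, id = "s1") {
  tibble::tibble(sample_id = id, cell_line = "unknown",
                 treatment = "unknown", wavenumber = wn, absorbance = a)
}

# five-Gaussian amide-I profile with a programmed alpha/beta area ratio;
# minor components (sidechain / beta-turn / antiparallel) take fixed area
# fractions and the remainder is split between alpha-helix and beta-sheet
make_amide_profile <- function(ratio, minors = c(sc = 0.08, turn = 0.12,
                                                 anti = 0.06),
                               sig = c(8, 10, 12, 9, 8),
                               wn = seq(1600, 1700, 1)) {
  cen <- c(1610, 1630, 1652, 1682, 1690)
  rest <- 1 - sum(minors)
  a_beta <- rest / (1 + ratio)
  areas <- c(minors[["sc"]], a_beta, ratio * a_beta, minors[["turn"]],
             minors[["anti"]])
  h <- areas / (sig * sqrt(2 * pi))
  y <- Reduce(`+`, lapply(1:5, function(j) gauss(wn, cen[j], sig[j], h[j])))
  as_spectra(data.frame(wavenumber = wn, absorbance = y))
}

# a noise/jitter/baseline/scatter-free model for exactness tests
clean_model <- function(seed = 1, ...) {
  synthetic_model(jitter_sd = 0, baseline_c0 = c(0, 0), baseline_c1 = c(0, 0),
                  baseline_c2 = c(0, 0), scatter_a = c(0, 0),
                  scatter_b = c(1, 1), noise_sd = 0, seed = seed, ...)
}
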