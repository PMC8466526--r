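#' Extended multiplicative signal correction (EMSC)
#'
#' Models each raw spectrum as
#' \deqn{A(\nu) = a + b\,m(\nu) + \sum_{k=1}^{p} d_k T_k(\tilde\nu)}
#' where \eqn{m(\nu)} is a reference spectrum (the set mean by default),
#' \eqn{T_k} are monomials in the wavenumber rescaled to \[-1, 1\] and the
#' coefficients are found per cell by ordinary least squares. The corrected
#' spectrum is \eqn{(A - a - \sum_k d_k T_k)/b}, which removes additive
#' baselines up to degree `poly_order` and multiplicative scatter in one
#' step.
#'
#' @param spectra A spectra table.
#' @param poly_order Degree of the polynomial baseline part (default 2).
#' @param reference Optional reference spectrum as a numeric vector on the
#'   set's grid, or a one-cell spectra table. Default: the set mean, which
#'   requires at least two cells.
#' @param models If `TRUE`, return a list with elements `spectra` (corrected)
#'   and `coefficients` (tibble of per-cell a, b, d1..dp); otherwise (the
#'   default) return just the corrected spectra table, for piping.
#' @return See `models`.
#' @examples
#' m <- synthetic_model(noise_sd = 0)
#' s <- generate_population(m, n_per_group = 3,
#'                          groups = list(c("GIC7", "control")))
#' corrected <- emsc_correct(s)
#' @export
emsc_correct <- function(spectra, poly_order = 2, reference = NULL,
                         models = FALSE) {
  m <- spc_matrix(spectra)
  if (is.null(reference)) {
    if (nrow(m$A) < 2) {
      abort("EMSC with the default mean reference needs at least 2 spectra")
    }
    ref <- colMeans(m$A)
  } else if (is.data.frame(reference)) {
    rm_ <- spc_matrix(reference)
    if (length(rm_$wn) != length(m$wn) || !all(rm_$wn == m$wn)) {
      abort("reference spectrum is not on the set's grid")
    }
    ref <- rm_$A[1, ]
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != length(m$wn)) {
      abort("reference length does not match the grid")
    }
  }

  nu <- 2 * (m$wn - min(m$wn)) / (max(m$wn) - min(m$wn)) - 1
  X <- cbind(intercept = 1, reference = ref)
  if (poly_order >= 1) {
    P <- vapply(seq_len(poly_order), function(k) nu^k, numeric(length(nu)))
    colnames(P) <- paste0("d", seq_len(poly_order))
    X <- cbind(X, P)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("EMSC design is singular; collinear column(s): ",
                 paste(dropped, collapse = ", "),
                 " (is the reference constant?)"))
  }

  coefs <- t(qr.coef(qrX, t(m$A)))   # one row per cell: a, b, d1..dp
  b <- coefs[, 2]
  if (any(b <= 1e-6)) {
    abort(paste0("EMSC gain b <= 1e-6 for cell(s): ",
                 paste(rownames(m$A)[b <= 1e-6], collapse = ", ")))
  }
  additive <- coefs[, -2, drop = FALSE] %*% t(X[, -2, drop = FALSE])
  corrected <- (m$A - additive) / b
  out <- spectra_from_matrix(m$wn, corrected, m$labels)
  if (!models) return(out)
  ctab <- tibble::as_tibble(coefs)
  names(ctab) <- c("a", "b", colnames(X)[-(1:2)])
  list(spectra = out,
       coefficients = dplyr::bind_cols(m$labels["sample_id"], ctab))
}

per_cell <- function(spectra, f, ...) {
  spectra |>
    dplyr::group_by(.data$sample_id, .data$cell_line, .data$treatment) |>
    dplyr::group_modify(function(d, key) f(d, ...)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "cell_line", "treatment",
                  "wavenumber", "absorbance")
}

#' Standard normal variate (SNV) normalization
#'
#' Centers each cell's spectrum to mean 0 and scales to sample standard
#' deviation 1 (denominator n - 1, the chemometrics convention).
#'
#' @param spectra A spectra table.
#' @return The normalized spectra table.
#' @export
snv_normalize <- function(spectra) {
  per_cell(spectra, function(d, ...) {
    s <- sd(d$absorbance)
    if (!is.finite(s) || s == 0) {
      abort("SNV undefined for a constant spectrum (zero variance)")
    }
    d$absorbance <- (d$absorbance - mean(d$absorbance)) / s
    d
  })
}

#' Unit-vector normalization
#'
#' Scales each cell's spectrum to unit Euclidean norm, preserving direction.
#'
#' @param spectra A spectra table.
#' @return The normalized spectra table.
#' @export
unit_vector_normalize <- function(spectra) {
  per_cell(spectra, function(d, ...) {
    nrm <- sqrt(sum(d$absorbance^2))
    if (nrm == 0) abort("cannot unit-vector normalize an all-zero spectrum")
    d$absorbance <- d$absorbance / nrm
    d
  })
}

# Lower convex hull of (x, y) by Andrew's monotone chain; returns indices of
# hull vertices in ascending x. x must be strictly ascending.
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # drop b if it lies on or above the segment a-i (cross product <= 0)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Rubber-band baseline correction
#'
#' Estimates the baseline of each cell's spectrum as the lower convex hull of
#' its (wavenumber, absorbance) points, evaluated by linear interpolation
#' between hull vertices, and subtracts it. The corrected spectrum is
#' non-negative everywhere and zero at the hull vertices (including both
#' endpoints).
#'
#' @param spectra A spectra table (at least 3 points per cell).
#' @return The baseline-corrected spectra table.
#' @export
rubber_band_correct <- function(spectra) {
  per_cell(spectra, function(d, ...) {
    if (nrow(d) < 3) abort("rubber-band correction needs at least 3 points")
    h <- lower_hull_idx(d$wavenumber, d$absorbance)
    base <- approx(d$wavenumber[h], d$absorbance[h],
                   xout = d$wavenumber, method = "linear")$y
    d$absorbance <- pmax(d$absorbance - base, 0)
    d
  })
}

#' Linear baseline correction between two anchor wavenumbers
#'
#' Subtracts from each cell the straight line through the spectrum's values
#' at `anchor_lo` and `anchor_hi` (linearly interpolated if the anchors fall
#' between grid points). The result is zero at both anchors. This is the
#' baseline used on the amide-I window 1600-1700 cm^-1 before
#' secondary-structure deconvolution.
#'
#' @param spectra A spectra table.
#' @param anchor_lo,anchor_hi Anchor wavenumbers inside the grid span.
#' @return The corrected spectra table.
#' @export
linear_baseline_correct <- function(spectra, anchor_lo, anchor_hi) {
  if (anchor_lo == anchor_hi) abort("anchors must differ")
  wn <- spc_grid(spectra)
  if (min(anchor_lo, anchor_hi) < min(wn) || max(anchor_lo, anchor_hi) > max(wn)) {
    abort("anchors must lie inside the grid span")
  }
  per_cell(spectra, function(d, ...) {
    y_lo <- approx(d$wavenumber, d$absorbance, xout = anchor_lo)$y
    y_hi <- approx(d$wavenumber, d$absorbance, xout = anchor_hi)$y
    slope <- (y_hi - y_lo) / (anchor_hi - anchor_lo)
    d$absorbance <- d$absorbance - (y_lo + slope * (d$wavenumber - anchor_lo))
    d
  })
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Convolves each cell's spectrum with least-squares polynomial-fit
#' coefficients (defaults: window 9 points, 3rd-order polynomial, 2nd
#' derivative -- the standard choice for resolving overlapped amide-I
#' components, whose band centres appear as second-derivative minima).
#' Derivatives are scaled by the actual grid spacing, which must be uniform.
#' The `(window - 1) / 2` points at each end of the grid have no full window
#' and are dropped rather than padded, so edge artefacts can never feed the
#' downstream minima search.
#'
#' @param spectra A spectra table on an equally spaced grid.
#' @param window Odd window length in points (default 9).
#' @param poly Polynomial order, less than `window` (default 3).
#' @param deriv Derivative order 0, 1 or 2 (default 2).
#' @return Spectra table on the interior grid (edges removed).
#' @export
savgol_derivative <- function(spectra, window = 9, poly = 3, deriv = 2) {
  if (window %% 2 != 1) abort("window must be odd")
  if (poly >= window) abort("poly must be smaller than window")
  if (!deriv %in% 0:2) abort("deriv must be 0, 1 or 2")
  wn <- spc_grid(spectra)
  dw <- diff(wn)
  h <- mean(dw)
  if (any(abs(dw - h) > 1e-6 * abs(h))) {
    abort("grid is not equally spaced; resample_spectra() first")
  }
  if (length(wn) < window) abort("grid shorter than the smoothing window")

  # central-row SG coefficients, including the factorial(deriv)/h^deriv scale
  half <- (window - 1) %/% 2
  F <- signal::sgolay(p = poly, n = window, m = deriv, ts = h)
  w <- F[half + 1, ]
  keep <- (half + 1):(length(wn) - half)

  per_cell(spectra, function(d, ...) {
    y <- d$absorbance
    conv <- vapply(keep, function(i) sum(w * y[(i - half):(i + half)]),
                   numeric(1))
    tibble::tibble(wavenumber = d$wavenumber[keep], absorbance = conv)
  })
}
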