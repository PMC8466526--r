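#' Tidy single-cell spectra tables
#'
#' Throughout the package a *spectra table* is a long tibble with one row per
#' (cell, wavenumber) pair and the columns
#' \describe{
#'   \item{`sample_id`}{unique cell identifier (character)}
#'   \item{`cell_line`}{cell-line label, e.g. `"GIC7"` or `"PG88"`}
#'   \item{`treatment`}{treatment label, e.g. `"control"`, `"200uM"`, `"2mM"`}
#'   \item{`wavenumber`}{position in cm^-1, ascending within each cell}
#'   \item{`absorbance`}{absorbance in AU}
#' }
#' All cells in one table share a common wavenumber grid. `as_spectra()`
#' validates (and, where possible, repairs) a data frame into this contract:
#' rows are sorted to an ascending grid (FTIR instruments typically emit
#' descending wavenumbers), and non-finite absorbances or grid mismatches are
#' rejected.
#'
#' @param x A data frame with at least `wavenumber` and `absorbance` columns.
#'   Missing label columns are filled with `"unknown"` (`cell_line`,
#'   `treatment`) or a single `"s1"` (`sample_id`).
#' @return A validated spectra tibble, ascending in wavenumber within cell.
#' @examples
#' df <- data.frame(wavenumber = c(1700, 1650, 1600), absorbance = c(0, 1, 0))
#' as_spectra(df)
#' @export
as_spectra <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("wavenumber", "absorbance") %in% names(x))) {
    abort("spectra tables need `wavenumber` and `absorbance` columns")
  }
  if (!"sample_id" %in% names(x)) x$sample_id <- "s1"
  if (!"cell_line" %in% names(x)) x$cell_line <- "unknown"
  if (!"treatment" %in% names(x)) x$treatment <- "unknown"
  x <- dplyr::select(x, "sample_id", "cell_line", "treatment",
                     "wavenumber", "absorbance")
  x$sample_id <- as.character(x$sample_id)
  x$cell_line <- as.character(x$cell_line)
  x$treatment <- as.character(x$treatment)
  if (anyNA(x$sample_id) || anyNA(x$cell_line) || anyNA(x$treatment)) {
    abort("incomplete labels: sample_id/cell_line/treatment must not be NA")
  }
  if (!all(is.finite(x$absorbance))) {
    abort("non-finite absorbance values are not allowed after ingestion")
  }
  x <- dplyr::arrange(x, .data$sample_id, .data$wavenumber)
  validate_spectra(x)
  x
}

validate_spectra <- function(x) {
  wn <- spc_grid(x)
  if (any(wn < 400) || any(wn > 8000)) {
    abort("wavenumbers outside the plausible mid/near-IR range [400, 8000] cm^-1")
  }
  if (length(wn) < 9) {
    abort("grid too short: at least 9 points needed (smallest Savitzky-Golay window)")
  }
  invisible(x)
}

#' Shared wavenumber grid of a spectra table
#'
#' @param spectra A spectra table (see [as_spectra()]).
#' @return Ascending numeric vector of wavenumbers common to every cell.
#' @export
spc_grid <- function(spectra) {
  wn_by <- split(spectra$wavenumber, spectra$sample_id)
  wn <- wn_by[[1]]
  if (anyDuplicated(wn)) abort("duplicate wavenumbers within a spectrum")
  if (is.unsorted(wn, strictly = TRUE)) {
    abort("wavenumber grid must be strictly ascending within each cell")
  }
  ok <- vapply(wn_by, function(w) length(w) == length(wn) && all(w == wn),
               logical(1))
  if (!all(ok)) {
    abort(paste0("cells do not share a common grid: ",
                 paste(names(wn_by)[!ok], collapse = ", ")))
  }
  wn
}

#' Convert between spectra tables and absorbance matrices
#'
#' `spc_matrix()` reshapes a spectra table into the cells-by-wavenumbers
#' matrix used by multivariate methods; `spectra_from_matrix()` is its
#' inverse.
#'
#' @param spectra A spectra table.
#' @return For `spc_matrix()`: a list with `wn` (grid), `A` (matrix, one row
#'   per cell, columns in grid order, rownames = sample ids) and `labels`
#'   (tibble of sample_id/cell_line/treatment, one row per cell).
#' @export
spc_matrix <- function(spectra) {
  wn <- spc_grid(spectra)
  labels <- dplyr::distinct(spectra, .data$sample_id, .data$cell_line,
                            .data$treatment)
  if (anyDuplicated(labels$sample_id)) {
    abort("sample_id maps to more than one (cell_line, treatment) pair")
  }
  spectra <- dplyr::arrange(spectra, .data$sample_id, .data$wavenumber)
  ids <- sort(unique(spectra$sample_id))
  A <- matrix(spectra$absorbance[order(match(spectra$sample_id, ids))],
              nrow = length(ids), ncol = length(wn), byrow = TRUE,
              dimnames = list(ids, NULL))
  labels <- labels[match(ids, labels$sample_id), ]
  list(wn = wn, A = A, labels = labels)
}

#' @rdname spc_matrix
#' @param wn Ascending wavenumber grid.
#' @param A Matrix of absorbances, one row per cell.
#' @param labels Tibble with columns sample_id, cell_line, treatment (one row
#'   per row of `A`).
#' @export
spectra_from_matrix <- function(wn, A, labels) {
  stopifnot(nrow(A) == nrow(labels), ncol(A) == length(wn))
  tbl <- tibble::tibble(
    sample_id = rep(labels$sample_id, each = length(wn)),
    cell_line = rep(labels$cell_line, each = length(wn)),
    treatment = rep(labels$treatment, each = length(wn)),
    wavenumber = rep(wn, times = nrow(A)),
    absorbance = as.vector(t(A))
  )
  as_spectra(tbl)
}

#' Spectral regions
#'
#' A region is a closed wavenumber interval \[lo, hi\]. `region()` builds one;
#' `ftir_regions()` returns the preset intervals used for glioma single-cell
#' analysis: DNA 900-1350, fingerprint 1000-1800, protein 1480-1800, lipids
#' 2800-3000, amide I 1600-1700, amide II 1480-1600 and the boron-cluster
#' B-H stretch window 2460-2620 cm^-1.
#'
#' @param name Region name.
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`.
#' @return A `ftir_region` object (named list with `name`, `lo`, `hi`).
#' @examples
#' region("amide_i", 1600, 1700)
#' names(ftir_regions())
#' @export
region <- function(name, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    abort("region needs numeric bounds with lo < hi")
  }
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "ftir_region")
}

#' @export
print.ftir_region <- function(x, ...) {
  cat(sprintf("<region> %s: %g-%g cm^-1\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' @rdname region
#' @export
ftir_regions <- function() {
  list(
    dna         = region("dna", 900, 1350),
    fingerprint = region("fingerprint", 1000, 1800),
    protein     = region("protein", 1480, 1800),
    lipids      = region("lipids", 2800, 3000),
    amide_i     = region("amide_i", 1600, 1700),
    amide_ii    = region("amide_ii", 1480, 1600),
    bh          = region("bh", 2460, 2620)
  )
}

as_region <- function(r) {
  if (inherits(r, "ftir_region")) return(r)
  if (is.character(r) && length(r) == 1) {
    presets <- ftir_regions()
    if (!r %in% names(presets)) {
      abort(paste0("unknown preset region '", r, "'; see ftir_regions()"))
    }
    return(presets[[r]])
  }
  if (is.numeric(r) && length(r) == 2) return(region("custom", min(r), max(r)))
  abort("region must be an ftir_region, a preset name, or c(lo, hi)")
}

#' Restrict spectra to a wavenumber region
#'
#' Keeps exactly the grid points with `lo <= wavenumber <= hi` (closed
#' interval); no edge interpolation is performed, so the region content is
#' defined by the measured grid, matching how integration windows are
#' conventionally stated.
#'
#' @param spectra A spectra table.
#' @param r A region: an [region()] object, a preset name from
#'   [ftir_regions()], or a numeric `c(lo, hi)`.
#' @return The restricted spectra table.
#' @examples
#' s <- as_spectra(data.frame(wavenumber = seq(800, 4000, 2), absorbance = 0))
#' nrow(extract_region(s, "dna"))  # 226 grid points per cell
#' @export
extract_region <- function(spectra, r) {
  r <- as_region(r)
  out <- dplyr::filter(spectra, .data$wavenumber >= r$lo,
                       .data$wavenumber <= r$hi)
  if (nrow(out) == 0) {
    abort(sprintf("region %s [%g, %g] does not intersect the grid",
                  r$name, r$lo, r$hi))
  }
  out
}

#' Resample spectra onto a target grid
#'
#' Needed to pool files recorded on unequal grids before multivariate
#' analysis. The default cubic-spline interpolation keeps smooth absorption
#' bands accurate even when coarsening or refining the grid by a factor of
#' a few (linear interpolation clips band maxima noticeably at typical
#' widths); `method = "linear"` is available for strictly local behaviour.
#' Either way, values at grid points shared with the source are unchanged
#' and extrapolation outside the recorded span is refused.
#'
#' @param spectra A spectra table.
#' @param target Ascending numeric vector of target wavenumbers, inside the
#'   span of the source grid.
#' @param method `"spline"` (default) or `"linear"`.
#' @return Spectra table on the target grid.
#' @export
resample_spectra <- function(spectra, target, method = c("spline", "linear")) {
  method <- match.arg(method)
  wn <- spc_grid(spectra)
  target <- sort(unique(as.numeric(target)))
  if (min(target) < min(wn) || max(target) > max(wn)) {
    abort("target grid requires extrapolation outside the recorded span")
  }
  interp <- function(x, y) {
    if (method == "spline") {
      stats::spline(x, y, xout = target, method = "natural")$y
    } else {
      approx(x, y, xout = target, method = "linear")$y
    }
  }
  spectra |>
    dplyr::group_by(.data$sample_id, .data$cell_line, .data$treatment) |>
    dplyr::reframe(
      absorbance = interp(.data$wavenumber, .data$absorbance),
      wavenumber = target
    ) |>
    as_spectra()
}
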