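#' Region-wise principal component analysis of spectra
#'
#' Runs mean-centred PCA (via singular value decomposition) on one spectral
#' region after the preprocessing chain conventionally used for that region:
#' \describe{
#'   \item{`"snv"`}{EMSC then per-cell SNV -- the chain for the fingerprint
#'     and lipids regions.}
#'   \item{`"d2"`}{EMSC, Savitzky-Golay second derivative (window 9, order
#'     3), then unit-vector normalization -- the chain for the DNA region,
#'     where derivative spectra resolve the overlapped phosphate bands.}
#'   \item{`"none"`}{no preprocessing (the data are taken as given).}
#' }
#' No autoscaling is applied: spectra are already normalized upstream, so
#' only column mean-centring is performed. Loadings follow a deterministic
#' sign convention (each component's largest-magnitude element is positive),
#' making scores reproducible across runs.
#'
#' @param spectra A spectra table.
#' @param region Region to analyse (see [extract_region()]).
#' @param recipe Preprocessing chain, one of `"snv"`, `"d2"`, `"none"`.
#' @param k Number of components to keep (default 3, matching the PC-1..PC-3
#'   score/loading plots typical of this analysis); must be < number of
#'   cells.
#' @return An object of class `ftir_pca` with elements `scores` (cells x k),
#'   `loadings` (wavenumbers x k, orthonormal columns), `explained` (variance
#'   fractions), `center`, `wn`, `labels`, `region`, `recipe`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' m <- synthetic_model(seed = 7)
#' s <- generate_population(m, n_per_group = 10,
#'                          groups = list(c("GIC7", "control"), c("GIC7", "2mM")))
#' p <- run_pca(s, "lipids", recipe = "snv")
#' glance(p)
#' @export
run_pca <- function(spectra, region, recipe = c("snv", "d2", "none"), k = 3) {
  recipe <- match.arg(recipe)
  r <- as_region(region)
  s <- extract_region(spectra, r)
  s <- switch(recipe,
    snv  = snv_normalize(emsc_correct(s)),
    d2   = unit_vector_normalize(savgol_derivative(emsc_correct(s))),
    none = s)
  m <- spc_matrix(s)
  n <- nrow(m$A)
  if (k >= n) abort("k must be smaller than the number of spectra")
  if (all(abs(sweep(m$A, 2, m$A[1, ])) < 1e-14)) {
    abort("degenerate set: all spectra identical, PCA undefined")
  }
  p <- stats::prcomp(m$A, center = TRUE, scale. = FALSE, rank. = k)
  # sign convention: largest-|loading| element of each PC made positive
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rotation <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  explained <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  structure(list(scores = scores, loadings = rotation, explained = explained,
                 center = p$center, wn = m$wn, labels = m$labels,
                 region = r, recipe = recipe),
            class = "ftir_pca")
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> region %s [%g-%g], recipe '%s', %d cells, %d components\n",
              x$region$name, x$region$lo, x$region$hi, x$recipe,
              nrow(x$scores), ncol(x$scores)))
  cat("explained:", paste0(sprintf("%.1f%%", 100 * x$explained),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a region-wise PCA
#'
#' @param x A `ftir_pca` object.
#' @param matrix Which quantity to return: `"scores"` (one row per cell and
#'   component, with labels), `"loadings"` (one row per wavenumber and
#'   component) or `"eigenvalues"` (explained-variance fractions).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ftir_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  k <- ncol(x$scores)
  if (matrix == "scores") {
    out <- tibble::as_tibble(x$scores)
    names(out) <- paste0("PC", seq_len(k))
    dplyr::bind_cols(x$labels, out) |>
      tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                          values_to = "score")
  } else if (matrix == "loadings") {
    out <- tibble::as_tibble(x$loadings)
    names(out) <- paste0("PC", seq_len(k))
    dplyr::bind_cols(tibble::tibble(wavenumber = x$wn), out) |>
      tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                          values_to = "loading")
  } else {
    tibble::tibble(component = paste0("PC", seq_len(k)),
                   explained = x$explained,
                   cumulative = cumsum(x$explained))
  }
}

#' @rdname tidy.ftir_pca
#' @export
glance.ftir_pca <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$scores), n_wavenumbers = length(x$wn),
                 k = ncol(x$scores), region = x$region$name,
                 recipe = x$recipe,
                 cum_explained = sum(x$explained))
}

#' Plot PCA scores or loadings
#'
#' @param object A `ftir_pca` object.
#' @param type `"scores"` (PC1 vs PC2 scatter, coloured by treatment, shaped
#'   by cell line) or `"loadings"` (loading curves vs wavenumber).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ftir_pca <- function(object, type = c("scores", "loadings"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    d <- dplyr::bind_cols(object$labels,
                          tibble::tibble(PC1 = object$scores[, 1],
                                         PC2 = object$scores[, 2]))
    ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                    colour = .data$treatment,
                                    shape = .data$cell_line)) +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = sprintf("PC-1 (%.1f%%)", 100 * object$explained[1]),
        y = sprintf("PC-2 (%.1f%%)", 100 * object$explained[2]),
        title = sprintf("PCA scores, %s region", object$region$name))
  } else {
    tidy(object, "loadings") |>
      ggplot2::ggplot(ggplot2::aes(.data$wavenumber, .data$loading,
                                   colour = .data$component)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "loading",
                    title = sprintf("PCA loadings, %s region",
                                    object$region$name))
  }
}
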