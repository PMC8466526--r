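#' Component band library for synthetic single-cell spectra
#'
#' Gaussian component bands emulating the mid-IR absorptions of a glioma
#' cell plus the cobaltabis(dicarbollide) boron-cluster drug: protein amide I
#' secondary-structure components (sidechain 1610, beta-sheet 1630,
#' alpha-helix 1652, beta-turn 1682, antiparallel beta-sheet 1690 cm^-1) and
#' amide II; DNA phosphate stretches; lipid CH2/CH3 stretches with the
#' olefinic =C-H band at 3010 cm^-1; and the drug's B-H stretch doublet at
#' 2557 cm^-1 with its 2537 cm^-1 sub-peak plus the cluster C-H at
#' 3031 cm^-1. Amplitudes are synthetic conventions chosen to give realistic
#' relative band intensities; only their directions of change across groups
#' mimic the biology.
#'
#' @return Tibble with columns `assignment`, `center`, `sigma`, `amplitude`.
#' @export
band_library <- function() {
  tibble::tribble(
    ~assignment,       ~center, ~sigma, ~amplitude,
    "sidechain",         1610,     8,     0.050,
    "amideI_beta",       1630,    10,     0.180,
    "amideI_alpha",      1652,    12,     0.420,
    "amideI_turn",       1682,     9,     0.060,
    "amideI_anti",       1690,     8,     0.040,
    "amideII",           1545,    18,     0.300,
    "phosphate_asym",    1236,    16,     0.120,
    "phosphate_sym",     1085,    15,     0.150,
    "ch2_sym",           2852,     9,     0.100,
    "ch2_asym",          2922,    10,     0.160,
    "ch3_asym",          2960,     9,     0.100,
    "olefinic",          3010,     8,     0.020,
    "BH_main",           2557,    10,     0.030,
    "BH_sub",            2537,     9,     0.015,
    "Cc_H",              3031,     6,     0.008
  )
}

#' Default group-effect table
#'
#' Multiplicative per-assignment amplitude factors for each
#' (cell_line, treatment) group. Control rows carry exactly 0 for the drug
#' bands (`BH_main`, `BH_sub`, `Cc_H`); treated rows carry positive factors,
#' larger at 2 mM than at 200 uM. Protein factors shift the
#' alpha-helix/beta-sheet balance downwards under treatment and make PG88
#' strongly alpha-dominated; lipid factors lower the olefinic (unsaturation)
#' band under treatment and move the CH3/CH2 ratio in opposite directions in
#' the two lines. Magnitudes are synthetic conventions (the directions, not
#' the sizes, follow the observed biology).
#'
#' @return Tibble with columns `cell_line`, `treatment`, `assignment`,
#'   `factor`; assignments not listed for a group default to 1.
#' @export
default_group_effects <- function() {
  base <- tibble::tribble(
    ~treatment, ~assignment,     ~factor,
    "control",  "BH_main",        0,
    "control",  "BH_sub",         0,
    "control",  "Cc_H",           0,
    "200uM",    "BH_main",        1,
    "200uM",    "BH_sub",         1,
    "200uM",    "Cc_H",           1,
    "200uM",    "olefinic",       0.80,
    "2mM",      "BH_main",        6,
    "2mM",      "BH_sub",         6,
    "2mM",      "Cc_H",           6,
    "2mM",      "olefinic",       0.65
  )
  protein <- tibble::tribble(
    ~cell_line, ~treatment, ~assignment,    ~factor,
    "PG88",     "control",  "amideI_alpha",  1.30,
    "PG88",     "control",  "amideI_beta",   0.35,
    "GIC7",     "200uM",    "amideI_alpha",  0.80,
    "GIC7",     "200uM",    "amideI_beta",   1.40,
    "PG88",     "200uM",    "amideI_alpha",  1.10,
    "PG88",     "200uM",    "amideI_beta",   0.48,
    "GIC7",     "2mM",      "amideI_alpha",  0.95,
    "GIC7",     "2mM",      "amideI_beta",   1.05,
    "PG88",     "2mM",      "amideI_alpha",  1.18,
    "PG88",     "2mM",      "amideI_beta",   0.46,
    "GIC7",     "200uM",    "ch3_asym",      1.10,
    "PG88",     "200uM",    "ch3_asym",      0.85,
    "PG88",     "200uM",    "ch2_asym",      1.10
  )
  grid <- tidyr::expand_grid(cell_line = c("GIC7", "PG88"),
                             treatment = c("control", "200uM", "2mM"))
  dplyr::bind_rows(
    dplyr::left_join(grid, base, by = "treatment",
                     relationship = "many-to-many"),
    protein
  ) |>
    dplyr::filter(!is.na(.data$assignment)) |>
    dplyr::distinct(.data$cell_line, .data$treatment, .data$assignment,
                    .keep_all = TRUE)
}

#' Synthetic single-cell spectrum model
#'
#' Bundles everything needed to generate labelled control/treated
#' populations: a Gaussian component [band_library()], a group-effect table,
#' a random degree-<=2 polynomial baseline, a multiplicative scatter
#' transform, per-cell lognormal amplitude jitter, additive Gaussian noise,
#' and a seed. Per cell, the generated spectrum is
#' \deqn{A(\nu) = a + b\Big[\sum_j h_j f_j j_j e^{-(\nu-\mu_j)^2/2\sigma_j^2}
#'   + \mathrm{baseline}(\nu)\Big] + \varepsilon(\nu)}
#' with draws in the documented order: band jitters (library order), the
#' baseline coefficients (constant, linear, quadratic), the scatter offset
#' `a` and gain `b`, then the noise vector.
#'
#' @param grid Wavenumber grid; default 800-4000 cm^-1 at 2 cm^-1 spacing
#'   (a 4 cm^-1 instrument resolution stored with the typical 2x
#'   oversampling).
#' @param bands Component band tibble, see [band_library()].
#' @param group_effects Group-effect tibble, see [default_group_effects()].
#' @param jitter_sd Lognormal sd of per-cell band-amplitude jitter
#'   (default 0.1); 0 disables jitter.
#' @param baseline_c0,baseline_c1,baseline_c2 Ranges (length-2) for the
#'   polynomial baseline coefficients on the wavenumber rescaled to
#'   \[-1, 1\].
#' @param scatter_a,scatter_b Ranges for the additive offset and
#'   multiplicative gain of the scatter transform.
#' @param noise_sd Additive Gaussian noise sd in AU (default 0.005).
#' @param seed Integer seed giving bit-identical populations.
#' @return An object of class `synthetic_model`.
#' @export
synthetic_model <- function(grid = seq(800, 4000, by = 2),
                            bands = band_library(),
                            group_effects = default_group_effects(),
                            jitter_sd = 0.1,
                            baseline_c0 = c(0, 0.10),
                            baseline_c1 = c(-0.05, 0.05),
                            baseline_c2 = c(-0.02, 0.02),
                            scatter_a = c(-0.02, 0.02),
                            scatter_b = c(0.7, 1.3),
                            noise_sd = 0.005,
                            seed = 1L) {
  stopifnot(all(bands$amplitude >= 0), all(bands$sigma >= 2),
            all(bands$sigma <= 60), noise_sd >= 0, jitter_sd >= 0)
  if (any(group_effects$factor < 0)) abort("group-effect factors must be >= 0")
  bh <- group_effects$assignment %in% c("BH_main", "BH_sub") &
    group_effects$treatment == "control"
  if (any(group_effects$factor[bh] != 0)) {
    abort("control groups must have B-H factors exactly 0")
  }
  structure(list(grid = as.numeric(grid), bands = bands,
                 group_effects = group_effects, jitter_sd = jitter_sd,
                 baseline_c0 = baseline_c0, baseline_c1 = baseline_c1,
                 baseline_c2 = baseline_c2, scatter_a = scatter_a,
                 scatter_b = scatter_b, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_model")
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat(sprintf("<synthetic_model> %d bands, %d groups, grid %g-%g cm^-1 (%d pts), noise sd %g, seed %d\n",
              nrow(x$bands),
              nrow(dplyr::distinct(x$group_effects, .data$cell_line, .data$treatment)),
              min(x$grid), max(x$grid), length(x$grid), x$noise_sd, x$seed))
  invisible(x)
}

group_factors <- function(model, cell_line, treatment) {
  known <- dplyr::distinct(model$group_effects, .data$cell_line, .data$treatment)
  if (!any(known$cell_line == cell_line & known$treatment == treatment)) {
    abort(sprintf("unknown group (%s, %s); add it to group_effects",
                  cell_line, treatment))
  }
  ge <- dplyr::filter(model$group_effects, .data$cell_line == !!cell_line,
                      .data$treatment == !!treatment)
  f <- setNames(rep(1, nrow(model$bands)), model$bands$assignment)
  f[ge$assignment[ge$assignment %in% names(f)]] <-
    ge$factor[ge$assignment %in% names(f)]
  f
}

gauss_sum <- function(wn, centers, sigmas, heights) {
  y <- numeric(length(wn))
  for (j in seq_along(centers)) {
    y <- y + heights[j] * exp(-(wn - centers[j])^2 / (2 * sigmas[j]^2))
  }
  y
}

#' Noiseless group template spectrum
#'
#' The pure component-band sum for a group (no jitter, baseline, scatter or
#' noise): the curve that per-group mean spectra converge to as the number
#' of generated cells grows.
#'
#' @param model A [synthetic_model()].
#' @param cell_line,treatment Group labels present in the effect table.
#' @return A one-cell spectra table.
#' @export
group_template <- function(model, cell_line, treatment) {
  f <- group_factors(model, cell_line, treatment)
  y <- gauss_sum(model$grid, model$bands$center, model$bands$sigma,
                 model$bands$amplitude * f)
  as_spectra(tibble::tibble(
    sample_id = paste(cell_line, treatment, "template", sep = "_"),
    cell_line = cell_line, treatment = treatment,
    wavenumber = model$grid, absorbance = y))
}

# One cell's absorbance vector, consuming draws from the current RNG stream
# in the documented order.
draw_cell <- function(model, f) {
  nb <- nrow(model$bands)
  # lognormal with unit mean; sd 0 degenerates to exactly 1 (draws still consumed)
  jit <- stats::rlnorm(nb, meanlog = -model$jitter_sd^2 / 2,
                       sdlog = model$jitter_sd)
  y <- gauss_sum(model$grid, model$bands$center, model$bands$sigma,
                 model$bands$amplitude * f * jit)
  nu <- 2 * (model$grid - min(model$grid)) / diff(range(model$grid)) - 1
  c0 <- stats::runif(1, model$baseline_c0[1], model$baseline_c0[2])
  c1 <- stats::runif(1, model$baseline_c1[1], model$baseline_c1[2])
  c2 <- stats::runif(1, model$baseline_c2[1], model$baseline_c2[2])
  a <- stats::runif(1, model$scatter_a[1], model$scatter_a[2])
  b <- stats::runif(1, model$scatter_b[1], model$scatter_b[2])
  eps <- stats::rnorm(length(model$grid), 0, model$noise_sd)
  a + b * (y + c0 + c1 * nu + c2 * nu^2) + eps
}

#' Generate one labelled synthetic cell spectrum
#'
#' Consumes the global RNG stream (seed it, or use [generate_population()]
#' which seeds from the model). Draw order per cell: band amplitude jitters
#' in band-library order, baseline coefficients, scatter offset and gain,
#' noise vector.
#'
#' @inheritParams group_template
#' @param sample_id Identifier for the generated cell.
#' @return A one-cell spectra table.
#' @export
generate_spectrum <- function(model, cell_line, treatment,
                              sample_id = "cell_1") {
  f <- group_factors(model, cell_line, treatment)
  as_spectra(tibble::tibble(
    sample_id = sample_id, cell_line = cell_line, treatment = treatment,
    wavenumber = model$grid, absorbance = draw_cell(model, f)))
}

#' Generate a labelled population of synthetic cells
#'
#' Emulates a microspectroscopy campaign recording on the order of 100-200
#' single-cell spectra per sample. Seeds the RNG from `model$seed` (the
#' previous RNG state is restored afterwards), so identical models give
#' bit-identical populations. Cells are drawn group by group in the order
#' given, each consuming draws as documented in [generate_spectrum()].
#'
#' @param model A [synthetic_model()].
#' @param n_per_group Cells per group (default 100).
#' @param groups List of `c(cell_line, treatment)` pairs; default all groups
#'   in the model's effect table.
#' @return A spectra table of `n_per_group * length(groups)` cells.
#' @export
generate_population <- function(model, n_per_group = 100, groups = NULL) {
  if (n_per_group < 1) abort("n_per_group must be >= 1")
  if (is.null(groups)) {
    g <- dplyr::distinct(model$group_effects, .data$cell_line, .data$treatment)
    groups <- purrr::pmap(g, function(cell_line, treatment)
      c(cell_line, treatment))
  }
  if (length(groups) == 0) abort("empty group list")
  with_seed(model$seed, {
    purrr::map_dfr(groups, function(g) {
      f <- group_factors(model, g[1], g[2])
      purrr::map_dfr(seq_len(n_per_group), function(i) {
        tibble::tibble(
          sample_id = sprintf("%s_%s_%03d", g[1], g[2], i),
          cell_line = g[1], treatment = g[2],
          wavenumber = model$grid, absorbance = draw_cell(model, f))
      })
    }) |> as_spectra()
  })
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic hyperspectral map of one cell
#'
#' Builds an `nx` by `ny` raster (physical step `step_um` micrometres,
#' emulating single-cell mapping at 1.5 um point spacing) for one treated
#' cell: cell-body bands fall off with a broad Gaussian profile around the
#' nucleus, while the drug's B-H doublet is additionally scaled by a tighter
#' radial profile peaked at `nucleus_center`, emulating nuclear accumulation
#' of the boron cluster. Pixels far outside the cell carry only baseline and
#' noise. Also returns the boolean nucleus mask (pixel centres within
#' `nucleus_radius_um` of the nucleus centre).
#'
#' @param model A [synthetic_model()]; its seed drives the map noise.
#' @param nx,ny Pixel counts.
#' @param step_um Distance between pixels in micrometres.
#' @param cell_line,treatment Group generating the per-pixel spectra.
#' @param nucleus_center Pixel `c(px, py)` of the nucleus centre (1-based).
#' @param nucleus_radius_um Nucleus radius in micrometres (> 0); the nucleus
#'   must fit inside the field.
#' @return List with `map` (a [hypermap()]) and `mask` (ny x nx logical
#'   matrix, rows = py).
#' @export
generate_map <- function(model, nx = 21, ny = 21, step_um = 1.5,
                         cell_line = "GIC7", treatment = "2mM",
                         nucleus_center = c(ceiling(nx / 2), ceiling(ny / 2)),
                         nucleus_radius_um = 4.5) {
  if (nucleus_radius_um <= 0) abort("nucleus_radius_um must be > 0")
  cx <- (nucleus_center[1] - 1) * step_um
  cy <- (nucleus_center[2] - 1) * step_um
  if (nucleus_center[1] < 1 || nucleus_center[1] > nx ||
      nucleus_center[2] < 1 || nucleus_center[2] > ny) {
    abort("nucleus centre must lie inside the mapped field")
  }
  f <- group_factors(model, cell_line, treatment)
  is_bh <- model$bands$assignment %in% c("BH_main", "BH_sub")
  idx <- seq_len(nx * ny)
  px <- ((idx - 1) %% nx) + 1
  py <- ((idx - 1) %/% nx) + 1
  d_um <- sqrt(((px - 1) * step_um - cx)^2 + ((py - 1) * step_um - cy)^2)
  body <- exp(-d_um^2 / (2 * (2 * nucleus_radius_um)^2))
  nucleus <- exp(-d_um^2 / (2 * (nucleus_radius_um / 2)^2))
  nu <- 2 * (model$grid - min(model$grid)) / diff(range(model$grid)) - 1

  cube <- with_seed(model$seed, {
    t(vapply(idx, function(i) {
      h <- model$bands$amplitude * f *
        ifelse(is_bh, nucleus[i], body[i])
      y <- gauss_sum(model$grid, model$bands$center, model$bands$sigma, h)
      c0 <- stats::runif(1, model$baseline_c0[1], model$baseline_c0[2])
      y + c0 * (1 + 0.1 * nu) +
        stats::rnorm(length(model$grid), 0, model$noise_sd)
    }, numeric(length(model$grid))))
  })
  mask <- matrix(d_um <= nucleus_radius_um, nrow = ny, ncol = nx, byrow = TRUE)
  list(map = hypermap(model$grid, cube, nx, ny, step_um), mask = mask)
}
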