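#' Two-group comparison by t-test
#'
#' Welch's two-sided t-test (unequal variances) by default, as appropriate
#' for per-cell band metrics whose spread differs between treatment groups;
#' set `var_equal = TRUE` for the pooled-variance variant. Significance
#' stars follow the usual thresholds: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001 (p exactly 0.05 is not significant). Two groups that are
#' both constant with equal means are reported as t = 0, p = 1 by
#' convention.
#'
#' @param values_a,values_b Numeric samples, each of size >= 2, all finite.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param metric Optional metric name recorded in the output.
#' @param label_a,label_b Optional group labels recorded in the output.
#' @return One-row tibble: metric, group labels, per-group mean/sd/n,
#'   `t_statistic`, `p_value`, `stars`.
#' @examples
#' compare_groups_ttest(c(1, 2, 3), c(11, 12, 13))
#' @export
compare_groups_ttest <- function(values_a, values_b, var_equal = FALSE,
                                 metric = "metric", label_a = "A",
                                 label_b = "B") {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  if (!all(is.finite(values_a)) || !all(is.finite(values_b))) {
    abort("groups must contain only finite values")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(values_a) - mean(values_b)) * Inf,
                 p.value = 0)
    }
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  tibble::tibble(
    metric = metric, group_a = label_a, group_b = label_b,
    mean_a = mean(values_a), sd_a = sd(values_a), n_a = length(values_a),
    mean_b = mean(values_b), sd_b = sd(values_b), n_b = length(values_b),
    t_statistic = tt$statistic, p_value = tt$p.value,
    stars = significance_stars(tt$p.value))
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Cell viability percentage from A570 absorbances
#'
#' The resazurin-reduction readout:
#' `(A570_sample - A570_blank) / (A570_control - A570_blank) * 100`.
#'
#' @param a570_sample,a570_blank,a570_control Absorbances at 570 nm
#'   (vectorized over `a570_sample`).
#' @return Viability in percent.
#' @examples
#' viability_percent(0.35, 0.1, 0.6)  # 50
#' @export
viability_percent <- function(a570_sample, a570_blank, a570_control) {
  if (any(a570_control == a570_blank)) {
    abort("control and blank absorbances must differ")
  }
  (a570_sample - a570_blank) / (a570_control - a570_blank) * 100
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the input (a synthetic model
#' or a spectra file), the region recipes for PCA, the groups to
#' deconvolve, the group comparisons to test, the output directory and the
#' seed.
#'
#' @param model A [synthetic_model()] used to generate the input population
#'   (its seed is overridden by `seed`); or `NULL` if `input_path` is given.
#' @param input_path Optional path of a spectra table read with
#'   [read_spectra()] instead of generating data.
#' @param n_per_group Cells per group when generating.
#' @param groups List of `c(cell_line, treatment)` pairs; default all groups
#'   of the model.
#' @param pca_regions Named character vector mapping region preset names to
#'   recipes (default: dna = "d2", fingerprint = "snv", lipids = "snv").
#' @param deconv_groups List of `c(cell_line, treatment)` pairs to
#'   deconvolve; default = `groups`.
#' @param comparisons List of two-element lists, each naming two groups to
#'   compare on every metric, e.g.
#'   `list(list(c("GIC7","control"), c("GIC7","200uM")))`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed controlling every random draw of the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model = synthetic_model(),
                            input_path = NULL,
                            n_per_group = 50,
                            groups = NULL,
                            pca_regions = c(dna = "d2", fingerprint = "snv",
                                            lipids = "snv"),
                            deconv_groups = NULL,
                            comparisons = NULL,
                            out_dir = tempfile("ftirm_run_"),
                            seed = 1L) {
  if (is.null(model) && is.null(input_path)) {
    abort("provide a synthetic model or an input path")
  }
  if (!is.null(model)) model$seed <- as.integer(seed)
  if (is.null(groups) && !is.null(model)) {
    g <- dplyr::distinct(model$group_effects, .data$cell_line, .data$treatment)
    groups <- purrr::pmap(g, function(cell_line, treatment)
      c(cell_line, treatment))
  }
  if (is.null(deconv_groups)) deconv_groups <- groups
  if (is.null(comparisons) && !is.null(groups)) {
    lines <- unique(vapply(groups, `[`, character(1), 1))
    comparisons <- purrr::compact(purrr::map(lines, function(cl) {
      have <- purrr::keep(groups, ~ .x[1] == cl)
      if (length(have) >= 2) list(have[[1]], have[[2]]) else NULL
    }))
  }
  structure(list(model = model, input_path = input_path,
                 n_per_group = n_per_group, groups = groups,
                 pca_regions = pca_regions, deconv_groups = deconv_groups,
                 comparisons = comparisons, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tbl <- function(x, path) {
  utils::write.csv(format(as.data.frame(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full single-cell analysis pipeline
#'
#' Executes, in order: data synthesis (or loading), region-wise PCA with the
#' configured recipes, amide-I deconvolution per group, the per-cell metric
#' table (B-H index, unsaturation index, CH3/CH2 ratio), two-group t-tests
#' on every metric for the configured comparisons, and a provenance
#' manifest (seed, config hash, package version). All outputs are delimited
#' text tables under `cfg$out_dir`; rerunning with the same config and seed
#' is bit-identical. Any stage error aborts the run, removes partial
#' outputs, and reports the failing stage.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`spectra`, `pca`,
#'   `deconvolution`, `metrics`, `comparisons`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) abort("cfg must be a pipeline_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "setup"
  out <- tryCatch({
    stage <- "input"
    spectra <- if (!is.null(cfg$input_path)) {
      read_spectra(cfg$input_path)
    } else {
      generate_population(cfg$model, cfg$n_per_group, cfg$groups)
    }

    stage <- "pca"
    pca <- purrr::imap(cfg$pca_regions, function(recipe, region_name) {
      p <- run_pca(spectra, region_name, recipe = recipe)
      for (mt in c("scores", "loadings", "eigenvalues")) {
        f <- file.path(cfg$out_dir, sprintf("pca_%s_%s.csv", region_name, mt))
        write_tbl(tidy(p, mt), f)
        written <<- c(written, f)
      }
      p
    })

    stage <- "deconvolution"
    deconv <- purrr::map(cfg$deconv_groups, function(g) {
      deconvolve_amide_i(spectra, cell_line = g[1], treatment = g[2])
    })
    dtab <- purrr::map_dfr(deconv, glance)
    f <- file.path(cfg$out_dir, "deconvolution_table.csv")
    write_tbl(dtab, f); written <- c(written, f)

    stage <- "metrics"
    metrics <- spectral_metrics(spectra)
    f <- file.path(cfg$out_dir, "metrics.csv")
    write_tbl(metrics, f); written <- c(written, f)

    stage <- "comparisons"
    comp <- purrr::map_dfr(cfg$comparisons, function(pair) {
      ga <- pair[[1]]; gb <- pair[[2]]
      purrr::map_dfr(c("bh_index", "unsaturation_index", "ch3_ch2_ratio"),
                     function(mname) {
        va <- metrics[[mname]][metrics$cell_line == ga[1] &
                                 metrics$treatment == ga[2]]
        vb <- metrics[[mname]][metrics$cell_line == gb[1] &
                                 metrics$treatment == gb[2]]
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        compare_groups_ttest(va, vb, metric = mname,
                             label_a = paste(ga, collapse = "/"),
                             label_b = paste(gb, collapse = "/"))
      })
    })
    f <- file.path(cfg$out_dir, "comparisons.csv")
    write_tbl(comp, f); written <- c(written, f)

    stage <- "manifest"
    cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
    manifest <- c(
      sprintf("ftirmcell_version: %s", as.character(packageVersion("ftirmcell"))),
      sprintf("seed: %d", cfg$seed),
      sprintf("config_hash: %s", cfg_hash),
      sprintf("n_cells: %d", dplyr::n_distinct(spectra$sample_id)),
      sprintf("stages: input, pca (%s), deconvolution, metrics, comparisons",
              paste(names(cfg$pca_regions), collapse = ", ")))
    f <- file.path(cfg$out_dir, "manifest.txt")
    writeLines(manifest, f); written <- c(written, f)

    list(spectra = spectra, pca = pca, deconvolution = deconv,
         metrics = metrics, comparisons = comp, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
  invisible(out)
}
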