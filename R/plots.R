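#' Plot spectra or group-mean spectra
#'
#' Line plot of absorbance against wavenumber (axis reversed, the
#' spectroscopic convention). With `mean_by_group = TRUE` (default) one mean
#' curve per (cell_line, treatment) group is drawn; otherwise every cell is
#' drawn with light transparency.
#'
#' @param spectra A spectra table.
#' @param mean_by_group Draw group means instead of individual cells.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra, mean_by_group = TRUE) {
  if (mean_by_group) {
    d <- spectra |>
      dplyr::summarise(absorbance = mean(.data$absorbance),
                       .by = c("cell_line", "treatment", "wavenumber")) |>
      dplyr::mutate(group = paste(.data$cell_line, .data$treatment))
    ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                    colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance (AU)")
  } else {
    ggplot2::ggplot(spectra,
                    ggplot2::aes(.data$wavenumber, .data$absorbance,
                                 group = .data$sample_id,
                                 colour = .data$treatment)) +
      ggplot2::geom_line(alpha = 0.25) +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance (AU)")
  }
}
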