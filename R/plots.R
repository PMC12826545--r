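#' Boxplots of degree of anisotropy by compression and density group
#'
#' @param doa_tbl The `doa` table of a `visr_study` (or any tibble with
#'   `metric`, `compression_mm`, `doa`, `dense`).
#' @return A ggplot object.
#' @export
plot_doa <- function(doa_tbl) {
  df <- dplyr::mutate(
    doa_tbl,
    group = ifelse(.data$dense, "dense", "non-dense"),
    metric_lab = toupper(.data$metric),
    compression = factor(.data$compression_mm))
  ggplot2::ggplot(df, ggplot2::aes(.data$compression, .data$doa,
                                   fill = .data$compression)) +
    ggplot2::geom_boxplot(show.legend = FALSE, na.rm = TRUE) +
    ggplot2::facet_grid(ggplot2::vars(.data$metric_lab),
                        ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "compression (mm)", y = "degree of anisotropy")
}

#' Boxplots of percent change between compression levels
#'
#' @param pct_tbl A percent-change table of a `visr_study` (`doa_change` or
#'   `pct_change`), with columns `metric`, `pair`, `pct_change`, `dense`.
#' @return A ggplot object.
#' @export
plot_percent_change <- function(pct_tbl) {
  df <- dplyr::mutate(
    pct_tbl,
    group = ifelse(.data$dense, "dense", "non-dense"),
    metric_lab = toupper(.data$metric),
    pair = factor(.data$pair, levels = c("0-2", "2-5", "0-5")))
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$pct_change,
                                   fill = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(show.legend = FALSE, na.rm = TRUE) +
    ggplot2::facet_grid(ggplot2::vars(.data$metric_lab),
                        ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "compression pair (mm)", y = "percent change (%)")
}
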