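# ggplot2 views of the main result types.

#' @export
autoplot.timex_track <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "value")
}

#' @export
autoplot.timex_profile <- function(object, ...) {
  autoplot.timex_track(object) +
    ggplot2::labs(y = "scaled S/G1 ratio",
                  title = paste0(attr(object, "homolog") %||% "", " timing profile"))
}

#' Plot two homolog profiles with called domains
#'
#' Maternal and paternal profiles overlaid, with significant asynchronous
#' domains shaded.
#'
#' @param mat,pat Homolog `timex_profile` tracks.
#' @param ards Optional `timex_ards` tibble.
#' @return A ggplot.
#' @export
plot_homolog_profiles <- function(mat, pat, ards = NULL) {
  both <- dplyr::bind_rows(
    mutate(as_tibble(mat), homolog = "maternal"),
    mutate(as_tibble(pat), homolog = "paternal"))
  p <- ggplot2::ggplot(both,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$value,
                                    colour = .data$homolog)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(maternal = "#c0392b",
                                            paternal = "#2c3e50")) +
    ggplot2::labs(x = "position (Mb)", y = "scaled S/G1 ratio")
  if (!is.null(ards) && nrow(ards) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(ards),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "#e377c2",
      inherit.aes = FALSE)
  }
  p
}

#' @export
autoplot.timex_power_grid <- function(object, metric = "detection_rate", ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$excess * 100),
                               y = factor(.data$size / 1000),
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data[[metric]], 2)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = if (metric == "detection_rate")
      c(0, 1) else NULL) +
    ggplot2::labs(x = "S-phase read excess (%)", y = "spike size (kb)",
                  fill = metric)
}

#' @export
autoplot.timex_ards <- function(object, ...) {
  tbl <- as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$length / 1e6,
                                    y = .data$delay_minutes,
                                    colour = .data$sign)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "domain length (Mb)", y = "timing delay (min)",
                  colour = NULL)
}
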