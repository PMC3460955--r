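## ggplot2 views of the main result types.

#' Plot one sample's CN profile along a chromosome
#'
#' Probe-level CN values colored by their five-state classification, with
#' horizontal guides at the calling cutoffs.
#'
#' @param profiles Wide CN probe table.
#' @param sample Sample column to plot.
#' @param chrom Optional chromosome to restrict to.
#' @param thresholds A [calling_thresholds()].
#' @return A ggplot object.
#' @export
plot_cn_profile <- function(profiles, sample, chrom = NULL,
                            thresholds = calling_thresholds()) {
  df <- profiles[, c("chrom", "pos", sample)]
  names(df)[3] <- "cn"
  if (!is.null(chrom)) df <- df[df$chrom == chrom, ]
  df$state <- factor(classify_cn_value(df$cn, thresholds),
                     levels = CN_STATES)
  cuts <- c(thresholds$homdel_max, thresholds$loss_max,
            thresholds$gain_min, thresholds$amp_min)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$cn,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(yintercept = cuts, linetype = "dashed",
                        linewidth = 0.3, colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "CN (arbitrary units)",
                  colour = "state", title = sample) +
    ggplot2::theme_minimal()
}

#' Plot recurrence of regions across the cohort
#'
#' Horizontal bars of per-region recurrence frequency, split by event
#' kind.
#'
#' @param regions Region tibble from [minimal_common_region()] (needs
#'   `chrom`, `start`, `end`, `kind`, `frequency_pct`).
#' @return A ggplot object.
#' @export
plot_recurrence <- function(regions) {
  df <- regions |>
    dplyr::mutate(label = sprintf("%s:%.1f-%.1f Mb", .data$chrom,
                                  .data$start / 1e6, .data$end / 1e6))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_pct,
                                   y = stats::reorder(.data$label,
                                                      .data$frequency_pct),
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cases with event (%)", y = NULL, fill = "kind") +
    ggplot2::theme_minimal()
}

#' @describeIn km_estimate Step plot of a Kaplan-Meier curve with censor
#'   marks.
#' @param object A `cna_km` curve.
#' @param ... Unused.
#' @export
autoplot.cna_km <- function(object, ...) {
  df <- tibble::as_tibble(object)
  cens <- df[df$n_censor > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "S(t)") +
    ggplot2::theme_minimal()
}
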