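# ggplot2 views of the three result types: fingerprint series, hotspot
# tables, RMSD traces, and the dose-response fit.

#' Plot interaction occupancy as a bar chart
#'
#' @param rows Hotspot rows from [aggregate_hotspots()].
#' @return A ggplot object: occupancy per residue, coloured by interaction
#'   type.
#' @export
plot_hotspots <- function(rows) {
  rows <- mutate(rows, residue = factor(.data$residue,
                                        levels = unique(.data$residue)))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$residue,
                                     y = .data$occupancy,
                                     fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "occupancy (% of frames)",
                  fill = "interaction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot backbone and ligand-movement RMSD traces
#'
#' @param traces Output of [rmsd_traces()].
#' @param stability_line Draw the 2.000 Angstrom stability threshold?
#' @return A ggplot object with time (ns) on the x axis.
#' @export
plot_rmsd_trace <- function(traces, stability_line = TRUE) {
  long <- tidyr::pivot_longer(traces,
                              cols = c("backbone_rmsd", "ligmove_rmsd"),
                              names_to = "metric", values_to = "rmsd")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps / 1000,
                                          y = .data$rmsd,
                                          colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)", colour = NULL) +
    ggplot2::theme_minimal()
  if (stability_line) {
    p <- p + ggplot2::geom_hline(yintercept = STABILITY_CUTOFF,
                                 linetype = "dashed")
  }
  p
}

#' @describeIn direct_ifp_series Tile plot of per-frame interaction bits
#'   (one tile per residue and frame, shaded by the number of set bits).
#' @param object An `ifp_series`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ifp_series <- function(object, ...) {
  df <- as_tibble(object)
  df$n_bits <- rowSums(fingerprint_matrix(df))
  df$residue <- residue_label(df$res_name, df$res_seq, df$i_code)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$residue,
                                   fill = .data$n_bits)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "bits set") +
    ggplot2::labs(x = "frame", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn ic50_loglinear Dose-response scatter with the fitted
#'   log-linear line and the IC50 crossing.
#' @param object An `ic50_fit`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ic50_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$log_conc,
                                            y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log10(object$ic50),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10 concentration", y = "inhibition (%)") +
    ggplot2::theme_minimal()
}
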