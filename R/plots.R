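#' Plot consensus assignments on the HMQC plane
#'
#' Scatter of the consensus \eqn{^1}H/\eqn{^{13}}C shifts, colored by
#' confidence class and shaped by residue type, with the conventional
#' reversed ppm axes.
#'
#' @param object a `methyl_consensus` table.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.methyl_consensus <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat <- dat[!is.na(dat$shift_c) & !is.na(dat$shift_h), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$shift_h, y = .data$shift_c,
                                    color = .data$strength,
                                    shape = .data$restype)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_manual(values = c(strong = "#1b7837",
                                           weak = "#bdbdbd")) +
    ggplot2::labs(x = "1H shift (ppm)", y = "13C shift (ppm)",
                  color = "confidence", shape = "residue") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.methyl_consensus
#' @export
autoplot.methyl_pipeline <- function(object, ...) {
  autoplot(object$consensus, ...)
}

#' Agreement-fraction histogram of a consensus set
#'
#' @param consensus a `methyl_consensus` table.
#' @param threshold strong threshold drawn as a vertical line.
#' @return a ggplot object.
#' @export
plot_agreement <- function(consensus, threshold = attr(consensus, "threshold")) {
  dat <- tibble::as_tibble(consensus)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction,
                                    fill = .data$strength)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(strong = "#1b7837",
                                          weak = "#bdbdbd")) +
    ggplot2::labs(x = "run agreement fraction", y = "methyls",
                  fill = "confidence") +
    ggplot2::theme_minimal()
}

#' Heat-map of a parameter sweep
#'
#' @param object a `methyl_sweep` table from [sweep_parameters()].
#' @param metric column to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.methyl_sweep <- function(object, metric = "pct_strong", ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$d_cut),
                               y = factor(.data$p_noe),
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = "distance cutoff (A)", y = "expected-NOE probability") +
    ggplot2::theme_minimal()
}
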