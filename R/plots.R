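#' Plot a chromatogram with detected peaks
#'
#' @param trace A trace tibble (baseline drawn if present).
#' @param peaks Optional peak table; apexes are marked and numbered.
#' @return A ggplot object.
#' @export
plot_chromatogram <- function(trace, peaks = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = paste(trace_detector(trace), "signal")) +
    ggplot2::theme_minimal()
  if ("baseline" %in% names(trace)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$baseline),
                                colour = "steelblue", linetype = 2,
                                linewidth = 0.3)
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    apex <- dplyr::mutate(
      peaks, y = .data$height + if ("baseline" %in% names(trace)) {
        trace$baseline[vapply(peaks$rt_apex, function(rt) {
          which.min(abs(trace$time - rt))
        }, integer(1))]
      } else 0)
    p <- p + ggplot2::geom_text(
      data = apex, ggplot2::aes(x = .data$rt_apex, y = .data$y,
                                label = .data$peak),
      vjust = -0.4, size = 2.5, colour = "firebrick")
  }
  p
}

#' Plot an observed isotope envelope against a candidate's theory
#'
#' @param observed An [observed_envelope()].
#' @param formula Candidate formula string.
#' @param adduct Candidate adduct.
#' @return A ggplot object (observed sticks up, theoretical down).
#' @export
plot_isotope_fit <- function(observed, formula, adduct) {
  theo <- isotope_pattern(formula, adduct = adduct)
  obs <- tibble::tibble(mz = observed$mz,
                        abundance = 100 * observed$intensity /
                          max(observed$intensity),
                        which = "observed")
  th <- tibble::tibble(mz = theo$mz, abundance = -theo$abundance,
                       which = "theoretical")
  ggplot2::ggplot(dplyr::bind_rows(obs, th),
                  ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                               yend = .data$abundance,
                               colour = .data$which)) +
    ggplot2::geom_segment(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "m/z", y = "relative abundance",
                  title = paste(format_formula(formula), "as", adduct)) +
    ggplot2::theme_minimal()
}

#' Autoplot an extract report
#'
#' Bar chart of percent of total CAD signal per peak, coloured by
#' identification confidence tier.
#'
#' @param object An `extract_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.extract_report <- function(object, ...) {
  rec <- tidy(object)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$peak, y = .data$cad_percent,
                                    fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "CAD peak number", y = "% of total CAD signal",
                  fill = "confidence") +
    ggplot2::theme_minimal()
}
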