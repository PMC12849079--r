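#' Plot group mean OCR traces with injection markers
#'
#' The classical mitostress trace figure: per-group mean +/- SD OCR against
#' time, with dashed vertical lines at each injection.
#'
#' @param plate A [plate_run()].
#' @param what `"ocr"` or `"ecar"`.
#' @return A ggplot object.
#' @export
plot_traces <- function(plate, what = c("ocr", "ecar")) {
  what <- match.arg(what)
  td <- group_trace_data(plate)
  m <- paste0(what, "_mean"); s <- paste0(what, "_sd")
  inj <- td[!is.na(td$injection), c("time_min", "injection")]
  inj <- dplyr::distinct(inj)
  ylab <- if (what == "ocr") "OCR (pmol O2/min)" else "ECAR (mpH/min)"
  ggplot2::ggplot(td, ggplot2::aes(x = .data$time_min, y = .data[[m]],
                                   colour = .data$group)) +
    ggplot2::geom_vline(data = inj,
                        ggplot2::aes(xintercept = .data$time_min - 3),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[m]] - .data[[s]],
                                      ymax = .data[[m]] + .data[[s]],
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(data = inj,
                       ggplot2::aes(x = .data$time_min - 3, y = Inf,
                                    label = .data$injection),
                       inherit.aes = FALSE, vjust = 1.2, size = 3) +
    ggplot2::labs(x = "Time (min)", y = ylab, colour = "Group",
                  fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot the energy map
#'
#' Basal OCR against basal ECAR, one point per animal with group mean +/- SD
#' crosshairs.
#'
#' @param summaries Animal-level table from [aggregate_by_animal()] (needs
#'   `last_basal` and `basal_ecar` columns).
#' @return A ggplot object.
#' @export
plot_energy_map <- function(summaries) {
  gm <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(summaries), .data$group),
    ocr = mean(.data$last_basal), ocr_sd = stats::sd(.data$last_basal),
    ecar = mean(.data$basal_ecar), ecar_sd = stats::sd(.data$basal_ecar),
    .groups = "drop")
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$basal_ecar, y = .data$last_basal,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_errorbar(data = gm,
                           ggplot2::aes(x = .data$ecar,
                                        ymin = .data$ocr - .data$ocr_sd,
                                        ymax = .data$ocr + .data$ocr_sd),
                           inherit.aes = FALSE, width = 0) +
    ggplot2::geom_errorbarh(data = gm,
                            ggplot2::aes(y = .data$ocr,
                                         xmin = .data$ecar - .data$ecar_sd,
                                         xmax = .data$ecar + .data$ecar_sd),
                            inherit.aes = FALSE, height = 0) +
    ggplot2::geom_point(data = gm,
                        ggplot2::aes(x = .data$ecar, y = .data$ocr,
                                     colour = .data$group),
                        shape = 18, size = 4) +
    ggplot2::labs(x = "Basal ECAR (mpH/min)", y = "Basal OCR (pmol O2/min)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Autoplot a reference line
#'
#' @param object A `reference_line`.
#' @param ... Unused.
#' @return A ggplot object: mean +/- SD OCR per reading.
#' @method autoplot reference_line
#' @export
autoplot.reference_line <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$measurement_index,
                                   y = .data$mean_ocr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ocr - .data$sd_ocr,
                                      ymax = .data$mean_ocr + .data$sd_ocr),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Reading", y = "OCR (pmol O2/min)",
                  title = sprintf("%s reference line (n = %d wells)",
                                  object$kind, object$n_wells)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
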