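#' Plot an incremental-locus scan
#'
#' Draws the three heritability/predictability curves against the fraction of
#' (association-sorted) loci included in the model: the whole-data
#' heritability `H` keeps rising as neutral loci are appended, while the
#' cross-validated `Hcv` and `Pcv` plateau once the causal loci are covered.
#'
#' @param object A `gblup_scan` tibble from [scan_loci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gblup_scan
#' @export
autoplot.gblup_scan <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("H", "Hcv", "Pcv"), names_to = "measure") |>
    dplyr::mutate(measure = factor(.data$measure, levels = c("H", "Hcv", "Pcv")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$prop_loci, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Fraction of sorted loci included",
                  y = "Heritability / predictability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation results across repeats
#'
#' One point per repeat for each measure (Hcv, Hcv_alt, Pcv), with the mean
#' across repeats marked by a crossbar.
#'
#' @param object A `gblup_cv` object from [cv_gblup()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gblup_cv
#' @export
autoplot.gblup_cv <- function(object, ...) {
  long <- object$results |>
    tidyr::pivot_longer(-"repeat_index", names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = "Estimate") +
    ggplot2::theme_minimal()
}
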