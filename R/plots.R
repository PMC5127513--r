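#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a Mendelian-randomisation result
#'
#' Per-instrument Wald ratios with the pooled estimate, on the odds-ratio
#' scale (log-spaced axis).
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.mr_result <- function(object, ...) {
  per <- tidy(object)
  pooled <- glance(object)
  dat <- dplyr::bind_rows(
    dplyr::transmute(per, label = .data$snp, or = .data$or,
                     l95 = .data$l95, u95 = .data$u95, pooled = FALSE),
    tibble::tibble(label = paste0("Pooled (", toupper(pooled$method), ")"),
                   or = pooled$or, l95 = pooled$l95, u95 = pooled$u95,
                   pooled = TRUE))
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$l95, xmax = .data$u95),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled, size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4),
                               guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR for disease per 1-SD exposure", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of an observational meta-analysis
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.meta_result <- function(object, ...) {
  per <- tidy(object)
  pooled <- glance(object)
  dat <- dplyr::bind_rows(
    dplyr::transmute(per, label = .data$study, rr = .data$rr,
                     l95 = .data$l95, u95 = .data$u95, pooled = FALSE),
    tibble::tibble(label = sprintf("Pooled (I² = %.0f%%)", object$I2),
                   rr = pooled$rr, l95 = pooled$l95, u95 = pooled$u95,
                   pooled = TRUE))
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rr, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$l95, xmax = .data$u95),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled, size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4),
                               guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "RR per 1-SD biomarker", y = NULL) +
    ggplot2::theme_minimal()
}

#' Specificity-scan plot
#'
#' Effect size against -log10 p for every trait in a metabolome-wide scan,
#' with the multiplicity-control threshold drawn and significant traits
#' highlighted.
#'
#' @param object A `scan_result` from [metabolome_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.scan_result <- function(object, ...) {
  m <- attr(object, "m")
  alpha <- attr(object, "alpha")
  dat <- dplyr::filter(tibble::as_tibble(object), !.data$untestable)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta, y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = -log10(alpha / m), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Trait SD per score unit",
                  y = expression(-log[10](p)), colour = "Significant") +
    ggplot2::theme_minimal()
}
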