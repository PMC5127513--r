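#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Mendelian-randomisation result
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return Per-instrument Wald estimates (`snp`, `theta`, `se`, `p`) with
#'   OR-scale columns, or the pooled row only when no per-instrument
#'   estimates were retained.
#' @exportS3Method generics::tidy
#' @export
tidy.mr_result <- function(x, ...) {
  if (is.null(x$estimates)) return(glance(x))
  dplyr::mutate(x$estimates,
                or = exp(.data$theta),
                l95 = exp(.data$theta - z975() * .data$se),
                u95 = exp(.data$theta + z975() * .data$se))
}

#' @rdname tidy.mr_result
#' @return `glance()` returns a one-row tibble: `method`, `n_snps`, `theta`,
#'   `se`, `or`, `l95`, `u95`, `p`, `excluded`.
#' @exportS3Method generics::glance
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snps = x$n_snps,
                 theta = x$theta, se = x$se,
                 or = exp(x$theta), l95 = exp(x$ci95[1]), u95 = exp(x$ci95[2]),
                 p = x$p,
                 excluded = paste(x$excluded, collapse = ","))
}

#' Tidy a fixed-effect meta-analysis
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return Per-study rows with ratio-scale effect and CI.
#' @exportS3Method generics::tidy
#' @export
tidy.meta_result <- function(x, ...) {
  dplyr::mutate(x$studies,
                rr = exp(.data$theta),
                l95 = exp(.data$theta - z975() * .data$se),
                u95 = exp(.data$theta + z975() * .data$se))
}

#' @rdname tidy.meta_result
#' @return `glance()` returns one row: pooled `theta`, `se`, `rr`, `l95`,
#'   `u95`, `p`, `Q`, `I2`, `k`.
#' @exportS3Method generics::glance
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(theta = x$theta, se = x$se,
                 rr = exp(x$theta), l95 = exp(x$ci95[1]), u95 = exp(x$ci95[2]),
                 p = x$p, Q = x$Q, I2 = x$I2, k = x$k)
}
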