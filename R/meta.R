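#' Fixed-effect inverse-variance meta-analysis with I-squared
#'
#' Pools per-study log relative risks (hazard ratios, odds ratios and risk
#' ratios are treated interchangeably on the log scale, the usual
#' approximation for uncommon outcomes) with inverse-variance weights, and
#' quantifies between-study heterogeneity with Cochran's Q and the
#' I-squared statistic `I2 = max(0, (Q - (k - 1)) / Q) * 100`.
#'
#' The pooling kernel is the same code path as [ivw_pool()], so the genetic
#' and observational arms of an analysis cannot drift apart numerically.
#'
#' @param studies Tibble with columns `study`, `theta` (log relative risk
#'   per 1-SD biomarker) and `se`; optionally `n_cases`, `n_noncases`.
#' @return A `meta_result` object: pooled `theta`, `se`, `ci95`, `p`, `Q`,
#'   `I2` (percent), `k`, and the input `studies`.
#' @examples
#' fixed_effect_meta(tibble::tibble(study = c("a", "b"),
#'                                  theta = c(0.1, 0.3), se = c(0.1, 0.1)))
#' @export
fixed_effect_meta <- function(studies) {
  stopifnot(is.data.frame(studies), all(c("theta", "se") %in% names(studies)))
  if (nrow(studies) == 0) stop("at least one study is required", call. = FALSE)
  if (is.null(studies$study)) studies$study <- paste0("study", seq_len(nrow(studies)))
  k <- pool_fixed(studies$theta, studies$se)
  if (k$Q < 1e-10) k$Q <- 0   # Q is scale-invariant; snap float dust to zero
  I2 <- if (k$Q > 0) max(0, (k$Q - (k$k - 1)) / k$Q) * 100 else 0
  z <- k$theta / k$se
  structure(
    list(theta = k$theta, se = k$se,
         ci95 = c(k$theta - z975() * k$se, k$theta + z975() * k$se),
         p = 2 * stats::pnorm(-abs(z)),
         Q = k$Q, I2 = I2, k = k$k, studies = tibble::as_tibble(studies)),
    class = "meta_result"
  )
}

#' Read observational study estimates from delimited text
#'
#' Accepts a tab-delimited table with columns `STUDY`, `EFFECT` (a relative
#' risk, odds ratio or hazard ratio per 1-SD biomarker) and either `SE` (of
#' the log effect) or `L95`/`U95` bounds, plus optional `N_CASES`,
#' `N_NONCASES`. Effects are moved to the log scale on read.
#'
#' @param path File path.
#' @return Tibble suitable for [fixed_effect_meta()].
#' @export
read_observational <- function(path) {
  raw <- readr::read_tsv(path, na = c(".", "", "NA"), show_col_types = FALSE)
  if (!all(c("STUDY", "EFFECT") %in% names(raw))) {
    stop("need STUDY and EFFECT columns", call. = FALSE)
  }
  se <- if ("SE" %in% names(raw)) {
    raw$SE
  } else if (all(c("L95", "U95") %in% names(raw))) {
    se_from_ci(raw$L95, raw$U95, log_scale = TRUE)
  } else {
    stop("need SE or both L95 and U95", call. = FALSE)
  }
  out <- tibble::tibble(study = raw$STUDY, theta = log(raw$EFFECT), se = se)
  if ("N_CASES" %in% names(raw)) out$n_cases <- raw$N_CASES
  if ("N_NONCASES" %in% names(raw)) out$n_noncases <- raw$N_NONCASES
  out
}

#' Compare the genetic and observational arms
#'
#' Places a Mendelian-randomisation estimate and an observational pooled
#' estimate side by side on the common log-relative-risk-per-SD scale and
#' reports whether their 95% confidence intervals overlap and the ratio of
#' the point estimates. No significance test of the difference is
#' performed; the comparison is descriptive.
#'
#' @param genetic An `mr_result`.
#' @param observational A `meta_result`.
#' @return One-row tibble: both point estimates and CIs (ratio scale),
#'   `ratio` of point estimates (genetic / observational, ratio scale) and
#'   `ci_overlap`.
#' @export
compare_arms <- function(genetic, observational) {
  stopifnot(inherits(genetic, "mr_result"), inherits(observational, "meta_result"))
  overlap <- genetic$ci95[1] <= observational$ci95[2] &&
    observational$ci95[1] <= genetic$ci95[2]
  tibble::tibble(
    genetic_rr = exp(genetic$theta),
    genetic_l95 = exp(genetic$ci95[1]), genetic_u95 = exp(genetic$ci95[2]),
    observational_rr = exp(observational$theta),
    observational_l95 = exp(observational$ci95[1]),
    observational_u95 = exp(observational$ci95[2]),
    ratio = exp(genetic$theta - observational$theta),
    ci_overlap = overlap
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Fixed-effect meta-analysis of %d studies\n  log-RR per SD: %.4f (se %.4f)\n  RR per SD: %.3f (95%% CI %.3f-%.3f), p = %.3g\n  Q = %.3f, I2 = %.1f%%\n",
    x$k, x$theta, x$se, exp(x$theta), exp(x$ci95[1]), exp(x$ci95[2]),
    x$p, x$Q, x$I2))
  invisible(x)
}
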