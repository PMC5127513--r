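#' Per-instrument Wald ratio estimates
#'
#' For each harmonised variant, the causal effect of a 1-SD difference in
#' the exposure on the log-odds of disease is estimated as the ratio of the
#' SNP-outcome to the SNP-exposure association, `theta = Gamma / gamma`,
#' with the first-order standard error `se(Gamma) / |gamma|`. The
#' second-order delta-method SE, which also propagates uncertainty in
#' `gamma`, is available via `second_order = TRUE`.
#'
#' @param pairs Harmonised pairs tibble from [harmonise()] (columns `snp`,
#'   `gamma`, `gamma_se`, `Gamma`, `Gamma_se`).
#' @param second_order Include the exposure-side variance term
#'   `Gamma^2 * gamma_se^2 / gamma^4` in the SE.
#' @return Tibble with `snp`, `theta`, `se`, `p` (two-sided normal).
#' @export
wald_ratio <- function(pairs, second_order = FALSE) {
  stopifnot(all(c("snp", "gamma", "Gamma", "Gamma_se") %in% names(pairs)))
  if (any(pairs$gamma == 0)) {
    stop("undefined instrument: exposure effect gamma = 0 for ",
         paste(pairs$snp[pairs$gamma == 0], collapse = ", "), call. = FALSE)
  }
  theta <- pairs$Gamma / pairs$gamma
  var1 <- (pairs$Gamma_se / pairs$gamma)^2
  se <- if (second_order) {
    sqrt(var1 + pairs$Gamma^2 * pairs$gamma_se^2 / pairs$gamma^4)
  } else {
    sqrt(var1)
  }
  tibble::tibble(snp = pairs$snp, theta = theta, se = se,
                 p = 2 * stats::pnorm(-abs(theta / se)))
}

# Shared fixed-effect inverse-variance pooling kernel: one implementation
# behind both the MR and the observational meta-analysis entry points.
pool_fixed <- function(theta, se) {
  stopifnot(length(theta) >= 1, length(theta) == length(se), all(se > 0))
  w <- se^-2
  theta_hat <- sum(w * theta) / sum(w)
  se_hat <- sum(w)^-0.5
  Q <- sum(w * (theta - theta_hat)^2)
  list(theta = theta_hat, se = se_hat, Q = Q, k = length(theta))
}

new_mr_result <- function(method, theta, se, n_snps, excluded = character(0),
                          estimates = NULL) {
  z <- theta / se
  structure(
    list(method = method, theta = theta, se = se,
         ci95 = c(theta - z975() * se, theta + z975() * se),
         p = 2 * stats::pnorm(-abs(z)), n_snps = n_snps,
         excluded = excluded, estimates = estimates),
    class = "mr_result"
  )
}

#' Inverse-variance-weighted pooling of Wald ratios
#'
#' Fixed-effect pooling of per-instrument causal estimates with weights
#' `se^-2`, appropriate for mutually independent instruments. No
#' overdispersion scaling is applied.
#'
#' @param estimates Tibble from [wald_ratio()] (columns `snp`, `theta`, `se`).
#' @return An `mr_result` object; see [tidy.mr_result()] and
#'   [glance.mr_result()] for tibble views and [to_or_scale()] for the
#'   odds-ratio scale.
#' @export
ivw_pool <- function(estimates) {
  if (is.null(estimates) || nrow(estimates) == 0) {
    stop("at least one instrument estimate is required", call. = FALSE)
  }
  k <- pool_fixed(estimates$theta, estimates$se)
  new_mr_result("ivw", k$theta, k$se, k$k, estimates = estimates)
}

#' Generalised least-squares pooling for correlated instruments
#'
#' When instruments are in linkage disequilibrium, their Wald ratios are not
#' independent and plain IVW understates the pooled standard error. This
#' estimator regresses the SNP-outcome effects on the SNP-exposure effects
#' through the origin, weighting by `Omega^-1` where
#' `Omega[j,k] = se_j * se_k * rho[j,k]` is built from the outcome standard
#' errors and the LD correlation matrix:
#' `theta = (gamma' Omega^-1 gamma)^-1 gamma' Omega^-1 Gamma`, with
#' `se = (gamma' Omega^-1 gamma)^-1/2`. Linear solves are used throughout;
#' `Omega` is never explicitly inverted.
#'
#' With an identity correlation matrix this reduces exactly to [ivw_pool()].
#'
#' @param pairs Harmonised pairs tibble (columns `snp`, `gamma`, `Gamma`,
#'   `Gamma_se`).
#' @param ld LD correlation matrix covering `pairs$snp` (see [ld_matrix()]).
#' @return An `mr_result` object with `method = "gls"`.
#' @export
gls_pool <- function(pairs, ld) {
  stopifnot(all(c("snp", "gamma", "Gamma", "Gamma_se") %in% names(pairs)))
  miss <- setdiff(pairs$snp, rownames(ld))
  if (length(miss)) {
    stop("variant(s) missing from LD matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rho <- ld[pairs$snp, pairs$snp, drop = FALSE]
  s <- pairs$Gamma_se
  Omega <- rho * tcrossprod(s)
  if (rcond(Omega) < 1e-12) {
    stop("instrument correlation matrix is near-singular (condition number > 1e12); ",
         "prune instruments more aggressively", call. = FALSE)
  }
  g <- pairs$gamma
  sol_g <- solve(Omega, g)
  denom <- sum(g * sol_g)            # gamma' Omega^-1 gamma
  theta <- sum(sol_g * pairs$Gamma) / denom
  se <- denom^-0.5
  new_mr_result("gls", theta, se, nrow(pairs),
                estimates = wald_ratio(pairs))
}

#' Refit a causal estimate after excluding instruments
#'
#' Sensitivity-analysis helper: drops the named variants (for example a
#' known pleiotropic locus) and re-runs the requested estimator with all
#' other settings unchanged. The exclusions are recorded on the result.
#'
#' @param pairs Harmonised pairs tibble.
#' @param exclude Character vector of variant ids to drop (must be a subset
#'   of `pairs$snp`; at least one instrument must remain).
#' @param method `"ivw"` or `"gls"`.
#' @param ld LD matrix, required for `method = "gls"`.
#' @return An `mr_result` with `excluded` populated.
#' @export
exclude_and_refit <- function(pairs, exclude = character(0),
                              method = c("ivw", "gls"), ld = NULL) {
  method <- match.arg(method)
  unknown <- setdiff(exclude, pairs$snp)
  if (length(unknown)) {
    stop("exclusion ids not among instruments: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- pairs[!pairs$snp %in% exclude, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop("exclusion removes every instrument", call. = FALSE)
  }
  res <- if (method == "ivw") {
    ivw_pool(wald_ratio(keep))
  } else {
    if (is.null(ld)) stop("gls requires an LD matrix", call. = FALSE)
    gls_pool(keep, ld)
  }
  res$excluded <- exclude
  res
}

#' Express a causal estimate as an odds ratio per SD
#'
#' @param result An `mr_result` (log-odds per 1-SD exposure).
#' @return One-row tibble: `or`, `l95`, `u95`, `p`.
#' @export
to_or_scale <- function(result) {
  stopifnot(inherits(result, "mr_result"))
  tibble::tibble(or = exp(result$theta),
                 l95 = exp(result$ci95[1]), u95 = exp(result$ci95[2]),
                 p = result$p)
}

#' @export
print.mr_result <- function(x, ...) {
  or <- to_or_scale(x)
  cat(sprintf(
    "Mendelian randomisation (%s, %d instrument%s%s)\n  log-odds per SD: %.4f (se %.4f)\n  OR per SD: %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    toupper(x$method), x$n_snps, if (x$n_snps == 1) "" else "s",
    if (length(x$excluded)) paste0("; excluded: ", paste(x$excluded, collapse = ", ")) else "",
    x$theta, x$se, or$or, or$l95, or$u95, x$p))
  invisible(x)
}
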