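#' Build a genetic risk score from dosages
#'
#' Computes the per-individual weighted sum of allele dosages
#' `S_i = sum_j w_j * G_ij`. Weights are typically per-allele effect sizes
#' for a weighted score, or all 1 for an unweighted predisposition score.
#'
#' @param genotypes Dosage matrix, individuals x variants (column names are
#'   variant ids).
#' @param weights Tibble with columns `snp` and `weight`; or a character
#'   vector of variant ids for an unweighted (unit-weight) score.
#' @param missing How to handle missing dosages: `"mean_impute"` (default,
#'   per-variant mean) or `"drop"` (individuals with any missing dosage get
#'   `NA`).
#' @return Numeric vector of scores, one per individual.
#' @export
build_score <- function(genotypes, weights, missing = c("mean_impute", "drop")) {
  missing <- match.arg(missing)
  genotypes <- as.matrix(genotypes)
  if (is.character(weights)) {
    weights <- tibble::tibble(snp = weights, weight = 1)
  }
  stopifnot(all(c("snp", "weight") %in% names(weights)),
            all(is.finite(weights$weight)))
  absent <- setdiff(weights$snp, colnames(genotypes))
  if (length(absent)) {
    stop("score variant(s) absent from genotypes: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  g <- genotypes[, weights$snp, drop = FALSE]
  if (missing == "mean_impute") {
    g <- apply(g, 2, mean_impute)
  }
  as.numeric(g %*% weights$weight)
}

#' Scale a genetic score so one unit predicts 1 SD of exposure
#'
#' Rescales the score by the slope of the regression of the (standardised)
#' exposure on the score, so that a one-unit difference in the scaled score
#' corresponds to a genetically predicted difference of 1 SD in the
#' exposure (the regression of exposure on the scaled score has slope 1).
#' This is the individual-level analogue of expressing causal estimates per
#' SD of the exposure.
#'
#' @param score Numeric score vector, e.g. from [build_score()].
#' @param exposure Standardised exposure vector of the same length.
#' @return The rescaled score, with the fitted slope in attribute `"slope"`.
#' @export
scale_score_to_sd <- function(score, exposure) {
  stopifnot(length(score) == length(exposure))
  slope <- stats::coef(stats::lm(exposure ~ score))[["score"]]
  if (!is.finite(slope) || slope <= 0) {
    stop("score does not positively predict the exposure (slope ",
         format(slope, digits = 3), "); instruments incoherent with exposure",
         call. = FALSE)
  }
  out <- score * slope
  attr(out, "slope") <- slope
  out
}

#' Variance in a phenotype explained by lead variants
#'
#' R-squared from the joint linear regression of a standardised phenotype
#' on all lead-variant dosages. Exactly collinear (duplicated) variants are
#' handled through R's pivoting least squares, with a warning.
#'
#' @param phenotype Standardised numeric vector.
#' @param lead_genotypes Dosage matrix of the lead variants.
#' @return R-squared as a fraction in `[0, 1]`.
#' @export
variance_explained <- function(phenotype, lead_genotypes) {
  g <- as.matrix(lead_genotypes)
  stopifnot(length(phenotype) == nrow(g), ncol(g) >= 1)
  g <- apply(g, 2, mean_impute)
  fit <- stats::lm(phenotype ~ g)
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear lead variants; dropped redundant columns in the fit")
  }
  summary(fit)$r.squared
}

#' Fraction of heritability explained
#'
#' Ratio of the variance explained by the lead variants to a heritability
#' estimate for the trait (chip-based or family-based), `r2 / h2`.
#'
#' @param r2 Variance explained, a fraction in `[0, 1]`.
#' @param h2 Heritability, a fraction in `(0, 1]`.
#' @return The fraction `r2 / h2` (multiply by 100 to report a percentage).
#' @examples
#' heritability_fraction(0.015, 0.20)  # 0.075, i.e. 7.5%
#' @export
heritability_fraction <- function(r2, h2) {
  stopifnot(is.numeric(r2), is.numeric(h2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 must be in [0, 1]", call. = FALSE)
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must be in (0, 1]", call. = FALSE)
  r2 / h2
}

#' Metabolome-wide specificity scan of a genetic score
#'
#' Regresses each (standardised) metabolite on the score, optionally
#' adjusting for covariates, and flags associations that survive
#' multiplicity control across the `m` traits tested. A specific score is
#' expected to light up only the traits in its own pathway.
#'
#' @param score Numeric score vector.
#' @param metabolites Numeric matrix or data frame, individuals x traits
#'   (column names are trait names), each trait standardised.
#' @param covariates Optional covariate matrix; both score and traits are
#'   residualised on it before the per-trait regressions.
#' @param alpha Family-wise (Bonferroni) or FDR (BH) level, default `0.05`.
#' @param method `"bonferroni"` (default, flag when `p < alpha / m`) or
#'   `"bh"` (Benjamini-Hochberg step-up).
#' @return A `scan_result` tibble with one row per trait: `trait`, `beta`
#'   (per unit of score), `se`, `p`, `significant`, `untestable` (constant
#'   traits); attributes `m`, `alpha`, `method`.
#' @export
metabolome_scan <- function(score, metabolites, covariates = NULL,
                            alpha = 0.05, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  y <- as.matrix(metabolites)
  stopifnot(nrow(y) == length(score), ncol(y) >= 1)
  traits <- colnames(y)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(y)))

  n <- length(score)
  df_adj <- 2L
  if (!is.null(covariates)) {
    cm <- cbind(1, as.matrix(covariates))
    qrc <- qr(cm)
    score <- qr.resid(qrc, score)
    y <- qr.resid(qrc, y)
    df_adj <- 1L + qrc$rank
  }

  sc <- score - mean(score)
  ssx <- sum(sc^2)
  untestable <- apply(y, 2, function(col) stats::var(col) == 0)

  beta <- as.numeric(crossprod(y, sc)) / ssx
  fitted_ss <- beta^2 * ssx
  tot_ss <- colSums(sweep(y, 2, colMeans(y))^2)
  sigma2 <- unname(pmax(tot_ss - fitted_ss, 0)) / (n - df_adj)
  se <- sqrt(sigma2 / ssx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - df_adj)

  beta[untestable] <- NA_real_; se[untestable] <- NA_real_; p[untestable] <- NA_real_
  m <- sum(!untestable)
  sig <- if (method == "bonferroni") {
    !is.na(p) & p < alpha / m
  } else {
    adj <- rep(NA_real_, length(p))
    adj[!untestable] <- stats::p.adjust(p[!untestable], method = "BH")
    !is.na(adj) & adj < alpha
  }

  out <- tibble::tibble(trait = traits, beta = beta, se = se, p = p,
                        significant = sig, untestable = unname(untestable))
  class(out) <- c("scan_result", class(out))
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  out
}
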