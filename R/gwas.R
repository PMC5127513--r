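#' Per-SNP association scan on a dosage matrix
#'
#' Fits one additive-coded regression per variant: linear for quantitative
#' phenotypes, logistic for binary ones. Missing dosages are mean-imputed
#' per variant. Two-sided p-values come from the normal approximation to the
#' Wald statistic in both models, for cross-model consistency.
#'
#' Quantitative phenotypes should be on the SD scale so that betas are
#' per-allele effects in SD units; set `standardise = TRUE` to have the scan
#' centre and scale the phenotype itself.
#'
#' @param genotypes Numeric matrix of allele dosages in `[0, 2]`,
#'   individuals in rows, variants in columns (column names are variant ids).
#' @param phenotype Numeric vector (linear) or 0/1 vector (logistic), one
#'   value per individual.
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @param model `"linear"` or `"logistic"`.
#' @param standardise Centre/scale a quantitative phenotype before fitting.
#' @return A tibble with one row per variant: `snp`, `beta`, `se`, `z`, `p`,
#'   `n`, and `untestable` (monomorphic variants or non-converged logistic
#'   fits, which carry `NA` estimates and a `note`).
#' @export
snp_association <- function(genotypes, phenotype, covariates = NULL,
                            model = c("linear", "logistic"),
                            standardise = FALSE) {
  model <- match.arg(model)
  genotypes <- as.matrix(genotypes)
  if (length(phenotype) != nrow(genotypes)) {
    stop("phenotype length must match the number of individuals", call. = FALSE)
  }
  if (model == "logistic" && !all(phenotype %in% c(0, 1, NA))) {
    stop("logistic model requires a 0/1 phenotype", call. = FALSE)
  }
  if (standardise && model == "linear") {
    phenotype <- as.numeric(scale(phenotype))
  }
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(genotypes)))

  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)

  res <- purrr::map(seq_len(ncol(genotypes)), function(j) {
    g <- mean_impute(genotypes[, j])
    if (stats::var(g) == 0) {
      return(tibble::tibble(snp = ids[j], beta = NA_real_, se = NA_real_,
                            z = NA_real_, p = NA_real_, n = length(g),
                            untestable = TRUE, note = "monomorphic"))
    }
    X <- cbind(g = g, covm)
    term <- if (ncol(X) == 1) "X" else "Xg"   # lm's naming for matrix terms
    if (model == "linear") {
      fit <- stats::lm(phenotype ~ X)
      cf <- summary(fit)$coefficients
      beta <- cf[term, 1]; se <- cf[term, 2]
      note <- NA_character_; bad <- FALSE
    } else {
      fit <- suppressWarnings(stats::glm(phenotype ~ X, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      bad <- !fit$converged || !term %in% rownames(cf)
      if (!bad) { beta <- cf[term, 1]; se <- cf[term, 2] }
      note <- if (bad) "logistic_fit_failed" else NA_character_
    }
    if (bad) {
      return(tibble::tibble(snp = ids[j], beta = NA_real_, se = NA_real_,
                            z = NA_real_, p = NA_real_, n = length(g),
                            untestable = TRUE, note = note))
    }
    z <- beta / se
    tibble::tibble(snp = ids[j], beta = beta, se = se, z = z,
                   p = 2 * stats::pnorm(-abs(z)), n = length(g),
                   untestable = FALSE, note = note)
  })
  dplyr::bind_rows(res)
}

mean_impute <- function(x) {
  miss <- is.na(x)
  if (any(miss)) x[miss] <- mean(x[!miss])
  x
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' Combines per-study Z statistics as `sum(sqrt(n) * z) / sqrt(sum(n))`, the
#' weighting that makes a meta-analysis insensitive to between-study
#' differences in measurement scale (different metabolomics platforms, for
#' instance). Signs must already be aligned to a common effect allele.
#'
#' @param studies A data frame with columns `z` and `n` (one row per study).
#' @return A one-row tibble with `z`, `p` (two-sided), `k` (study count) and
#'   `n_total`.
#' @examples
#' meta_z(data.frame(z = c(2, 2), n = c(5000, 5000)))  # z = 2 * sqrt(2)
#' @export
meta_z <- function(studies) {
  stopifnot(is.data.frame(studies), all(c("z", "n") %in% names(studies)))
  if (nrow(studies) < 1) stop("at least one study is required", call. = FALSE)
  if (any(studies$n <= 0)) stop("sample sizes must be positive", call. = FALSE)
  z <- sum(sqrt(studies$n) * studies$z) / sqrt(sum(studies$n))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)),
                 k = nrow(studies), n_total = sum(studies$n))
}

#' Select lead SNPs by windowed greedy clumping
#'
#' Picks the variant with the smallest p-value strictly below the
#' genome-wide threshold, claims a window of +/- `window` base pairs around
#' it on the same chromosome, and repeats on the unclaimed variants. Ties in
#' p are broken by ascending (chromosome, position).
#'
#' @param stats Tibble with at least `snp`, `chrom`, `pos`, `p`.
#' @param threshold Significance threshold; only `p < threshold` (strict)
#'   qualifies. Default `5e-8`, the conventional genome-wide level.
#' @param window Half-width of the exclusion window in base pairs
#'   (default 1 Mb), applied on each side of a lead.
#' @return Tibble of lead rows in selection order, with attributes
#'   `threshold` and `window`. Any two leads on one chromosome are more than
#'   `window` apart. An empty selection is valid.
#' @export
select_lead_snps <- function(stats, threshold = 5e-8, window = 1e6) {
  stopifnot(all(c("snp", "chrom", "pos", "p") %in% names(stats)))
  cand <- stats[!is.na(stats$p) & stats$p < threshold, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos), , drop = FALSE]
  leads <- cand[0, , drop = FALSE]
  while (nrow(cand) > 0) {
    lead <- cand[1, , drop = FALSE]
    leads <- rbind(leads, lead)
    claimed <- cand$chrom == lead$chrom & abs(cand$pos - lead$pos) <= window
    cand <- cand[!claimed, , drop = FALSE]
  }
  leads <- tibble::as_tibble(leads)
  # defensive: the all-pairs spacing guarantee must hold on every run
  if (nrow(leads) > 1) {
    by_chr <- split(leads$pos, leads$chrom)
    ok <- all(vapply(by_chr, function(p) {
      length(p) < 2 || min(diff(sort(p))) > window
    }, logical(1)))
    stopifnot(ok)
  }
  attr(leads, "threshold") <- threshold
  attr(leads, "window") <- window
  leads
}

#' Prune candidate instruments to a pairwise LD bound
#'
#' Greedy selection by ascending p-value: a candidate is kept only when its
#' squared correlation with every already-kept variant is below `r2_max`.
#' The returned set therefore satisfies the all-pairs constraint used to
#' define "imperfect linkage disequilibrium" instrument sets.
#'
#' @param stats Tibble with `snp` and `p`.
#' @param ld LD correlation matrix covering all candidate ids
#'   (see [ld_matrix()]).
#' @param r2_max Pairwise r-squared bound, default `0.8` (kept pairs must be
#'   strictly below it).
#' @return Character vector of kept variant ids, in selection order.
#' @export
prune_correlated <- function(stats, ld, r2_max = 0.8) {
  stopifnot(all(c("snp", "p") %in% names(stats)))
  missing_ids <- setdiff(stats$snp, rownames(ld))
  if (length(missing_ids)) {
    stop("variant(s) missing from LD matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ord <- stats[order(stats$p, stats$snp), ]
  kept <- character(0)
  for (id in ord$snp) {
    if (all(ld[id, kept]^2 < r2_max)) kept <- c(kept, id)
  }
  kept
}

#' Estimate LD from a dosage matrix
#'
#' Pearson correlation of per-variant mean-imputed dosage vectors, followed
#' by positive-semi-definite repair. Zero-variance (monomorphic) variants
#' have undefined correlations; their entries are `NA` and their ids are
#' returned in the `"untestable"` attribute.
#'
#' @param genotypes Dosage matrix, individuals x variants.
#' @param ids Variant ids to include; default all columns.
#' @return LD correlation matrix (class as from [ld_matrix()]).
#' @export
compute_ld <- function(genotypes, ids = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("v", seq_len(ncol(genotypes)))
    if (is.null(ids)) ids <- colnames(genotypes)
  }
  g <- apply(genotypes[, ids, drop = FALSE], 2, mean_impute)
  sds <- apply(g, 2, stats::sd)
  flat <- names(sds)[sds == 0]
  r <- suppressWarnings(stats::cor(g))
  if (length(flat)) {
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
    diag(r) <- 1
    warning("zero-variance variant(s), correlations undefined: ",
            paste(flat, collapse = ", "))
    attr(r, "untestable") <- flat
    return(r)
  }
  ld_matrix(r, ids = ids)
}
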