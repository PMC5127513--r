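#' Convert a confidence interval to a standard error
#'
#' Recovers the standard error of an effect estimate from its reported
#' confidence interval. For ratio measures (odds ratios, relative risks,
#' hazard ratios) the interval is first mapped to the log scale, so the
#' returned value is the standard error of the log effect.
#'
#' The normal quantile for a 95% interval is fixed at 1.959964 (6 decimal
#' places) so that CI-to-SE conversions are bit-for-bit reproducible.
#'
#' @param lower,upper Lower and upper confidence bounds. Must satisfy
#'   `lower <= upper`, and both must be positive when `log_scale = TRUE`.
#' @param level Coverage of the interval as a fraction, default `0.95`.
#' @param log_scale If `TRUE` (default) the bounds are log-transformed before
#'   taking the half-width, as appropriate for ORs/RRs/HRs.
#' @return The (log-scale, if requested) standard error, a positive scalar.
#'   Vectorised over `lower` and `upper`.
#' @examples
#' se_from_ci(1.01, 1.05)          # SE of ln(OR) for an OR of 1.03 (1.01-1.05)
#' se_from_ci(0.1, 0.5, log_scale = FALSE)
#' @export
se_from_ci <- function(lower, upper, level = 0.95, log_scale = TRUE) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (any(lower > upper, na.rm = TRUE)) {
    stop("`lower` must not exceed `upper`", call. = FALSE)
  }
  if (length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single fraction in (0, 1)", call. = FALSE)
  }
  if (log_scale && any(lower <= 0, na.rm = TRUE)) {
    stop("bounds must be positive on the ratio scale", call. = FALSE)
  }
  z <- ci_z(level)
  t <- if (log_scale) log else identity
  (t(upper) - t(lower)) / (2 * z)
}

# Normal quantile for a two-sided interval; 0.95 is pinned to 6 d.p. so the
# CI<->SE round trip is reproducible across platforms.
ci_z <- function(level) {
  if (isTRUE(all.equal(level, 0.95))) 1.959964 else stats::qnorm((1 + level) / 2)
}

#' @keywords internal
z975 <- function() 1.959964

#' Read GWAS summary statistics from delimited text
#'
#' Parses a tab-delimited summary-statistic file into a harmonisation-ready
#' tibble. Column detection is header-driven, so column order is irrelevant.
#' Odds ratios are converted to log-odds, and 95% confidence bounds to
#' standard errors, on read; the returned `beta` column is therefore always
#' an additive per-allele effect (SD units for quantitative traits, log-odds
#' for binary ones).
#'
#' @param path Path to a tab-delimited file with a header row. `"."` denotes
#'   a missing value.
#' @param dialect Named character vector mapping canonical column names to
#'   the file's column names; see [sumstats_dialect()].
#' @return A tibble with columns `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`, and, when present in the
#'   input, `n_cases`, `n_controls` and `z`. Rows keep their input order.
#' @details Malformed rows (non-numeric effect, missing alleles) raise an
#'   error naming the offending line numbers. An `eaf` outside (0, 1) raises
#'   a validation error naming the variant.
#' @seealso [write_sumstats()], [harmonise()]
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  raw <- readr::read_tsv(path, na = c(".", "", "NA"), show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  nm <- names(raw)

  pick <- function(key) {
    cand <- dialect[[key]]
    hit <- cand[cand %in% nm]
    if (length(hit) == 0) NULL else raw[[hit[[1]]]]
  }
  need <- function(key) {
    v <- pick(key)
    if (is.null(v)) {
      stop(sprintf("missing mandatory column for '%s' (looked for: %s)",
                   key, paste(dialect[[key]], collapse = ", ")), call. = FALSE)
    }
    v
  }

  num <- function(x, what) {
    if (is.null(x)) return(NULL)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("malformed %s at line(s) %s",
                   what, paste(bad + 1L, collapse = ", ")), call. = FALSE)
    }
    out
  }

  out <- tibble::tibble(
    snp = need("snp"),
    chrom = as.character(need("chrom")),
    pos = as.integer(num(need("pos"), "position")),
    effect_allele = toupper(need("effect_allele")),
    other_allele = toupper(need("other_allele")),
    eaf = num(need("eaf"), "EAF"),
    p = num(need("p"), "p-value"),
    n = num(pick("n"), "sample size")
  )

  beta <- num(pick("beta"), "beta")
  or <- num(pick("or"), "odds ratio")
  se <- num(pick("se"), "SE")
  l95 <- num(pick("l95"), "L95")
  u95 <- num(pick("u95"), "U95")

  if (is.null(beta) && is.null(or)) {
    stop("missing mandatory column: need BETA or OR", call. = FALSE)
  }
  if (is.null(se) && (is.null(l95) || is.null(u95))) {
    stop("missing mandatory column: need SE or both L95 and U95", call. = FALSE)
  }

  if (is.null(beta)) {
    if (any(or <= 0, na.rm = TRUE)) stop("odds ratios must be positive", call. = FALSE)
    beta <- log(or)
    if (is.null(se)) se <- se_from_ci(l95, u95, log_scale = TRUE)
  } else if (is.null(se)) {
    se <- se_from_ci(l95, u95, log_scale = FALSE)
  }
  out$beta <- beta
  out$se <- se

  ncase <- num(pick("n_cases"), "case count")
  nctrl <- num(pick("n_controls"), "control count")
  if (!is.null(ncase)) out$n_cases <- as.integer(ncase)
  if (!is.null(nctrl)) out$n_controls <- as.integer(nctrl)
  zcol <- num(pick("z"), "z-score")
  out$z <- if (is.null(zcol)) out$beta / out$se else zcol

  validate_sumstats(out)
  out[c("snp", "chrom", "pos", "effect_allele", "other_allele", "eaf",
        "beta", "se", "p", "n", "z",
        intersect(c("n_cases", "n_controls"), names(out)))]
}

#' Default summary-statistic column dialect
#'
#' Maps canonical field names to the column headers accepted on read. Supply
#' a modified copy to [read_sumstats()] for files with non-standard headers.
#'
#' @return A named list of character vectors of acceptable headers.
#' @export
sumstats_dialect <- function() {
  list(
    snp = c("SNP", "ID", "RSID", "variant_id"),
    chrom = c("CHR", "CHROM", "chromosome"),
    pos = c("POS", "BP", "position"),
    effect_allele = c("EA", "A1", "effect_allele"),
    other_allele = c("OA", "A2", "other_allele"),
    eaf = c("EAF", "FRQ", "AF"),
    beta = c("BETA", "beta"),
    or = c("OR", "odds_ratio"),
    se = c("SE", "se"),
    l95 = c("L95", "CI_L", "OR_L95"),
    u95 = c("U95", "CI_U", "OR_U95"),
    p = c("P", "PVAL", "p_value"),
    n = c("N", "n"),
    n_cases = c("N_CASES", "NCASE"),
    n_controls = c("N_CONTROLS", "NCONTROL"),
    z = c("Z", "ZSCORE")
  )
}

#' Write summary statistics to tab-delimited text
#'
#' Inverse of [read_sumstats()]: writes the canonical columns with the
#' standard headers at full precision, so a read/write round trip preserves
#' every field.
#'
#' @param stats Sumstats tibble as produced by [read_sumstats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  validate_sumstats(stats)
  out <- tibble::tibble(
    SNP = stats$snp, CHR = stats$chrom, POS = stats$pos,
    EA = stats$effect_allele, OA = stats$other_allele,
    EAF = fmt_full(stats$eaf), BETA = fmt_full(stats$beta),
    SE = fmt_full(stats$se), P = fmt_full(stats$p), N = fmt_full(stats$n),
    Z = fmt_full(stats$z)
  )
  if ("n_cases" %in% names(stats)) out$N_CASES <- stats$n_cases
  if ("n_controls" %in% names(stats)) out$N_CONTROLS <- stats$n_controls
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

fmt_full <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 15, format = "g"))
}

validate_sumstats <- function(stats) {
  stopifnot(is.data.frame(stats))
  required <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "p")
  miss <- setdiff(required, names(stats))
  if (length(miss)) {
    stop("sumstats missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_eaf <- which(!is.na(stats$eaf) & (stats$eaf <= 0 | stats$eaf >= 1))
  if (length(bad_eaf)) {
    stop("EAF outside (0,1) for variant(s): ",
         paste(stats$snp[bad_eaf], collapse = ", "), call. = FALSE)
  }
  if (any(stats$se <= 0, na.rm = TRUE)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  same <- which(stats$effect_allele == stats$other_allele)
  if (length(same)) {
    stop("effect and other allele identical for variant(s): ",
         paste(stats$snp[same], collapse = ", "), call. = FALSE)
  }
  if (!is.null(stats$z)) {
    zchk <- abs(stats$z - stats$beta / stats$se) <=
      1e-6 * pmax(1, abs(stats$z))
    if (any(!zchk, na.rm = TRUE)) {
      stop("z inconsistent with beta/se for variant(s): ",
           paste(stats$snp[which(!zchk)], collapse = ", "), call. = FALSE)
    }
  }
  invisible(stats)
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  unname(ALLELE_COMPLEMENT[ea] == oa)
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns SNP-to-exposure and SNP-to-outcome association estimates onto a
#' common effect allele so that Wald ratios can be formed. Handles three
#' situations: outcome reported on the opposite allele (effect sign flipped,
#' EAF complemented), outcome reported on the opposite DNA strand (alleles
#' complemented), and palindromic variants (A/T or G/C) whose strand cannot
#' be inferred from intermediate allele frequencies.
#'
#' @param exposure,outcome Sumstats tibbles (see [read_sumstats()]) indexed
#'   by `snp`; the exposure betas are per-allele effects in SD units of the
#'   exposure, the outcome betas log-odds of disease.
#' @param palindromic One of `"exclude"` (default: drop palindromic variants
#'   with EAF inside the ambiguity window), `"keep"` (align assuming same
#'   strand) or `"error"`.
#' @param eaf_window Ambiguity window for palindromic variants, default
#'   `c(0.42, 0.58)`: inside it the strand cannot be resolved from frequency.
#' @return A tibble with one row per resolvable variant: `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `gamma`, `gamma_se` (exposure),
#'   `Gamma`, `Gamma_se`, outcome `p` (`Gamma_p`), `flipped` and
#'   `palindromic` flags. Variants dropped (unpaired, irreconcilable alleles,
#'   ambiguous palindromes) are reported in the `"dropped"` attribute with a
#'   reason code and counted in a message.
#' @export
harmonise <- function(exposure, outcome,
                      palindromic = c("exclude", "keep", "error"),
                      eaf_window = c(0.42, 0.58)) {
  palindromic <- match.arg(palindromic)
  validate_sumstats(exposure)
  validate_sumstats(outcome)

  shared <- intersect(exposure$snp, outcome$snp)
  n_unpaired <- length(setdiff(union(exposure$snp, outcome$snp), shared))
  if (n_unpaired > 0) {
    message(n_unpaired, " variant(s) present in only one of exposure/outcome dropped")
  }

  exp <- exposure[match(shared, exposure$snp), ]
  out <- outcome[match(shared, outcome$snp), ]

  rows <- purrr::map(seq_along(shared), function(i) {
    e_ea <- exp$effect_allele[i]; e_oa <- exp$other_allele[i]
    o_ea <- out$effect_allele[i]; o_oa <- out$other_allele[i]
    pal <- is_palindromic(e_ea, e_oa)

    status <- NULL
    flipped <- FALSE
    if (o_ea == e_ea && o_oa == e_oa) {
      # already aligned
    } else if (o_ea == e_oa && o_oa == e_ea) {
      flipped <- TRUE
    } else if (!pal &&
               identical(unname(ALLELE_COMPLEMENT[o_ea]), e_ea) &&
               identical(unname(ALLELE_COMPLEMENT[o_oa]), e_oa)) {
      # opposite strand, same orientation
    } else if (!pal &&
               identical(unname(ALLELE_COMPLEMENT[o_ea]), e_oa) &&
               identical(unname(ALLELE_COMPLEMENT[o_oa]), e_ea)) {
      flipped <- TRUE
    } else {
      status <- "irreconcilable_alleles"
    }

    ambiguous <- pal && !is.na(exp$eaf[i]) &&
      exp$eaf[i] > eaf_window[1] && exp$eaf[i] < eaf_window[2]
    if (is.null(status) && ambiguous) {
      if (palindromic == "exclude") status <- "palindromic_ambiguous"
      if (palindromic == "error") {
        stop("ambiguous palindromic variant: ", shared[i], call. = FALSE)
      }
    }
    if (!is.null(status)) {
      return(list(drop = tibble::tibble(snp = shared[i], reason = status)))
    }

    Gamma <- if (flipped) -out$beta[i] else out$beta[i]
    list(pair = tibble::tibble(
      snp = shared[i],
      effect_allele = e_ea, other_allele = e_oa,
      eaf = exp$eaf[i],
      gamma = exp$beta[i], gamma_se = exp$se[i], gamma_p = exp$p[i],
      Gamma = Gamma, Gamma_se = out$se[i], Gamma_p = out$p[i],
      flipped = flipped, palindromic = pal
    ))
  })

  pairs <- dplyr::bind_rows(purrr::map(rows, "pair"))
  dropped <- dplyr::bind_rows(purrr::map(rows, "drop"))
  if (nrow(dropped)) {
    message(nrow(dropped), " variant(s) excluded during harmonisation (",
            paste(unique(dropped$reason), collapse = ", "), ")")
  }
  attr(pairs, "dropped") <- dropped
  pairs
}
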