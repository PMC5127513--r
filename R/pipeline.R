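#' Run the full simulation-to-report pipeline
#'
#' Orchestrates simulate -> per-SNP scans -> LD -> lead selection -> pruning
#' -> Mendelian randomisation (IVW and GLS) -> observational meta-analysis
#' -> arm comparison, as one reproducible run. All randomness flows from the
#' config seed through a deterministic per-stage split, so re-running an
#' identical config reproduces byte-identical numeric outputs.
#'
#' @param config A [sim_config()], a list of arguments for it, or the path
#'   to a YAML file of such arguments.
#' @param out_dir Optional directory; when given, the report tables are
#'   written as TSV, and the report plus run manifest as JSON.
#' @param n_obs_studies Number of synthetic sub-studies the cohort is split
#'   into for the observational arm (default 5).
#' @param gw_threshold,window,r2_max Lead-selection and pruning settings;
#'   defaults are genome-wide significance `5e-8`, a 1 Mb window, and
#'   pairwise `r2 < 0.8`.
#' @return A list of class `mr_report`: `lead_table` (per-instrument
#'   estimates styled as a lead-SNP table), `mr` (list of `mr_result` for
#'   IVW and GLS), `observational` (`meta_result`), `concordance`
#'   (from [compare_arms()]), `scan` (exposure GWAS tibble), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_obs_studies = 5,
                         gw_threshold = 5e-8, window = 1e6, r2_max = 0.8) {
  t0 <- Sys.time()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)

  cohort <- simulate_cohort(config)
  g <- cohort$genotypes
  ph <- cohort$phenotypes

  scan_exp <- snp_association(g, ph$exposure, model = "linear")
  scan_exp$chrom <- "1"
  scan_exp$pos <- as.integer(seq_len(nrow(scan_exp)) * 2e6)

  keep <- ph$sampled
  scan_out <- snp_association(g[keep, , drop = FALSE], ph$outcome[keep],
                              model = "logistic")

  ld <- compute_ld(g)
  leads <- select_lead_snps(scan_exp, threshold = gw_threshold, window = window)
  candidates <- if (nrow(leads) > 0) leads else scan_exp
  instruments <- prune_correlated(candidates, ld, r2_max = r2_max)

  exp_stats <- scan_exp[scan_exp$snp %in% instruments, ]
  out_stats <- scan_out[scan_out$snp %in% instruments, ]
  pairs <- tibble::tibble(
    snp = exp_stats$snp,
    gamma = exp_stats$beta, gamma_se = exp_stats$se, gamma_p = exp_stats$p,
    Gamma = out_stats$beta[match(exp_stats$snp, out_stats$snp)],
    Gamma_se = out_stats$se[match(exp_stats$snp, out_stats$snp)],
    Gamma_p = out_stats$p[match(exp_stats$snp, out_stats$snp)]
  )
  mr_ivw <- ivw_pool(wald_ratio(pairs))
  mr_gls <- gls_pool(pairs, ld)

  obs <- observational_arm(ph, n_obs_studies,
                           seed = stage_seed(config$seed, "obs_split"))
  concordance <- compare_arms(mr_ivw, obs)

  lead_table <- dplyr::left_join(
    pairs,
    tibble::tibble(snp = scan_exp$snp, chrom = scan_exp$chrom,
                   pos = scan_exp$pos, eaf = config$eaf),
    by = "snp"
  )

  manifest <- list(
    seed = config$seed,
    config_digest = digest_of(unclass(config)),
    version = as.character(utils::packageVersion("bcaamr")),
    n_individuals = config$n,
    n_instruments = length(instruments),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_digests = list(
      genotypes = digest_of(g),
      exposure_scan = digest_of(scan_exp),
      outcome_scan = digest_of(scan_out),
      mr_ivw = digest_of(mr_ivw[c("theta", "se")]),
      mr_gls = digest_of(mr_gls[c("theta", "se")]),
      observational = digest_of(obs[c("theta", "se", "Q")])
    )
  )

  report <- structure(
    list(lead_table = lead_table,
         mr = list(ivw = mr_ivw, gls = mr_gls),
         observational = obs, concordance = concordance,
         scan = scan_exp, instruments = instruments,
         manifest = manifest),
    class = "mr_report"
  )

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Split the cohort into sub-studies and fit a per-SD logistic association of
# outcome on exposure in each: a deliberately confounded observational arm.
observational_arm <- function(ph, n_studies, seed) {
  set.seed(seed)
  idx <- sample(rep_len(seq_len(n_studies), nrow(ph)))
  ests <- purrr::map(seq_len(n_studies), function(s) {
    d <- ph[idx == s & ph$sampled, ]
    fit <- stats::glm(outcome ~ exposure, data = d, family = stats::binomial())
    cf <- summary(fit)$coefficients
    tibble::tibble(study = paste0("substudy", s),
                   theta = cf["exposure", 1], se = cf["exposure", 2],
                   n_cases = sum(d$outcome), n_noncases = sum(1 - d$outcome))
  })
  fixed_effect_meta(dplyr::bind_rows(ests))
}

digest_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$lead_table, file.path(out_dir, "lead_table.tsv"))
  readr::write_tsv(report$scan, file.path(out_dir, "exposure_scan.tsv"))
  mr_tab <- dplyr::bind_rows(purrr::map(report$mr, glance))
  readr::write_tsv(mr_tab, file.path(out_dir, "mr_results.tsv"))
  readr::write_tsv(glance(report$observational),
                   file.path(out_dir, "observational_meta.tsv"))
  readr::write_tsv(report$concordance, file.path(out_dir, "concordance.tsv"))
  jsonlite::write_json(
    list(mr = mr_tab, observational = glance(report$observational),
         concordance = report$concordance, manifest = report$manifest),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Mendelian randomisation pipeline report\n")
  cat(sprintf("  %d instruments after lead selection and pruning\n",
              length(x$instruments)))
  print(x$mr$ivw)
  print(x$mr$gls)
  print(x$observational)
  cat(sprintf("  genetic/observational ratio %.3f, CI overlap: %s\n",
              x$concordance$ratio, x$concordance$ci_overlap))
  invisible(x)
}
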