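#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the generative model used to
#' exercise the pipeline without cohort data: biallelic SNPs in
#' Hardy-Weinberg equilibrium with block LD, a standardised quantitative
#' exposure with additive per-allele effects plus a shared confounder, and
#' a binary outcome generated from the exposure through a logistic model.
#'
#' Defaults mirror the study conditions the pipeline is aimed at: per-allele
#' exposure effects in the 0.06-0.13 SD range, a causal log-odds effect of
#' `log(1.5)` per SD of exposure, and a 10% baseline disease prevalence.
#'
#' @param n Number of individuals.
#' @param eaf Vector of effect-allele frequencies, each in (0, 1).
#' @param gamma Per-allele exposure effects in SD units of the final
#'   (standardised) exposure; recycled against `eaf`.
#' @param ld Target haplotype correlation matrix (one value per SNP pair),
#'   or `NULL` for independent SNPs; must be positive semi-definite. Use
#'   [ld_blocks()] to build a block-exchangeable matrix.
#' @param theta Causal effect on the outcome, log-odds per 1 SD of exposure.
#' @param prevalence Baseline disease prevalence in (0, 1).
#' @param confounding Length-2 numeric `c(a, b)`: effect of a standard
#'   normal confounder U on the exposure (`a`, SD units) and on the outcome
#'   log-odds (`b`).
#' @param pleiotropy Optional vector of direct SNP-outcome log-odds effects
#'   (default all 0; the Mendelian-randomisation design assumes absence).
#' @param n_exposure,n_outcome,case_fraction Sample sizes and outcome case
#'   fraction used by the summary-statistic shortcut
#'   [simulate_sumstats()].
#' @param sampling Optional case-control sampling: list with
#'   `case_fraction` and `control_fraction` of cases/controls to retain.
#' @param seed Integer seed; mandatory, every artefact of the generator is
#'   a pure function of (config, seed).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n = 10000,
                       eaf = c(0.46, 0.89, 0.79, 0.40),
                       gamma = c(0.09, 0.11, 0.09, 0.07),
                       ld = NULL,
                       theta = log(1.5),
                       prevalence = 0.10,
                       confounding = c(a = 0.3, b = 0.3),
                       pleiotropy = NULL,
                       n_exposure = 16596,
                       n_outcome = 50000,
                       case_fraction = 0.15,
                       sampling = NULL,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  m <- max(length(eaf), length(gamma))
  eaf <- rep_len(eaf, m)
  gamma <- rep_len(gamma, m)
  stopifnot(n >= 1, all(eaf > 0 & eaf < 1),
            prevalence > 0 && prevalence < 1,
            length(confounding) == 2,
            n_exposure >= 1, n_outcome >= 1,
            case_fraction > 0 && case_fraction < 1)
  if (is.null(ld)) ld <- diag(m)
  ld <- as.matrix(ld)
  if (nrow(ld) != m) stop("ld dimension must match the number of SNPs", call. = FALSE)
  ev <- eigen((ld + t(ld)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("target LD matrix is not positive semi-definite", call. = FALSE)
  }
  if (is.null(pleiotropy)) pleiotropy <- rep(0, m)
  pleiotropy <- rep_len(pleiotropy, m)

  var_g <- genetic_variance(gamma, eaf, ld)
  a <- unname(confounding[1])
  if (var_g + a^2 >= 1) {
    stop(sprintf("genetic variance (%.3f) plus confounder variance (%.3f) must stay below 1 so the exposure can be standardised",
                 var_g, a^2), call. = FALSE)
  }

  structure(
    list(n = n, eaf = eaf, gamma = gamma, ld = ld, theta = theta,
         prevalence = prevalence,
         confounding = c(a = a, b = unname(confounding[2])),
         pleiotropy = pleiotropy,
         n_exposure = n_exposure, n_outcome = n_outcome,
         case_fraction = case_fraction, sampling = sampling,
         snp_ids = paste0("snp", seq_len(m)), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Approximate variance of the genetic component of the (pre-noise) exposure:
# dosage variance 2f(1-f) per SNP; cross terms use the latent haplotype
# correlation as the dosage correlation (exact for independent SNPs, a close
# upper bound under LD).
genetic_variance <- function(gamma, eaf, ld) {
  sd_g <- sqrt(2 * eaf * (1 - eaf))
  as.numeric(t(gamma * sd_g) %*% ld %*% (gamma * sd_g))
}

#' Block-exchangeable LD matrix
#'
#' @param sizes Integer vector of block sizes.
#' @param r Within-block correlation (recycled per block); blocks are
#'   mutually independent.
#' @return Correlation matrix of dimension `sum(sizes)`.
#' @export
ld_blocks <- function(sizes, r) {
  r <- rep_len(r, length(sizes))
  blocks <- purrr::map2(sizes, r, function(s, rho) {
    b <- matrix(rho, s, s); diag(b) <- 1; b
  })
  m <- sum(sizes)
  out <- matrix(0, m, m)
  at <- 0
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

# Deterministic per-stage seed splitting: hash the stage name into the top
# seed so adding a stage never perturbs another stage's draws.
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000000007
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium with block LD
#'
#' Haplotypes are drawn from a latent Gaussian copula with the target
#' correlation and thresholded at the allele-frequency quantile; the two
#' haplotypes of an individual are independent, so Hardy-Weinberg holds by
#' construction. Dosages are the per-individual haplotype sums in
#' `{0, 1, 2}`. The realised (empirical) dosage correlation differs
#' slightly from the latent target and is recorded in the
#' `"realised_ld"` attribute for oracle use.
#'
#' @param config A [sim_config()].
#' @return Dosage matrix `n x m` with variant ids as column names.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  m <- length(config$eaf)
  L <- tryCatch(chol(config$ld + diag(1e-10, m)),
                error = function(e) stop("target LD matrix is not positive semi-definite",
                                         call. = FALSE))
  thresh <- stats::qnorm(config$eaf)
  draw_haplo <- function() {
    z <- matrix(stats::rnorm(config$n * m), config$n, m) %*% L
    sweep(z, 2, thresh, "<") * 1
  }
  g <- draw_haplo() + draw_haplo()
  colnames(g) <- config$snp_ids
  rownames(g) <- paste0("id", seq_len(config$n))
  if (m > 1) {
    attr(g, "realised_ld") <- suppressWarnings(stats::cor(g))
  } else {
    attr(g, "realised_ld") <- matrix(1, 1, 1)
  }
  g
}

#' Simulate a standardised exposure from genotypes
#'
#' The exposure is `X = sum_j gamma_j (G_j - 2 f_j) + a U + e`, where U is
#' a standard normal confounder shared with the outcome and the noise
#' variance is chosen so the total variance is 1 — per-allele effects are
#' therefore directly in SD units. The realisation is then empirically
#' standardised.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return Tibble with columns `exposure` (unit variance) and `confounder`.
#' @export
simulate_exposure <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "exposure"))
  n <- nrow(genotypes)
  centred <- sweep(genotypes, 2, 2 * config$eaf)
  gpart <- as.numeric(centred %*% config$gamma)
  a <- config$confounding["a"]
  var_g <- genetic_variance(config$gamma, config$eaf, config$ld)
  noise_sd <- sqrt(1 - var_g - a^2)
  u <- stats::rnorm(n)
  x <- gpart + a * u + noise_sd * stats::rnorm(n)
  tibble::tibble(exposure = as.numeric(scale(x)), confounder = u)
}

#' Simulate a binary outcome from the exposure
#'
#' Disease status is Bernoulli with
#' `P(D = 1) = plogis(b0 + theta * X + b * U + sum_j p_j G_j)`, where `b0`
#' is solved numerically so the population prevalence matches the
#' configuration. Optionally a case-control subsample (all cases plus a
#' fraction of controls) is drawn; because the logistic model's slope is
#' invariant under outcome-dependent sampling, downstream logistic fits
#' still estimate valid odds ratios.
#'
#' @param exposure Tibble from [simulate_exposure()] (or a numeric vector,
#'   in which case `confounder` must be supplied separately).
#' @param config A [sim_config()].
#' @param genotypes Optional dosage matrix, required when the pleiotropy
#'   knob is non-zero.
#' @param confounder Numeric vector when `exposure` is a bare vector.
#' @return Tibble with `outcome` (0/1) and `sampled` (logical; all `TRUE`
#'   without case-control sampling). The attained intercept is in attribute
#'   `"b0"`.
#' @export
simulate_outcome <- function(exposure, config, genotypes = NULL,
                             confounder = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(exposure)) {
    confounder <- exposure$confounder
    exposure <- exposure$exposure
  }
  if (is.null(confounder)) confounder <- rep(0, length(exposure))
  set.seed(stage_seed(config$seed, "outcome"))
  eta <- config$theta * exposure + config$confounding["b"] * confounder
  if (any(config$pleiotropy != 0)) {
    if (is.null(genotypes)) {
      stop("pleiotropic effects configured; supply `genotypes`", call. = FALSE)
    }
    eta <- eta + as.numeric(genotypes %*% config$pleiotropy)
  }
  b0 <- tryCatch(
    stats::uniroot(function(b) mean(stats::plogis(b + eta)) - config$prevalence,
                   lower = -50, upper = 50, tol = 1e-10)$root,
    error = function(e) stop("prevalence unreachable for the configured effects: ",
                             conditionMessage(e), call. = FALSE))
  d <- stats::rbinom(length(eta), 1, stats::plogis(b0 + eta))

  sampled <- rep(TRUE, length(d))
  if (!is.null(config$sampling)) {
    cf <- config$sampling$case_fraction %||% 1
    kf <- config$sampling$control_fraction %||% 1
    keep_case <- d == 1 & stats::runif(length(d)) < cf
    keep_ctrl <- d == 0 & stats::runif(length(d)) < kf
    sampled <- keep_case | keep_ctrl
  }
  out <- tibble::tibble(outcome = d, sampled = sampled)
  attr(out, "b0") <- b0
  out
}

#' Simulate a complete cohort
#'
#' Runs the three generative stages under the config's seed and returns the
#' pieces together with the true-parameter record for oracle checks.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `phenotypes` (tibble: id, exposure,
#'   confounder, outcome, sampled) and `truth` (the config).
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  xu <- simulate_exposure(g, config)
  d <- simulate_outcome(xu, config, genotypes = g)
  list(
    genotypes = g,
    phenotypes = tibble::tibble(id = rownames(g), xu, d),
    truth = config
  )
}

#' Simulate two-sample GWAS summary statistics directly
#'
#' Summary-statistic shortcut that bypasses individual-level simulation:
#' exposure effects are drawn as `gamma_hat ~ MVN(gamma, D_g rho D_g)` and
#' outcome effects as `Gamma_hat ~ MVN(theta * gamma + pleiotropy,
#' D_G rho D_G)`, with errors correlated across SNPs according to the LD
#' matrix `rho`. Standard errors follow the standard large-sample forms:
#' `1 / sqrt(2 f (1-f) n_exposure)` for a unit-variance quantitative
#' exposure and `1 / sqrt(2 f (1-f) n_outcome phi (1-phi))` for a logistic
#' outcome with case fraction `phi`.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` sumstats tibbles (same layout
#'   as [read_sumstats()]), `ld` (the target correlation matrix with ids),
#'   and `truth`.
#' @export
simulate_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "sumstats"))
  m <- length(config$eaf)
  f <- config$eaf
  se_g <- 1 / sqrt(2 * f * (1 - f) * config$n_exposure)
  phi <- config$case_fraction
  se_G <- 1 / sqrt(2 * f * (1 - f) * config$n_outcome * phi * (1 - phi))

  rho <- (config$ld + t(config$ld)) / 2
  gamma_hat <- drop(MASS::mvrnorm(1, mu = config$gamma,
                                  Sigma = rho * tcrossprod(se_g)))
  Gamma_hat <- drop(MASS::mvrnorm(1, mu = config$theta * config$gamma + config$pleiotropy,
                                  Sigma = rho * tcrossprod(se_G)))

  mk <- function(beta, se, n, cases = NULL) {
    out <- tibble::tibble(
      snp = config$snp_ids, chrom = "1",
      pos = as.integer(seq_len(m) * 2e6),
      effect_allele = "A", other_allele = "G",
      eaf = f, beta = beta, se = se,
      p = 2 * stats::pnorm(-abs(beta / se)),
      n = n, z = beta / se
    )
    if (!is.null(cases)) {
      out$n_cases <- round(cases)
      out$n_controls <- round(n - cases)
    }
    out
  }
  ld <- rho
  dimnames(ld) <- list(config$snp_ids, config$snp_ids)
  list(
    exposure = mk(gamma_hat, se_g, config$n_exposure),
    outcome = mk(Gamma_hat, se_G, config$n_outcome,
                 cases = phi * config$n_outcome),
    ld = ld,
    truth = config
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
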