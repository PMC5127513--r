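test_that("sim_config validates its generative parameters", {
  expect_error(sim_config(eaf = 1.2, seed = 1), "eaf")
  expect_error(sim_config(seed = 1, prevalence = 0), "prevalence")
  expect_error(sim_config(), "seed")
  bad_ld <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  expect_error(sim_config(eaf = c(0.3, 0.3, 0.3), gamma = 0.1,
                          ld = bad_ld, seed = 1), "positive semi-definite")
  # exposure variance budget: genetic + confounder must stay below 1
  expect_error(sim_config(eaf = 0.5, gamma = 1.4, seed = 1), "standardised")
})

test_that("genotypes respect allele frequencies, independence, and the seed", {
  cfg <- sim_config(n = 50000, eaf = c(0.5, 0.5), gamma = c(0.1, 0.1),
                    ld = diag(2), seed = 61)
  g <- simulate_genotypes(cfg)
  expect_true(all(g %in% 0:2))
  # mean dosage 2 * eaf = 1.0 within binomial tolerance
  expect_equal(unname(colMeans(g)), c(1, 1), tolerance = 0.01)
  # independent block: empirical |r| < 0.02 at this n
  expect_lt(abs(cor(g[, 1], g[, 2])), 0.02)
  # determinism: same config, byte-identical draw
  expect_identical(g, simulate_genotypes(cfg))
})

test_that("genotypes sit in Hardy-Weinberg equilibrium", {
  withr::local_seed(62)
  cfg <- sim_config(n = 2000, eaf = runif(1000, 0.1, 0.9),
                    gamma = 0, seed = 62)
  g <- simulate_genotypes(cfg)
  pvals <- apply(g, 2, function(x) {
    f <- mean(x) / 2
    expected <- 2000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
    observed <- tabulate(x + 1, 3)
    suppressWarnings(stats::chisq.test(observed, p = expected / sum(expected))$p.value)
  })
  # nominal chi-square rejection rate at alpha = 0.01
  expect_lt(abs(mean(pvals < 0.01) - 0.01), 0.011)
})

test_that("exposure realises configured per-allele effects in SD units", {
  cfg <- sim_config(n = 20000, eaf = 0.5, gamma = 0.10, theta = 0,
                    confounding = c(0.3, 0.3), seed = 63)
  g <- simulate_genotypes(cfg)
  x <- simulate_exposure(g, cfg)
  expect_equal(sd(x$exposure), 1, tolerance = 1e-9)
  slope <- coef(lm(x$exposure ~ g[, 1]))[[2]]
  expect_lt(abs(slope - 0.10), 0.02)

  # all-null configuration: associations are null
  cfg0 <- sim_config(n = 5000, eaf = c(0.3, 0.5), gamma = 0,
                     confounding = c(0, 0), theta = 0, seed = 64)
  g0 <- simulate_genotypes(cfg0)
  x0 <- simulate_exposure(g0, cfg0)
  scan <- snp_association(g0, x0$exposure)
  expect_true(all(scan$p > 1e-4))
})

test_that("outcome prevalence solver hits its target", {
  cfg <- sim_config(n = 100000, eaf = 0.5, gamma = 0.1, theta = 0,
                    prevalence = 0.10, confounding = c(0, 0), seed = 65)
  g <- simulate_genotypes(cfg)
  x <- simulate_exposure(g, cfg)
  d <- simulate_outcome(x, cfg)
  expect_lt(abs(mean(d$outcome) - 0.10), 0.005)
})

test_that("case-control sampling keeps cases and a control fraction", {
  cfg <- sim_config(n = 20000, eaf = 0.5, gamma = 0.1, theta = log(1.5),
                    prevalence = 0.2,
                    sampling = list(case_fraction = 1, control_fraction = 0.25),
                    seed = 66)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  expect_true(all(ph$sampled[ph$outcome == 1]))
  ctrl_kept <- mean(ph$sampled[ph$outcome == 0])
  expect_equal(ctrl_kept, 0.25, tolerance = 0.02)
  # truth record reproduces the config exactly
  expect_identical(co$truth, cfg)
})

test_that("summary-statistic shortcut is unbiased and nearly noiseless at huge n", {
  cfg <- sim_config(theta = log(1.5), n_exposure = 1e10, n_outcome = 1e10,
                    seed = 67)
  ss <- simulate_sumstats(cfg)
  r <- ivw_pool(wald_ratio(harmonise(ss$exposure, ss$outcome)))
  expect_equal(r$theta, log(1.5), tolerance = 1e-3)

  # determinism of the shortcut
  ss2 <- simulate_sumstats(cfg)
  expect_identical(ss$outcome$beta, ss2$outcome$beta)
})

test_that("a null causal effect yields centred IVW estimates", {
  reps <- 200
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(theta = 0, seed = 6800 + i)
    ss <- simulate_sumstats(cfg)
    est[i] <- ivw_pool(wald_ratio(harmonise(ss$exposure, ss$outcome)))$theta
  }
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(reps))
})

test_that("individual-level and summary-level routes give matching estimates", {
  # matched small-n two-sample designs; compare the two theta-hat samples
  reps <- 120
  n_exp <- 3000; n_out <- 4000
  est_ind <- est_sum <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n = n_exp, eaf = c(0.46, 0.60, 0.40, 0.30),
                      gamma = c(0.12, 0.12, 0.11, 0.12) * 2,
                      theta = log(1.5), prevalence = 0.15,
                      confounding = c(0.2, 0.2),
                      n_exposure = n_exp, n_outcome = n_out,
                      case_fraction = 0.15, seed = 70000 + i)
    # route 1: individual-level exposure scan + outcome scan in a second cohort
    g1 <- simulate_genotypes(cfg)
    x1 <- simulate_exposure(g1, cfg)
    exp_scan <- snp_association(g1, x1$exposure)
    cfg2 <- sim_config(n = n_out, eaf = cfg$eaf, gamma = cfg$gamma,
                       theta = log(1.5), prevalence = 0.15,
                       confounding = c(0.2, 0.2),
                       seed = 90000 + i)
    co2 <- simulate_cohort(cfg2)
    out_scan <- snp_association(co2$genotypes, co2$phenotypes$outcome,
                                model = "logistic")
    pairs <- tibble::tibble(snp = exp_scan$snp,
                            gamma = exp_scan$beta, gamma_se = exp_scan$se,
                            Gamma = out_scan$beta, Gamma_se = out_scan$se)
    est_ind[i] <- ivw_pool(wald_ratio(pairs))$theta
    # route 2: summary-statistic shortcut at the same n, matched case share
    cfg_ss <- sim_config(eaf = cfg$eaf, gamma = cfg$gamma, theta = log(1.5),
                         n_exposure = n_exp, n_outcome = n_out,
                         case_fraction = mean(co2$phenotypes$outcome),
                         seed = 80000 + i)
    ss <- simulate_sumstats(cfg_ss)
    est_sum[i] <- ivw_pool(wald_ratio(harmonise(ss$exposure, ss$outcome)))$theta
  }
  ks <- suppressWarnings(stats::ks.test(est_ind, est_sum))
  expect_gt(ks$p.value, 0.01)
})

test_that("the pleiotropy knob biases naive MR as expected", {
  reps <- 60
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(theta = 0, pleiotropy = c(0.05, 0.05, 0.05, 0.05),
                      seed = 7100 + i)
    ss <- simulate_sumstats(cfg)
    est[i] <- ivw_pool(wald_ratio(harmonise(ss$exposure, ss$outcome)))$theta
  }
  expect_gt(mean(est), 0.2)  # direct SNP-outcome effects masquerade as causal
})
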