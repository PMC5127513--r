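test_that("wald_ratio matches hand-computed worked examples", {
  # valine-style single instrument: gamma 0.10, OR 1.04
  p <- toy_pairs("rs1440581", gamma = 0.10, Gamma = log(1.04),
                 Gamma_se = se_from_ci(1.02, 1.07))
  w <- wald_ratio(p)
  expect_equal(w$theta, log(1.04) / 0.10, tolerance = 1e-5)
  expect_equal(exp(w$theta), 1.480, tolerance = 1e-3)

  # gamma 0.09, OR 1.03 (1.01-1.05): theta 0.3284, se 0.1101
  p2 <- toy_pairs("rs7678928", gamma = 0.09, Gamma = log(1.03),
                  Gamma_se = 0.009908)
  w2 <- wald_ratio(p2)
  expect_equal(w2$theta, 0.3284, tolerance = 1e-3)
  expect_equal(w2$se, 0.1101, tolerance = 1e-3)

  # null outcome effect -> null ratio
  expect_equal(wald_ratio(toy_pairs("x", 0.1, 0, 0.01))$theta, 0)
  expect_error(wald_ratio(toy_pairs("x", 0, 0.1, 0.01)), "gamma = 0")

  # second-order SE adds the exposure-side term
  w3 <- wald_ratio(toy_pairs("x", 0.1, 0.05, 0.02, gamma_se = 0.02),
                   second_order = TRUE)
  expect_equal(w3$se, sqrt((0.02 / 0.1)^2 + 0.05^2 * 0.02^2 / 0.1^4),
               tolerance = 1e-12)
})

test_that("ivw_pool matches closed forms and an external fixed-effect fit", {
  one <- tibble::tibble(snp = "a", theta = 0.25, se = 0.1)
  r1 <- ivw_pool(one)
  expect_equal(r1$theta, 0.25)
  expect_equal(r1$se, 0.1)

  two <- tibble::tibble(snp = c("a", "b"), theta = c(0.2, 0.4), se = 0.1)
  r2 <- ivw_pool(two)
  expect_equal(r2$theta, 0.3)
  expect_equal(r2$se, 0.1 / sqrt(2), tolerance = 1e-12)

  expect_error(ivw_pool(tibble::tibble(theta = numeric(0), se = numeric(0))),
               "at least one")

  # independent cross-check against metafor's fixed-effect estimator
  withr::local_seed(31)
  est <- tibble::tibble(snp = paste0("s", 1:6), theta = rnorm(6, 0.3, 0.2),
                        se = runif(6, 0.05, 0.3))
  ours <- ivw_pool(est)
  ref <- metafor::rma(yi = est$theta, sei = est$se, method = "FE")
  expect_equal(ours$theta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, as.numeric(ref$se), tolerance = 1e-10)
})

test_that("gls_pool reduces to IVW under identity correlation", {
  withr::local_seed(32)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    pr <- toy_pairs(paste0("s", 1:m), gamma = runif(m, 0.05, 0.15),
                    Gamma = rnorm(m, 0.04, 0.02),
                    Gamma_se = runif(m, 0.005, 0.03))
    ld <- ld_matrix(diag(m), ids = pr$snp)
    g <- gls_pool(pr, ld)
    i_ <- ivw_pool(wald_ratio(pr))
    expect_equal(g$theta, i_$theta, tolerance = 1e-10)
    expect_equal(g$se, i_$se, tolerance = 1e-10)
  }
})

test_that("gls_pool agrees with the explicit-inverse formula", {
  withr::local_seed(33)
  for (i in 1:50) {
    m <- 3
    rho <- random_corr(m)
    pr <- toy_pairs(paste0("s", 1:m), gamma = runif(m, 0.05, 0.15),
                    Gamma = rnorm(m, 0.04, 0.02),
                    Gamma_se = runif(m, 0.005, 0.03))
    ld <- ld_matrix(rho, ids = pr$snp)
    g <- gls_pool(pr, ld)
    o <- oracle_gls(pr$gamma, pr$Gamma, pr$Gamma_se, ld)
    expect_equal(g$theta, o$theta, tolerance = 1e-8)
    expect_equal(g$se, o$se, tolerance = 1e-8)
  }
})

test_that("near-duplicate instruments recover the single-instrument estimate", {
  pr1 <- toy_pairs("a", gamma = 0.1, Gamma = 0.04, Gamma_se = 0.012)
  pr2 <- toy_pairs(c("a", "b"), gamma = c(0.1, 0.1),
                   Gamma = c(0.04, 0.04), Gamma_se = c(0.012, 0.012))
  ld <- ld_matrix(matrix(c(1, 0.999, 0.999, 1), 2), ids = c("a", "b"))
  g <- gls_pool(pr2, ld)
  w <- wald_ratio(pr1)
  expect_equal(g$theta, w$theta, tolerance = 1e-3)
  # and a perfectly singular correlation is refused with advice
  ld_bad <- matrix(1, 2, 2); dimnames(ld_bad) <- list(c("a", "b"), c("a", "b"))
  expect_error(gls_pool(pr2, ld_bad), "prune")
})

test_that("theta is equivariant to exposure rescaling and allele recoding", {
  withr::local_seed(34)
  pr <- toy_pairs(paste0("s", 1:5), gamma = runif(5, 0.05, 0.15),
                  Gamma = rnorm(5, 0.04, 0.02), Gamma_se = runif(5, 0.01, 0.03))
  base <- ivw_pool(wald_ratio(pr))
  for (c_ in c(0.5, 2, 10)) {
    sc <- pr; sc$gamma <- sc$gamma * c_
    expect_equal(ivw_pool(wald_ratio(sc))$theta, base$theta / c_,
                 tolerance = 1e-12)
  }
  # flipping one instrument's coded allele (negate gamma and Gamma)
  fl <- pr
  fl$gamma[2] <- -fl$gamma[2]; fl$Gamma[2] <- -fl$Gamma[2]
  expect_equal(ivw_pool(wald_ratio(fl))$theta, base$theta, tolerance = 1e-12)
  ld <- ld_matrix(random_corr(5), ids = pr$snp)
  # under GLS the flip also flips the instrument's correlations
  ld_fl <- ld
  ld_fl[2, ] <- -ld_fl[2, ]; ld_fl[, 2] <- -ld_fl[, 2]; diag(ld_fl) <- 1
  expect_equal(gls_pool(fl, ld_fl)$theta, gls_pool(pr, ld)$theta,
               tolerance = 1e-12)
})

test_that("exclusion refits drop instruments and keep everything else fixed", {
  pr <- bcaa_instruments("isoleucine")
  full <- ivw_pool(wald_ratio(pr))
  same <- exclude_and_refit(pr, character(0))
  expect_equal(same$theta, full$theta)

  drop1 <- exclude_and_refit(pr, "rs1420601")
  expect_identical(drop1$excluded, "rs1420601")
  expect_identical(drop1$n_snps, 3L)

  two <- pr[1:2, ]
  solo <- exclude_and_refit(two, two$snp[2])
  expect_equal(solo$theta, wald_ratio(two[1, ])$theta)
  expect_equal(solo$se, wald_ratio(two[1, ])$se)

  expect_error(exclude_and_refit(two, two$snp), "every instrument")
  expect_error(exclude_and_refit(pr, "rs999"), "not among")
})

test_that("to_or_scale exponentiates point estimate and CI", {
  null <- ivw_pool(tibble::tibble(snp = "a", theta = 0, se = 0.1))
  expect_equal(to_or_scale(null)$or, 1.0)
  r <- ivw_pool(tibble::tibble(snp = "a", theta = 0.39221, se = 0.1))
  expect_equal(to_or_scale(r)$or, 1.480, tolerance = 1e-3)
  gckr <- ivw_pool(tibble::tibble(snp = "rs1260326", theta = log(0.94), se = 0.1))
  expect_equal(to_or_scale(gckr)$or, 0.94, tolerance = 1e-12)
})

test_that("IVW recovers a true causal effect from simulated summary stats", {
  # generic strong-instrument two-sample design: 20 instruments, both
  # samples of order 50,000
  theta_true <- 0.40
  reps <- 500
  est <- se <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(eaf = rep(c(0.2, 0.35, 0.5, 0.65), 5),
                      gamma = rep(c(0.07, 0.09, 0.11, 0.13), 5),
                      theta = theta_true, n_exposure = 50000,
                      n_outcome = 50000, case_fraction = 0.15,
                      seed = 4000 + i)
    ss <- simulate_sumstats(cfg)
    h <- harmonise(ss$exposure, ss$outcome)
    r <- ivw_pool(wald_ratio(h))
    est[i] <- r$theta; se[i] <- r$se
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - theta_true), 3 * mc_se)
  cover <- mean(abs(est - theta_true) <= z975() * se)
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.98)
})

test_that("tidy and glance views expose per-instrument and pooled rows", {
  pr <- bcaa_instruments("isoleucine")
  r <- ivw_pool(wald_ratio(pr))
  td <- tidy(r)
  expect_identical(nrow(td), 4L)
  expect_true(all(c("snp", "theta", "se", "or") %in% names(td)))
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$or, exp(r$theta))
  expect_s3_class(autoplot(r), "ggplot")
})
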