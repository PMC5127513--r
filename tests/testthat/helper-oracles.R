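# Fixture builders and independent brute-force oracles used across tests.

toy_sumstats <- function(snp, beta, se, eaf = 0.3, ea = "A", oa = "G",
                         chrom = "1", pos = seq_along(snp) * 10L, n = 1000) {
  tibble::tibble(
    snp = snp, chrom = chrom, pos = as.integer(pos),
    effect_allele = rep_len(ea, length(snp)),
    other_allele = rep_len(oa, length(snp)),
    eaf = rep_len(eaf, length(snp)),
    beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n = rep_len(n, length(snp)), z = beta / se
  )
}

toy_pairs <- function(snp, gamma, Gamma, Gamma_se, gamma_se = 0.01) {
  tibble::tibble(snp = snp, gamma = gamma, gamma_se = rep_len(gamma_se, length(snp)),
                 Gamma = Gamma, Gamma_se = Gamma_se)
}

# Independent windowed-clumping oracle: repeatedly scan the full remaining
# table for the best (p, chrom, pos) row, then discard everything inside the
# window on the same chromosome.
oracle_leads <- function(stats, threshold = 5e-8, window = 1e6) {
  df <- as.data.frame(stats[!is.na(stats$p) & stats$p < threshold, ])
  picked <- character(0)
  while (nrow(df) > 0) {
    best <- 1
    for (i in seq_len(nrow(df))) {
      if (df$p[i] < df$p[best] ||
          (df$p[i] == df$p[best] &&
           (df$chrom[i] < df$chrom[best] ||
            (df$chrom[i] == df$chrom[best] && df$pos[i] < df$pos[best])))) {
        best <- i
      }
    }
    picked <- c(picked, df$snp[best])
    drop <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(df))) {
      drop[i] <- df$chrom[i] == df$chrom[best] &&
        abs(df$pos[i] - df$pos[best]) <= window
    }
    df <- df[!drop, , drop = FALSE]
  }
  picked
}

# Independent pruning oracle: walk candidates in (p, snp) order with an
# explicit double loop over kept variants.
oracle_prune <- function(stats, ld, r2_max = 0.8) {
  ord <- stats$snp[order(stats$p, stats$snp)]
  kept <- character(0)
  for (id in ord) {
    ok <- TRUE
    for (k in kept) if (ld[id, k]^2 >= r2_max) ok <- FALSE
    if (ok) kept <- c(kept, id)
  }
  kept
}

# All-pairs feasibility check by exhaustive enumeration.
feasible_set <- function(ids, ld, r2_max = 0.8) {
  if (length(ids) < 2) return(TRUE)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && ld[ids[i], ids[j]]^2 >= r2_max) return(FALSE)
    }
  }
  TRUE
}

# Random correlation matrix via a random Gram matrix, rescaled.
random_corr <- function(m) {
  A <- matrix(stats::rnorm(m * (m + 2)), m + 2, m)
  S <- crossprod(A)
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

# Direct GLS formula with an explicit matrix inverse (oracle for gls_pool).
oracle_gls <- function(gamma, Gamma, se, rho) {
  Omega <- rho * tcrossprod(se)
  Oi <- solve(Omega)
  denom <- as.numeric(t(gamma) %*% Oi %*% gamma)
  list(theta = as.numeric(t(gamma) %*% Oi %*% Gamma) / denom,
       se = denom^-0.5)
}
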