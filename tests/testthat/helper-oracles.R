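# Independent oracles used across tests.

# Full-enumeration HWE exact test: probability of each heterozygote count
# conditional on allele counts, via exact rational-free factorial arithmetic.
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het
  nr <- min(na, 2 * n - na)
  hets <- seq(nr %% 2, nr, by = 2)
  pr <- sapply(hets, function(h) {
    hr <- (nr - h) / 2
    hc <- n - h - hr
    # multinomial coefficient x 2^h, unnormalised
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
          h * log(2))
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# OLS Wald p with ML variance (sigma^2 = RSS/n), the reduction target for the
# mixed model at K = I; computed through lm.fit (QR), an independent route
# from the eigen-rotation in the package.
ols_wald_oracle <- function(x, y) {
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (sd(x) == 0) return(NA_real_)
  X <- cbind(1, x)
  q <- lm.fit(X, y)
  s2 <- sum(q$residuals^2) / length(y)
  se <- sqrt(chol2inv(qr.R(q$qr))[2, 2] * s2)
  pchisq((q$coefficients[2] / se)^2, df = 1, lower.tail = FALSE)
}

# Small two-population genotype sample with known Balding-Nichols divergence
bn_two_pop <- function(n_per_pop, m, fst, seed) {
  F <- simulate_ancestral_freqs(m, 2, fst, seed = seed)
  Q <- rbind(matrix(c(1, 0), n_per_pop, 2, byrow = TRUE),
             matrix(c(0, 1), n_per_pop, 2, byrow = TRUE))
  list(geno = simulate_genotypes(F, Q, seed = seed + 1),
       labels = rep(1:2, each = n_per_pop))
}
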