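test_that("ancestral frequencies follow the Balding-Nichols model", {
  F <- simulate_ancestral_freqs(5000, 2, 0.2, seed = 1)
  expect_true(all(F > 0 & F < 1))
  p <- attr(F, "base_freq")
  # E[F_kj | p] = p; Var = F p(1-p): check both moments loosely
  expect_lt(max(abs(colMeans(F) - p)), 0.9)   # per-locus draws vary
  expect_lt(abs(mean(F[1, ] - p)), 0.01)
  v <- mean((F[1, ] - p)^2 / (p * (1 - p)))
  expect_equal(v, 0.2, tolerance = 0.05)
  # near-zero divergence collapses onto the base frequency
  F0 <- simulate_ancestral_freqs(500, 2, 1e-4, seed = 2)
  expect_lt(max(abs(F0[1, ] - attr(F0, "base_freq"))), 0.05)
  # determinism
  expect_identical(simulate_ancestral_freqs(100, 2, 0.2, seed = 9),
                   simulate_ancestral_freqs(100, 2, 0.2, seed = 9))
  expect_error(simulate_ancestral_freqs(100, 2, 1.2), "configuration")
})

test_that("genotype sampling matches the admixture mixture frequencies", {
  # degenerate: single ancestry, fixed locus -> all genotypes 2
  F <- matrix(1 - 1e-12, 1, 3)
  Q <- matrix(1, 5, 1)
  g <- simulate_genotypes(F, Q, seed = 1)
  expect_true(all(g$g == 2L))
  # binomial mean at pi = 0.5
  F <- matrix(0.5, 1, 10000)
  g <- simulate_genotypes(F, matrix(1, 1, 1), seed = 2)
  expect_equal(mean(g$g), 1.0, tolerance = 0.02)
  # sample allele frequency tracks pi per locus: regression slope ~ 1
  F <- simulate_ancestral_freqs(400, 2, 0.2, seed = 3)
  Q <- simulate_admixture_q(500, 2, 0.5, seed = 4)
  g <- simulate_genotypes(F, Q, seed = 5)
  pibar <- colMeans(Q %*% F)
  fhat <- locus_freq(g)
  expect_equal(unname(coef(lm(fhat ~ pibar))[2]), 1, tolerance = 0.05)
  # allele frequency converges to mixture mean within 3 binomial SDs
  sd3 <- 3 * sqrt(pibar * (1 - pibar) / (2 * 500))
  expect_true(all(abs(fhat - pibar) < pmax(3.5 * sd3, 0.05)))
  expect_error(simulate_genotypes(F, Q[, 1, drop = FALSE]), "input error")
})

test_that("liability phenotype model has the stated closed-form behaviour", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 50, n_causal = 5,
                    causal_effect = 0, ancestry_effect = 0, intercept = 0)
  F <- simulate_ancestral_freqs(50, 2, 0.2, seed = 1)
  Q <- simulate_admixture_q(1000, 2, 0.5, seed = 2)
  g <- simulate_genotypes(F, Q, seed = 3)
  ph <- simulate_phenotypes(g, Q, cfg, seed = 4)
  expect_equal(mean(ph$status), 0.5, tolerance = 0.06)
  # intercept -> -inf: all residents, IO ~ Beta(8,2) mean 0.8
  cfg2 <- sim_config(n_individuals = 1000, n_snps = 50, causal_effect = 0,
                     ancestry_effect = 0, intercept = -30)
  ph2 <- simulate_phenotypes(g, Q, cfg2, seed = 5)
  expect_true(all(ph2$status == 0))
  expect_equal(mean(ph2$io), 0.8, tolerance = 0.03)
  # ancestry effect 3 with Q in {0,1}: migrant fraction gap = logis(3)-logis(0)
  cfg3 <- sim_config(n_individuals = 2000, n_snps = 50, causal_effect = 0,
                     ancestry_effect = 3, intercept = 0)
  Qh <- rbind(matrix(c(1, 0), 1000, 2, byrow = TRUE),
              matrix(c(0, 1), 1000, 2, byrow = TRUE))
  gh <- simulate_genotypes(F, Qh, seed = 6)
  ph3 <- simulate_phenotypes(gh, Qh, cfg3, seed = 7)
  gap <- mean(ph3$status[1:1000]) - mean(ph3$status[1001:2000])
  expect_equal(gap, plogis(3) - plogis(0), tolerance = 0.05)
})

test_that("simulated tracks have the designed NSD geometry", {
  cfg <- sim_config(step_sd_km = 1e-12, migration_distance_km = 50)
  tr <- simulate_track("resident", cfg, seed = 1)
  expect_lt(max(abs(tr$fixes$x)), 1e-6)
  expect_lt(max(abs(tr$fixes$y)), 1e-6)
  expect_equal(nrow(tr$fixes), 365)  # full year, no dropped fixes
  # migrant plateau at distance^2
  trm <- simulate_track("migrant", cfg, seed = 2)
  nsd <- compute_nsd(trm, 1)
  plateau <- mean(nsd$nsd[nsd$day >= 200 & nsd$day <= 250])
  expect_equal(plateau, 2500, tolerance = 0.01)
  # at least 30 days on the second range
  expect_gt(sum(nsd$nsd > 0.9 * 2500), 30)
  # missingness thins fixes
  cfg2 <- sim_config(missing_fix_rate = 0.3)
  tr2 <- simulate_track("resident", cfg2, seed = 3)
  expect_lt(nrow(tr2$fixes), 330)
  expect_error(sim_config(migration_distance_km = -1), "configuration")
})

test_that("fixture sets are byte-identical across runs and round-trip", {
  cfg <- sim_config(n_individuals = 10, n_snps = 100, seed = 42)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  p1 <- write_fixture_set(cfg, d1)
  p2 <- write_fixture_set(cfg, d2)
  for (nm in names(p1))
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), info = nm)
  vcf_lines <- readLines(p1$vcf)
  expect_equal(sum(!startsWith(vcf_lines, "#")), 100)
  header <- strsplit(vcf_lines[grep("^#CHROM", vcf_lines)], "\t")[[1]]
  expect_length(header, 9 + 10)
  g <- read_vcf(p1$vcf)
  sim <- simulate_dataset(cfg)
  expect_identical(unname(g$g), unname(sim$geno$g))
})
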