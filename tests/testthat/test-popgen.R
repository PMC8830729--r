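test_that("centered GRM matches the hand-computed example and is PSD", {
  # 3 individuals x 2 loci: g = [[0,2],[1,1],[2,0]], f = (0.5, 0.5)
  # centered dosages: [[-1,1],[0,0],[1,-1]]
  # K = (1/2) X X^T = [[1,0,-1],[0,0,0],[-1,0,1]]
  g <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
  K <- compute_grm(genotype_matrix(g))
  expect_equal(unclass(K),
               matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3),
               ignore_attr = TRUE)
  # identical individuals have identical rows and K_ii = K_ij
  g2 <- rbind(g, g[1, ])
  K2 <- compute_grm(genotype_matrix(g2))
  expect_equal(K2[1, ], K2[4, ], ignore_attr = TRUE)
  expect_equal(K2[1, 1], K2[1, 4])
  # PSD and permutation equivariance on simulated data
  sim <- bn_two_pop(30, 400, 0.1, seed = 7)
  Ks <- compute_grm(sim$geno)
  ev <- eigen(Ks, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_equal(unclass(Ks), unclass(t(Ks)), tolerance = 1e-12)
  perm <- sample(nrow(Ks))
  Kp <- compute_grm(genotype_matrix(sim$geno$g[perm, ]))
  expect_equal(unclass(Kp), unclass(Ks)[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-12)
  # VanRaden scaling has diagonal mean ~ 1 under Hardy-Weinberg
  F <- simulate_ancestral_freqs(5000, 1, 0.05, seed = 8)
  gh <- simulate_genotypes(F, matrix(1, 200, 1), seed = 9)
  Kv <- compute_grm(gh, scale = "vanraden")
  expect_equal(mean(diag(Kv)), 1, tolerance = 0.02)
})

test_that("PCA separates diverged populations on PC1", {
  sim <- bn_two_pop(50, 1000, 0.2, seed = 11)
  pc <- pca_genotypes(sim$geno)
  expect_true(all(diff(pc$values) <= 1e-8))   # non-increasing
  side <- sign(pc$vectors[, 1])
  purity <- max(mean(side[sim$labels == 1] > 0), mean(side[sim$labels == 1] < 0))
  expect_gt(purity, 0.99)
  # scree gap: K = 2 simulated -> top 1 eigenvalue dominates the rest
  expect_gt(pc$values[1] / pc$values[2], 5)
})

test_that("Weir-Cockerham F_ST hits known targets", {
  # fixed differences give F_ST = 1
  g <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  est <- fst_between(genotype_matrix(g), rep(1:2, each = 10), n_boot = 0)
  expect_equal(est$estimate, 1)
  # a null split of one panmictic population is ~ 0
  F <- simulate_ancestral_freqs(10000, 1, 0.05, seed = 21)
  gp <- simulate_genotypes(F, matrix(1, 200, 1), seed = 22)
  e0 <- fst_between(gp, rep(1:2, 100), n_boot = 0)
  expect_lt(abs(e0$estimate), 0.005)
  # Balding-Nichols two populations at F = 0.05: estimate in [0.04, 0.06],
  # CI brackets the estimate
  sim <- bn_two_pop(100, 10000, 0.05, seed = 23)
  e <- fst_between(sim$geno, sim$labels, n_boot = 500, seed = 1)
  expect_gt(e$estimate, 0.04)
  expect_lt(e$estimate, 0.06)
  expect_true(e$ci[1] < e$estimate & e$estimate < e$ci[2])
  expect_error(fst_between(genotype_matrix(g), c(1, rep(2, 19))), "2 individuals")
})

test_that("cluster assignment and MAF-by-cluster comparisons behave", {
  Q <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.5))
  asg <- assign_clusters(Q)
  expect_equal(asg$cluster, c(1, 2, 1))
  expect_true(asg$tie[3])
  # identical frequencies -> Wilcoxon p = 1 under ties
  g <- matrix(rep(rbinom(40, 2, 0.3), each = 10), 10, 40)
  mb <- maf_by_cluster(genotype_matrix(g), rep(1:2, each = 5), 1:40)
  expect_equal(unname(mb$maf[, 1]), unname(mb$maf[, 2]))
  expect_gt(mb$pairwise_p[1, 2], 0.99)
  # a planted +0.2 frequency shift in one cluster is detected
  set.seed(31)
  g1 <- sapply(runif(50, 0.15, 0.3), function(p) rbinom(40, 2, p))
  g2 <- sapply(runif(50, 0.35, 0.5), function(p) rbinom(40, 2, p))
  gall <- rbind(g1, g2)
  mb2 <- maf_by_cluster(genotype_matrix(gall), rep(1:2, each = 40), 1:50)
  expect_lt(mb2$kruskal_p, 0.001)
  expect_lt(mb2$pairwise_p[1, 2], 0.001)
  # with two groups Kruskal-Wallis chi^2 equals the Wilcoxon z^2
  # (rounded to avoid representation-level near-ties confusing the tie tables)
  x <- round(mb2$maf[, 1], 10); y <- round(mb2$maf[, 2], 10)
  kw <- kruskal.test(list(x, y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  ties <- table(r)
  w <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z2 <- (w - mu)^2 / sig2
  expect_equal(unname(kw$statistic), z2, tolerance = 1e-6)
})
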