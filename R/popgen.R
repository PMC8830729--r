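#' Genetic relatedness (kinship) matrix
#'
#' Centered construction: K = (1/m) * sum_j (x_j - 2 f_j)(x_j - 2 f_j)^T over
#' loci j, with f_j the sample alternate-allele frequency. Missing entries
#' are mean-imputed per locus; monomorphic loci are skipped with a warning.
#' `scale = "vanraden"` divides by sum_j 2 f_j (1 - f_j) instead of m, which
#' gives a diagonal mean of ~1 under Hardy--Weinberg.
#'
#' @param geno a `genotype_matrix`
#' @param scale `"centered"` (default) or `"vanraden"`
#' @return an n x n symmetric matrix of class `kinship_matrix`
#' @export
compute_grm <- function(geno, scale = c("centered", "vanraden")) {
  scale <- match.arg(scale)
  g <- if (inherits(geno, "genotype_matrix")) geno$g else as.matrix(geno)
  f <- colMeans(g, na.rm = TRUE) / 2
  mono <- f <= 0 | f >= 1 | !is.finite(f)
  if (any(mono)) {
    warnf("skipping %d monomorphic locus/loci in GRM", sum(mono))
    g <- g[, !mono, drop = FALSE]; f <- f[!mono]
  }
  m <- ncol(g)
  X <- sweep(g, 2, 2 * f)
  X[is.na(X)] <- 0                      # mean imputation after centering
  denom <- if (scale == "centered") m else sum(2 * f * (1 - f))
  K <- tcrossprod(X) / denom
  K <- (K + t(K)) / 2
  structure(K, class = c("kinship_matrix", "matrix"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d x %d, diag mean %.3f\n",
              nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Principal component analysis of genotypes
#'
#' Loci are mean-imputed, centered at 2f and standardised by
#' sqrt(2 f (1 - f)); the individual-by-individual covariance is then
#' eigendecomposed. Monomorphic loci are skipped.
#'
#' @param geno a `genotype_matrix`
#' @param n_pc number of components to return
#' @return object of class `geno_pca`: `vectors` (n x n_pc), `values`
#'   (all eigenvalues, non-increasing), `var_explained`
#' @export
pca_genotypes <- function(geno, n_pc = 10L) {
  g <- if (inherits(geno, "genotype_matrix")) geno$g else as.matrix(geno)
  f <- colMeans(g, na.rm = TRUE) / 2
  keep <- f > 0 & f < 1
  g <- g[, keep, drop = FALSE]; f <- f[keep]
  X <- sweep(g, 2, 2 * f)
  X <- sweep(X, 2, sqrt(2 * f * (1 - f)), "/")
  X[is.na(X)] <- 0
  K <- tcrossprod(X) / ncol(X)
  e <- eigen(K, symmetric = TRUE)
  n_pc <- min(n_pc, ncol(e$vectors))
  structure(list(vectors = e$vectors[, seq_len(n_pc), drop = FALSE],
                 values = e$values,
                 var_explained = e$values / sum(pmax(e$values, 0))),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("geno_pca: leading eigenvalues",
      paste(signif(head(x$values, 5), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Weir--Cockerham F_ST between groups
#'
#' The 1984 variance-components estimator, combined across loci as a ratio
#' of averages (sum a / sum (a+b+c)); the 95% CI is a percentile bootstrap
#' over loci.
#'
#' @param geno a `genotype_matrix`
#' @param labels group label per individual (>= 2 groups, each >= 2 members)
#' @param n_boot bootstrap resamples over loci (0 to skip the CI)
#' @param seed RNG seed for the bootstrap
#' @return object of class `fst_est`: `estimate`, `ci` (2-vector),
#'   `per_locus` components, `method`
#' @export
fst_between <- function(geno, labels, n_boot = 10000L, seed = 1L) {
  g <- if (inherits(geno, "genotype_matrix")) geno$g else as.matrix(geno)
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stopf("each group needs >= 2 individuals")
  r <- nlevels(labels)
  # per-group, per-locus sample size, allele frequency, heterozygote freq
  ni <- pi <- hi <- matrix(0, r, ncol(g))
  for (k in seq_len(r)) {
    gk <- g[labels == levels(labels)[k], , drop = FALSE]
    ni[k, ] <- colSums(!is.na(gk))
    pi[k, ] <- colMeans(gk, na.rm = TRUE) / 2
    hi[k, ] <- colMeans(gk == 1, na.rm = TRUE)
  }
  ok <- colSums(ni >= 1) == r & apply(ni, 2, min) > 0
  ni <- ni[, ok, drop = FALSE]; pi <- pi[, ok, drop = FALSE]
  hi <- hi[, ok, drop = FALSE]
  nbar <- colMeans(ni)
  nc <- (colSums(ni) - colSums(ni^2) / colSums(ni)) / (r - 1)
  pbar <- colSums(ni * pi) / colSums(ni)
  s2 <- colSums(ni * sweep(pi, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * hi) / colSums(ni)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  est <- sum(a) / sum(tot)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    m <- length(a)
    boot <- numeric(n_boot)
    chunk <- 1000L
    done <- 0L
    while (done < n_boot) {
      nb <- min(chunk, n_boot - done)
      idx <- matrix(sample.int(m, m * nb, replace = TRUE), m, nb)
      asum <- colSums(matrix(a[idx], m, nb))
      tsum <- colSums(matrix(tot[idx], m, nb))
      boot[done + seq_len(nb)] <- asum / tsum
      done <- done + nb
    }
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  structure(list(estimate = est, ci = ci,
                 per_locus = data.frame(a = a, total = tot),
                 method = "Weir-Cockerham 1984, ratio of averages",
                 n_loci = length(a), n_boot = n_boot),
            class = "fst_est")
}

#' @export
print.fst_est <- function(x, ...) {
  cat(sprintf("F_ST = %.4f (95%% CI %.4f-%.4f; %s; %d loci)\n",
              x$estimate, x$ci[1], x$ci[2], x$method, x$n_loci))
  invisible(x)
}

#' Minor-allele-frequency comparison between clusters
#'
#' Per-cluster allele frequencies for a SNP subset, compared across clusters
#' with a Kruskal--Wallis test and pairwise two-sided Wilcoxon rank-sum
#' tests (exact when both groups have fewer than 20 SNPs, normal
#' approximation with tie correction otherwise; raw, uncorrected pairwise
#' p-values).
#'
#' @param geno a `genotype_matrix`
#' @param labels cluster label per individual
#' @param snp_subset locus indices (or ids) to compare
#' @return list: `maf` (SNP x cluster matrix), `kruskal_p`,
#'   `pairwise_p` (cluster x cluster matrix)
#' @export
maf_by_cluster <- function(geno, labels, snp_subset) {
  if (!length(snp_subset)) stopf("input error: empty SNP subset")
  if (is.character(snp_subset)) snp_subset <- match(snp_subset, geno$loci$id)
  labels <- as.factor(labels)
  g <- geno$g[, snp_subset, drop = FALSE]
  maf <- sapply(levels(labels), function(l) {
    f <- colMeans(g[labels == l, , drop = FALSE], na.rm = TRUE) / 2
    pmin(f, 1 - f)
  })
  vals <- as.vector(maf)
  grp <- factor(rep(colnames(maf), each = nrow(maf)))
  kp <- if (nlevels(grp) > 1) kruskal.test(vals, grp)$p.value else NA_real_
  lv <- levels(labels)
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    xi <- maf[, i]; xj <- maf[, j]
    exact <- length(xi) < 20 && length(xj) < 20
    pw[i, j] <- pw[j, i] <-
      suppressWarnings(wilcox.test(xi, xj, exact = exact)$p.value)
  }
  list(maf = maf, kruskal_p = kp, pairwise_p = pw)
}
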