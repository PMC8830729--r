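#' Fit the null linear mixed model y = W a + u + e
#'
#' u ~ N(0, s_g^2 K), e ~ N(0, s_e^2 I). K is eigendecomposed once; the
#' variance ratio lambda = s_g^2 / s_e^2 is profiled out by maximum
#' likelihood on a 61-point log grid over [1e-5, 1e5] refined by Brent's
#' method. The rotated data are cached for per-SNP tests.
#'
#' @param y phenotype vector (complete)
#' @param K kinship matrix (symmetric PSD)
#' @param W fixed-covariate design matrix (default intercept only)
#' @return object of class `lmm_null`: eigen cache (`U`, `d`), rotated
#'   `y_r`, `W_r`, `lambda` (null ML estimate), `loglik`
#' @export
fit_null_model <- function(y, K, W = NULL) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  if (sd(y) == 0) stopf("degenerate phenotype: constant y")
  e <- tryCatch(eigen(K, symmetric = TRUE),
                error = function(err) stopf("eigendecomposition failure: %s",
                                            conditionMessage(err)))
  d <- pmax(e$values, 0)
  U <- e$vectors
  y_r <- drop(crossprod(U, y))
  W_r <- crossprod(U, W)
  opt <- optimize_lambda(y_r, W_r, d)
  structure(list(U = U, d = d, y_r = y_r, W_r = W_r, n = n,
                 lambda = opt$lambda, loglik = opt$loglik),
            class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf("lmm_null: n = %d, lambda_hat = %.4g, logLik = %.2f\n",
              x$n, x$lambda, x$loglik))
  invisible(x)
}

# Profile ML log-likelihood of lambda given rotated data.
# v_i = lambda d_i + 1; alpha, sigma_e^2 profiled in closed form.
lmm_profile_ll <- function(log_lambda, y_r, X_r, d) {
  lambda <- exp(log_lambda)
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(X_r, X_r * w)
  XtWy <- crossprod(X_r, y_r * w)
  ab <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(ab)) return(list(ll = -Inf))
  r <- y_r - drop(X_r %*% ab)
  rss_w <- sum(r^2 * w)
  n <- length(y_r)
  s2 <- rss_w / n
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) - 0.5 * sum(log(v)) - 0.5 * n
  list(ll = ll, beta = drop(ab), s2 = s2, XtWX = XtWX, lambda = lambda)
}

optimize_lambda <- function(y_r, X_r, d, n_grid = 61L) {
  grid <- seq(log(1e-5), log(1e5), length.out = n_grid)
  lls <- vapply(grid, function(g) lmm_profile_ll(g, y_r, X_r, d)$ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  op <- optimize(function(g) lmm_profile_ll(g, y_r, X_r, d)$ll,
                 interval = c(lo, hi), maximum = TRUE)
  best <- if (op$objective > lls[i]) op$maximum else grid[i]
  fit <- lmm_profile_ll(best, y_r, X_r, d)
  list(lambda = exp(best), loglik = fit$ll, fit = fit)
}

#' Wald test of one SNP in the mixed model
#'
#' The SNP dosage (mean-imputed) joins the fixed design; by default lambda is
#' re-optimised under the alternative, then the GLS effect and its standard
#' error give the Wald statistic (beta/se)^2 compared to chi-square(1).
#'
#' @param x SNP dosage vector aligned to the phenotype
#' @param null a `lmm_null` cache
#' @param reoptimize re-estimate lambda per SNP (default) or reuse the null
#'   lambda
#' @return list: `beta`, `se`, `p`, `lambda`; or NULL for a monomorphic SNP
#' @export
wald_test_snp <- function(x, null, reoptimize = TRUE) {
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (sd(x) == 0) return(NULL)
  x_r <- drop(crossprod(null$U, x))
  X_r <- cbind(null$W_r, x_r)
  fit <- if (reoptimize) optimize_lambda(null$y_r, X_r, null$d)$fit
    else lmm_profile_ll(log(null$lambda), null$y_r, X_r, null$d)
  j <- ncol(X_r)
  Vinv <- tryCatch(solve(fit$XtWX), error = function(e) NULL)
  if (is.null(Vinv)) return(NULL)
  beta <- unname(fit$beta[j])
  se <- sqrt(Vinv[j, j] * fit$s2)
  stat <- (beta / se)^2
  list(beta = beta, se = se, p = pchisq(stat, 1, lower.tail = FALSE),
       stat = stat, lambda = fit$lambda)
}

#' Mixed-model association scan over all SNPs
#'
#' One univariate Wald test per SNP against the phenotype, with the kinship
#' matrix as the random-effect covariance. Binary phenotypes are analysed by
#' the same linear model on 0/1. Returns per-SNP effect, standard error,
#' Wald p, Bonferroni-adjusted p, significance flag, MAF and PVE.
#'
#' @param geno a `genotype_matrix` (individuals aligned to `y`)
#' @param y phenotype vector
#' @param K kinship matrix; identity (NULL) reduces every test to OLS
#' @param W covariate design (default intercept only)
#' @param reoptimize per-SNP lambda re-optimisation (default TRUE)
#' @param alpha significance level on the adjusted p (default 0.05)
#' @return object of class `assoc_scan`: data.frame `results` with columns
#'   chrom, pos, id, maf, beta, se, p_wald, p_bonf, significant, pve,
#'   relative_pve; `lambda_gc`; `null` model
#' @export
association_scan <- function(geno, y, K = NULL, W = NULL, reoptimize = TRUE,
                             alpha = 0.05) {
  g <- if (inherits(geno, "genotype_matrix")) geno$g else as.matrix(geno)
  loci <- if (inherits(geno, "genotype_matrix")) geno$loci else
    data.frame(chrom = "chr1", pos = seq_len(ncol(g)),
               id = paste0("snp_", seq_len(ncol(g))))
  if (length(y) != nrow(g)) stopf("input error: phenotype length mismatch")
  if (is.null(K)) K <- diag(length(y))
  null <- fit_null_model(y, K, W)
  m <- ncol(g)
  beta <- se <- p <- stat <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    r <- wald_test_snp(g[, j], null, reoptimize = reoptimize)
    if (is.null(r)) next
    beta[j] <- r$beta; se[j] <- r$se; p[j] <- r$p; stat[j] <- r$stat
  }
  tested <- !is.na(p)
  p_bonf <- bonferroni_adjust(p, sum(tested))
  maf <- locus_maf(g)
  pve <- compute_pve(beta, se, maf, length(y))
  sig <- !is.na(p_bonf) & p_bonf < alpha
  rel <- rep(NA_real_, m)
  if (any(sig)) rel[sig] <- relative_pve(pve[sig])
  res <- data.frame(chrom = loci$chrom, pos = loci$pos, id = loci$id,
                    maf = maf, beta = beta, se = se, p_wald = p,
                    p_bonf = p_bonf, significant = sig, pve = pve,
                    relative_pve = rel, stringsAsFactors = FALSE)
  structure(list(results = res, lambda_gc = genomic_inflation(stat[tested]),
                 null = null, n = length(y), m_tested = sum(tested)),
            class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("assoc_scan: %d SNPs tested, n = %d, lambda_GC = %.2f, %d significant (Bonferroni)\n",
              x$m_tested, x$n, x$lambda_gc, sum(x$results$significant, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.assoc_scan <- function(object, ...) {
  r <- object$results
  top <- r[order(r$p_wald), ][seq_len(min(10, nrow(r))), ]
  cat(sprintf("Top associations (of %d tested; lambda_GC = %.2f):\n",
              object$m_tested, object$lambda_gc))
  print(top, row.names = FALSE, digits = 3)
  invisible(top)
}

#' Manhattan-style plot of an association scan
#' @param x an `assoc_scan`
#' @param ... passed to `plot`
#' @export
plot.assoc_scan <- function(x, ...) {
  r <- x$results[!is.na(x$results$p_wald), ]
  chrom <- factor(r$chrom, levels = unique(r$chrom))
  idx <- seq_len(nrow(r))
  plot(idx, -log10(r$p_wald), pch = 16, cex = 0.5,
       col = c("grey30", "steelblue")[(as.integer(chrom) %% 2) + 1],
       xlab = "locus", ylab = expression(-log[10](p)), ...)
  thr <- 0.05 / x$m_tested
  graphics::abline(h = -log10(thr), lty = 2, col = "red")
  invisible(x)
}

#' Bonferroni adjustment
#' @param p p-values
#' @param m number of tests (default `length(p)`)
#' @return pmin(1, p * m)
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stopf("input error: m must be >= 1")
  pmin(1, p * m)
}

#' Genomic inflation factor
#'
#' lambda_GC = median(observed chi-square(1) statistics) divided by the
#' theoretical null median (qchisq(0.5, 1) = 0.4549...).
#'
#' @param stats Wald chi-square statistics
#' @return lambda_GC
#' @export
genomic_inflation <- function(stats) {
  median(stats, na.rm = TRUE) / qchisq(0.5, df = 1)
}

#' Per-SNP proportion of variance explained
#'
#' PVE = 2 b^2 MAF(1-MAF) / (2 b^2 MAF(1-MAF) + se(b)^2 * 2N * MAF(1-MAF)),
#' from the effect estimate, its standard error, the minor allele frequency
#' and the sample size. Invariant under allele relabelling (MAF <-> 1-MAF
#' with a sign flip of b).
#'
#' @param beta,se effect and standard error
#' @param maf minor allele frequency in (0, 0.5]
#' @param n sample size (>= 2)
#' @return PVE in [0, 1]; NA where maf is 0
#' @export
compute_pve <- function(beta, se, maf, n) {
  if (any(n < 2)) stopf("input error: n must be >= 2")
  h <- 2 * maf * (1 - maf)
  num <- beta^2 * h
  out <- num / (num + se^2 * 2 * n * maf * (1 - maf))
  out[maf <= 0] <- NA_real_
  out
}

#' Relative PVE over the significant SNP set
#' @param pve PVE values of the significant SNPs
#' @return percentages summing to 100
#' @export
relative_pve <- function(pve) 100 * pve / sum(pve)
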