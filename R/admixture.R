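#' Maximum-likelihood admixture estimation
#'
#' Fits the binomial admixture model
#' \deqn{L = \sum_{ij} g_{ij}\log\sum_k Q_{ik}F_{kj} +
#'   (2-g_{ij})\log\sum_k Q_{ik}(1-F_{kj})}
#' by EM over the admixture proportions Q (rows on the simplex) and ancestral
#' frequencies F (clipped to [1e-6, 1-1e-6]). The log-likelihood is
#' non-decreasing across iterations; convergence is declared when the
#' increase falls below `tol` (default 1e-6) or after `max_iter` iterations,
#' and the best of `n_restarts` random initialisations is kept.
#'
#' @param geno a `genotype_matrix` (or dosage matrix; NA = missing)
#' @param K number of ancestral clusters (>= 1)
#' @param seed RNG seed for the initialisations
#' @param n_restarts random restarts (best likelihood kept)
#' @param tol log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations
#' @param mask optional logical matrix of entries to hold out (treated as
#'   missing during fitting; used by cross-validation)
#' @return object of class `admixture_fit`: `Q`, `F`, `loglik` (trace),
#'   `logLik` (final), `K`, `converged`
#' @export
fit_admixture <- function(geno, K, seed = 1L, n_restarts = 5L, tol = 1e-6,
                          max_iter = 2000L, mask = NULL) {
  g <- if (inherits(geno, "genotype_matrix")) geno$g else as.matrix(geno)
  if (K < 1) stopf("input error: K must be >= 1")
  Gi <- g
  if (!is.null(mask)) Gi[mask] <- NA
  Gi[is.na(Gi)] <- -1L
  storage.mode(Gi) <- "integer"
  n <- nrow(Gi); m <- ncol(Gi)
  set.seed(seed)
  f0 <- colMeans(g, na.rm = TRUE) / 2
  f0[!is.finite(f0)] <- 0.5
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    Q0 <- rdirichlet(n, rep(1, K))
    # perturb the pooled frequencies so clusters can separate
    F0 <- pmin(pmax(matrix(rep(f0, each = K), K, m) +
                      matrix(runif(K * m, -0.1, 0.1), K, m), 1e-3), 1 - 1e-3)
    if (K == 1L) { Q0 <- matrix(1, n, 1); F0 <- matrix(f0, 1, m) }
    res <- em_admixture_cpp(Gi, Q0, F0, as.integer(max_iter), tol, 1e-6)
    ll <- tail(res$loglik, 1)
    if (is.null(best) || ll > best$logLik)
      best <- list(Q = res$Q, F = res$F, loglik = res$loglik, logLik = ll,
                   converged = res$converged)
    if (K == 1L) break
  }
  if (!best$converged)
    warnf("admixture EM did not converge in %d iterations (K = %d)", max_iter, K)
  structure(c(best, list(K = K, n = n, m = m)), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, n = %d, m = %d, logLik = %.1f (%s, %d EM iterations)\n",
              x$K, x$n, x$m, x$logLik,
              if (x$converged) "converged" else "NOT converged",
              length(x$loglik)))
  invisible(x)
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$logLik, df = object$n * (object$K - 1) + object$K * object$m,
            class = "logLik")
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' Ancestry bar plot of an admixture fit
#' @param x an `admixture_fit`
#' @param ... passed to `barplot`
#' @export
plot.admixture_fit <- function(x, ...) {
  graphics::barplot(t(x$Q), border = NA, space = 0,
                    col = grDevices::hcl.colors(x$K, "Dark 3"),
                    xlab = "individual", ylab = "ancestry proportion Q", ...)
  invisible(x)
}

#' Cross-validate the number of clusters K
#'
#' Entry-level masking: the non-missing genotype entries are split at random
#' into `folds` folds; each fold is held out in turn, the model is fitted on
#' the rest, and the held-out entries are scored by their binomial deviance
#' against the predicted allele dosage 2 * sum_k Q_ik F_kj. The selected K
#' minimises the mean cross-validation error.
#'
#' @param geno a `genotype_matrix`
#' @param k_range integer vector of K values
#' @param folds number of folds (>= 2)
#' @param seed RNG seed
#' @param n_restarts restarts per fit
#' @param tol,max_iter EM controls (a looser tolerance speeds CV up)
#' @return object of class `admixture_cv`: `cv_error` (K x fold matrix),
#'   `mean_error`, `selected_k`
#' @export
cross_validate_k <- function(geno, k_range = 1:4, folds = 5L, seed = 1L,
                             n_restarts = 2L, tol = 1e-4, max_iter = 500L) {
  if (folds < 2) stopf("input error: folds must be >= 2")
  g <- if (inherits(geno, "genotype_matrix")) geno$g else as.matrix(geno)
  obs <- which(!is.na(g))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs)))
  err <- matrix(NA_real_, length(k_range), folds,
                dimnames = list(paste0("K", k_range), NULL))
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    for (fd in seq_len(folds)) {
      mask <- matrix(FALSE, nrow(g), ncol(g))
      mask[obs[fold_of == fd]] <- TRUE
      fit <- fit_admixture(g, K, seed = derive_seed(seed, sprintf("cv%d_%d", K, fd)),
                           n_restarts = n_restarts, tol = tol,
                           max_iter = max_iter, mask = mask)
      pi <- fit$Q %*% fit$F
      pi <- pmin(pmax(pi, 1e-6), 1 - 1e-6)
      held <- obs[fold_of == fd]
      gh <- g[held]; ph <- pi[held]
      # mean binomial (2 trials) deviance of the held-out entries
      err[ki, fd] <- mean(-2 * (gh * log(ph) + (2 - gh) * log(1 - ph)))
    }
  }
  mean_err <- rowMeans(err)
  structure(list(cv_error = err, mean_error = mean_err,
                 k_range = k_range,
                 selected_k = k_range[which.min(mean_err)]),
            class = "admixture_cv")
}

#' @export
print.admixture_cv <- function(x, ...) {
  cat("admixture_cv: mean CV error by K\n")
  print(round(x$mean_error, 4))
  cat("selected K =", x$selected_k, "\n")
  invisible(x)
}

#' Assign individuals to clusters from Q
#'
#' Hard assignment by argmax over the Q row; exact ties go to the lower
#' cluster index and are flagged. The maximum Q is kept for reporting
#' per-cluster mean ancestry.
#'
#' @param Q n x K admixture proportion matrix (or an `admixture_fit`)
#' @return data.frame: `cluster`, `max_q`, `tie`
#' @export
assign_clusters <- function(Q) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  cl <- apply(Q, 1, which.max)
  mx <- Q[cbind(seq_len(nrow(Q)), cl)]
  tie <- apply(Q, 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1)
  data.frame(cluster = cl, max_q = mx, tie = tie)
}

#' Align estimated clusters to reference labels
#'
#' Admixture clusters are identified only up to permutation; this picks the
#' column permutation of Q minimising the mean absolute difference to a
#' reference Q (enumerates permutations; K small).
#'
#' @param Q estimated n x K matrix
#' @param Q_ref reference n x K matrix
#' @return Q with columns permuted to best match `Q_ref`
#' @export
align_q <- function(Q, Q_ref) {
  K <- ncol(Q)
  perms <- permutations_of(seq_len(K))
  errs <- vapply(perms, function(p) mean(abs(Q[, p, drop = FALSE] - Q_ref)),
                 numeric(1))
  Q[, perms[[which.min(errs)]], drop = FALSE]
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}
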