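#' Linear regression of the overlap index on ancestry
#'
#' OLS of IO on one cluster's admixture proportion Q (Q columns are
#' compositional, so one predictor is used at a time), with intercept.
#'
#' @param io overlap-index values, one per individual
#' @param q admixture proportion for the chosen cluster
#' @return a `regression_result` data.frame row: beta, se, statistic
#'   (t value), p, r_squared, aic, n
#' @export
regress_io_on_q <- function(io, q) {
  if (length(io) != length(q) || anyNA(io) || anyNA(q))
    stopf("input error: aligned, complete vectors required")
  if (length(io) < 3) stopf("input error: n must be >= 3")
  if (sd(q) == 0) stopf("input error: constant predictor")
  fit <- lm(io ~ q)
  s <- summary(fit)
  regression_result("linear", "io", beta = s$coefficients["q", 1],
                    se = s$coefficients["q", 2],
                    statistic = s$coefficients["q", 3],
                    p = s$coefficients["q", 4],
                    r_squared = s$r.squared, aic = AIC(fit),
                    n = length(io), fit = fit)
}

#' Logistic regression of migrant status on ancestry
#'
#' Maximum-likelihood logistic fit of the 0/1 migrant indicator on one
#' cluster's Q; the coefficient is on the log-odds scale. Perfect separation
#' is flagged rather than silently diverging. McFadden's pseudo-R^2 is
#' reported.
#'
#' @param status 0/1 migrant indicator
#' @param q admixture proportion
#' @return a `regression_result` row (statistic = z value)
#' @export
regress_migrant_on_q <- function(status, q) {
  if (length(unique(status)) < 2)
    stopf("input error: both classes must be present")
  if (sd(q) == 0) stopf("input error: constant predictor")
  fit <- suppressWarnings(glm(status ~ q, family = binomial()))
  sep <- !isTRUE(fit$converged) || anyNA(coef(fit)) ||
    any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (sep) warnf("possible complete separation; estimates unreliable")
  s <- summary(fit)
  null_ll <- logLik(glm(status ~ 1, family = binomial()))
  mcfadden <- 1 - as.numeric(logLik(fit)) / as.numeric(null_ll)
  r <- regression_result("logistic", "nsd_class",
                         beta = s$coefficients["q", 1],
                         se = s$coefficients["q", 2],
                         statistic = s$coefficients["q", 3],
                         p = s$coefficients["q", 4],
                         r_squared = mcfadden, aic = AIC(fit),
                         n = length(status), fit = fit)
  attr(r, "separation") <- sep
  r
}

#' Regression of migration on ancestry with an ecotype random intercept
#'
#' Linear (ML, not REML, so AICs compare across models) or logistic
#' (adaptive Gauss--Hermite quadrature, 15 nodes) mixed model with ecotype
#' as a random intercept. A variance estimate at the zero boundary is
#' reported as 0 with a flag.
#'
#' @param response IO (linear) or 0/1 status (logistic)
#' @param q admixture proportion
#' @param ecotype grouping factor (>= 2 levels)
#' @param family `"linear"` or `"logistic"`
#' @return a `regression_result` row with `ranef_var` and `boundary` flag
#' @export
regress_with_ecotype <- function(response, q, ecotype,
                                 family = c("linear", "logistic")) {
  family <- match.arg(family)
  ecotype <- as.factor(ecotype)
  if (nlevels(ecotype) < 2) stopf("input error: >= 2 ecotypes required")
  dat <- data.frame(y = response, q = q, ecotype = ecotype)
  if (family == "linear") {
    fit <- lme4::lmer(y ~ q + (1 | ecotype), data = dat, REML = FALSE)
    s <- summary(fit)$coefficients
    beta <- s["q", "Estimate"]; se <- s["q", "Std. Error"]
    stat <- s["q", "t value"]
    p <- 2 * pnorm(-abs(stat))
  } else {
    fit <- suppressMessages(
      lme4::glmer(y ~ q + (1 | ecotype), data = dat, family = binomial(),
                  nAGQ = 15))
    s <- summary(fit)$coefficients
    beta <- s["q", "Estimate"]; se <- s["q", "Std. Error"]
    stat <- s["q", "z value"]; p <- s["q", "Pr(>|z|)"]
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- vc$vcov[vc$grp == "ecotype"][1]
  boundary <- rv < 1e-8
  r <- regression_result(paste0("mixed-", family), "response", beta = beta,
                         se = se, statistic = stat, p = p,
                         r_squared = NA_real_, aic = AIC(fit),
                         n = length(response), fit = fit)
  r$ranef_var <- if (boundary) 0 else rv
  r$boundary <- boundary
  r
}

regression_result <- function(model, response, beta, se, statistic, p,
                              r_squared, aic, n, fit = NULL) {
  out <- data.frame(model = model, response = response, beta = beta, se = se,
                    statistic = statistic, p = p, r_squared = r_squared,
                    aic = aic, n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("regression_result", "data.frame")
  out
}

#' @export
print.regression_result <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Group comparisons of a migration metric across ecotypes
#'
#' Kruskal--Wallis across all groups plus pairwise two-sided Wilcoxon
#' rank-sum tests (exact when both groups have n < 20, normal approximation
#' with tie correction otherwise). Pairwise p-values are raw (no multiplicity
#' correction) unless `p_adjust` is set.
#'
#' @param values metric values (e.g. IO or migration distance)
#' @param groups ecotype labels
#' @param p_adjust optional method for [stats::p.adjust()]
#' @return list: `kruskal_p`, `pairwise_p` (matrix), `group_means`
#' @export
ecotype_group_tests <- function(values, groups, p_adjust = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stopf("input error: >= 2 groups required")
  if (any(table(groups) < 2)) stopf("input error: each group needs n >= 2")
  kp <- kruskal.test(values, groups)$p.value
  lv <- levels(groups)
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    xi <- values[groups == lv[i]]; xj <- values[groups == lv[j]]
    exact <- length(xi) < 20 && length(xj) < 20
    pw[i, j] <- pw[j, i] <-
      suppressWarnings(wilcox.test(xi, xj, exact = exact, correct = TRUE)$p.value)
  }
  if (!is.null(p_adjust)) {
    up <- pw[upper.tri(pw)]
    pw[upper.tri(pw)] <- p.adjust(up, method = p_adjust)
    pw[lower.tri(pw)] <- t(pw)[lower.tri(pw)]
  }
  list(kruskal_p = kp, pairwise_p = pw,
       group_means = tapply(values, groups, mean))
}
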