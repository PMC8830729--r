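#' @useDynLib migragen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rbinom runif rnorm rgamma dnorm coef cor
#'   kruskal.test lm glm binomial logLik median optimize pchisq qchisq
#'   pnorm qnorm quantile sd setNames var wilcox.test AIC resid predict
#'   complete.cases na.omit plogis p.adjust rbinom fitted ave
#' @importFrom utils read.csv write.csv read.delim head tail write.table
#' @importFrom tools md5sum
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Stages of the pipeline draw from independent streams so that rerunning one
#' stage does not perturb another. The sub-seed is a deterministic hash of the
#' master seed and the label, kept below 2^31.
#'
#' @param seed master integer seed
#' @param label character stage label
#' @return an integer seed
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h * 2654435761) %% 2147483647)
}

# Dirichlet draws via gamma normalisation
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Convert a calendar date to a numeric day of year
#'
#' Day 1 is 1 January; leap years follow the calendar, so 29 February is
#' day 60 and 10 April of a non-leap year is day 100.
#'
#' @param date a `Date`, date-time, or string coercible to `Date`
#' @return integer day-of-year index (1--366)
#' @export
#' @examples
#' date_to_numeric("2017-04-10")  # 100
date_to_numeric <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (any(is.na(d))) stopf("invalid date: %s", paste(date[is.na(d)], collapse = ", "))
  as.POSIXlt(d)$yday + 1L
}
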