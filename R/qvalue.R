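#' Estimate the proportion of true null hypotheses
#'
#' Storey's pi0 estimator. For a single tuning value \code{lambda}, the
#' estimate is \code{#\{p > lambda\} / (m * (1 - lambda))}: p-values above
#' \code{lambda} are treated as coming (mostly) from the uniform null
#' component. The \code{"smoother"} method evaluates this over a grid of
#' lambda values and extrapolates a cubic smoothing spline to the largest
#' lambda, damping the bias/variance trade-off of any single choice. The
#' result is clamped to (0, 1] (floor \code{1/m}).
#'
#' Heavily discrete p-values (e.g. from unfuzzed rank or permutation tests)
#' make the empirical tail \code{#\{p > lambda\}} a poor estimate of the null
#' proportion; the estimate is still returned as-is, since that error is part
#' of what makes discrete tests conservative in q-value pipelines.
#'
#' @param p numeric vector of p-values.
#' @param method \code{"smoother"} (default) or \code{"fixed"} (single
#'   lambda).
#' @param lambda tuning grid in (0, 1); a scalar for \code{"fixed"} (default
#'   0.5), a grid for \code{"smoother"} (default \code{seq(0.05, 0.95, 0.05)}).
#' @return a single pi0 estimate in (0, 1], with the method recorded in the
#'   \code{"pi0_method"} attribute.
#' @examples
#' estimatePi0(runif(1e4), method = "fixed", lambda = 0.5)  # ~1
#' @export
estimatePi0 <- function(p, method = c("smoother", "fixed"), lambda = NULL) {
  method <- match.arg(method)
  .checkPValues(p)
  m <- length(p)
  if (is.null(lambda))
    lambda <- if (method == "fixed") 0.5 else seq(0.05, 0.95, by = 0.05)
  if (any(lambda <= 0 | lambda >= 1))
    fpConfigError("lambda values must lie strictly inside (0, 1)")
  piHat <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  pi0 <- if (method == "fixed") {
    if (length(lambda) != 1L)
      fpConfigError("method 'fixed' takes a single lambda")
    piHat
  } else if (length(lambda) < 4L) {
    piHat[length(piHat)]
  } else {
    fit <- stats::smooth.spline(lambda, piHat, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }
  pi0 <- min(1, max(pi0, 1 / m))
  attr(pi0, "pi0_method") <- method
  pi0
}

#' Convert p-values to q-values
#'
#' Storey's tail-area q-values by the step-up construction: with order
#' statistics \code{p(1) <= ... <= p(m)},
#' \code{q(i) = min_\{t >= i\} pi0 * m * p(t) / t}, mapped back to the input
#' order and capped at 1. Tied p-values receive identical q-values, and
#' q-values are non-decreasing in p. With \code{pi0 = 1} this is exactly the
#' Benjamini-Hochberg adjusted p-value.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0 proportion of true nulls in (0, 1]; estimated via
#'   \code{\link{estimatePi0}} when missing.
#' @param ... passed to \code{\link{estimatePi0}} when \code{pi0} is missing.
#' @return numeric vector of q-values with attributes \code{"pi0"} and
#'   \code{"pi0_method"}.
#' @examples
#' pValuesToQValues(c(0.01, 0.02, 0.90, 0.95), pi0 = 1)  # 0.04 0.04 0.95 0.95
#' @export
pValuesToQValues <- function(p, pi0 = NULL, ...) {
  .checkPValues(p)
  m <- length(p)
  pi0Method <- "supplied"
  if (is.null(pi0)) {
    pi0 <- estimatePi0(p, ...)
    pi0Method <- attr(pi0, "pi0_method")
  }
  if (length(pi0) != 1L || is.na(pi0) || pi0 <= 0 || pi0 > 1)
    fpConfigError("pi0 must be a single value in (0, 1]")
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(as.numeric(pi0) * m * p[o] / seq.int(m, 1L)))
  q <- q[order(o)]
  names(q) <- names(p)
  attr(q, "pi0") <- as.numeric(pi0)
  attr(q, "pi0_method") <- pi0Method
  q
}

#' Count discoveries at an FDR threshold
#'
#' Number of variables with q-value at or below \code{alpha}; rejecting these
#' controls the FDR at \code{alpha} when the null p-values are uniform.
#'
#' @param q numeric vector of q-values (or a \linkS4class{FuzzyPermResult}).
#' @param alpha FDR level(s) in (0, 1).
#' @return integer vector of counts, one per \code{alpha}.
#' @export
countDiscoveries <- function(q, alpha = 0.05) {
  if (is(q, "FuzzyPermResult")) q <- qvalues(q)
  .checkPValues(q)
  if (any(alpha <= 0 | alpha >= 1))
    fpConfigError("alpha must lie strictly inside (0, 1)")
  vapply(alpha, function(a) sum(q <= a), integer(1))
}
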