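#' Add fuzzy terms to p-values
#'
#' Adds \code{epsilon * u} to each p-value, where \code{u} is a uniform(0,1)
#' draw. The fuzz term is what turns the discrete permutation p-value into a
#' randomized p-value: ties between p-values are broken almost surely, while
#' the ranking of p-values whose gap exceeds \code{epsilon} is untouched.
#' Fuzzified values may exceed 1 by at most \code{epsilon}; they are used only
#' for comparisons and are deliberately not clipped (clipping would reintroduce
#' ties at 1).
#'
#' The default \code{epsilon = 1e-12} sits comfortably between double-precision
#' resolution (~1e-16) and the gaps between distinct p-values in practice, so
#' it breaks exact ties without ever reordering distinct values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param epsilon positive fuzz scale (default \code{1e-12}).
#' @param u optional vector of uniform(0,1) draws, one per p-value; drawn
#'   internally when missing. Supplying \code{u} makes the operation
#'   deterministic (used for worked examples and cross-checks).
#' @return numeric vector \code{p + epsilon * u}.
#' @examples
#' fuzzify(0.744222017, epsilon = 1e-6, u = 0.154)  # 0.744222171
#' @export
fuzzify <- function(p, epsilon = 1e-12, u = NULL) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0)
    fpConfigError("epsilon must be a single positive number")
  .checkPValues(p)
  if (is.null(u)) u <- runif(length(p))
  if (length(u) != length(p))
    fpInputError("length of uniform draws must match length of p-values")
  p + epsilon * u
}

#' Permutation p-value by fractional tie counting
#'
#' Equivalent single-draw form of the fuzzy comparison: given, for one
#' variable, the number of permutations whose p-value falls strictly below the
#' observed one and the number tying it exactly, the fuzzy count of "at most
#' as extreme" permutations is \code{strictLess} plus a discrete-uniform number
#' of the ties. Under the randomized construction the ties beaten are
#' Binomial(\code{ties}, U) with U uniform(0,1), whose marginal is
#' discrete-uniform on \code{0:ties}; a single draw
#' \code{floor(u * (ties + 1))} therefore reproduces the same distribution of
#' the permutation p-value without per-permutation fuzz terms.
#'
#' @param strictLess number of permutations with p-value strictly below the
#'   observed p-value.
#' @param ties number of permutations tying the observed p-value exactly.
#' @param k total number of permutations.
#' @param u a uniform(0,1) draw; drawn internally when missing.
#' @return the permutation p-value \code{(strictLess + floor(u*(ties+1))) / k}.
#' @examples
#' fractionalCountPValue(3, 0, k = 10, u = 0.99)  # no ties: exactly 3/10
#' @export
fractionalCountPValue <- function(strictLess, ties, k, u = NULL) {
  if (length(k) != 1L || k < 1L) fpConfigError("k must be a positive integer")
  if (length(strictLess) != length(ties))
    fpInputError("strictLess and ties must have equal length")
  if (any(strictLess < 0) || any(ties < 0) || any(strictLess + ties > k))
    fpInputError("need 0 <= strictLess, 0 <= ties, strictLess + ties <= k")
  if (is.null(u)) u <- runif(length(strictLess))
  u <- pmin(u, 1 - .Machine$double.eps)   # guard u == 1
  (strictLess + floor(u * (ties + 1))) / k
}
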