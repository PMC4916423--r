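#' Generate case/control label permutations
#'
#' Produces permuted group assignments preserving the group sizes. In
#' \code{"random"} mode, \code{k} assignments are drawn independently and
#' uniformly (with replacement) from the \code{choose(n, n1)} possible case
#' sets. In \code{"exhaustive"} mode every distinct assignment is returned
#' exactly once -- including the observed one, the usual exact-permutation
#' convention -- and \code{k} is implied by \code{choose(n, n1)}, which must
#' not exceed \code{exhaustiveCap}.
#'
#' @param labels observed group labels (see \code{\link{twoSamplePValues}}).
#' @param k number of permutations (random mode; ignored in exhaustive mode).
#' @param mode \code{"random"} or \code{"exhaustive"}.
#' @param seed optional integer seed.
#' @param exhaustiveCap refuse exhaustive enumeration beyond this many
#'   assignments.
#' @return integer matrix with one row per permutation and one column per
#'   sample, entries 0/1 (1 = case).
#' @examples
#' generatePermutations(c(1, 1, 0, 0), mode = "exhaustive")  # all 6
#' @export
generatePermutations <- function(labels, k = 1000L,
                                 mode = c("random", "exhaustive"),
                                 seed = NULL, exhaustiveCap = 20000L) {
  mode <- match.arg(mode)
  if (!is.numeric(labels) && !is.logical(labels) && !is.factor(labels) &&
      !is.character(labels))
    fpInputError("labels must be a vector")
  lab <- .checkLabels(labels, matrix(0, 1L, length(labels)))
  idx <- .permCaseIndex(lab, k, mode, seed, exhaustiveCap)
  n <- length(lab)
  out <- matrix(0L, nrow = ncol(idx), ncol = n)
  out[cbind(rep(seq_len(ncol(idx)), each = nrow(idx)), as.vector(idx))] <- 1L
  out
}

## case-index matrix (n1 x k), one column per permutation
.permCaseIndex <- function(lab, k, mode, seed, exhaustiveCap) {
  n <- length(lab); n1 <- sum(lab == 1L)
  if (mode == "exhaustive") {
    nc <- choose(n, n1)
    if (nc > exhaustiveCap)
      fpConfigError(sprintf(
        "exhaustive mode needs choose(%d, %d) = %.0f assignments, above the cap of %d",
        n, n1, nc, exhaustiveCap))
    utils::combn(n, n1)
  } else {
    if (length(k) != 1L || is.na(k) || k < 1L)
      fpConfigError("k must be a positive integer")
    withSeed(seed, matrix(vapply(seq_len(k), function(i) sample.int(n, n1),
                                 integer(n1)), nrow = n1))
  }
}

## Core counting pass shared by the fuzzy and standard permutation methods.
## Both are accumulated from the same permutation stream so that the fuzzy
## p-value never exceeds the standard one on a paired run.
##
## The fuzzy comparison p*_b + eps*u_b <= p_obs + eps*u0 is evaluated in its
## small-eps limit: with eps below the smallest nonzero gap between distinct
## p-values (the default 1e-12 in double precision), the event is exactly
## [p*_b < p_obs] or [p*_b = p_obs and u_b <= u0]. The engine computes that
## event directly, detecting ties with a relative tolerance (1e-8) so that
## assignments that are mathematically tied -- e.g. the label swap, or equal
## value configurations in tied data -- are recognised as ties even when the
## two floating-point evaluations differ in the last bits. This keeps the
## tie-as-extreme convention of the standard count, and the fuzzy tie-break,
## exact instead of fragile.
##
## RNG order under `seed` (fixed, documented): (1) the permutation stream,
## (2) the m observed-p fuzz draws, (3) per-permutation fuzz draws in
## permutation order (randomized mode) or m tie-allocation draws after the
## counting pass (fractional mode). Standard-only consumers use (1) only,
## so fuzzy and standard runs with the same seed share permutations.
.permutationEngine <- function(x, labels, test, k = 1000L,
                               mode = c("random", "exhaustive"),
                               epsilon = 1e-12, seed = NULL,
                               tieMode = c("randomized", "fractional"),
                               varEqual = TRUE, enumCap = 20000L,
                               exhaustiveCap = 20000L,
                               uObs = NULL, uPerm = NULL) {
  mode <- match.arg(mode); tieMode <- match.arg(tieMode)
  .checkMatrix(x)
  labels <- .checkLabels(labels, x, minPerGroup = if (test == "t") 2L else 1L)
  if (mode == "random" && (length(k) != 1L || is.na(k) || k < 1L))
    fpConfigError("k must be a positive integer")
  if (epsilon <= 0) fpConfigError("epsilon must be positive")
  m <- nrow(x)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  st <- .testState(x, n1, n0, test, varEqual = varEqual, enumCap = enumCap)
  pObs <- drop(.testPValues(st, .labelIndicator(labels), test))

  withSeed(seed, {
    caseIdx <- .permCaseIndex(labels, k, mode, seed = NULL, exhaustiveCap)
    k <- ncol(caseIdx)
    if (is.null(uObs)) uObs <- if (tieMode == "randomized") runif(m)
    if (!is.null(uObs) && length(uObs) != m)
      fpInputError("uObs must have one draw per variable")

    tol <- 1e-8 * pmax(pObs, 1e-12)        # relative tie tolerance
    countF  <- numeric(m)   # fuzzy:    strict-less plus fuzz-won ties
    countLE <- numeric(m)   # standard: p*_b <= p_obs (ties extreme)
    countLT <- numeric(m)   # strict, for fractional tie allocation
    chunk <- max(1L, min(k, as.integer(2^22 %/% m) + 1L))
    done <- 0L
    while (done < k) {
      b <- seq.int(done + 1L, min(k, done + chunk))
      P <- matrix(0, nrow = n1 + n0, ncol = length(b))
      P[cbind(as.vector(caseIdx[, b, drop = FALSE]),
              rep(seq_along(b), each = n1))] <- 1
      pStar <- .testPValues(st, P, test)
      lt  <- pStar < pObs - tol
      tie <- abs(pStar - pObs) <= tol
      nLT <- rowSums(lt)
      countLE <- countLE + nLT + rowSums(tie)
      countLT <- countLT + nLT
      if (tieMode == "randomized") {
        U <- if (is.null(uPerm)) matrix(runif(length(pStar)), nrow = m)
             else uPerm[, b, drop = FALSE]
        countF <- countF + nLT + rowSums(tie & (U <= uObs))
      }
      done <- b[length(b)]
    }
    if (tieMode == "fractional")
      countF <- fractionalCountPValue(countLT, countLE - countLT, k) * k

    list(pObs = pObs, countFuzzy = countF, countStd = countLE, k = k,
         n1 = n1, n0 = n0, epsilon = epsilon, tieMode = tieMode)
  })
}

.countToP <- function(count, k, addOne) {
  if (addOne) (count + 1) / (k + 1) else count / k
}

#' Fuzzy permutation p-values
#'
#' The randomized-p-value permutation test: per-variable two-sample test
#' p-values are fuzzified (observed value once, each permuted value with a
#' fresh independent draw) and the permutation p-value is the proportion of
#' the \code{k} permuted fuzzified p-values at or below the observed fuzzified
#' p-value. The fuzz breaks the ties that make small-sample permutation
#' p-values discrete, so under the null the result is uniform(0,1) and the
#' downstream q-values are well calibrated.
#'
#' @inheritParams twoSamplePValues
#' @inheritParams generatePermutations
#' @param epsilon fuzz scale; see \code{\link{fuzzify}}. The comparisons are
#'   evaluated in the small-epsilon limit (valid whenever \code{epsilon} is
#'   below the smallest nonzero gap between distinct p-values, as the default
#'   \code{1e-12} is in practice): strict orderings are decided by the
#'   p-values themselves and exact ties are broken by the uniform draws,
#'   which makes the tie-break robust to floating-point rounding.
#' @param tieMode \code{"randomized"} (per-permutation fuzz draws, the
#'   reference construction) or \code{"fractional"} (tie counts allocated by a
#'   single discrete-uniform draw per variable; distributionally equivalent,
#'   see \code{\link{fractionalCountPValue}}).
#' @param addOne if \code{TRUE} report \code{(count+1)/(k+1)} instead of the
#'   default \code{count/k} (which can be exactly 0).
#' @param uObs,uPerm optional explicit uniform draws (length-m vector; m x k
#'   matrix) for the observed and permuted fuzz terms; drawn internally when
#'   missing. Randomized mode only.
#' @return named numeric p-value vector with a \code{"method"} attribute.
#' @seealso \code{\link{standardPermutationPValues}} for the unfuzzed
#'   comparator, \code{\link{fuzzyPermFdr}} for the full pipeline to q-values.
#' @export
fuzzyPermutationPValues <- function(x, labels, test = c("t", "wilcoxon"),
                                    k = 1000L, mode = c("random", "exhaustive"),
                                    epsilon = 1e-12, seed = NULL,
                                    tieMode = c("randomized", "fractional"),
                                    addOne = FALSE, varEqual = TRUE,
                                    enumCap = 20000L, exhaustiveCap = 20000L,
                                    uObs = NULL, uPerm = NULL) {
  test <- match.arg(test)
  eng <- .permutationEngine(x, labels, test, k = k, mode = mode,
                            epsilon = epsilon, seed = seed, tieMode = tieMode,
                            varEqual = varEqual, enumCap = enumCap,
                            exhaustiveCap = exhaustiveCap,
                            uObs = uObs, uPerm = uPerm)
  p <- .countToP(eng$countFuzzy, eng$k, addOne)
  names(p) <- rownames(x)
  attr(p, "method") <- paste0("fuzzy_perm_", test)
  attr(p, "k") <- eng$k
  p
}

#' Standard permutation p-values
#'
#' The classical permutation comparator: proportion of permutations whose test
#' p-value is at most the observed p-value, ties counted as extreme (the
#' conservative convention). With few subjects this p-value is heavily
#' discrete, which is precisely the behaviour the fuzzy method removes.
#'
#' @inheritParams fuzzyPermutationPValues
#' @return named numeric p-value vector with a \code{"method"} attribute.
#' @export
standardPermutationPValues <- function(x, labels, test = c("t", "wilcoxon"),
                                       k = 1000L,
                                       mode = c("random", "exhaustive"),
                                       seed = NULL, addOne = FALSE,
                                       varEqual = TRUE, enumCap = 20000L,
                                       exhaustiveCap = 20000L) {
  test <- match.arg(test)
  eng <- .permutationEngine(x, labels, test, k = k, mode = mode,
                            seed = seed, varEqual = varEqual,
                            enumCap = enumCap, exhaustiveCap = exhaustiveCap)
  p <- .countToP(eng$countStd, eng$k, addOne)
  names(p) <- rownames(x)
  attr(p, "method") <- paste0("std_perm_", test)
  attr(p, "k") <- eng$k
  p
}
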