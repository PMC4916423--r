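#' Fuzzy permutation FDR analysis
#'
#' End-to-end pipeline for one dataset: per-variable two-sample test, optional
#' (fuzzy or standard) permutation p-values, Storey pi0 estimate and q-values.
#' This is the screening workflow for large-p-small-n case/control studies:
#' with \code{method = "fuzzy"} the permutation p-values are randomized via
#' tiny fuzz terms, making them uniform(0,1) under the null even at a handful
#' of subjects, so q-value FDR control is calibrated rather than conservative.
#'
#' @inheritParams fuzzyPermutationPValues
#' @param method \code{"fuzzy"} (fuzzy permutation, the default),
#'   \code{"standard"} (tie-conservative permutation comparator) or
#'   \code{"none"} (q-values straight from the raw test p-values).
#' @param pi0Method passed to \code{\link{estimatePi0}}.
#' @param ... passed to the matrix method.
#' @return a \linkS4class{FuzzyPermResult}.
#' @examples
#' x <- matrix(rnorm(200 * 8), nrow = 200,
#'             dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
#' res <- fuzzyPermFdr(x, rep(c(1, 0), each = 4), test = "t", k = 200, seed = 7)
#' res
#' head(as.data.frame(res))
#' @export
setGeneric("fuzzyPermFdr",
  function(x, labels, test = c("t", "wilcoxon"),
           method = c("fuzzy", "standard", "none"), k = 1000L,
           mode = c("random", "exhaustive"), epsilon = 1e-12, seed = NULL,
           ...) standardGeneric("fuzzyPermFdr"),
  signature = "x")

#' @rdname fuzzyPermFdr
#' @export
setMethod("fuzzyPermFdr", "matrix",
  function(x, labels, test = c("t", "wilcoxon"),
           method = c("fuzzy", "standard", "none"), k = 1000L,
           mode = c("random", "exhaustive"), epsilon = 1e-12, seed = NULL,
           tieMode = c("randomized", "fractional"), addOne = FALSE,
           varEqual = TRUE, enumCap = 20000L, exhaustiveCap = 20000L,
           pi0Method = c("smoother", "fixed")) {
    test <- match.arg(test); method <- match.arg(method)
    mode <- match.arg(mode); pi0Method <- match.arg(pi0Method)
    .checkMatrix(x)
    labels <- .checkLabels(labels, x, minPerGroup = if (test == "t") 2L else 1L)

    if (method == "none") {
      rawP <- suppressWarnings(
        as.numeric(twoSamplePValues(x, labels, test = test,
                                    varEqual = varEqual, enumCap = enumCap)))
      permP <- numeric(0)
      workP <- rawP
      kUsed <- 0L
    } else {
      eng <- .permutationEngine(x, labels, test, k = k, mode = mode,
                                epsilon = epsilon, seed = seed,
                                tieMode = tieMode, varEqual = varEqual,
                                enumCap = enumCap,
                                exhaustiveCap = exhaustiveCap)
      rawP <- as.numeric(eng$pObs)
      count <- if (method == "fuzzy") eng$countFuzzy else eng$countStd
      permP <- as.numeric(.countToP(count, eng$k, addOne))
      workP <- permP
      kUsed <- as.integer(eng$k)
    }
    q <- pValuesToQValues(workP, method = pi0Method)
    ids <- rownames(x)
    if (is.null(ids)) ids <- sprintf("V%d", seq_len(nrow(x)))
    new("FuzzyPermResult", variableIds = ids, rawP = rawP, permP = permP,
        qvalues = as.numeric(q), pi0 = attr(q, "pi0"),
        pi0Method = attr(q, "pi0_method"), test = test, method = method,
        k = kUsed,
        epsilon = if (method == "fuzzy") epsilon else NA_real_,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })

#' @rdname fuzzyPermFdr
#' @export
setMethod("fuzzyPermFdr", "SummarizedExperiment",
  function(x, labels = "group", test = c("t", "wilcoxon"),
           method = c("fuzzy", "standard", "none"), k = 1000L,
           mode = c("random", "exhaustive"), epsilon = 1e-12, seed = NULL,
           ...) {
    if (missing(labels)) labels <- "group"
    fuzzyPermFdr(.seMatrix(x), .seLabels(x, labels), test = match.arg(test),
                 method = match.arg(method), k = k, mode = match.arg(mode),
                 epsilon = epsilon, seed = seed, ...)
  })
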