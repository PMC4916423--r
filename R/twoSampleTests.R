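## Vectorized two-sample tests across all variables of a matrix, evaluated at
## one or many case/control assignments simultaneously. Each assignment is a
## column of an n x B indicator matrix P (1 = case), so group sums for all B
## assignments come from a single matrix product -- this is what makes k
## permutations of m variables affordable.

## --- Student t -------------------------------------------------------------

.tTestState <- function(x, n1, n0, varEqual = TRUE) {
  x2 <- x * x
  S  <- rowSums(x)
  SS <- rowSums(x2)
  n  <- n1 + n0
  ## rows with (numerically) zero total variance: every permutation gives the
  ## same degenerate 0/0 statistic; define p = 1 (group means necessarily equal)
  totSS <- SS - S * S / n
  constRow <- totSS <= 1e-12 * pmax(SS, .Machine$double.xmin)
  list(x = x, x2 = x2, S = S, SS = SS, n1 = n1, n0 = n0, n = n,
       varEqual = varEqual, constRow = constRow)
}

## P: n x B 0/1 indicator matrix of case membership -> m x B two-sided p-values
.tTestPValues <- function(st, P) {
  s1  <- st$x %*% P
  ss1 <- st$x2 %*% P
  n1 <- st$n1; n0 <- st$n0; n <- st$n
  m1 <- s1 / n1
  m0 <- (st$S - s1) / n0
  d  <- m1 - m0
  v1 <- pmax(ss1 - s1 * s1 / n1, 0)
  v0 <- pmax((st$SS - ss1) - (st$S - s1)^2 / n0, 0)
  if (st$varEqual) {
    sp2 <- (v1 + v0) / (n - 2)
    se  <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df  <- n - 2
  } else {
    w1 <- v1 / (n1 - 1) / n1
    w0 <- v0 / (n0 - 1) / n0
    se <- sqrt(w1 + w0)
    df <- (w1 + w0)^2 / (w1^2 / (n1 - 1) + w0^2 / (n0 - 1))
    df[!is.finite(df)] <- n - 2
  }
  tstat <- d / se
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  ## se == 0: p = 0 if the means actually separate (|t| = Inf), else 1
  degen <- !is.finite(tstat)
  if (any(degen)) p[degen] <- ifelse(abs(d[degen]) > 0, 0, 1)
  if (any(st$constRow)) p[st$constRow, ] <- 1
  p
}

## --- Wilcoxon rank sum -----------------------------------------------------

## Exact two-sided p as twice the smaller tail (point included), capped at 1.
## Untied rows share the closed-form rank-sum null distribution; tied rows
## (mid-ranks) get their own exact distribution by enumerating all C(n, n1)
## case assignments, provided C(n, n1) <= enumCap; beyond the cap (or n > 25
## for untied rows) a tie-corrected normal approximation is used.
.wilcoxState <- function(x, n1, n0, enumCap = 20000L) {
  n <- n1 + n0
  R <- t(apply(x, 1L, rank, ties.method = "average"))
  tied <- apply(x, 1L, function(v) anyDuplicated(v) > 0L)
  st <- list(R = R, n1 = n1, n0 = n0, n = n, tied = tied)

  if (n <= 25L) {
    u <- 0:(n1 * n0)
    d <- dwilcox(u, n1, n0)
    lo <- cumsum(d)
    hi <- rev(cumsum(rev(d)))
    st$pTab <- pmin(1, 2 * pmin(lo, hi))   # indexed by U = W - n1(n1+1)/2
    st$minW <- n1 * (n1 + 1) / 2
  }

  tiedIdx <- which(tied)
  nComb <- choose(n, n1)
  if (length(tiedIdx) && nComb <= enumCap && n <= 25L) {
    combos <- utils::combn(n, n1)
    ## store each tied row's sorted doubled rank sums (integers; mid-ranks
    ## are multiples of 1/2) for exact tail counting via findInterval
    st$tieTab <- lapply(tiedIdx, function(j) {
      w2 <- as.integer(round(2 * colSums(matrix(R[j, combos], nrow = n1))))
      sort(w2)
    })
    names(st$tieTab) <- as.character(tiedIdx)
    st$nComb <- ncol(combos)
  }
  st
}

.wilcoxTailNormal <- function(W, Rrow, n1, n0, cc = 0) {
  n <- n1 + n0
  mu <- n1 * (n + 1) / 2
  sig2 <- n1 * n0 / (n * (n - 1)) * (sum(Rrow^2) - n * (n + 1)^2 / 4)
  if (sig2 <= 0) return(rep(1, length(W)))
  z <- (abs(W - mu) - cc) / sqrt(sig2)
  pmin(1, 2 * pnorm(z, lower.tail = FALSE))
}

.wilcoxPValues <- function(st, P) {
  W <- st$R %*% P
  p <- W                                  # same shape
  untied <- !st$tied
  if (!is.null(st$pTab)) {
    if (any(untied)) {
      u <- round(W[untied, , drop = FALSE] - st$minW)
      p[untied, ] <- st$pTab[u + 1]
    }
  } else if (any(untied)) {
    rk <- seq_len(st$n)
    for (j in which(untied))
      p[j, ] <- .wilcoxTailNormal(W[j, ], rk, st$n1, st$n0, cc = 0.5)
  }
  if (any(st$tied)) {
    for (j in which(st$tied)) {
      tab <- st$tieTab[[as.character(j)]]
      if (!is.null(tab)) {
        w2 <- as.integer(round(2 * W[j, ]))
        nle <- findInterval(w2, tab)
        nge <- st$nComb - findInterval(w2 - 1L, tab)
        p[j, ] <- pmin(1, 2 * pmin(nle, nge) / st$nComb)
      } else {
        p[j, ] <- .wilcoxTailNormal(W[j, ], st$R[j, ], st$n1, st$n0, cc = 0)
      }
    }
  }
  p
}

## --- shared dispatch -------------------------------------------------------

.testState <- function(x, n1, n0, test, varEqual = TRUE, enumCap = 20000L) {
  switch(test,
    t        = .tTestState(x, n1, n0, varEqual),
    wilcoxon = .wilcoxState(x, n1, n0, enumCap),
    fpConfigError(sprintf("unknown test '%s' (use 't' or 'wilcoxon')", test))
  )
}

.testPValues <- function(st, P, test) {
  switch(test, t = .tTestPValues(st, P), wilcoxon = .wilcoxPValues(st, P))
}

.labelIndicator <- function(labels) matrix(as.numeric(labels == 1L), ncol = 1L)

#' Two-sample p-values for every variable of a matrix
#'
#' Computes a two-sided p-value per variable (row) comparing cases against
#' controls, using either the classical pooled-variance Student t test
#' (\code{n1 + n0 - 2} degrees of freedom) or the Wilcoxon rank-sum test with
#' its exact small-sample null distribution.
#'
#' For the Wilcoxon test, rows without tied observations use the exact
#' closed-form rank-sum distribution whenever \code{n1 + n0 <= 25}; rows with
#' ties use mid-ranks and an exact null distribution enumerated over all
#' \code{choose(n, n1)} case assignments when that count is at most
#' \code{enumCap}, and a tie-corrected normal approximation otherwise. The
#' two-sided p-value is twice the smaller tail (the observed point included),
#' capped at 1.
#'
#' A variable with zero pooled variance and equal group means (in particular,
#' a constant variable) is assigned p = 1 under the t test, with a warning.
#'
#' @param x numeric matrix, variables in rows, samples in columns; or a
#'   \linkS4class{SummarizedExperiment} (first assay used).
#' @param labels group membership of the columns: a 0/1 vector (1 = case), a
#'   logical, or a two-level factor/character (levels \code{case}/\code{control}
#'   recognised by name). For a \code{SummarizedExperiment}, the name of a
#'   \code{colData} column (default \code{"group"}).
#' @param test \code{"t"} or \code{"wilcoxon"}.
#' @param varEqual for the t test: pooled variance (default \code{TRUE}) or
#'   Welch.
#' @param enumCap largest number of case assignments enumerated for exact
#'   tied-row Wilcoxon distributions.
#' @return named numeric vector of two-sided p-values, one per variable, with
#'   a \code{"method"} attribute (\code{"t_raw"} or \code{"wilcoxon_raw"}).
#' @examples
#' x <- matrix(rnorm(50), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
#' twoSamplePValues(x, rep(c(1, 0), each = 5), test = "wilcoxon")
#' @export
setGeneric("twoSamplePValues",
  function(x, labels, test = c("t", "wilcoxon"), varEqual = TRUE,
           enumCap = 20000L) standardGeneric("twoSamplePValues"),
  signature = "x")

#' @rdname twoSamplePValues
#' @export
setMethod("twoSamplePValues", "matrix",
  function(x, labels, test = c("t", "wilcoxon"), varEqual = TRUE,
           enumCap = 20000L) {
    test <- match.arg(test)
    .checkMatrix(x)
    labels <- .checkLabels(labels, x, minPerGroup = if (test == "t") 2L else 1L)
    st <- .testState(x, sum(labels == 1L), sum(labels == 0L), test,
                     varEqual = varEqual, enumCap = enumCap)
    p <- drop(.testPValues(st, .labelIndicator(labels), test))
    if (test == "t" && any(st$constRow))
      warning(sum(st$constRow),
              " variable(s) with zero pooled variance; p-value set to 1")
    names(p) <- rownames(x)
    attr(p, "method") <- paste0(test, "_raw")
    p
  })

#' @rdname twoSamplePValues
#' @export
setMethod("twoSamplePValues", "SummarizedExperiment",
  function(x, labels = "group", test = c("t", "wilcoxon"), varEqual = TRUE,
           enumCap = 20000L) {
    if (missing(labels)) labels <- "group"
    twoSamplePValues(.seMatrix(x), .seLabels(x, labels), test = match.arg(test),
                     varEqual = varEqual, enumCap = enumCap)
  })

.seMatrix <- function(se) {
  m <- SummarizedExperiment::assay(se, 1L)
  if (!is.matrix(m)) m <- as.matrix(m)
  m
}

.seLabels <- function(se, labels) {
  if (is.character(labels) && length(labels) == 1L) {
    cd <- SummarizedExperiment::colData(se)
    if (!labels %in% colnames(cd))
      fpInputError(sprintf("colData column '%s' not found", labels))
    cd[[labels]]
  } else labels
}
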