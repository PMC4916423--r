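## Classed conditions so callers (and the CLI) can distinguish bad data from
## bad configuration. Input errors exit 2 at the command line, config errors 3.

fpInputError <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("fp_input_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

fpConfigError <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("fp_config_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

## Run `expr` under a fixed RNG seed without clobbering the caller's stream.
## seed = NULL leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed per pipeline stage, so e.g. the permutation stream
## of a run is identical whether or not fuzz draws are later consumed.
deriveSeed <- function(seed, stage) {
  if (is.null(seed) || is.na(seed)) return(NULL)
  (as.integer(seed) * 48271L + stage * 9973L) %% 2147483562L
}

.checkMatrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    fpInputError("expression data must be a numeric matrix (variables x samples)")
  if (nrow(x) < 1L || ncol(x) < 2L)
    fpInputError("need at least 1 variable and 2 samples")
  if (!all(is.finite(x)))
    fpInputError("expression matrix contains non-finite values (NA/NaN/Inf)")
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    fpInputError(sprintf("duplicated variable identifier: '%s'",
                         rownames(x)[duplicated(rownames(x))][1L]))
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    fpInputError(sprintf("duplicated sample identifier: '%s'",
                         colnames(x)[duplicated(colnames(x))][1L]))
  invisible(x)
}

## Coerce group labels to a 0/1 integer vector (1 = case) and validate
## against the matrix. Accepts 0/1 numerics, logicals, or a two-level
## factor/character whose *second* sorted level is the case unless the
## levels are exactly case/control.
.checkLabels <- function(labels, x, minPerGroup = 1L) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L)
      fpInputError("group labels must have exactly two levels")
    caseLevel <- if (setequal(lv, c("case", "control"))) "case" else lv[2L]
    labels <- as.integer(as.character(labels) == caseLevel)
  } else if (is.logical(labels)) {
    labels <- as.integer(labels)
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L)))
      fpInputError("numeric group labels must be 0 (control) or 1 (case)")
  }
  if (length(labels) != ncol(x))
    fpInputError(sprintf("label length (%d) does not match number of samples (%d)",
                         length(labels), ncol(x)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < minPerGroup || n0 < minPerGroup)
    fpInputError(sprintf("each group needs at least %d samples (got n1=%d, n0=%d)",
                         minPerGroup, n1, n0))
  labels
}

.checkPValues <- function(p) {
  if (length(p) < 1L) fpInputError("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    fpInputError("p-values must lie in [0, 1] with no missing values")
  invisible(p)
}
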