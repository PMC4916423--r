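#' Read an expression matrix from delimited text
#'
#' Expects one variable per row: first column the variable identifier, header
#' row the sample identifiers. The delimiter is auto-detected between tab and
#' comma. Missing, non-numeric or non-finite cells and duplicated identifiers
#' are rejected with an error naming the offender.
#'
#' @param path file path (TSV or CSV).
#' @return numeric matrix with variable row names and sample column names.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) fpInputError(sprintf("input file not found: %s", path))
  df <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "auto", data.table = FALSE,
                      fill = FALSE, na.strings = c("NA", "")),
    error = function(e) fpInputError(sprintf("cannot parse '%s': %s", path,
                                             conditionMessage(e))))
  if (ncol(df) < 3L)
    fpInputError("matrix file needs an identifier column and >= 2 samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    fpInputError(sprintf("duplicated variable id: '%s'",
                         ids[duplicated(ids)][1L]))
  ## an all-missing column arrives as logical NA; treat it as numeric so the
  ## finite-value check can name the offending cell
  df[-1L] <- lapply(df[-1L], function(v) if (is.logical(v)) as.numeric(v) else v)
  num <- vapply(df[-1L], is.numeric, logical(1))
  if (!all(num))
    fpInputError(sprintf("non-numeric values in column '%s'",
                         colnames(df)[-1L][!num][1L]))
  x <- as.matrix(df[-1L])
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    fpInputError(sprintf("missing/non-finite value at variable '%s', sample '%s'",
                         ids[bad[1L]], colnames(x)[bad[2L]]))
  }
  rownames(x) <- ids
  .checkMatrix(x)
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}: variable ids in the first
#' column (\code{variable_id}), samples in the header.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(x, path) {
  .checkMatrix(x)
  df <- data.frame(variable_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read or build group labels for a set of samples
#'
#' Either from a delimited two-column file mapping \code{sample_id} to
#' \code{case}/\code{control}, or from an explicit vector of case sample
#' identifiers. Every sample of the matrix must be covered exactly once.
#'
#' @param sampleIds sample identifiers of the matrix columns.
#' @param path labels file (two columns: sample id, \code{case} or
#'   \code{control}; tab or comma separated, no header required).
#' @param cases character vector of case sample ids (alternative to
#'   \code{path}).
#' @return integer 0/1 vector aligned to \code{sampleIds} (1 = case).
#' @export
readGroupLabels <- function(sampleIds, path = NULL, cases = NULL) {
  if (is.null(path) == is.null(cases))
    fpConfigError("supply exactly one of a labels file or a vector of case ids")
  if (!is.null(cases)) {
    missing <- setdiff(cases, sampleIds)
    if (length(missing))
      fpInputError(sprintf("case id '%s' not among the samples", missing[1L]))
    return(as.integer(sampleIds %in% cases))
  }
  if (!file.exists(path)) fpInputError(sprintf("labels file not found: %s", path))
  df <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "auto", data.table = FALSE),
    error = function(e) fpInputError(sprintf("cannot parse labels file: %s",
                                             conditionMessage(e))))
  ## tolerate an optional header line
  if (nrow(df) && !df[1L, 2L] %in% c("case", "control")) df <- df[-1L, ]
  if (ncol(df) != 2L)
    fpInputError("labels file must have two columns: sample_id, case|control")
  if (!all(df[[2L]] %in% c("case", "control")))
    fpInputError("labels must be 'case' or 'control'")
  lab <- setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  missing <- setdiff(sampleIds, names(lab))
  if (length(missing))
    fpInputError(sprintf("no label for sample '%s'", missing[1L]))
  as.integer(lab[sampleIds] == "case")
}

#' Write a results table as TSV
#'
#' Columns \code{variable_id}, \code{raw_p}, \code{perm_p}, \code{q_value},
#' in the input variable order (ranking is left to the consumer).
#'
#' @param result a \linkS4class{FuzzyPermResult}.
#' @param path output path.
#' @export
writeResultTable <- function(result, path) {
  stopifnot(is(result, "FuzzyPermResult"))
  data.table::fwrite(as.data.frame(result), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Run the full file-to-file analysis pipeline
#'
#' Read an expression matrix and labels, compute (permutation) p-values and
#' q-values, and write the results table plus an optional plain-text
#' \code{key=value} metadata sidecar echoing the resolved configuration, the
#' pi0 estimate and discovery counts. The configuration is validated before
#' any data is read; all randomness flows from the single \code{seed}.
#'
#' @inheritParams fuzzyPermFdr
#' @param input path of the expression matrix (TSV/CSV).
#' @param output path of the results TSV.
#' @param labelsFile,cases sample labels; see \code{\link{readGroupLabels}}.
#' @param alphas FDR levels reported in the metadata.
#' @param metadataOut optional path of the metadata sidecar.
#' @return the \linkS4class{FuzzyPermResult}, invisibly.
#' @export
runPipeline <- function(input, output, labelsFile = NULL, cases = NULL,
                        test = c("t", "wilcoxon"),
                        method = c("fuzzy", "standard", "none"),
                        k = 1000L, mode = c("random", "exhaustive"),
                        epsilon = 1e-12, seed = NULL,
                        alphas = c(0.01, 0.05, 0.10, 0.20, 0.40),
                        addOne = FALSE, exhaustiveCap = 20000L,
                        metadataOut = NULL) {
  test <- match.arg(test); method <- match.arg(method)
  mode <- match.arg(mode)
  ## configuration checks before touching the data
  if (method != "none" && mode == "random" &&
      (length(k) != 1L || is.na(k) || k < 1L))
    fpConfigError("k must be a positive integer")
  if (epsilon <= 0) fpConfigError("epsilon must be positive")
  if (any(alphas <= 0 | alphas >= 1))
    fpConfigError("alpha levels must lie strictly inside (0, 1)")
  if (is.null(labelsFile) == is.null(cases))
    fpConfigError("supply exactly one of --labels or --cases")

  x <- readExpressionMatrix(input)
  lab <- readGroupLabels(colnames(x), path = labelsFile, cases = cases)
  res <- fuzzyPermFdr(x, lab, test = test, method = method, k = k,
                      mode = mode, epsilon = epsilon, seed = seed,
                      addOne = addOne, exhaustiveCap = exhaustiveCap)
  writeResultTable(res, output)
  if (!is.null(metadataOut)) {
    disc <- countDiscoveries(res, alphas)
    lines <- c(
      sprintf("input=%s", input), sprintf("m=%d", nrow(x)),
      sprintf("n1=%d", sum(lab == 1L)), sprintf("n0=%d", sum(lab == 0L)),
      sprintf("test=%s", test), sprintf("method=%s", method),
      sprintf("mode=%s", mode), sprintf("k=%d", res@k),
      sprintf("epsilon=%g", epsilon), sprintf("add_one=%s", addOne),
      sprintf("seed=%s", if (is.null(seed)) "NA" else seed),
      sprintf("pi0=%.10g", pi0Estimate(res)),
      sprintf("discoveries_q%.2f=%d", alphas, disc))
    writeLines(lines, metadataOut)
  }
  invisible(res)
}
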