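#' FuzzyPermResult: per-variable results of a permutation FDR analysis
#'
#' Container returned by \code{\link{fuzzyPermFdr}}: raw two-sample test
#' p-values, permutation-based p-values (fuzzy or standard; absent when the
#' raw p-values are used directly), Storey q-values and the pi0 estimate they
#' were scaled by, together with the run configuration.
#'
#' @slot variableIds character, variable identifiers (input order).
#' @slot rawP raw two-sided test p-values.
#' @slot permP permutation p-values (length 0 when \code{method = "none"}).
#' @slot qvalues q-values of the working p-values.
#' @slot pi0 estimated proportion of true nulls.
#' @slot pi0Method how pi0 was obtained.
#' @slot test \code{"t"} or \code{"wilcoxon"}.
#' @slot method \code{"fuzzy"}, \code{"standard"} or \code{"none"}.
#' @slot k number of permutations (0 when \code{method = "none"}).
#' @slot epsilon fuzz scale used (NA unless fuzzy).
#' @slot seed seed used (NA when unseeded).
#' @aliases FuzzyPermResult
#' @export
setClass("FuzzyPermResult",
  representation(variableIds = "character", rawP = "numeric",
                 permP = "numeric", qvalues = "numeric", pi0 = "numeric",
                 pi0Method = "character", test = "character",
                 method = "character", k = "integer", epsilon = "numeric",
                 seed = "integer"))

setValidity("FuzzyPermResult", function(object) {
  m <- length(object@variableIds)
  msg <- character()
  if (length(object@rawP) != m || length(object@qvalues) != m)
    msg <- c(msg, "rawP and qvalues must match variableIds in length")
  if (length(object@permP) && length(object@permP) != m)
    msg <- c(msg, "permP must be empty or match variableIds in length")
  for (nm in c("rawP", "permP", "qvalues")) {
    v <- slot(object, nm)
    if (length(v) && (anyNA(v) || any(v < 0 | v > 1)))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  }
  if (length(object@pi0) != 1L || object@pi0 <= 0 || object@pi0 > 1)
    msg <- c(msg, "pi0 must be a single value in (0, 1]")
  if (!object@test %in% c("t", "wilcoxon"))
    msg <- c(msg, "test must be 't' or 'wilcoxon'")
  if (!object@method %in% c("fuzzy", "standard", "none"))
    msg <- c(msg, "method must be 'fuzzy', 'standard' or 'none'")
  if (length(msg)) msg else TRUE
})

#' @describeIn FuzzyPermResult raw test p-values.
#' @param object,x a \code{FuzzyPermResult}.
#' @export
setGeneric("rawPValues", function(object) standardGeneric("rawPValues"))
setMethod("rawPValues", "FuzzyPermResult", function(object) {
  structure(object@rawP, names = object@variableIds)
})

#' @describeIn FuzzyPermResult permutation p-values (NULL for method "none").
#' @export
setGeneric("permPValues", function(object) standardGeneric("permPValues"))
setMethod("permPValues", "FuzzyPermResult", function(object) {
  if (!length(object@permP)) return(NULL)
  structure(object@permP, names = object@variableIds)
})

#' @describeIn FuzzyPermResult q-values.
#' @export
setGeneric("qvalues", function(object) standardGeneric("qvalues"))
setMethod("qvalues", "FuzzyPermResult", function(object) {
  structure(object@qvalues, names = object@variableIds)
})

#' @describeIn FuzzyPermResult estimated null proportion.
#' @export
setGeneric("pi0Estimate", function(object) standardGeneric("pi0Estimate"))
setMethod("pi0Estimate", "FuzzyPermResult", function(object) object@pi0)

#' @describeIn FuzzyPermResult results as a data.frame
#'   (variable_id, raw_p, perm_p, q_value) in input variable order.
#' @param row.names,optional,... as for \code{\link[base]{as.data.frame}}.
#' @export
as.data.frame.FuzzyPermResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(variable_id = x@variableIds,
             raw_p = x@rawP,
             perm_p = if (length(x@permP)) x@permP else NA_real_,
             q_value = x@qvalues,
             stringsAsFactors = FALSE)
}

setMethod("show", "FuzzyPermResult", function(object) {
  desc <- switch(object@method,
    fuzzy    = sprintf("fuzzy permutation (%s test, k = %d, epsilon = %g)",
                       object@test, object@k, object@epsilon),
    standard = sprintf("standard permutation (%s test, k = %d)",
                       object@test, object@k),
    none     = sprintf("raw %s test (no permutation)", object@test))
  cat("FuzzyPermResult:", length(object@variableIds), "variables\n")
  cat("  method:", desc, "\n")
  cat(sprintf("  pi0 estimate: %.4f (%s)\n", object@pi0, object@pi0Method))
  for (a in c(0.01, 0.05, 0.10))
    cat(sprintf("  discoveries at q <= %.2f: %d\n", a,
                sum(object@qvalues <= a)))
})

#' SimScenario: specification of a synthetic benchmark dataset
#'
#' Describes one large-p-small-n simulation scenario: a distribution family,
#' the fraction of non-null variables (the signal-to-noise ratio, "high" =
#' 10\%, "low" = 1\%), a strong or weak effect, group sizes, and a seed.
#' Null variables are drawn identically in both groups from the family's null
#' parameters; non-null variables use the family's alternative parameters in
#' the case group only. See \code{\link{scenarioParams}} for the parameter
#' sets and \code{\link{simulateDataset}} to realise a dataset.
#'
#' @slot family one of \code{"normal"}, \code{"gamma"},
#'   \code{"truncated_normal"}, \code{"beta"}.
#' @slot m number of variables.
#' @slot propNonnull fraction of non-null variables in [0, 1].
#' @slot effect \code{"strong"} or \code{"weak"}.
#' @slot n1,n0 cases and controls.
#' @slot seed scenario seed (NA allowed).
#' @aliases SimScenario
#' @export
setClass("SimScenario",
  representation(family = "character", m = "integer", propNonnull = "numeric",
                 effect = "character", n1 = "integer", n0 = "integer",
                 seed = "integer"))

setValidity("SimScenario", function(object) {
  msg <- character()
  if (!object@family %in% c("normal", "gamma", "truncated_normal", "beta"))
    msg <- c(msg, "unsupported distribution family")
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (is.na(object@propNonnull) || object@propNonnull < 0 ||
      object@propNonnull > 1)
    msg <- c(msg, "propNonnull must lie in [0, 1]")
  if (!object@effect %in% c("strong", "weak"))
    msg <- c(msg, "effect must be 'strong' or 'weak'")
  if (object@n1 < 1L || object@n0 < 1L)
    msg <- c(msg, "need at least one case and one control")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation scenario
#'
#' @param family distribution family: \code{"normal"}, \code{"gamma"},
#'   \code{"truncated_normal"} or \code{"beta"}.
#' @param effect \code{"strong"} or \code{"weak"} alternative.
#' @param snr \code{"high"} (10\% of variables non-null) or \code{"low"} (1\%);
#'   ignored when \code{propNonnull} is given.
#' @param m number of variables (default 20000, the benchmark scale).
#' @param n1,n0 group sizes (default 5 and 5).
#' @param propNonnull explicit non-null fraction overriding \code{snr}.
#' @param seed scenario seed.
#' @return a \linkS4class{SimScenario}.
#' @examples
#' simScenario("beta", effect = "weak", snr = "low", seed = 1)
#' @export
simScenario <- function(family = c("normal", "gamma", "truncated_normal",
                                   "beta"),
                        effect = c("strong", "weak"),
                        snr = c("high", "low"),
                        m = 20000L, n1 = 5L, n0 = 5L,
                        propNonnull = NULL, seed = NA_integer_) {
  family <- match.arg(family); effect <- match.arg(effect)
  snr <- match.arg(snr)
  if (is.null(propNonnull))
    propNonnull <- if (snr == "high") 0.10 else 0.01
  new("SimScenario", family = family, m = as.integer(m),
      propNonnull = propNonnull, effect = effect,
      n1 = as.integer(n1), n0 = as.integer(n0), seed = as.integer(seed))
}

#' @describeIn SimScenario the distribution family.
#' @param object a \code{SimScenario}.
#' @export
setGeneric("distFamily", function(object) standardGeneric("distFamily"))
setMethod("distFamily", "SimScenario", function(object) object@family)

#' @describeIn SimScenario the non-null fraction.
#' @export
setGeneric("propNonnull", function(object) standardGeneric("propNonnull"))
setMethod("propNonnull", "SimScenario", function(object) object@propNonnull)

#' @describeIn SimScenario the effect level ("strong"/"weak").
#' @export
setGeneric("effectLevel", function(object) standardGeneric("effectLevel"))
setMethod("effectLevel", "SimScenario", function(object) object@effect)

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario: %s, %s effect, %.3g%% non-null, m = %d, n1 = %d, n0 = %d%s\n",
    object@family, object@effect, 100 * object@propNonnull, object@m,
    object@n1, object@n0,
    if (is.na(object@seed)) "" else sprintf(", seed = %d", object@seed)))
})
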