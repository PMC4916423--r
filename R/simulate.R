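#' Distribution parameters for a simulation scenario
#'
#' Null and alternative parameter sets per family. Defaults (overridable only
#' by editing the returned list and sampling manually) are chosen to span the
#' qualitative regimes of interest at n1 = n0 = 5: a well-behaved symmetric
#' family (normal), a skewed positive family (gamma), a bounded light-tailed
#' family (truncated normal) and a strongly skewed bounded family (beta) that
#' stresses the normality assumption of the t test.
#'
#' \itemize{
#'   \item normal: null N(0, 1); alternative mean shifted by +3 (strong) or
#'     +1 (weak) standard deviations.
#'   \item gamma: null shape 2, scale 1; alternative shape scaled by 5
#'     (strong) or 1.5 (weak), same scale.
#'   \item truncated_normal: the normal settings truncated to [-2, 2], the
#'     mean shift applied before truncation.
#'   \item beta: null Beta(0.3, 0.6), a bathtub-shaped bounded distribution --
#'     the strongest stressor of the t test's normality assumption;
#'     alternative Beta(20, 0.5) (strong) or Beta(10, 1) (weak), mass shifted
#'     to the upper boundary.
#' }
#'
#' Strong effects are sized so that, at the default benchmark scale
#' (m = 20000, n1 = n0 = 5, 10\% non-null), the FDP-versus-q curve beyond
#' rank 500 populates the q range below 0.10; weak effects give partial power
#' at best.
#'
#' @param family distribution family.
#' @param effect \code{"strong"} or \code{"weak"}.
#' @return list with elements \code{null} and \code{alt}, each a named
#'   parameter list.
#' @export
scenarioParams <- function(family, effect = c("strong", "weak")) {
  effect <- match.arg(effect)
  strong <- effect == "strong"
  switch(family,
    normal = list(null = list(mean = 0, sd = 1),
                  alt  = list(mean = if (strong) 3 else 1, sd = 1)),
    gamma = list(null = list(shape = 2, scale = 1),
                 alt  = list(shape = 2 * (if (strong) 5 else 1.5),
                             scale = 1)),
    truncated_normal = list(
      null = list(mean = 0, sd = 1, lower = -2, upper = 2),
      alt  = list(mean = if (strong) 3 else 1, sd = 1, lower = -2,
                  upper = 2)),
    beta = list(null = list(shape1 = 0.3, shape2 = 0.6),
                alt  = if (strong) list(shape1 = 20, shape2 = 0.5)
                       else list(shape1 = 10, shape2 = 1)),
    fpConfigError(sprintf("unsupported distribution family '%s'", family))
  )
}

## inverse-CDF sampler, exact on the truncation interval
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

.rfamily <- function(n, family, par) {
  switch(family,
    normal = rnorm(n, par$mean, par$sd),
    gamma  = rgamma(n, shape = par$shape, scale = par$scale),
    truncated_normal = .rtruncnorm(n, par$mean, par$sd, par$lower, par$upper),
    beta   = rbeta(n, par$shape1, par$shape2))
}

#' Simulate a large-p-small-n dataset with known truth
#'
#' Realises a \linkS4class{SimScenario}: every variable is drawn independently;
#' null variables use the family's null parameters in both groups, non-null
#' variables (the first \code{round(m * propNonnull)} rows) use the
#' alternative parameters in the case group only. Reproducible under the
#' scenario seed.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @return a \linkS4class{SummarizedExperiment} with assay \code{"exprs"},
#'   \code{colData} column \code{group} (factor case/control), \code{rowData}
#'   column \code{nonnull} (logical truth mask) and the scenario in
#'   \code{metadata}.
#' @examples
#' se <- simulateDataset(simScenario("normal", m = 100, seed = 1))
#' table(SummarizedExperiment::rowData(se)$nonnull)
#' @export
simulateDataset <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  validObject(scenario)
  m <- scenario@m; n1 <- scenario@n1; n0 <- scenario@n0
  par <- scenarioParams(scenario@family, scenario@effect)
  nAlt <- as.integer(round(m * scenario@propNonnull))
  truth <- c(rep(TRUE, nAlt), rep(FALSE, m - nAlt))

  x <- withSeed(if (is.na(scenario@seed)) NULL else scenario@seed, {
    mat <- matrix(.rfamily(m * (n1 + n0), scenario@family, par$null),
                  nrow = m, ncol = n1 + n0)
    if (nAlt > 0L)
      mat[seq_len(nAlt), seq_len(n1)] <-
        .rfamily(nAlt * n1, scenario@family, par$alt)
    mat
  })
  rownames(x) <- sprintf("V%05d", seq_len(m))
  colnames(x) <- c(sprintf("case%d", seq_len(n1)),
                   sprintf("ctrl%d", seq_len(n0)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x),
    colData = S4Vectors::DataFrame(
      group = factor(rep(c("case", "control"), c(n1, n0)),
                     levels = c("case", "control"))),
    rowData = S4Vectors::DataFrame(nonnull = truth),
    metadata = list(scenario = scenario))
}

#' False discovery proportion along the q-value ranking
#'
#' Sorts q-values ascending and, for each rank \code{r} from
#' \code{startRank} up, reports the realized false discovery proportion
#' FDP(r) = (number of null variables among the r smallest q-values) / r,
#' paired with the r-th smallest q-value. The default \code{startRank = 501}
#' skips the unstable small-denominator head of the curve.
#'
#' @param q numeric q-value vector (or a \linkS4class{FuzzyPermResult}).
#' @param truth logical mask, TRUE for non-null variables.
#' @param startRank first rank reported.
#' @return data.frame with columns \code{rank}, \code{qvalue}, \code{fdp}.
#' @examples
#' evaluateFdpCurve(c(.01, .02, .03, .2, .5),
#'                  truth = c(FALSE, TRUE, TRUE, FALSE, TRUE), startRank = 1)
#' @export
evaluateFdpCurve <- function(q, truth, startRank = 501L) {
  if (is(q, "FuzzyPermResult")) q <- qvalues(q)
  .checkPValues(q)
  if (length(truth) != length(q))
    fpInputError("truth mask length must match the q-value vector")
  truth <- as.logical(truth)
  if (anyNA(truth)) fpInputError("truth mask must be TRUE/FALSE")
  m <- length(q)
  if (startRank < 1L || startRank > m)
    fpConfigError("startRank must lie between 1 and the number of variables")
  o <- order(q)
  fdp <- cumsum(!truth[o]) / seq_len(m)
  keep <- seq.int(startRank, m)
  data.frame(rank = keep, qvalue = q[o][keep], fdp = fdp[keep])
}

.methodTags <- c("t_raw", "wilcoxon_raw", "fuzzy_perm_t",
                 "fuzzy_perm_wilcoxon", "std_perm_t", "std_perm_wilcoxon")

## map a method tag onto the pipeline arguments
.tagArgs <- function(tag) {
  if (!tag %in% .methodTags)
    fpConfigError(sprintf("unknown method tag '%s'", tag))
  list(test = if (grepl("wilcoxon", tag)) "wilcoxon" else "t",
       method = if (grepl("^fuzzy", tag)) "fuzzy"
                else if (grepl("^std", tag)) "standard" else "none")
}

#' Benchmark methods over simulated scenarios
#'
#' Runs a set of testing methods over a set of scenarios and collects, per
#' (scenario, method) cell, the q-values, the FDP-versus-q curve and
#' discovery counts at the requested FDR levels. Method tags:
#' \code{t_raw}, \code{wilcoxon_raw} (no permutation),
#' \code{fuzzy_perm_t}, \code{fuzzy_perm_wilcoxon},
#' \code{std_perm_t}, \code{std_perm_wilcoxon}.
#'
#' The analysis seed of each cell is derived deterministically from the
#' scenario seed, so a benchmark is reproducible end to end.
#'
#' @param scenarios list of \linkS4class{SimScenario} (or a single one).
#' @param methods character vector of method tags.
#' @param k permutations per permutation-based method.
#' @param epsilon fuzz scale for the fuzzy methods.
#' @param alphas FDR levels for discovery counts.
#' @param startRank see \code{\link{evaluateFdpCurve}}.
#' @param verbose print one line per cell.
#' @return list with \code{table} (data.frame: scenario, family, effect, snr,
#'   method, pi0, one row per alpha with discoveries), \code{curves} (named
#'   list of FDP curves) and \code{results} (named list of
#'   \linkS4class{FuzzyPermResult}).
#' @export
runBenchmark <- function(scenarios, methods = .methodTags, k = 1000L,
                         epsilon = 1e-12,
                         alphas = c(0.01, 0.05, 0.10, 0.20, 0.40),
                         startRank = 501L, verbose = FALSE) {
  if (is(scenarios, "SimScenario")) scenarios <- list(scenarios)
  if (!length(scenarios) || !length(methods))
    fpConfigError("need at least one scenario and one method")
  for (tag in methods) .tagArgs(tag)   # validate early

  rows <- list(); curves <- list(); results <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    se <- simulateDataset(sc)
    x <- .seMatrix(se)
    truth <- SummarizedExperiment::rowData(se)$nonnull
    labels <- as.integer(SummarizedExperiment::colData(se)$group == "case")
    scName <- sprintf("%s_%s_%s", sc@family, sc@effect,
                      if (sc@propNonnull >= 0.05) "high" else "low")
    for (tag in methods) {
      a <- .tagArgs(tag)
      res <- fuzzyPermFdr(x, labels, test = a$test, method = a$method,
                          k = k, epsilon = epsilon,
                          seed = deriveSeed(sc@seed, match(tag, .methodTags)))
      cellName <- paste(scName, tag, sep = ".")
      results[[cellName]] <- res
      curves[[cellName]] <-
        if (startRank <= sc@m) evaluateFdpCurve(res, truth, startRank)
      disc <- countDiscoveries(res, alphas)
      rows[[cellName]] <- data.frame(
        scenario = scName, family = sc@family, effect = sc@effect,
        snr = if (sc@propNonnull >= 0.05) "high" else "low",
        method = tag, pi0 = pi0Estimate(res), alpha = alphas,
        discoveries = disc, stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("%-40s pi0 = %.3f, discoveries@0.05 = %d", cellName,
                        pi0Estimate(res), disc[match(0.05, alphas)]))
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       curves = curves, results = results)
}
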