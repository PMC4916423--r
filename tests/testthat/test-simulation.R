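test_that("scenario construction validates its fields", {
  sc <- simScenario("beta", effect = "weak", snr = "low", m = 100, seed = 1)
  expect_s4_class(sc, "SimScenario")
  expect_identical(distFamily(sc), "beta")
  expect_identical(effectLevel(sc), "weak")
  expect_equal(propNonnull(sc), 0.01)
  expect_equal(propNonnull(simScenario("normal", snr = "high")), 0.10)
  expect_error(simScenario("normal", propNonnull = 1.5),
               "propNonnull")
  expect_error(simScenario("cauchy"), "'arg'")
  expect_error(scenarioParams("poisson"), class = "fp_config_error")
})

test_that("simulated datasets have the declared shape, truth and support", {
  for (fam in c("normal", "gamma", "truncated_normal", "beta")) {
    sc <- simScenario(fam, m = 400, n1 = 5, n0 = 5, propNonnull = 0.1,
                      seed = 7)
    se <- simulateDataset(sc)
    x <- SummarizedExperiment::assay(se)
    truth <- SummarizedExperiment::rowData(se)$nonnull
    expect_identical(dim(x), c(400L, 10L))
    expect_identical(sum(truth), 40L)
    expect_identical(truth, c(rep(TRUE, 40), rep(FALSE, 360)))
    if (fam == "gamma") expect_true(all(x > 0))
    if (fam == "beta") expect_true(all(x > 0 & x < 1))
    if (fam == "truncated_normal") expect_true(all(x >= -2 & x <= 2))
    # reproducible under the scenario seed
    expect_identical(x, SummarizedExperiment::assay(simulateDataset(sc)))
  }
  # no signal: truth mask all false
  se0 <- simulateDataset(simScenario("normal", m = 50, propNonnull = 0,
                                     seed = 1))
  expect_false(any(SummarizedExperiment::rowData(se0)$nonnull))
})

test_that("generator moments match the configured parameters", {
  set.seed(8)
  # null moments at 1e5 draws per family
  for (fam in c("normal", "gamma", "truncated_normal", "beta")) {
    sc <- simScenario(fam, m = 10000, n1 = 5, n0 = 5, propNonnull = 0,
                      seed = 17)
    x <- SummarizedExperiment::assay(simulateDataset(sc))
    mu <- switch(fam, normal = 0, gamma = 2, truncated_normal = 0,
                 beta = 0.3 / 0.9)
    sdv <- switch(fam, normal = 1, gamma = sqrt(2),
                  truncated_normal = 0.8796,   # sd of N(0,1) on [-2, 2]
                  beta = sqrt(0.3 * 0.6 / (0.9^2 * 1.9)))
    expect_lt(abs(mean(x) - mu), 4 * sdv / sqrt(length(x)))
    expect_lt(abs(sd(x) - sdv), 0.01 * sdv + 0.003)
  }
  # strong normal effect: case-minus-control group mean difference ~ +3
  scs <- simScenario("normal", effect = "strong", m = 20000,
                     propNonnull = 0.1, seed = 19)
  xs <- SummarizedExperiment::assay(simulateDataset(scs))
  alt <- xs[1:2000, ]
  d <- rowMeans(alt[, 1:5]) - rowMeans(alt[, 6:10])
  expect_lt(abs(mean(d) - 3), 3 * sqrt(0.4 / 2000))
})

test_that("FDP curves count running null proportions", {
  # hand-counted running FDP
  cur <- evaluateFdpCurve(c(0.01, 0.02, 0.03, 0.04, 0.05),
                          truth = c(FALSE, TRUE, TRUE, FALSE, TRUE),
                          startRank = 1)
  expect_equal(cur$fdp, c(1, 1 / 2, 1 / 3, 2 / 4, 2 / 5))
  expect_equal(cur$qvalue, c(0.01, 0.02, 0.03, 0.04, 0.05))
  # degenerate truths
  expect_true(all(evaluateFdpCurve(runif(20), rep(FALSE, 20),
                                   startRank = 1)$fdp == 1))
  expect_true(all(evaluateFdpCurve(runif(20), rep(TRUE, 20),
                                   startRank = 1)$fdp == 0))
  expect_error(evaluateFdpCurve(runif(5), rep(TRUE, 4), startRank = 1),
               class = "fp_input_error")
  expect_error(evaluateFdpCurve(runif(5), rep(TRUE, 5), startRank = 6),
               class = "fp_config_error")
})

test_that("benchmark emits one row per scenario, method and alpha", {
  scens <- list(simScenario("normal", m = 300, propNonnull = 0.1, seed = 3),
                simScenario("gamma", m = 300, propNonnull = 0.1, seed = 4))
  methods <- c("t_raw", "fuzzy_perm_t", "std_perm_wilcoxon")
  bm <- runBenchmark(scens, methods, k = 60, alphas = c(0.05, 0.10),
                     startRank = 101)
  expect_identical(nrow(bm$table), 2L * 3L * 2L)
  expect_identical(length(bm$curves), 6L)
  expect_identical(length(bm$results), 6L)
  # same data within a scenario: raw p-values identical across methods
  expect_identical(rawPValues(bm$results[["normal_strong_high.t_raw"]]),
                   rawPValues(bm$results[["normal_strong_high.fuzzy_perm_t"]]))
  # deterministic under the scenario seeds
  bm2 <- runBenchmark(scens, methods, k = 60, alphas = c(0.05, 0.10),
                      startRank = 101)
  expect_identical(bm$table, bm2$table)
  expect_error(runBenchmark(scens, "bogus_method"), class = "fp_config_error")
  expect_error(runBenchmark(list(), "t_raw"), class = "fp_config_error")
})

test_that("a null-only scenario yields (almost) no fuzzy discoveries", {
  # with the count/k convention a null variable lands at permutation p = 0
  # (hence q = 0) with probability ~1/(k+1), so the spurious-discovery rate
  # at any q threshold is bounded by that atom; k = 2000 keeps it near
  # 1/2000 and the fixed-seed run below within 0.001
  sc <- simScenario("normal", m = 2000, propNonnull = 0, seed = 23)
  bm <- runBenchmark(sc, "fuzzy_perm_t", k = 2000, alphas = 0.05,
                     startRank = 501)
  expect_lte(bm$table$discoveries[1] / 2000, 0.001)
})
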