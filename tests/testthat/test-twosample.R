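test_that("row t-test matches t.test on random data", {
  x <- rmat(60, 9, seed = 1)
  lab <- c(rep(1, 4), rep(0, 5))
  p <- twoSamplePValues(x, lab, test = "t")
  expect_equal(as.numeric(p), oracleTPValues(x, lab), tolerance = 1e-12)
  expect_identical(attr(p, "method"), "t_raw")
  expect_named(p, rownames(x))

  pw <- twoSamplePValues(x, lab, test = "t", varEqual = FALSE)
  ref <- apply(x, 1, function(r)
    t.test(r[lab == 1], r[lab == 0], var.equal = FALSE)$p.value)
  expect_equal(as.numeric(pw), unname(ref), tolerance = 1e-12)
})

test_that("Wilcoxon p-values are exact for untied and tied data", {
  x <- rmat(50, 10, seed = 2)
  lab <- rep(c(1, 0), each = 5)
  p <- twoSamplePValues(x, lab, test = "wilcoxon")
  ref <- apply(x, 1, function(r)
    wilcox.test(r[lab == 1], r[lab == 0], exact = TRUE)$p.value)
  expect_equal(as.numeric(p), unname(ref), tolerance = 1e-12)

  # heavy ties: mid-rank enumeration against the independent enumerator
  xi <- rmat(40, 8, seed = 3, gen = function(n) sample(0:3, n, replace = TRUE))
  labi <- rep(c(1, 0), each = 4)
  pi_ <- twoSamplePValues(xi, labi, test = "wilcoxon")
  expect_equal(as.numeric(pi_), oracleWilcoxPValues(xi, labi), tolerance = 1e-12)
})

test_that("degenerate inputs give the defined p-values", {
  # identical groups under t: statistic exactly 0
  x <- matrix(c(1:5, 1:5), nrow = 1)
  expect_equal(as.numeric(twoSamplePValues(x, rep(c(1, 0), each = 5), "t")), 1)

  # complete separation at n1 = n0 = 5: the most extreme of 252 assignments
  xs <- matrix(c(6:10, 1:5), nrow = 1)
  expect_equal(as.numeric(twoSamplePValues(xs, rep(c(1, 0), each = 5), "wilcoxon")),
               2 / 252, tolerance = 1e-12)

  # identical tied groups under Wilcoxon: central statistic
  xt <- matrix(c(10, 11, 12, 10, 11, 12), nrow = 1)
  expect_equal(as.numeric(twoSamplePValues(xt, c(1, 1, 1, 0, 0, 0), "wilcoxon")), 1)

  # constant variable: zero pooled variance, equal means -> p = 1 + warning
  xc <- rbind(rep(2.5, 8), rnorm(8))
  expect_warning(p <- twoSamplePValues(xc, rep(c(1, 0), each = 4), "t"),
                 "zero pooled variance")
  expect_equal(as.numeric(p[1]), 1)

  # zero pooled variance with separated means: |t| = Inf -> p = 0
  xz <- matrix(rep(c(1, 0), each = 4), nrow = 1)
  expect_equal(as.numeric(twoSamplePValues(xz, rep(c(1, 0), each = 4), "t")), 0)
})

test_that("input validation rejects malformed data", {
  x <- rmat(5, 6, seed = 4)
  expect_error(twoSamplePValues(x, c(1, 0, 1), "t"), class = "fp_input_error")
  expect_error(twoSamplePValues(x, rep(1, 6), "t"), class = "fp_input_error")
  expect_error(twoSamplePValues(x, c(1, 0, 0, 0, 0, 0), "t"),
               class = "fp_input_error")      # t needs n1 >= 2
  p <- twoSamplePValues(x, c(1, 0, 0, 0, 0, 0), "wilcoxon")  # wilcoxon: n1 = 1 ok
  expect_length(p, 5)
  xna <- x; xna[2, 3] <- NA
  expect_error(twoSamplePValues(xna, rep(c(1, 0), each = 3), "t"),
               class = "fp_input_error")
})

test_that("labels are accepted as factor, character, logical and 0/1", {
  x <- rmat(10, 6, seed = 5)
  p1 <- twoSamplePValues(x, c(1, 1, 1, 0, 0, 0), "t")
  p2 <- twoSamplePValues(x, factor(rep(c("case", "control"), each = 3)), "t")
  p3 <- twoSamplePValues(x, rep(c(TRUE, FALSE), each = 3), "t")
  expect_identical(p1, p2)
  expect_identical(p1, p3)
})

test_that("SummarizedExperiment dispatch uses assay and colData", {
  se <- simulateDataset(simScenario("normal", m = 30, n1 = 3, n0 = 3,
                                    seed = 9))
  p1 <- twoSamplePValues(se, test = "t")
  p2 <- twoSamplePValues(SummarizedExperiment::assay(se),
                         rep(c(1, 0), each = 3), test = "t")
  expect_identical(p1, p2)
  expect_error(twoSamplePValues(se, labels = "nosuch", test = "t"),
               class = "fp_input_error")
})
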