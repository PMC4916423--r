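test_that("exhaustive permutation enumerates every assignment exactly once", {
  p2 <- generatePermutations(c(1, 0), mode = "exhaustive")
  expect_identical(dim(p2), c(2L, 2L))

  p252 <- generatePermutations(rep(c(1, 0), each = 5), mode = "exhaustive")
  expect_identical(nrow(p252), 252L)
  expect_identical(anyDuplicated(p252), 0L)
  expect_true(all(rowSums(p252) == 5))
  # the observed assignment is among them
  expect_true(any(apply(p252, 1, identical, y = rep(c(1L, 0L), each = 5))))

  expect_error(generatePermutations(rep(c(1, 0), each = 5),
                                    mode = "exhaustive", exhaustiveCap = 100),
               class = "fp_config_error")
})

test_that("random permutations preserve group sizes and respect the seed", {
  lab <- c(1, 1, 1, 0, 0, 0, 0)
  pm <- generatePermutations(lab, k = 200, seed = 5)
  expect_identical(dim(pm), c(200L, 7L))
  expect_true(all(rowSums(pm) == 3))
  expect_identical(pm, generatePermutations(lab, k = 200, seed = 5))
  expect_false(identical(pm, generatePermutations(lab, k = 200, seed = 6)))
  expect_error(generatePermutations(lab, k = 0), class = "fp_config_error")
  # n1 = 1 edge case keeps matrix shape
  p1 <- generatePermutations(c(1, 0, 0), k = 10, seed = 1)
  expect_identical(dim(p1), c(10L, 3L))
})

test_that("permutation p-values are reproducible and k = 0 is rejected", {
  x <- rmat(30, 8, seed = 10)
  lab <- rep(c(1, 0), each = 4)
  a <- fuzzyPermutationPValues(x, lab, "t", k = 100, seed = 3)
  b <- fuzzyPermutationPValues(x, lab, "t", k = 100, seed = 3)
  expect_identical(a, b)
  expect_false(identical(
    as.numeric(a),
    as.numeric(fuzzyPermutationPValues(x, lab, "t", k = 100, seed = 4))))
  expect_error(fuzzyPermutationPValues(x, lab, "t", k = 0),
               class = "fp_config_error")
  expect_error(standardPermutationPValues(x, lab, "t", k = -1),
               class = "fp_config_error")
})

test_that("a constant variable has standard permutation p-value 1", {
  x <- rbind(rep(3.2, 10), rmat(1, 10, seed = 11))
  p <- standardPermutationPValues(x, rep(c(1, 0), each = 5), "t",
                                  mode = "exhaustive")
  expect_equal(as.numeric(p[1]), 1)
})

test_that("observed fuzz draw at the boundaries controls tie counting", {
  # strongly separated variable, exhaustive mode: only the identity and its
  # complement tie the observed p-value. With uObs = 0 no tie can count and
  # the fuzzy permutation p-value is exactly 0; with uObs = 1 every tie
  # counts, matching the standard count.
  x <- matrix(c(100, 101, 102, 1, 2, 3) + rnorm(6, sd = .01), nrow = 1)
  lab <- rep(c(1, 0), each = 3)
  k <- choose(6, 3)
  uPerm <- matrix(0.5, nrow = 1, ncol = k)
  p0 <- fuzzyPermutationPValues(x, lab, "t", mode = "exhaustive",
                                uObs = 0, uPerm = uPerm)
  p1 <- fuzzyPermutationPValues(x, lab, "t", mode = "exhaustive",
                                uObs = 1, uPerm = uPerm)
  ps <- standardPermutationPValues(x, lab, "t", mode = "exhaustive")
  expect_equal(as.numeric(p0), 0)
  expect_equal(as.numeric(p1), as.numeric(ps))
})

test_that("add-one mode shifts counts to (count+1)/(k+1)", {
  x <- rmat(20, 8, seed = 12)
  lab <- rep(c(1, 0), each = 4)
  p <- standardPermutationPValues(x, lab, "wilcoxon", k = 99, seed = 2)
  pa <- standardPermutationPValues(x, lab, "wilcoxon", k = 99, seed = 2,
                                   addOne = TRUE)
  expect_equal(as.numeric(pa), (as.numeric(p) * 99 + 1) / 100, tolerance = 1e-12)
  expect_true(all(pa > 0))
})

test_that("fractional and randomized modes agree when no p-values tie", {
  # continuous data, random mode: sampled assignments almost surely produce
  # no exact tie with the observed p-value, so both tie modes give the same
  # counts as the standard method
  x <- rmat(40, 12, seed = 13)
  lab <- rep(c(1, 0), each = 6)
  pr <- fuzzyPermutationPValues(x, lab, "t", k = 50, seed = 21,
                                tieMode = "randomized")
  pf <- fuzzyPermutationPValues(x, lab, "t", k = 50, seed = 21,
                                tieMode = "fractional")
  ps <- standardPermutationPValues(x, lab, "t", k = 50, seed = 21)
  expect_equal(as.numeric(pr), as.numeric(ps))
  expect_equal(as.numeric(pf), as.numeric(ps))
})

test_that("exhaustive pipeline matches the literal brute-force enumeration", {
  # small-instance oracle equivalence across both tests
  for (seed in 1:6) {
    set.seed(seed + 100)
    m <- sample(2:5, 1); n1 <- sample(2:4, 1); n0 <- sample(2:4, 1)
    x <- rmat(m, n1 + n0, seed = seed)
    lab <- rep(c(1, 0), c(n1, n0))
    k <- choose(n1 + n0, n1)
    uObs <- runif(m); uPerm <- matrix(runif(m * k), nrow = m)
    test <- if (seed %% 2) "t" else "wilcoxon"
    pf <- fuzzyPermutationPValues(x, lab, test, mode = "exhaustive",
                                  epsilon = 1e-12, uObs = uObs, uPerm = uPerm)
    ps <- standardPermutationPValues(x, lab, test, mode = "exhaustive")
    bf <- bruteForcePermutation(x, lab, test, 1e-12, uObs, uPerm)
    expect_identical(as.numeric(pf), bf$fuzzy)
    expect_identical(as.numeric(ps), bf$std)
  }
})
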