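# Independent brute-force oracles: per-variable scalar tests and a literal
# enumeration of the fuzzy/standard permutation counting. Deliberately slow
# and written against the algorithm definitions, not the package internals.

rmat <- function(m, n, seed, gen = rnorm) {
  set.seed(seed)
  matrix(gen(m * n), nrow = m,
         dimnames = list(sprintf("v%02d", seq_len(m)),
                         sprintf("s%02d", seq_len(n))))
}

# classical pooled-variance two-sided t, scalar per variable, with the
# defined degenerate conventions (0/0 -> p = 1, separation at zero pooled
# variance -> p = 0)
oracleTPValues <- function(x, lab) {
  unname(apply(x, 1L, function(r) {
    g1 <- r[lab == 1]; g0 <- r[lab == 0]
    n1 <- length(g1); n0 <- length(g0)
    d <- mean(g1) - mean(g0)
    sp2 <- ((n1 - 1) * stats::var(g1) + (n0 - 1) * stats::var(g0)) /
      (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    if (se == 0) return(if (d == 0) 1 else 0)
    2 * stats::pt(abs(d / se), df = n1 + n0 - 2, lower.tail = FALSE)
  }))
}

# exact two-sided rank-sum p by full enumeration (mid-ranks, twice the
# smaller tail including the observed point, capped at 1)
oracleWilcoxPValues <- function(x, lab) {
  n <- ncol(x); n1 <- sum(lab == 1)
  cb <- utils::combn(n, n1)
  unname(apply(x, 1L, function(r) {
    rk <- rank(r)
    ws <- colSums(matrix(rk[cb], nrow = n1))
    w <- sum(rk[lab == 1])
    min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
  }))
}

# literal Steps 1-6 over all C(n, n1) assignments, with the fuzzy comparison
# p*_b + eps*u_b <= p_obs + eps*u0 taken in its small-eps limit: strict order
# from the p-values (ties detected with the documented 1e-8 relative
# tolerance), exact ties decided by u_b <= u0
bruteForcePermutation <- function(x, lab, test, epsilon, uObs, uPerm) {
  n <- ncol(x); n1 <- sum(lab == 1)
  cb <- utils::combn(n, n1)
  pfun <- if (test == "t") oracleTPValues else oracleWilcoxPValues
  pObs <- pfun(x, lab)
  tol <- 1e-8 * pmax(pObs, 1e-12)
  k <- ncol(cb)
  countF <- countS <- numeric(nrow(x))
  for (b in seq_len(k)) {
    labB <- integer(n); labB[cb[, b]] <- 1L
    pB <- pfun(x, labB)
    lt <- pB < pObs - tol
    tie <- abs(pB - pObs) <= tol
    countS <- countS + lt + tie
    countF <- countF + lt + (tie & uPerm[, b] <= uObs)
  }
  list(fuzzy = countF / k, std = countS / k)
}

# q-values via the independent BH reference (equals the step-up construction
# at pi0 = 1)
referenceBH <- function(p) stats::p.adjust(p, method = "BH")
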