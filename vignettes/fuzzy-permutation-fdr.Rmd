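---
title: "Fuzzy permutation FDR control: methods and design notes"
author: "fuzzperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy permutation FDR control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

A case-control study measures $m$ variables on $n_1$ cases and $n_0$
controls, with $m$ in the tens of thousands and $n_1, n_0$ as small as 4 or
5. For each variable $j$ a two-sample test yields a p-value $p_j$, and the
goal is a rejection set whose false discovery rate is controlled at a chosen
level via q-values. The q-value machinery assumes null p-values are
uniform(0,1); at these sample sizes that assumption fails in both available
directions — asymptotic parametric p-values are miscalibrated (no central
limit theorem), and exact nonparametric p-values are discrete.

The fuzzy permutation procedure repairs this by external randomization:

1. $p_j$ from a two-sample test (pooled-variance Student t, or Wilcoxon
   rank-sum with its exact small-sample null distribution);
2. $\tilde p_j = p_j + \varepsilon U_j$, $U_j \sim \mathrm{U}(0,1)$, one
   draw per variable, fixed for the rest of the run;
3. permute the case/control labels, recompute $p^*_{jb}$, and fuzz each with
   a fresh independent draw, $\tilde p^*_{jb} = p^*_{jb} + \varepsilon U_{jb}$,
   for $b = 1, \dots, k$;
4. the permutation p-value is
   $\#\{b : \tilde p^*_{jb} \le \tilde p_j\} / k$;
5. estimate $\pi_0$ and convert to q-values; reject at $q \le \alpha$.

Exchangeability of the samples under the null is the only distributional
assumption: the permutation distribution is then a valid null reference for
any test statistic, and the fuzz terms make the resulting p-value continuous
and uniform. Because a permutation whose p-value ties the observed one is
counted with probability $U_{jb} \le U_j$ instead of always, the fuzzy
p-value never exceeds the standard (tie-as-extreme) permutation p-value on
the same permutation stream — the method is at least as powerful, uniformly.

# Tunable parameters

* `epsilon` (default `1e-12`): the fuzz scale. It must sit above the
  double-precision resolution (~1e-16) and below the smallest gap between
  distinct p-values; `1e-12` satisfies both for any realistic input. A
  larger value (e.g. `1e-6`) is only useful to make the fuzzified digits
  visible in worked examples via `fuzzify()`.
* `k` (default 1000): permutations. The permutation p-value has granularity
  $1/k$; k = 1000 supports q-value analysis down to q ≈ 0.01 at the
  benchmark scale, k = 5000 is preferable for final analyses.
* `mode`: `"random"` samples k label assignments uniformly with replacement;
  `"exhaustive"` enumerates all $\binom{n}{n_1}$ assignments once each
  (including the observed assignment — the usual exact-permutation
  convention), capped by `exhaustiveCap` (default 20000). At $n_1 = n_0 = 5$
  exhaustive mode costs only 252 evaluations and removes sampling noise.
* `addOne` (default `FALSE`): report $(c+1)/(k+1)$ instead of $c/k$. The
  plain proportion matches the algorithm's definition but has an atom at 0:
  a null variable lands at permutation p-value exactly 0 with probability
  $\approx 1/(k+1)$, and such variables get q = 0. At m = 20,000 and
  k = 1000 this contributes ~20 spurious q = 0 calls under a global null;
  `addOne` removes the atom at the price of a conservative $1/(k+1)$ shift.
  The default follows the plain proportion; choose `addOne` when absolute
  protection at very small q matters more than exact calibration.
* `tieMode`: `"randomized"` is the reference construction above;
  `"fractional"` replaces the per-permutation draws by a single
  discrete-uniform allocation of the tie count per variable
  (`fractionalCountPValue()`), which has the identical distribution — the
  number of ties beaten is Binomial($T$, $U_j$), whose marginal over $U_j$
  is uniform on $\{0, \dots, T\}$. The equivalence is verified empirically
  in the test suite (two-sample KS over $10^4$ replicates).
* `pi0Method`: `"smoother"` (default) is Storey's spline extrapolation of
  $\hat\pi_0(\lambda) = \#\{p_j > \lambda\}/(m(1-\lambda))$ over
  $\lambda = 0.05, 0.10, \dots, 0.95$; `"fixed"` uses a single
  $\lambda = 0.5$. The q-value step-up is
  $q_{(i)} = \min_{t \ge i} \hat\pi_0\, m\, p_{(t)}/t$, capped at 1.
  An alternative family of $\pi_0$ estimators (Grenander-based, as in
  fdrtool) exists; the Storey construction is used here because it is the
  one the q-value definition is built on, and $\hat\pi_0$ is always
  reported alongside the q-values so the scaling is transparent.

# Numerical conventions

**The small-$\varepsilon$ limit.** The engine evaluates the comparison
$\tilde p^*_{jb} \le \tilde p_j$ in its exact limit form: permutations with
$p^*_{jb} < p_j$ always count, permutations tied with the observed p-value
count iff $U_{jb} \le U_j$. This is identical to adding $\varepsilon U$
whenever $\varepsilon$ is below the smallest nonzero p-value gap (which the
default guarantees), and it is robust where literal floating-point addition
is not: assignments that are mathematically tied — the label swap when
$n_1 = n_0$, or equal value configurations in tied data — can differ in the
last bits between two evaluation orders, and an exact `==` would break such
ties arbitrarily instead of by the fuzz draw. Ties are therefore detected
with a relative tolerance of `1e-8`, far above rounding noise (~1e-16) and
far below any genuine gap between distinct permutation p-values. The test
suite checks the engine bit-for-bit against a literal brute-force
enumeration on small instances under this shared convention.

**Wilcoxon exactness.** Rows without ties use the closed-form exact
rank-sum distribution (any $n \le 25$). Rows with tied observations use
mid-ranks, whose exact null distribution depends on the observed tie
pattern; it is enumerated over all $\binom{n}{n_1}$ assignments when that
count is at most `enumCap` (default 20000, covering every $n \le 15$ and in
particular the 5+5 design), and approximated by a tie-corrected normal
beyond. Two-sided p-values are twice the smaller tail, observed point
included, capped at 1.

**Degenerate t statistics.** A variable with zero pooled variance and zero
mean difference (a constant variable is the common case) is defined to have
p = 1 — every permutation reproduces it, so its permutation p-value is 1 as
well. Zero pooled variance with separated means is the $|t| \to \infty$
limit and yields p = 0.

**RNG discipline.** All randomness in one run flows from a single seed in a
fixed order: permutation stream first, then the observed-p fuzz draws, then
per-permutation draws in permutation order. Fuzzy and standard runs with
the same seed therefore share their permutation stream (the dominance
property is testable run-to-run), and every result is bit-reproducible.

# The synthetic-data generator

`simScenario()`/`simulateDataset()` generate independent variables from four
families, null variables identically distributed in both groups, non-null
variables drawn from the family's alternative parameters in the case group
only:

| family | null | strong alternative | weak alternative |
|---|---|---|---|
| normal | N(0, 1) | N(3, 1) | N(1, 1) |
| gamma | shape 2, scale 1 | shape 10, scale 1 | shape 3, scale 1 |
| truncated normal | N(0,1) on [−2, 2] | N(3,1) on [−2, 2] | N(1,1) on [−2, 2] |
| beta | Beta(0.3, 0.6) | Beta(20, 0.5) | Beta(10, 1) |

Signal-to-noise: "high" = 10% of variables non-null, "low" = 1%. Group
sizes default to 5 + 5, the regime the method targets.

Rationale for the choices that were genuinely open:

* **Families** span the qualitative regimes of interest: a well-behaved
  symmetric family (normal), a skewed positive family (gamma), a bounded
  light-tailed family (truncated normal), and a bounded *bathtub-shaped*
  family (beta with both shape parameters below 1). The bathtub shape is
  the deliberate stressor of the t test: samples of five cluster at either
  boundary, producing occasional near-zero within-group variance and hence
  a severely inflated far tail of null t p-values (~6× at p ≈ 1e-4, ~30× at
  1e-5, measured at 5+5). Mildly skewed betas with one shape parameter
  above 1 do **not** produce this failure at the relevant tail — their raw-t
  rejection sets at q ≤ 0.01 are simply empty at m = 20,000 — which is why
  the null is bathtub-shaped here.
* **Effect sizes.** Strong effects are sized so that the FDP-versus-q curve
  beyond rank 500 (see below) populates q < 0.10 at the default benchmark
  scale: with a 2-sd shift at 5+5 the 501st smallest q-value is already
  ~0.15 and the calibration band q ∈ [0.02, 0.10] is empty, so strong means
  a 3-sd shift (and the gamma/beta analogues above). Weak effects (1 sd and
  analogues) give partial power at best — they exist to show behaviour when
  signals barely separate.
* **Truth mask** occupies the first `round(m * propNonnull)` rows;
  variables are independent, so position carries no information.

What the generator does *not* emulate: correlation between variables,
batch/technical structure, heavy-tailed measurement noise, or the tail
behaviour of any particular real platform. Passing the benchmark therefore
shows calibration and power properties under independence and the chosen
families — it does not certify behaviour under strong dependence, where FDP
around its expectation is far more variable.

# The FDP benchmark

`evaluateFdpCurve()` sorts q-values and reports, from `startRank` (default
501) upward, the realized false discovery proportion among the r smallest
q-values against the r-th q-value; the first 500 ranks are skipped because
FDPs with small denominators are noise. `runBenchmark()` crosses scenarios
with six method tags (`t_raw`, `wilcoxon_raw`, `fuzzy_perm_t`,
`fuzzy_perm_wilcoxon`, `std_perm_t`, `std_perm_wilcoxon`) and collects
q-values, FDP curves and discovery counts at α ∈ {0.01, 0.05, 0.10, 0.20,
0.40}, with each cell's analysis seed derived deterministically from the
scenario seed.

The package's default benchmark scale is m = 20,000 variables and k = 1,000
permutations — large enough for stable FDP curves and π₀ estimates, small
enough to run a full scenario in seconds on one core; a full-scale run
(m = 100,000, k = 5,000) is a matter of passing those values. The test
suite exercises the benchmark at these defaults: fuzzy permutation FDP
tracks nominal q within 0.02 on normal and gamma data, the three discrete
tests make no calls below q = 0.1 in the low-signal normal scenario, and
the raw t test's FDP at q ≤ 0.01 under the beta scenario is inflated several
fold.

# Known limitations

* The permutation p-value floor is 0 under the default counting convention
  (see `addOne` above); at q thresholds below ~1/k interpret discoveries
  accordingly.
* With $n_1 = n_0 = 5$ there are only 252 distinct assignments; random mode
  resamples them, and k ≫ 252 buys granularity of the fuzzy tie-breaks, not
  new permutations.
* π₀ estimation on heavily discrete p-values (the raw Wilcoxon and standard
  permutation comparators) is error-prone; this is faithfully reproduced —
  it is part of why those pipelines are conservative — and π₀ is always
  reported.
* The Wilcoxon tied-row path falls back to a tie-corrected normal
  approximation when $\binom{n}{n_1}$ exceeds `enumCap`; at such sample
  sizes discreteness is no longer the binding problem.
* Variables are treated as exchangeable under a global label permutation;
  covariate adjustment and stratified permutation are out of scope.
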