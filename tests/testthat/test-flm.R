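# The point-wise permutation F machinery: the per-point one-way ANOVA
# oracle, invariances, the paired-swap algebra, exact enumeration,
# counting rules and interval extraction.

# independent scalar oracle: one-way ANOVA F from stats::anova
anovaF <- function(a, b) {
  g <- factor(rep(c("A", "B"), c(length(a), length(b))))
  stats::anova(stats::lm(c(a, b) ~ g))$`F value`[1]
}

test_that("pointwiseF equals the scalar one-way ANOVA oracle", {
  set.seed(7)
  for (rep in 1:20) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1); G <- 12
    A <- matrix(rnorm(nA * G, 10, 3), nA, G)
    B <- matrix(rnorm(nB * G, 11, 3), nB, G)
    f <- pointwiseF(A, B)
    fOracle <- vapply(seq_len(G), function(t) anovaF(A[, t], B[, t]),
                      numeric(1))
    expect_equal(f, fOracle, tolerance = 1e-10)
  }
})

test_that("constant groups {1,2,3} vs {4,5,6} give F = 13.5 everywhere", {
  A <- matrix(rep(1:3, 5), 3, 5)
  B <- matrix(rep(4:6, 5), 3, 5)
  f <- pointwiseF(A, B)
  expect_equal(f, rep(anovaF(1:3, 4:6), 5))
  expect_equal(f, rep(13.5, 5))
})

test_that("identical groups give F = 0; degenerate variances are flagged", {
  A <- matrix(rnorm(12), 3, 4)
  expect_equal(pointwiseF(A, A[c(2, 1, 3), ]), rep(0, 4))
  # zero within, non-zero between -> Inf sentinel
  A2 <- matrix(1, 3, 2); B2 <- matrix(2, 3, 2)
  expect_equal(pointwiseF(A2, B2), c(Inf, Inf))
  # both zero -> 0
  expect_equal(pointwiseF(A2, A2), c(0, 0))
})

test_that("F is invariant to location shifts and group relabeling", {
  set.seed(8)
  A <- matrix(rnorm(20), 4, 5); B <- matrix(rnorm(25), 5, 5)
  expect_equal(pointwiseF(A + 100, B + 100), pointwiseF(A, B),
               tolerance = 1e-9)
  expect_equal(pointwiseF(B, A), pointwiseF(A, B))
})

test_that("the paired-swap batch algebra equals explicit relabeling", {
  set.seed(9)
  n <- 6; G <- 10
  A <- matrix(rnorm(n * G, 5), n, G)
  B <- matrix(rnorm(n * G, 6), n, G)
  masks <- permuteLabels(n, exact = TRUE)
  fast <- CircadianFLM:::pairedPermutationF(A, B, masks)
  for (p in seq_len(nrow(masks))) {
    sw <- masks[p, ]
    Ap <- A; Bp <- B
    Ap[sw, ] <- B[sw, ]; Bp[sw, ] <- A[sw, ]
    expect_equal(fast[p, ], pointwiseF(Ap, Bp), tolerance = 1e-9)
  }
})

test_that("paired label swaps enumerate 2^n assignments incl. identity", {
  m <- permuteLabels(4, exact = TRUE)
  expect_equal(dim(m), c(16, 4))
  expect_equal(nrow(unique(m)), 16)
  expect_true(any(rowSums(m) == 0))  # identity assignment present
  m15 <- permuteLabels(15, exact = TRUE)
  expect_equal(nrow(m15), 32768)
})

test_that("the permutation stream is reproducible under a fixed seed", {
  set.seed(33); a <- permuteLabels(8, nPerm = 50)
  set.seed(33); b <- permuteLabels(8, nPerm = 50)
  expect_identical(a, b)
})

smallProfiles <- function(n = 4, seed = 171, model = ActivityModel(),
                          G = 48) {
  tr <- smallTrial(n = n, seed = seed, model = model)
  lab <- classifyEpochs(tr$activity, tr$diary, tr$design)
  buildDailyProfiles(lab, gridSize = G)
}

test_that("exhaustive enumeration equals the unique-draw sampler", {
  prof <- smallProfiles(n = 4, seed = 181)
  exact <- suppressWarnings(
    pointwisePermutationTest(prof, nPerm = 16, seed = 1, exact = TRUE))
  sampled <- suppressWarnings(
    pointwisePermutationTest(prof, nPerm = 16, seed = 2,
                             uniquePerms = TRUE))
  expect_equal(exact@nPerm, 16L)
  # identical permutation distribution at every grid point
  expect_equal(apply(exact@Fperm, 2, sort), apply(sampled@Fperm, 2, sort),
               tolerance = 1e-12)
  # identity assignment reproduces the observed F inside the ensemble
  expect_true(all(apply(
    abs(exact@Fperm - rep(exact@Fobs, each = 16)) < 1e-9, 2, any)))
})

test_that("p-values follow the strict-greater counting rule", {
  prof <- smallProfiles(n = 4, seed = 191)
  res <- pointwisePermutationTest(prof, nPerm = 40, seed = 3)
  expect_true(all(res@pCurve >= 0 & res@pCurve <= 1))
  expect_true(all(abs(res@pCurve * res@nPerm -
                        round(res@pCurve * res@nPerm)) < 1e-9))
  byHand <- colMeans(res@Fperm > rep(res@Fobs, each = res@nPerm))
  expect_equal(res@pCurve, byHand)
  # plus-one convention as the alternative
  res2 <- pointwisePermutationTest(prof, nPerm = 40, seed = 3,
                                   pRule = "plusone")
  expect_equal(res2@pCurve,
               (1 + colSums(res2@Fperm > rep(res2@Fobs, each = 40))) / 41)
})

test_that("the critical curve is the nearest-rank empirical quantile", {
  prof <- smallProfiles(n = 4, seed = 201)
  res <- pointwisePermutationTest(prof, nPerm = 40, alpha = 0.05, seed = 4)
  r <- ceiling(0.95 * 40)
  expect_equal(res@critCurve,
               apply(res@Fperm, 2, function(col) sort(col)[r]))
  # significance <=> strictly above the critical curve, minLength 0
  sig <- res@Fobs > res@critCurve
  expect_equal(intervalsToMask(res@intervals)[res@grid %/% 1 + 1][sig],
               rep(TRUE, sum(sig)))
})

test_that("group relabeling leaves F_obs and the p-curve unchanged", {
  prof <- smallProfiles(n = 4, seed = 211)
  a <- pointwisePermutationTest(prof, nPerm = 64, seed = 5,
                                conditions = c("drug", "placebo"))
  b <- pointwisePermutationTest(prof, nPerm = 64, seed = 5,
                                conditions = c("placebo", "drug"))
  expect_equal(a@Fobs, b@Fobs)
  expect_equal(a@pCurve, b@pCurve)
})

test_that("few permutations relative to alpha triggers a warning", {
  prof <- smallProfiles(n = 4, seed = 221)
  expect_warning(pointwisePermutationTest(prof, nPerm = 10, alpha = 0.05,
                                          seed = 6),
                 "unstable")
})

test_that("paired scheme demands one curve per subject and condition", {
  prof <- smallProfiles(n = 4, seed = 231)
  broken <- prof[, -1]
  expect_error(pointwisePermutationTest(broken, nPerm = 20, seed = 1),
               "paired scheme requires")
})

test_that("interval extraction merges runs across midnight", {
  G <- 144
  mask <- rep(FALSE, G)
  # significant 23:00-24:00 (cells 139-144) and 00:00-06:00 (cells 1-36)
  mask[139:144] <- TRUE
  mask[1:36] <- TRUE
  mc <- rbind(drug = rep(1, G), placebo = rep(2, G))
  iv <- CircadianFLM:::significantIntervalsCore(
    mask, (seq_len(G) - 0.5) * 10, mc, c("drug", "placebo"), minLength = 0)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 1380)
  expect_equal(iv$end, 360)
  expect_equal(iv$length, 420)
  expect_equal(iv$higher, "placebo")
})

test_that("interval extraction filters short runs and handles edge cases", {
  G <- 144
  mc <- rbind(drug = rep(2, G), placebo = rep(1, G))
  none <- CircadianFLM:::significantIntervalsCore(
    rep(FALSE, G), (seq_len(G) - 0.5) * 10, mc, c("drug", "placebo"), 0)
  expect_equal(nrow(none), 0)
  # alternating single significant cells vanish under minLength = 15
  alt <- rep(c(TRUE, FALSE), length.out = G)
  iv <- CircadianFLM:::significantIntervalsCore(
    alt, (seq_len(G) - 0.5) * 10, mc, c("drug", "placebo"), minLength = 15)
  expect_equal(nrow(iv), 0)
  # fully significant clock
  full <- CircadianFLM:::significantIntervalsCore(
    rep(TRUE, G), (seq_len(G) - 0.5) * 10, mc, c("drug", "placebo"), 0)
  expect_equal(full$length, 1440)
  expect_equal(full$higher, "drug")
})

test_that("the test is deterministic given profiles and seed", {
  prof <- smallProfiles(n = 4, seed = 241)
  a <- pointwisePermutationTest(prof, nPerm = 30, seed = 11)
  b <- pointwisePermutationTest(prof, nPerm = 30, seed = 11)
  expect_equal(a@Fperm, b@Fperm)
  expect_equal(a@intervals, b@intervals)
})
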