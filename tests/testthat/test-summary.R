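# The summary (traditional) arm: night/day means, the mixed model with
# exact-recovery and calibration oracles, and AICc model averaging
# against its hand-computed identity.

test_that("summary means reproduce simple arithmetic", {
  # night of 450 NTA minutes totalling 900 counts -> mean 2.0
  counts <- rep(0L, 2 * 1440)
  nightIdx <- c(1381:1440, 1440 + 1:390)  # 23:00 day1 .. 06:30 day2
  counts[nightIdx] <- 2L
  act <- constantEpochs(days = 2, count = counts)
  diary <- uniformDiary("s1", as.Date("2018-04-02") + (-1:2),
                        "23:00", "06:30")
  design <- TrialDesign("s1", periodLength = 2, washoutLength = 0,
                        sequence = c("drug"))
  lab <- classifyEpochs(act, diary, design)
  st <- summarizeDayNight(lab)
  night1 <- st[st$segment == "NTA" & st$date == as.Date("2018-04-02"), ]
  expect_equal(night1$n_minutes, 450)
  expect_equal(night1$mean_count, 2.0)
})

test_that("minute-weighted NTA and DTA means recover the overall mean", {
  tr <- smallTrial(n = 3, seed = 251)
  lab <- classifyEpochs(tr$activity, tr$diary, tr$design)
  st <- summarizeDayNight(lab)
  total <- sum(st$mean_count * st$n_minutes)
  expect_equal(sum(st$n_minutes),
               nrow(epochTable(tr$activity)))
  expect_equal(total / sum(st$n_minutes),
               mean(epochTable(tr$activity)$count))
})

# constructed summary table: the response is subject intercept +
# delta * weekend plus a +/- epsilon perturbation within duplicated-row
# pairs. The perturbation is orthogonal to every regressor and to the
# per-subject sums, so the mixed-model weekend estimate is exactly delta
# while the fit stays non-degenerate.
exactTable <- function(delta = 0.4, nSubj = 6, nPairs = 5) {
  subj <- sprintf("s%02d", seq_len(nSubj))
  base <- seq(2, 4, length.out = nSubj)
  rows <- expand.grid(subject_id = subj, pair = seq_len(nPairs),
                      half = 1:2, stringsAsFactors = FALSE)
  rows$weekend <- rows$pair %in% c(2, 4)
  rows$condition <- ifelse(rows$pair <= 3, "drug", "placebo")
  eps <- 0.05 * rows$pair * ifelse(rows$half == 1, 1, -1)
  rows$mean_count <- base[match(rows$subject_id, subj)] +
    delta * rows$weekend + eps
  rows$idx <- (rows$pair - 1) * 2 + rows$half
  rows$segment <- "NTA"
  rows$date <- as.Date("2018-04-02") + rows$idx
  rows$n_minutes <- 450
  cov <- data.frame(subject_id = subj,
                    age = rep(c(8, 12.5, 9, 13, 10.5, 11),
                              length.out = nSubj),
                    weight = rep(c(25, 38, 31, 27, 35, 29),
                                 length.out = nSubj),
                    sex = rep(c("F", "M"), length.out = nSubj),
                    cbpi = rep(c(2, 5, 3.5, 6, 2.5, 4),
                               length.out = nSubj))
  merge(rows, cov, by = "subject_id")
}

test_that("a noise-free weekend effect is recovered exactly", {
  delta <- 0.4
  tab <- exactTable(delta = delta)
  fit <- suppressWarnings(
    fitActivityLMM(tab, "NTA", transform = "none", standardize = FALSE))
  expect_equal(unname(fit$coefficients["weekend", "Estimate"]), delta,
               tolerance = 1e-6)
  expect_lt(abs(fit$coefficients["treatment", "Estimate"]), 1e-6)
})

test_that("covariate rescaling leaves standardized estimates unchanged", {
  tr <- smallTrial(n = 6, seed = 261, periodLength = 6, washoutLength = 2)
  lab <- classifyEpochs(tr$activity, tr$diary, tr$design)
  st <- summarizeDayNight(lab, tr$cohort)
  st2 <- st
  st2$weight <- st2$weight * 1000  # kg -> g
  f1 <- suppressWarnings(fitActivityLMM(st, "NTA"))
  f2 <- suppressWarnings(fitActivityLMM(st2, "NTA"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("treatment rejection is calibrated on exchangeable null tables", {
  # summary tables built directly under the null: subject intercepts
  # plus noise, conditions assigned by period
  set.seed(271)
  nrep <- 200
  rej <- logical(nrep)
  subj <- sprintf("s%02d", 1:10)
  for (r in seq_len(nrep)) {
    rows <- expand.grid(subject_id = subj, idx = 1:14,
                        stringsAsFactors = FALSE)
    rows$condition <- ifelse(rows$idx <= 7, "drug", "placebo")
    rows$weekend <- rows$idx %% 7 < 2
    rows$segment <- "NTA"
    rows$mean_count <- exp(rnorm(10)[match(rows$subject_id, subj)] +
                             rnorm(nrow(rows), 0, 0.4))
    rows$age <- rnorm(10, 10, 2)[match(rows$subject_id, subj)]
    rows$weight <- rnorm(10, 30, 5)[match(rows$subject_id, subj)]
    rows$sex <- rep(c("F", "M"), 5)[match(rows$subject_id, subj)]
    rows$cbpi <- rnorm(10, 4, 1)[match(rows$subject_id, subj)]
    fit <- suppressWarnings(fitActivityLMM(rows, "NTA"))
    rej[r] <- fit$coefficients["treatment", "P(>|z|)"] < 0.05
  }
  p <- mean(rej)
  expect_lt(abs(p - 0.05), 3 * sqrt(0.05 * 0.95 / nrep) + 0.01)
})

test_that("a single candidate collapses model averaging to that fit", {
  tab <- exactTable()
  avg <- suppressWarnings(
    modelAverage(tab, "NTA", transform = "none", standardize = FALSE,
                 candidates = list(c("age", "weight", "sex", "cbpi",
                                     "weekend", "treatment"))))
  single <- suppressWarnings(
    lme4::lmer(mean_count ~ age + weight + sex2 + cbpi + weekend2 +
                 treatment2 + (1 | subject_id),
               data = transform(tab, sex2 = as.numeric(sex == "M"),
                                weekend2 = as.numeric(weekend),
                                treatment2 = as.numeric(condition ==
                                                          "drug")),
               REML = FALSE))
  got <- avg$coefficients["weekend", "Estimate"]
  expect_equal(unname(got), unname(lme4::fixef(single)[["weekend2"]]),
               tolerance = 1e-5)
  expect_equal(nrow(avg$models), 1)
  expect_equal(avg$models$weight, 1)
})

test_that("two-candidate averaging follows the w*b identity", {
  tr <- smallTrial(n = 6, seed = 281, periodLength = 6, washoutLength = 2)
  lab <- classifyEpochs(tr$activity, tr$diary, tr$design)
  st <- summarizeDayNight(lab, tr$cohort)
  avg <- suppressWarnings(
    modelAverage(st, "NTA", candidates = list("weekend", character(0))))

  # independent recomputation of the averaging identity
  d <- CircadianFLM:::lmmFrame(st, "NTA", "log1p", TRUE)
  f1 <- lme4::lmer(response ~ weekend + (1 | subject_id), data = d,
                   REML = FALSE)
  f0 <- lme4::lmer(response ~ 1 + (1 | subject_id), data = d, REML = FALSE)
  aicc <- function(f) {
    ll <- logLik(f); k <- attr(ll, "df"); n <- nobs(f)
    -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  a <- c(aicc(f1), aicc(f0))
  w <- exp(-(a - min(a)) / 2); w <- w / sum(w)
  b <- unname(lme4::fixef(f1)[["weekend"]])
  expect_equal(unname(avg$coefficients["weekend", "Estimate"]), w[1] * b,
               tolerance = 1e-8)
  # unconditional SE per the full-average formula
  seW <- sqrt(vcov(f1)["weekend", "weekend"])
  est <- w[1] * b
  seExp <- w[1] * sqrt(seW^2 + (b - est)^2) + w[2] * abs(0 - est)
  expect_equal(unname(avg$coefficients["weekend", "Std. Error"]),
               unname(seExp), tolerance = 1e-8)
})

test_that("the coefficient table has the canonical column layout", {
  tab <- exactTable()
  avg <- suppressWarnings(
    modelAverage(tab, "NTA", transform = "none", standardize = FALSE,
                 candidates = list("weekend", "treatment")))
  expect_identical(colnames(avg$coefficients),
                   c("Estimate", "Std. Error", "z value", "P(>|z|)"))
  expect_true(all(avg$coefficients[, "P(>|z|)"] >= 0 &
                    avg$coefficients[, "P(>|z|)"] <= 1))
  expect_equal(sum(avg$models$weight), 1)
})
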