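# Monte-Carlo oracles for the activity generator: a flat model recovers
# its mean by the law of large numbers, multiplicative effects recover
# their multipliers as mean ratios, and fixed seeds give bit-identical
# output.

flatModel <- function(mu, ...) {
  ActivityModel(intercept = log(mu), amp24 = 0, amp12 = 0, subjectSd = 0,
                weekendMultiplier = 1,
                effectWindows = nullEffectWindows(), ...)
}

test_that("a flat null model recovers its grand mean (law of large numbers)", {
  mu <- 5
  tr <- smallTrial(n = 2, seed = 21, model = flatModel(mu),
                   periodLength = 20, washoutLength = 5)
  counts <- epochTable(tr$activity)$count
  expect_gte(length(counts), 1e5)
  # NB variance = mu + mu^2/size
  mcse <- sqrt((mu + mu^2 / 12) / length(counts))
  expect_lt(abs(mean(counts) - mu), 4 * mcse)
  expect_true(all(counts >= 0 & counts == round(counts)))
})

test_that("weekend multiplier is recovered as a weekend/weekday mean ratio", {
  m <- flatModel(8)
  m@weekendMultiplier <- 1.5
  tr <- smallTrial(n = 3, seed = 22, model = m, periodLength = 14,
                   washoutLength = 7)
  ep <- epochTable(tr$activity)
  wknd <- isWeekendDate(as.Date(ep$timestamp, tz = "UTC"))
  ratio <- mean(ep$count[wknd]) / mean(ep$count[!wknd])
  expect_lt(abs(ratio - 1.5), 0.05)
})

test_that("a midnight-wrapping drug window halves in-window activity", {
  m <- flatModel(8)
  m@effectWindows <- data.frame(start = 1380, end = 360, multiplier = 0.5)
  tr <- smallTrial(n = 10, seed = 23, model = m, periodLength = 14,
                   washoutLength = 7)
  ep <- epochTable(tr$activity)
  lab <- epochTable(classifyEpochs(tr$activity, tr$diary, tr$design))
  inWin <- inClockWindow(lab$clock_minute, 1380, 360)
  drug <- lab$condition == "drug" & inWin
  plac <- lab$condition == "placebo" & inWin
  expect_gte(sum(lab$label[drug] == "NTA") / 60, 100)  # >= 100 night-hours
  ratio <- mean(lab$count[drug]) / mean(lab$count[plac])
  expect_lt(abs(ratio - 0.5), 0.03)
})

test_that("multiplier-1 windows are exactly the null model", {
  cohort <- smallCohort(4, seed = 31)
  design <- smallDesign(cohort, 3, 1, seed = 32)
  m1 <- flatModel(6)
  m2 <- flatModel(6)
  m2@effectWindows <- data.frame(start = 1380, end = 1440, multiplier = 1)
  a <- simulateActivity(cohort, design, m1, seed = 7)
  b <- simulateActivity(cohort, design, m2, seed = 7)
  expect_identical(epochTable(a$activity), epochTable(b$activity))
  expect_identical(a$diary, b$diary)
})

test_that("activity simulation is deterministic under a fixed seed", {
  cohort <- smallCohort(3, seed = 41)
  design <- smallDesign(cohort, seed = 42)
  a <- simulateActivity(cohort, design, ActivityModel(), seed = 5)
  b <- simulateActivity(cohort, design, ActivityModel(), seed = 5)
  expect_identical(epochTable(a$activity), epochTable(b$activity))
  expect_identical(a$diary, b$diary)
})

test_that("overlapping effect windows are rejected", {
  expect_error(
    ActivityModel(effectWindows = data.frame(
      start = c(1380, 300), end = c(360, 420), multiplier = c(0.5, 1.2))),
    "overlap")
  # wrap-aware: 23:00-06:00 and 06:00-07:00 do not overlap (half-open)
  expect_s4_class(
    ActivityModel(effectWindows = data.frame(
      start = c(1380, 360), end = c(360, 420), multiplier = c(0.5, 1.2))),
    "ActivityModel")
})

test_that("diary times stay within the truncation bounds", {
  tr <- smallTrial(n = 5, seed = 51)
  bed <- parseClock(tr$diary$bed_time)
  bed[bed < 720] <- bed[bed < 720] + 1440  # unwrap past-midnight beds
  expect_true(all(abs(bed - 1380) <= 120))
  rise <- parseClock(tr$diary$rise_time)
  expect_true(all(abs(rise - 390) <= 120))
})

test_that("mean intensity matches the closed-form cosinor", {
  m <- ActivityModel()
  t0 <- c(0, 360, 870)
  expected <- exp(m@intercept +
                    m@amp24 * cos(2 * pi * (t0 - m@phase24) / 1440) +
                    m@amp12 * cos(2 * pi * (t0 - m@phase12) / 720))
  expect_equal(activityIntensity(m, t0), expected)
  # drug condition applies the night-window multiplier inside 23:00-06:00
  expect_equal(activityIntensity(m, 1400, condition = "drug"),
               0.5 * activityIntensity(m, 1400))
  expect_equal(activityIntensity(m, 800, condition = "drug"),
               activityIntensity(m, 800))
})

test_that("questionnaire shifts are recovered in the mean at large n", {
  n <- 1500
  cohort <- simulateCohort(CohortSpec(nSubjects = n, nFemale = n / 2,
                                      nMale = n / 2), seed = 61)
  design <- TrialDesign(cohort, seed = 62)
  eff <- SnoreEffectSpec(baselineSd = rep(0.75, 6))
  sn <- simulateSnore(cohort, design, eff, seed = 63)
  ch <- changeScores(sn, design)
  d3 <- ch$difference[ch$measure == "item3" &
                        ch$contrast == "drug_vs_baseline"]
  se <- sd(d3) / sqrt(length(d3))
  expect_lt(abs(mean(d3) - (-1.80)), 3 * se + 0.02)
})

test_that("zero shifts give zero expected change", {
  n <- 400
  cohort <- simulateCohort(CohortSpec(nSubjects = n, nFemale = 200,
                                      nMale = 200), seed = 71)
  design <- TrialDesign(cohort, seed = 72)
  eff <- SnoreEffectSpec(drugShift = rep(0, 6), placeboShift = rep(0, 6),
                         baselineSd = rep(1, 6))
  sn <- simulateSnore(cohort, design, eff, seed = 73)
  ch <- changeScores(sn, design)
  d <- ch$difference[ch$contrast == "drug_vs_baseline"]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.02)
})

test_that("questionnaire simulation is deterministic and on-scale", {
  cohort <- smallCohort(5, seed = 81)
  design <- smallDesign(cohort, 14, 7, seed = 82)
  a <- simulateSnore(cohort, design, seed = 9)
  b <- simulateSnore(cohort, design, seed = 9)
  expect_identical(a, b)
  items <- as.matrix(a[paste0("item", 1:6)])
  expect_true(all(items >= 0 & items <= 10 & items == round(items)))
  expect_setequal(unique(a$day), c(0, 14, 21, 28, 35))
})
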