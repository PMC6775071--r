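# The night/day classifier: half-open [bed, rise) windows on the
# circular clock, evening-onset attribution, diary fallback, and the
# NTA/DTA partition invariant.

test_that("a 23:00-06:30 night contributes exactly 450 NTA minutes", {
  act <- constantEpochs(days = 2, count = 1)
  dates <- as.Date("2018-04-02") + (-1:2)
  diary <- uniformDiary("s1", dates, "23:00", "06:30")
  design <- TrialDesign("s1", periodLength = 1, washoutLength = 0,
                        sequence = c("drug"))
  lab <- epochTable(classifyEpochs(act, diary, design))
  # night onset day 1: 23:00-24:00 on day 1 plus 00:00-06:30 on day 2
  n1 <- sum(lab$label == "NTA" &
              lab$attr_date == as.Date("2018-04-02"))
  expect_equal(n1, 60 + 360 + 30)
})

test_that("bed and rise minutes follow the half-open convention", {
  act <- constantEpochs(days = 2, count = 1)
  dates <- as.Date("2018-04-02") + (-1:2)
  diary <- uniformDiary("s1", dates, "23:00", "06:30")
  design <- TrialDesign("s1", periodLength = 1, washoutLength = 0,
                        sequence = c("drug"))
  lab <- epochTable(classifyEpochs(act, diary, design))
  atBed <- lab$clock_minute == 23 * 60 & lab$day == 1
  atRise <- lab$clock_minute == 6 * 60 + 30 & lab$day == 2
  expect_true(all(lab$label[atBed] == "NTA"))
  expect_true(all(lab$label[atRise] == "DTA"))
})

test_that("NTA and DTA partition every observed minute", {
  tr <- smallTrial(n = 4, seed = 131)
  lab <- epochTable(classifyEpochs(tr$activity, tr$diary, tr$design))
  expect_equal(nrow(lab), nrow(epochTable(tr$activity)))
  expect_setequal(unique(lab$label), c("NTA", "DTA"))
  perSubj <- table(lab$subject_id, lab$label)
  expect_true(all(rowSums(perSubj) == trialDays(tr$design) * 1440))
})

test_that("classification reproduces the generator's own night windows", {
  tr <- smallTrial(n = 3, seed = 141)
  lab <- epochTable(classifyEpochs(tr$activity, tr$diary, tr$design))
  startPosix <- as.POSIXct(as.character(tr$design@startDate), tz = "UTC")
  for (s in unique(lab$subject_id)) {
    ls <- lab[lab$subject_id == s, ]
    am <- (as.numeric(ls$timestamp) - as.numeric(startPosix)) / 60
    ds <- tr$diary[tr$diary$subject_id == s, ]
    onset <- as.integer(ds$date - tr$design@startDate) + 1L
    bed <- parseClock(ds$bed_time)
    rise <- parseClock(ds$rise_time)
    bedAbs <- ifelse(bed >= 720, (onset - 1) * 1440 + bed,
                     onset * 1440 + bed)
    riseAbs <- bedAbs + ((rise - bedAbs %% 1440) %% 1440)
    inNight <- rep(FALSE, length(am))
    for (k in seq_along(bedAbs))
      inNight <- inNight | (am >= bedAbs[k] & am < riseAbs[k])
    expect_identical(ls$label == "NTA", inNight)
  }
})

test_that("missing diaries fall back to the fixed 00:00-05:00 night", {
  act <- constantEpochs(days = 3, count = 2)
  design <- TrialDesign("s1", periodLength = 2, washoutLength = 1,
                        sequence = c("placebo"))
  lab <- epochTable(classifyEpochs(act, NULL, design))
  expect_equal(sum(lab$label == "NTA"), 3 * 300)
  expect_true(all(lab$clock_minute[lab$label == "NTA"] < 300))
  # the fallback night after evening d is attributed to onset date d
  n2 <- lab[lab$label == "NTA" & lab$day == 2, ]
  expect_true(all(n2$attr_date == as.Date("2018-04-02")))
})

test_that("weekend flags follow onset-date (NTA) and calendar-date (DTA) rules", {
  # 2018-04-02 is a Monday; day 5 = Friday, day 6 = Saturday, day 7 = Sunday
  act <- constantEpochs(days = 7, count = 1)
  dates <- as.Date("2018-04-02") + (-1:7)
  diary <- uniformDiary("s1", dates, "23:00", "06:00")
  design <- TrialDesign("s1", periodLength = 4, washoutLength = 0,
                        sequence = c("drug"))
  lab <- epochTable(classifyEpochs(act, diary, design))
  friNight <- lab$label == "NTA" & lab$attr_date == as.Date("2018-04-06")
  monNight <- lab$label == "NTA" & lab$attr_date == as.Date("2018-04-02")
  satDay <- lab$label == "DTA" & lab$attr_date == as.Date("2018-04-07")
  friDay <- lab$label == "DTA" & lab$attr_date == as.Date("2018-04-06")
  expect_true(all(lab$weekend[friNight]))
  expect_false(any(lab$weekend[monNight]))
  expect_true(all(lab$weekend[satDay]))
  expect_false(any(lab$weekend[friDay]))
})

test_that("night epochs inherit the onset evening's condition", {
  tr <- smallTrial(n = 2, seed = 151, periodLength = 3, washoutLength = 1)
  lab <- epochTable(classifyEpochs(tr$activity, tr$diary, tr$design))
  s <- lab$subject_id[1]
  first <- tr$design@sequence[[s]]
  # after midnight on day 4 (washout day), night epochs still carry the
  # period-1 condition of their day-3 onset
  sel <- lab$subject_id == s & lab$day == 4 & lab$label == "NTA" &
    lab$clock_minute < 300
  expect_true(all(lab$condition[sel] == first))
  # daytime epochs on day 4 are washout
  selD <- lab$subject_id == s & lab$day == 4 & lab$label == "DTA"
  expect_true(all(lab$condition[selD] == "washout"))
})

test_that("epochs outside the design span are rejected", {
  act <- constantEpochs(days = 3, count = 1)
  design <- TrialDesign("s1", periodLength = 1, washoutLength = 0,
                        sequence = c("drug"))
  expect_error(classifyEpochs(act, NULL, design), "outside the design span")
})
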