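# Shared fixtures: a small crossover trial keeps unit tests fast; the
# full-size trial (15 subjects, 14-day periods, 7-day washout) is built
# only where a test needs the study-scale configuration.

smallCohort <- function(n = 6, seed = 11) {
  simulateCohort(CohortSpec(nSubjects = n, nFemale = ceiling(n / 2),
                            nMale = floor(n / 2)), seed = seed)
}

smallDesign <- function(cohort, periodLength = 4, washoutLength = 2,
                        seed = 12) {
  TrialDesign(cohort, periodLength = periodLength,
              washoutLength = washoutLength, seed = seed)
}

smallTrial <- function(n = 6, seed = 13, model = ActivityModel(),
                       periodLength = 4, washoutLength = 2) {
  cohort <- smallCohort(n, seed = seed)
  design <- smallDesign(cohort, periodLength, washoutLength,
                        seed = seed + 1)
  sim <- simulateActivity(cohort, design, model, seed = seed + 2)
  list(cohort = cohort, design = design, activity = sim$activity,
       diary = sim$diary, model = model)
}

fullTrial <- function(seed, model = ActivityModel()) {
  cohort <- simulateCohort(CohortSpec(), seed = seed)
  design <- TrialDesign(cohort, seed = seed + 1)
  sim <- simulateActivity(cohort, design, model, seed = seed + 2)
  list(cohort = cohort, design = design, activity = sim$activity,
       diary = sim$diary, model = model)
}

# Hand-built epoch table: one subject, given days x 1440 minutes of
# constant (or supplied) counts, starting at `startDate`.
constantEpochs <- function(subject = "s1", days = 1, count = 2,
                           startDate = as.Date("2018-04-02")) {
  nmin <- days * 1440L
  ts <- as.POSIXct(as.character(startDate), tz = "UTC") +
    (seq_len(nmin) - 1L) * 60
  counts <- if (length(count) == nmin) count else rep(count, nmin)
  EpochData(data.frame(subject_id = subject, timestamp = ts,
                       count = as.integer(counts),
                       stringsAsFactors = FALSE))
}

# Diary with identical bed/rise every night for the given onset dates.
uniformDiary <- function(subject, dates, bed = "23:00", rise = "06:30") {
  data.frame(subject_id = subject, date = dates, bed_time = bed,
             rise_time = rise, stringsAsFactors = FALSE)
}
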