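#' Construct an EpochData object
#'
#' @param epochs data.frame with columns \code{subject_id} (character),
#'   \code{timestamp} (POSIXct, naive local clock stored as UTC),
#'   \code{count} (non-negative integer), sorted by subject then time.
#' @return An [EpochData-class] object.
#' @export
EpochData <- function(epochs) {
  epochs <- as.data.frame(epochs)
  new("EpochData", epochs = epochs)
}

#' Extract the epoch table
#'
#' @param x an [EpochData-class] or [LabeledEpochs-class].
#' @return the underlying data.frame of minute epochs.
#' @export
epochTable <- function(x) {
  stopifnot(is(x, "EpochData") || is(x, "LabeledEpochs"))
  x@epochs
}

#' Simulate minute-epoch activity and sleep diaries for a crossover trial
#'
#' Generates one integer activity count per subject per minute over the
#' full trial span. Counts are negative binomial with log-mean
#' \code{intercept + two-harmonic cosinor(clock time) + subject random
#' intercept + log(weekendMultiplier) * [Sat/Sun date] +
#' log(window multiplier) * [drug condition and clock time in an effect
#' window]}. A sleep diary row (bed and rise time) is drawn for every
#' night a subject sleeps during the trial, including the night leading
#' into day 1 so early-morning epochs of the first day have a night
#' window.
#'
#' @param cohort data.frame from [simulateCohort()] (only
#'   \code{subject_id} is used here).
#' @param design a [TrialDesign-class]; subjects must match the cohort.
#' @param model an [ActivityModel-class].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list with elements \code{activity} (an [EpochData-class]) and
#'   \code{diary} (data.frame: \code{subject_id}, \code{date} [night
#'   onset date], \code{bed_time}, \code{rise_time} as \code{"HH:MM"}).
#' @examples
#' cohort <- simulateCohort(CohortSpec(nSubjects = 2, nFemale = 1), seed = 1)
#' design <- TrialDesign(cohort, periodLength = 2, washoutLength = 1)
#' sim <- simulateActivity(cohort, design, ActivityModel(), seed = 1)
#' sim$activity
#' @export
simulateActivity <- function(cohort, design, model = ActivityModel(),
                             seed = 1) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1,
            is(design, "TrialDesign"), is(model, "ActivityModel"))
  validObject(design); validObject(model)
  if (!setequal(cohort$subject_id, names(design@sequence)))
    stop("cohort subjects and design sequence do not match", call. = FALSE)
  set.seed(as.integer(seed))

  subjects <- cohort$subject_id
  nS <- length(subjects)
  D <- trialDays(design)
  minutesPerSubj <- D * 1440L

  ## -- diaries: nights with onset day 0 .. D (D + 1 nights per subject).
  ## Bed draws are on an extended clock so a bedtime after midnight
  ## (raw value > 1440) stays attached to its onset evening.
  nNights <- D + 1L
  diary <- vector("list", nS)
  nightStartAbs <- vector("list", nS)
  nightEndAbs <- vector("list", nS)
  for (i in seq_len(nS)) {
    bedRaw <- rtruncnorm(nNights, model@bedMean, model@bedSd, 120)
    riseRaw <- rtruncnorm(nNights, model@riseMean, model@riseSd, 120)
    onsetDay <- 0:D
    nightStartAbs[[i]] <- (onsetDay - 1) * 1440 + round(bedRaw)
    nightEndAbs[[i]] <- onsetDay * 1440 + round(riseRaw)
    diary[[i]] <- data.frame(
      subject_id = subjects[i],
      date = design@startDate + (onsetDay - 1L),
      bed_time = formatClock(round(bedRaw) %% 1440),
      rise_time = formatClock(round(riseRaw)),
      stringsAsFactors = FALSE)
  }
  diary <- do.call(rbind, diary)
  rownames(diary) <- NULL

  ## -- subject random intercepts
  bSubj <- stats::rnorm(nS, 0, model@subjectSd)

  ## -- deterministic clock / calendar structure (same for all subjects)
  minuteOfDay <- rep.int(0:1439, D)
  dayIdx <- rep(seq_len(D), each = 1440L)
  dates <- design@startDate + (seq_len(D) - 1L)
  weekendDay <- isWeekendDate(dates)
  harm <- model@amp24 * cos(2 * pi * ((0:1439) - model@phase24) / 1440) +
    model@amp12 * cos(2 * pi * ((0:1439) - model@phase12) / 720)
  drugMult <- windowMultiplierByMinute(model@effectWindows, model@doseRamp)
  logWknd <- log(model@weekendMultiplier)

  ## shared structure: base log-mean and, per sequence type, the drug
  ## window adjustment over the trial span
  baseLp <- harm[minuteOfDay + 1L] + logWknd * weekendDay[dayIdx]
  logDrug <- log(drugMult)
  drugAdj <- lapply(c(drug = "drug", placebo = "placebo"), function(first) {
    cond <- dayCondition(design, NULL, seq_len(D), first = first)
    adj <- numeric(minutesPerSubj)
    sel <- (cond == "drug")[dayIdx]
    adj[sel] <- logDrug[minuteOfDay[sel] + 1L]
    adj
  })
  counts <- vector("list", nS)
  for (i in seq_len(nS)) {
    lp <- model@intercept + bSubj[i] + baseLp +
      drugAdj[[design@sequence[[subjects[i]]]]]
    counts[[i]] <- stats::rnbinom(minutesPerSubj,
                                  size = model@dispersion, mu = exp(lp))
  }

  startPosix <- as.POSIXct(as.character(design@startDate), tz = "UTC")
  absMin <- (dayIdx - 1L) * 1440L + minuteOfDay
  epochs <- data.frame(
    subject_id = rep(subjects, each = minutesPerSubj),
    timestamp = rep(startPosix + absMin * 60, times = nS),
    count = as.integer(unlist(counts, use.names = FALSE)),
    stringsAsFactors = FALSE)

  list(activity = EpochData(epochs), diary = diary)
}
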