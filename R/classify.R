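## Night/day classification of minute epochs from sleep diaries.
##
## The night of onset date d runs [bed, rise) on the circular clock,
## half-open so the NTA/DTA partition is exact: the epoch at bed_time is
## night, the epoch at rise_time is day. A bed time at or after 12:00
## falls on the onset date itself; an earlier bed time is an
## after-midnight bedtime and falls on the following calendar day. The
## rise time is the first occurrence of that clock time after bed.

## Absolute night windows (minutes since design start) for one subject.
## onsetDay is the trial-day index of the night's evening (0 = night
## before day 1).
nightWindowsAbs <- function(onsetDay, bedMin, riseMin) {
  bedAbs <- ifelse(bedMin >= 720, (onsetDay - 1) * 1440 + bedMin,
                   onsetDay * 1440 + bedMin)
  span <- (riseMin - bedAbs %% 1440) %% 1440
  if (any(span == 0))
    stop("diary night with rise_time equal to bed_time", call. = FALSE)
  cbind(start = bedAbs, end = bedAbs + span)
}

#' Classify minute epochs as night-time or day-time activity
#'
#' Labels every epoch \code{"NTA"} if it falls inside the subject's
#' diary night window \code{[bed, rise)} for some night (on the circular
#' clock, half-open at rise), else \code{"DTA"}. Night epochs are
#' attributed to the night's evening-onset date; their condition is the
#' onset date's condition and they are "weekend" if the onset is a
#' Friday or Saturday. Day epochs keep their own calendar date and are
#' "weekend" on Saturday/Sunday. Nights without a diary row fall back to
#' a fixed default window (default 00:00-05:00, the fixed night
#' definition used before diary-based classification).
#'
#' @param activity an [EpochData-class].
#' @param diary diary data.frame ([readDiary()] schema), or \code{NULL}
#'   to use the default window everywhere.
#' @param design a [TrialDesign-class]; epochs must fall within the
#'   trial span.
#' @param defaultNight length-2 \code{"HH:MM"} vector, the fallback
#'   night window for nights missing from the diary.
#' @return A [LabeledEpochs-class] object.
#' @examples
#' cohort <- simulateCohort(CohortSpec(nSubjects = 2, nFemale = 1), seed = 1)
#' design <- TrialDesign(cohort, periodLength = 2, washoutLength = 1)
#' sim <- simulateActivity(cohort, design, seed = 1)
#' classifyEpochs(sim$activity, sim$diary, design)
#' @export
classifyEpochs <- function(activity, diary, design,
                           defaultNight = c("00:00", "05:00")) {
  stopifnot(is(activity, "EpochData"), is(design, "TrialDesign"))
  ep <- activity@epochs
  startPosix <- as.POSIXct(as.character(design@startDate), tz = "UTC")
  absMin <- as.integer(round(
    (as.numeric(ep$timestamp) - as.numeric(startPosix)) / 60))
  day <- absMin %/% 1440L + 1L
  clockMinute <- absMin %% 1440L
  D <- trialDays(design)
  if (any(day < 1L | day > D))
    stop("activity series extends outside the design span (days ",
         min(day), "..", max(day), " vs 1..", D, ")", call. = FALSE)

  defS <- parseClock(defaultNight[1])
  defE <- parseClock(defaultNight[2])
  n <- length(absMin)
  label <- rep("DTA", n)
  attrDay <- day
  condition <- character(n)
  bySubject <- split(seq_len(n), ep$subject_id)
  ## condition lookup by trial day (0 .. D + 1) per sequence type
  condLookup <- lapply(c(drug = "drug", placebo = "placebo"),
                       function(first)
                         dayCondition(design, NULL, 0:(D + 1L),
                                      first = first))

  for (s in names(bySubject)) {
    sel <- bySubject[[s]]
    am <- absMin[sel]
    needOnset <- (min(am) %/% 1440L):(max(am) %/% 1440L + 1L)

    if (!is.null(diary) && any(diary$subject_id == s)) {
      ds <- diary[diary$subject_id == s, , drop = FALSE]
      onset <- as.integer(ds$date - design@startDate) + 1L
      bed <- parseClock(ds$bed_time)
      rise <- parseClock(ds$rise_time)
    } else {
      onset <- integer(0); bed <- numeric(0); rise <- numeric(0)
    }
    missing <- setdiff(needOnset, onset)
    if (length(missing)) {
      onset <- c(onset, missing)
      bed <- c(bed, rep(defS, length(missing)))
      rise <- c(rise, rep(defE, length(missing)))
    }
    o <- order(onset)
    onset <- onset[o]; bed <- bed[o]; rise <- rise[o]
    win <- nightWindowsAbs(onset, bed, rise)
    if (any(diff(win[, "start"]) <= 0) ||
        any(win[-nrow(win), "end"] > win[-1L, "start"]))
      stop("overlapping or unordered diary nights for subject ", s,
           call. = FALSE)

    idx <- findInterval(am, win[, "start"])
    isNight <- idx >= 1L & am < win[pmax(idx, 1L), "end"]
    label[sel[isNight]] <- "NTA"
    ad <- day[sel]
    ad[isNight] <- onset[idx[isNight]]
    attrDay[sel] <- ad
    condition[sel] <- condLookup[[design@sequence[[s]]]][ad + 1L]
  }

  attrDate <- design@startDate + (attrDay - 1L)
  ## weekend by lookup over the small range of attribution days
  dayRange <- min(attrDay):max(attrDay)
  dateRange <- design@startDate + (dayRange - 1L)
  wkndDay <- isWeekendDate(dateRange)
  wkndNight <- isWeekendNightOnset(dateRange)
  pos <- attrDay - dayRange[1L] + 1L
  isNTA <- label == "NTA"
  weekend <- wkndDay[pos]
  weekend[isNTA] <- wkndNight[pos[isNTA]]
  out <- data.frame(
    subject_id = ep$subject_id, timestamp = ep$timestamp,
    count = ep$count, label = label, condition = condition,
    weekend = weekend, day = day, attr_date = attrDate,
    clock_minute = clockMinute, stringsAsFactors = FALSE)
  new("LabeledEpochs", epochs = out)
}
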