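#' Construct a two-period crossover design
#'
#' @param subjects character vector of subject ids, or a cohort
#'   data.frame as returned by [simulateCohort()].
#' @param periodLength days per treatment period (default 14).
#' @param washoutLength washout days between periods (default 7).
#' @param sequence optional character vector (\code{"drug"} /
#'   \code{"placebo"}) of period-1 conditions, one per subject. If
#'   \code{NULL}, a balanced randomized allocation is drawn using
#'   \code{seed}.
#' @param startDate calendar date of trial day 1 (default a Monday).
#' @param seed seed for the randomized allocation when \code{sequence}
#'   is \code{NULL}.
#' @return A [TrialDesign-class] object.
#' @examples
#' TrialDesign(sprintf("dog%02d", 1:15), seed = 42)
#' @export
TrialDesign <- function(subjects, periodLength = 14, washoutLength = 7,
                        sequence = NULL,
                        startDate = as.Date("2018-04-02"), seed = 1) {
  if (is.data.frame(subjects)) subjects <- subjects$subject_id
  subjects <- as.character(subjects)
  if (is.null(sequence)) {
    set.seed(as.integer(seed))
    n <- length(subjects)
    firsts <- c(rep("drug", ceiling(n / 2)), rep("placebo", floor(n / 2)))
    sequence <- sample(firsts)
  }
  names(sequence) <- subjects
  new("TrialDesign", periodLength = as.integer(periodLength),
      washoutLength = as.integer(washoutLength),
      sequence = sequence, startDate = as.Date(startDate))
}

#' Total number of trial days
#'
#' @param design a [TrialDesign-class].
#' @return integer: \code{2 * periodLength + washoutLength}.
#' @export
trialDays <- function(design) {
  2L * design@periodLength + design@washoutLength
}

#' Condition of each trial day per subject
#'
#' Day 1..periodLength is period 1 (the subject's first condition),
#' followed by washout days (condition \code{"washout"}), then period 2
#' (the other condition). Days outside the trial span (day < 1 or
#' day > total) are \code{"baseline"}.
#'
#' @param design a [TrialDesign-class].
#' @param subject subject id (must appear in the design's sequence);
#'   ignored when \code{first} is given.
#' @param day integer vector of trial day indices.
#' @param first optional period-1 condition overriding the subject
#'   lookup.
#' @return character vector of condition labels.
#' @examples
#' d <- TrialDesign(c("a", "b"), sequence = c("drug", "placebo"))
#' dayCondition(d, "a", c(1, 14, 15, 21, 22, 35))
#' @export
dayCondition <- function(design, subject, day, first = NULL) {
  if (is.null(first))
    first <- unname(design@sequence[as.character(subject)])
  if (length(first) != 1L || is.na(first))
    stop("subject '", subject, "' is not in the design", call. = FALSE)
  second <- if (first == "drug") "placebo" else "drug"
  p <- design@periodLength
  w <- design@washoutLength
  out <- rep("baseline", length(day))
  out[day >= 1 & day <= p] <- first
  out[day > p & day <= p + w] <- "washout"
  out[day > p + w & day <= 2 * p + w] <- second
  out
}

#' Full per-subject, per-day condition calendar
#'
#' @param design a [TrialDesign-class].
#' @return data.frame with columns \code{subject_id}, \code{day},
#'   \code{date}, \code{condition}.
#' @export
conditionCalendar <- function(design) {
  days <- seq_len(trialDays(design))
  subj <- names(design@sequence)
  out <- do.call(rbind, lapply(subj, function(s) {
    data.frame(subject_id = s, day = days,
               date = design@startDate + (days - 1L),
               condition = dayCondition(design, s, days),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Map assessment days to conditions
#'
#' Questionnaire assessments on trial day \code{d} report on the period
#' ending that day; day 0 is baseline, the last day of each treatment
#' period maps to that period's condition, and a day falling in the
#' washout maps to \code{"washout"}.
#'
#' @param design a [TrialDesign-class].
#' @param subject subject id.
#' @param day integer vector of assessment days (0-based trial days).
#' @return character vector of condition labels.
#' @export
assessmentCondition <- function(design, subject, day) {
  out <- dayCondition(design, subject, day)
  out[day == 0] <- "baseline"
  out
}
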