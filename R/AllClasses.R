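#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## Parameter specifications
## ---------------------------------------------------------------------------

#' Cohort specification
#'
#' Describes the population from which subject covariates are drawn:
#' sample size, sex split and the moments of the age, weight and baseline
#' pain-score (CBPI pain sub-score) distributions.
#'
#' @slot nSubjects integer, total number of subjects (>= 2).
#' @slot ageMean,ageSd numeric, years.
#' @slot weightMean,weightSd numeric, kg.
#' @slot cbpiMean,cbpiSd numeric, CBPI pain sub-score units (0-10 scale).
#' @slot nFemale,nMale integer, must sum to \code{nSubjects}.
#'
#' @seealso [CohortSpec()] for the user constructor, [simulateCohort()].
#' @name CohortSpec-class
#' @rdname CohortSpec-class
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    ageMean = "numeric", ageSd = "numeric",
    weightMean = "numeric", weightSd = "numeric",
    cbpiMean = "numeric", cbpiSd = "numeric",
    nFemale = "integer", nMale = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (length(object@nSubjects) != 1L || is.na(object@nSubjects) ||
      object@nSubjects < 2L)
    msgs <- c(msgs, "nSubjects: must be a single integer >= 2")
  for (fld in c("ageSd", "weightSd", "cbpiSd")) {
    v <- slot(object, fld)
    if (length(v) != 1L || is.na(v) || v < 0)
      msgs <- c(msgs, sprintf("%s: must be a single number >= 0", fld))
  }
  for (fld in c("ageMean", "weightMean", "cbpiMean")) {
    v <- slot(object, fld)
    if (length(v) != 1L || is.na(v))
      msgs <- c(msgs, sprintf("%s: must be a single finite number", fld))
  }
  if (length(object@nFemale) != 1L || length(object@nMale) != 1L ||
      is.na(object@nFemale) || is.na(object@nMale) ||
      object@nFemale < 0L || object@nMale < 0L)
    msgs <- c(msgs, "nFemale/nMale: must be single non-negative integers")
  else if (!length(msgs) &&
           object@nFemale + object@nMale != object@nSubjects)
    msgs <- c(msgs, "nFemale + nMale: must equal nSubjects")
  if (length(msgs)) msgs else TRUE
})

#' Two-period crossover trial design
#'
#' Each subject receives both conditions ("drug", "placebo") in the order
#' given by its sequence entry, in two periods of \code{periodLength} days
#' separated by a washout of \code{washoutLength} days. Day 1 is the first
#' calendar day of period 1; washout days carry no condition label.
#'
#' @slot periodLength integer, days per treatment period.
#' @slot washoutLength integer, days of washout between the periods.
#' @slot sequence named character vector, one entry per subject, each
#'   \code{"drug"} or \code{"placebo"} giving the period-1 condition;
#'   names are subject ids.
#' @slot startDate \code{Date}, calendar date of trial day 1.
#'
#' @seealso [TrialDesign()], [conditionCalendar()].
#' @name TrialDesign-class
#' @rdname TrialDesign-class
#' @exportClass TrialDesign
setClass("TrialDesign",
  representation(
    periodLength = "integer",
    washoutLength = "integer",
    sequence = "character",
    startDate = "Date"
  )
)

setValidity("TrialDesign", function(object) {
  msgs <- character()
  if (length(object@periodLength) != 1L || is.na(object@periodLength) ||
      object@periodLength < 1L)
    msgs <- c(msgs, "periodLength: must be a single integer >= 1")
  if (length(object@washoutLength) != 1L || is.na(object@washoutLength) ||
      object@washoutLength < 0L)
    msgs <- c(msgs, "washoutLength: must be a single integer >= 0")
  if (!length(object@sequence) || is.null(names(object@sequence)) ||
      anyDuplicated(names(object@sequence)))
    msgs <- c(msgs, "sequence: must be named by unique subject ids")
  if (!all(object@sequence %in% c("drug", "placebo")))
    msgs <- c(msgs, "sequence: entries must be 'drug' or 'placebo'")
  if (length(object@startDate) != 1L || is.na(object@startDate))
    msgs <- c(msgs, "startDate: must be a single Date")
  if (length(msgs)) msgs else TRUE
})

#' Circadian activity generative model
#'
#' Minute counts are drawn from a negative binomial distribution whose
#' log-mean is a two-harmonic cosinor in clock time plus a subject random
#' intercept, a weekend multiplier, and condition-specific clock-window
#' multipliers (the injectable treatment effect). Windows live on the
#' circular 1440-minute clock; a window with \code{start > end} wraps
#' across midnight.
#'
#' @slot intercept numeric, log counts/min at the cosinor mesor.
#' @slot amp24,phase24 numeric, amplitude (log scale) and acrophase
#'   (clock minute) of the 24-h harmonic.
#' @slot amp12,phase12 numeric, same for the 12-h harmonic.
#' @slot subjectSd numeric >= 0, SD of the per-subject log intercept.
#' @slot weekendMultiplier numeric > 0, multiplies the mean on Saturdays
#'   and Sundays (calendar date of the epoch).
#' @slot dispersion numeric > 0, negative binomial size parameter.
#' @slot effectWindows data.frame with columns \code{start}, \code{end}
#'   (clock minutes; \code{start} in [0, 1440), \code{end} in [0, 1440]
#'   with \code{end <= start} wrapping past midnight) and
#'   \code{multiplier} (> 0); applied to the mean under the drug
#'   condition only. Windows must be pairwise disjoint on the circular
#'   clock.
#' @slot bedMean,bedSd,riseMean,riseSd numeric, clock minutes; nightly
#'   diary bed and rise times are normal draws truncated at +/- 2 h.
#' @slot doseRamp logical; if TRUE the drug window multiplier decays
#'   linearly toward 1 over the hour before evening dosing (18:00),
#'   emulating end-of-dosing-interval loss of effect. Default FALSE.
#'
#' @seealso [ActivityModel()], [simulateActivity()], [activityIntensity()].
#' @name ActivityModel-class
#' @rdname ActivityModel-class
#' @exportClass ActivityModel
setClass("ActivityModel",
  representation(
    intercept = "numeric",
    amp24 = "numeric", phase24 = "numeric",
    amp12 = "numeric", phase12 = "numeric",
    subjectSd = "numeric",
    weekendMultiplier = "numeric",
    dispersion = "numeric",
    effectWindows = "data.frame",
    bedMean = "numeric", bedSd = "numeric",
    riseMean = "numeric", riseSd = "numeric",
    doseRamp = "logical"
  )
)

setValidity("ActivityModel", function(object) {
  msgs <- character()
  scalars <- c("intercept", "amp24", "phase24", "amp12", "phase12",
               "subjectSd", "weekendMultiplier", "dispersion",
               "bedMean", "bedSd", "riseMean", "riseSd")
  for (fld in scalars) {
    v <- slot(object, fld)
    if (length(v) != 1L || !is.finite(v))
      msgs <- c(msgs, sprintf("%s: must be a single finite number", fld))
  }
  if (!length(msgs)) {
    if (object@subjectSd < 0) msgs <- c(msgs, "subjectSd: must be >= 0")
    if (object@weekendMultiplier <= 0)
      msgs <- c(msgs, "weekendMultiplier: must be > 0")
    if (object@dispersion <= 0) msgs <- c(msgs, "dispersion: must be > 0")
    if (object@bedSd < 0 || object@riseSd < 0)
      msgs <- c(msgs, "bedSd/riseSd: must be >= 0")
  }
  ew <- object@effectWindows
  if (!all(c("start", "end", "multiplier") %in% names(ew))) {
    msgs <- c(msgs,
      "effectWindows: needs columns 'start', 'end', 'multiplier'")
  } else if (nrow(ew)) {
    # end == 1440 is the non-wrapping spelling of "to midnight"
    if (any(ew$start < 0 | ew$start >= 1440 | ew$end < 0 | ew$end > 1440))
      msgs <- c(msgs, "effectWindows: start/end must lie in [0, 1440]")
    if (any(ew$multiplier <= 0))
      msgs <- c(msgs, "effectWindows: multiplier must be > 0")
    if (!all(is.na(ew$start)) && circularWindowsOverlap(ew$start, ew$end))
      msgs <- c(msgs,
        "effectWindows: windows overlap on the circular clock")
  }
  if (length(object@doseRamp) != 1L || is.na(object@doseRamp))
    msgs <- c(msgs, "doseRamp: must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Questionnaire effect specification
#'
#' Generative parameters for a 6-item sleep-quality questionnaire scored
#' on an integer scale. Each item has a baseline mean and SD; drug and
#' placebo periods shift the item mean by the corresponding shift.
#' A shared subject effect induces within-subject correlation across
#' items and assessment days.
#'
#' @slot itemNames character(6).
#' @slot baselineMean,baselineSd numeric(6), item score units.
#' @slot drugShift,placeboShift numeric(6), additive shifts applied while
#'   the subject is in the corresponding condition.
#' @slot withinSubjectCor numeric in [0, 1], fraction of score variance
#'   attributed to the shared subject effect.
#' @slot scaleMin,scaleMax numeric, the item scale; generated scores are
#'   rounded and clamped to it.
#'
#' @seealso [SnoreEffectSpec()], [simulateSnore()].
#' @name SnoreEffectSpec-class
#' @rdname SnoreEffectSpec-class
#' @exportClass SnoreEffectSpec
setClass("SnoreEffectSpec",
  representation(
    itemNames = "character",
    baselineMean = "numeric", baselineSd = "numeric",
    drugShift = "numeric", placeboShift = "numeric",
    withinSubjectCor = "numeric",
    scaleMin = "numeric", scaleMax = "numeric"
  )
)

setValidity("SnoreEffectSpec", function(object) {
  msgs <- character()
  n <- length(object@itemNames)
  if (n < 1L) msgs <- c(msgs, "itemNames: at least one item")
  for (fld in c("baselineMean", "baselineSd", "drugShift", "placeboShift"))
    if (length(slot(object, fld)) != n)
      msgs <- c(msgs, sprintf("%s: must have one entry per item", fld))
  if (any(object@baselineSd < 0))
    msgs <- c(msgs, "baselineSd: must be >= 0")
  if (length(object@withinSubjectCor) != 1L ||
      object@withinSubjectCor < 0 || object@withinSubjectCor > 1)
    msgs <- c(msgs, "withinSubjectCor: must be in [0, 1]")
  if (object@scaleMin >= object@scaleMax)
    msgs <- c(msgs, "scaleMin: must be < scaleMax")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Minute-epoch activity data
#'
#' Long-format minute-stamped activity counts for one or more subjects.
#' Timestamps are naive local clock time (stored as UTC POSIXct); within a
#' subject they are strictly increasing with 1-minute spacing inside a day
#' (gaps between days are allowed) and counts are non-negative integers.
#'
#' @slot epochs data.frame with columns \code{subject_id} (character),
#'   \code{timestamp} (POSIXct) and \code{count} (integer).
#'
#' @seealso [EpochData()], [readActivity()], [simulateActivity()].
#' @name EpochData-class
#' @rdname EpochData-class
#' @exportClass EpochData
setClass("EpochData", representation(epochs = "data.frame"))

setValidity("EpochData", function(object) {
  ep <- object@epochs
  msgs <- character()
  need <- c("subject_id", "timestamp", "count")
  if (!all(need %in% names(ep)))
    return("epochs: needs columns subject_id, timestamp, count")
  if (nrow(ep) > 1L) {
    if (!inherits(ep$timestamp, "POSIXct"))
      msgs <- c(msgs, "epochs$timestamp: must be POSIXct")
    if (any(ep$count < 0, na.rm = TRUE) ||
        any(ep$count != round(ep$count), na.rm = TRUE))
      msgs <- c(msgs, "epochs$count: must be non-negative integers")
    # strictly increasing timestamps within subject (sorted by subject)
    # implies both ordering and no duplicate (subject, timestamp) rows
    sameSubj <- ep$subject_id[-1L] == ep$subject_id[-nrow(ep)]
    dt <- diff(as.numeric(ep$timestamp))
    if (any(sameSubj & dt <= 0))
      msgs <- c(msgs,
        "epochs: timestamps must be strictly increasing within subject")
  }
  if (length(msgs)) msgs else TRUE
})

#' Labeled minute epochs
#'
#' An [EpochData-class] table augmented with, per epoch: the night/day
#' label (\code{"NTA"} while inside the diary night window, \code{"DTA"}
#' otherwise), the trial condition (\code{drug}, \code{placebo},
#' \code{washout} or \code{baseline}), the weekend flag, the trial day
#' index and the attribution date (night epochs are attributed to the
#' evening-onset date of their night).
#'
#' @slot epochs data.frame with columns \code{subject_id},
#'   \code{timestamp}, \code{count}, \code{label}, \code{condition},
#'   \code{weekend}, \code{day}, \code{attr_date}, \code{clock_minute}.
#'
#' @seealso [classifyEpochs()], [buildDailyProfiles()],
#'   [summarizeDayNight()].
#' @name LabeledEpochs-class
#' @rdname LabeledEpochs-class
#' @exportClass LabeledEpochs
setClass("LabeledEpochs", representation(epochs = "data.frame"))

setValidity("LabeledEpochs", function(object) {
  ep <- object@epochs
  need <- c("subject_id", "timestamp", "count", "label", "condition",
            "weekend", "day", "attr_date", "clock_minute")
  if (!all(need %in% names(ep)))
    return(paste("epochs: needs columns", paste(need, collapse = ", ")))
  if (nrow(ep)) {
    if (!all(unique(ep$label) %in% c("NTA", "DTA")))
      return("epochs$label: must be 'NTA' or 'DTA'")
    if (!all(unique(ep$condition) %in%
             c("drug", "placebo", "washout", "baseline")))
      return("epochs$condition: invalid condition label")
  }
  TRUE
})

#' Fixed-grid daily activity profiles
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"activity"} assay is a
#' G x N matrix of mean counts/min: one row per clock-grid cell (cell i
#' covers clock minutes [i*1440/G, (i+1)*1440/G)), one column per profile
#' (a subject x condition mean or a single subject-day). The
#' \code{"minutes"} assay holds the number of observed member minutes per
#' cell, used for exact re-binning and coverage accounting; cells with no
#' observed minutes are \code{NA} in the activity assay.
#'
#' Column metadata carries \code{subject_id}, \code{condition},
#' \code{n_days} and \code{coverage} (fraction of non-missing cells);
#' row metadata carries \code{minute_start} and \code{minute_mid}.
#'
#' @seealso [buildDailyProfiles()], [rebinProfiles()],
#'   [pointwisePermutationTest()].
#' @name DailyProfiles-class
#' @rdname DailyProfiles-class
#' @exportClass DailyProfiles
setClass("DailyProfiles", contains = "SummarizedExperiment")

setValidity("DailyProfiles", function(object) {
  msgs <- character()
  if (!all(c("activity", "minutes") %in% assayNames(object)))
    return("assays 'activity' and 'minutes' are required")
  if (1440L %% nrow(object) != 0L)
    msgs <- c(msgs, "grid size must divide 1440")
  a <- assay(object, "activity")
  if (any(a < 0, na.rm = TRUE))
    msgs <- c(msgs, "activity values must be >= 0")
  need <- c("subject_id", "condition")
  if (!all(need %in% colnames(colData(object))))
    msgs <- c(msgs, "colData needs subject_id and condition")
  if (length(msgs)) msgs else TRUE
})

#' Penalized B-spline fit of a daily profile
#'
#' A single 24-hour profile smoothed with a cyclic cubic (order 4)
#' B-spline basis; the roughness penalty is chosen by generalized
#' cross-validation unless a smoothing parameter is fixed. Because clock
#' time is periodic the fitted curve and its first derivative agree at
#' minutes 0 and 1440.
#'
#' @slot basis list with elements \code{nBasis}, \code{order},
#'   \code{circular}, \code{sp} (the smoothing parameter actually used).
#' @slot coefficients numeric, the fitted spline coefficients.
#' @slot grid numeric, clock minutes at which the curve was evaluated.
#' @slot fitted numeric, curve values on \code{grid}.
#' @slot transform character, \code{"none"} or \code{"log1p"}.
#'
#' @seealso [smoothProfile()].
#' @name FunctionalCurve-class
#' @rdname FunctionalCurve-class
#' @exportClass FunctionalCurve
setClass("FunctionalCurve",
  representation(
    basis = "list",
    coefficients = "numeric",
    grid = "numeric",
    fitted = "numeric",
    transform = "character"
  )
)

setValidity("FunctionalCurve", function(object) {
  if (length(object@grid) != length(object@fitted))
    return("grid and fitted must have the same length")
  if (!all(is.finite(object@fitted)))
    return("fitted values must be finite")
  TRUE
})

#' Point-wise permutation F-test result
#'
#' Holds everything the point-wise test produces: the observed F curve,
#' the permutation F ensemble, the point-wise critical curve (empirical
#' 1-alpha permutation quantile), the p-value curve (proportion of
#' permutation F values strictly larger than the observed F), the group
#' mean curves on the transformed scale, and the significant clock-time
#' intervals (maximal runs where the observed F exceeds the critical
#' curve, merged across midnight).
#'
#' @slot grid numeric(G), clock-minute midpoints of the grid cells.
#' @slot Fobs numeric(G), observed F curve (>= 0; may contain Inf where
#'   within-group variance is 0 with non-zero between-group variance).
#' @slot Fperm matrix (nPerm x G) of permutation F curves.
#' @slot critCurve numeric(G), nearest-rank empirical (1-alpha) quantile
#'   of the permutation F values at each grid point.
#' @slot pCurve numeric(G), point-wise permutation p-values.
#' @slot alpha numeric, the significance level.
#' @slot nPerm integer, number of permutations.
#' @slot scheme character, \code{"paired"} or \code{"unpaired"}.
#' @slot pRule character, \code{"greater"} (strict-count, p = b/n) or
#'   \code{"plusone"} (p = (1+b)/(1+n)).
#' @slot seed integer seed that generated the permutation stream.
#' @slot groupLevels character(2), condition labels (A, B).
#' @slot meanCurves matrix (2 x G), group mean smoothed curves on the
#'   transformed scale, rows named by \code{groupLevels}.
#' @slot intervals data.frame of significant intervals (minLength = 0):
#'   columns \code{start}, \code{end} (clock minutes, half-open, wrapped
#'   when start > end), \code{length} (minutes), \code{higher} (which
#'   group's mean curve is higher over the interval).
#'
#' @seealso [pointwisePermutationTest()], [extractSignificantIntervals()],
#'   [plotFLM()].
#' @name FLMResult-class
#' @rdname FLMResult-class
#' @exportClass FLMResult
setClass("FLMResult",
  representation(
    grid = "numeric",
    Fobs = "numeric",
    Fperm = "matrix",
    critCurve = "numeric",
    pCurve = "numeric",
    alpha = "numeric",
    nPerm = "integer",
    scheme = "character",
    pRule = "character",
    seed = "integer",
    groupLevels = "character",
    meanCurves = "matrix",
    intervals = "data.frame"
  )
)

setValidity("FLMResult", function(object) {
  G <- length(object@grid)
  msgs <- character()
  if (length(object@Fobs) != G || length(object@critCurve) != G ||
      length(object@pCurve) != G)
    msgs <- c(msgs, "Fobs, critCurve and pCurve must match the grid")
  if (ncol(object@Fperm) != G)
    msgs <- c(msgs, "Fperm must have one column per grid point")
  if (any(object@Fobs < 0, na.rm = TRUE))
    msgs <- c(msgs, "Fobs must be >= 0")
  if (any(object@pCurve < 0 | object@pCurve > 1))
    msgs <- c(msgs, "pCurve values must lie in [0, 1]")
  if (!object@scheme %in% c("paired", "unpaired"))
    msgs <- c(msgs, "scheme must be 'paired' or 'unpaired'")
  if (length(object@groupLevels) != 2L)
    msgs <- c(msgs, "exactly two group levels are required")
  if (nrow(object@meanCurves) != 2L || ncol(object@meanCurves) != G)
    msgs <- c(msgs, "meanCurves must be a 2 x G matrix")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects (",
      object@nFemale, "F /", object@nMale, "M )\n")
  cat(sprintf("  age %.2f +/- %.2f y | weight %.2f +/- %.2f kg | CBPI %.2f +/- %.2f\n",
              object@ageMean, object@ageSd, object@weightMean,
              object@weightSd, object@cbpiMean, object@cbpiSd))
})

setMethod("show", "TrialDesign", function(object) {
  cat("TrialDesign: 2 x", object@periodLength, "day periods,",
      object@washoutLength, "day washout;",
      length(object@sequence), "subjects\n")
  cat("  start:", format(object@startDate), "| drug-first:",
      sum(object@sequence == "drug"), "| placebo-first:",
      sum(object@sequence == "placebo"), "\n")
})

setMethod("show", "ActivityModel", function(object) {
  cat("ActivityModel (negative binomial, two-harmonic cosinor)\n")
  cat(sprintf("  intercept %.2f | amp24 %.2f @ %d min | amp12 %.2f @ %d min\n",
              object@intercept, object@amp24, as.integer(object@phase24),
              object@amp12, as.integer(object@phase12)))
  cat(sprintf("  subjectSd %.2f | weekend x%.2f | dispersion %.1f\n",
              object@subjectSd, object@weekendMultiplier, object@dispersion))
  if (nrow(object@effectWindows)) {
    cat("  drug effect windows:\n")
    for (i in seq_len(nrow(object@effectWindows)))
      cat(sprintf("    %s-%s x%.2f\n",
                  formatClock(object@effectWindows$start[i]),
                  formatClock(object@effectWindows$end[i]),
                  object@effectWindows$multiplier[i]))
  } else cat("  no drug effect windows (null model)\n")
})

setMethod("show", "SnoreEffectSpec", function(object) {
  cat("SnoreEffectSpec:", length(object@itemNames), "items on [",
      object@scaleMin, ",", object@scaleMax, "] scale\n")
  print(data.frame(item = object@itemNames,
                   baseline = object@baselineMean,
                   sd = object@baselineSd,
                   drug_shift = object@drugShift,
                   placebo_shift = object@placeboShift))
})

setMethod("show", "EpochData", function(object) {
  ep <- object@epochs
  cat("EpochData:", nrow(ep), "minute epochs,",
      length(unique(ep$subject_id)), "subjects\n")
  if (nrow(ep))
    cat("  span:", format(min(ep$timestamp)), "to",
        format(max(ep$timestamp)), "\n")
})

setMethod("show", "LabeledEpochs", function(object) {
  ep <- object@epochs
  cat("LabeledEpochs:", nrow(ep), "epochs,",
      length(unique(ep$subject_id)), "subjects\n")
  if (nrow(ep)) {
    cat("  label:", sum(ep$label == "NTA"), "NTA /",
        sum(ep$label == "DTA"), "DTA\n")
    cat("  condition:", paste(sprintf("%s=%d",
        names(table(ep$condition)), as.vector(table(ep$condition))),
        collapse = " "), "\n")
  }
})

setMethod("show", "DailyProfiles", function(object) {
  cat("DailyProfiles:", ncol(object), "profiles on a", nrow(object),
      "-cell clock grid (", 1440 / nrow(object), "min/cell )\n")
  cd <- colData(object)
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
  cat("  subjects:", length(unique(cd$subject_id)), "\n")
})

setMethod("show", "FunctionalCurve", function(object) {
  cat("FunctionalCurve: cyclic B-spline, nBasis =", object@basis$nBasis,
      ", transform =", object@transform, "\n")
  cat(sprintf("  %d grid points, range [%.3f, %.3f], sp = %.4g\n",
              length(object@grid), min(object@fitted), max(object@fitted),
              object@basis$sp))
})

setMethod("show", "FLMResult", function(object) {
  cat("FLMResult: point-wise permutation F-test (", object@scheme,
      "scheme )\n")
  cat(sprintf("  %d grid points | %d permutations | alpha = %.3f | seed = %d\n",
              length(object@grid), object@nPerm, object@alpha, object@seed))
  cat("  groups:", paste(object@groupLevels, collapse = " vs "), "\n")
  nsig <- sum(object@Fobs > object@critCurve)
  cat(sprintf("  significant grid points: %d / %d (%.1f%%)\n",
              nsig, length(object@grid), 100 * nsig / length(object@grid)))
  if (nrow(object@intervals)) {
    cat("  significant intervals:\n")
    for (i in seq_len(nrow(object@intervals)))
      cat(sprintf("    %s-%s (%d min, %s higher)\n",
                  formatClock(object@intervals$start[i]),
                  formatClock(object@intervals$end[i]),
                  as.integer(object@intervals$length[i]),
                  object@intervals$higher[i]))
  } else cat("  no significant intervals\n")
})
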