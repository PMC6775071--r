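#' Assemble fixed-grid 24-hour activity profiles
#'
#' Collapses labeled minute epochs onto a circular clock grid of
#' \code{gridSize} cells (cell i covers clock minutes
#' \code{[i*1440/G, (i+1)*1440/G)}). With
#' \code{aggregation = "per_condition_mean"} (the default, matching a
#' paired crossover analysis) each profile is one subject x condition:
#' the cell value is the mean count over every member minute of that
#' subject's days in that condition. With \code{aggregation = "per_day"}
#' each profile is one subject-day. Cells with no observed minutes are
#' \code{NA}; profiles whose missing-cell fraction exceeds
#' \code{maxMissing} are dropped with a warning.
#'
#' @param labeled a [LabeledEpochs-class].
#' @param gridSize number of clock cells G; must divide 1440 (default
#'   144, i.e. 10-minute cells).
#' @param aggregation \code{"per_condition_mean"} or \code{"per_day"}.
#' @param conditions conditions to keep for \code{per_condition_mean}
#'   (default \code{c("drug", "placebo")}; washout/baseline epochs are
#'   excluded from treatment profiles).
#' @param maxMissing maximum tolerated fraction of missing cells per
#'   profile (default 0.2).
#' @return A [DailyProfiles-class] object.
#' @examples
#' cohort <- simulateCohort(CohortSpec(nSubjects = 2, nFemale = 1), seed = 1)
#' design <- TrialDesign(cohort, periodLength = 2, washoutLength = 1)
#' sim <- simulateActivity(cohort, design, seed = 1)
#' lab <- classifyEpochs(sim$activity, sim$diary, design)
#' buildDailyProfiles(lab, gridSize = 144)
#' @export
buildDailyProfiles <- function(labeled, gridSize = 144,
                               aggregation = c("per_condition_mean",
                                               "per_day"),
                               conditions = c("drug", "placebo"),
                               maxMissing = 0.2) {
  stopifnot(is(labeled, "LabeledEpochs"))
  aggregation <- match.arg(aggregation)
  G <- as.integer(gridSize)
  if (G < 1L || 1440L %% G != 0L)
    stop("gridSize must divide 1440", call. = FALSE)
  w <- 1440L %/% G
  ep <- labeled@epochs

  epCondition <- ep$condition
  epSubject <- ep$subject_id
  epClock <- ep$clock_minute
  epCount <- ep$count
  epAttrDate <- ep$attr_date

  if (aggregation == "per_condition_mean") {
    condIdx <- match(epCondition, conditions)
    sel <- which(!is.na(condIdx))
    if (!length(sel)) stop("no epochs in the requested conditions",
                           call. = FALSE)
    condIdx <- condIdx[sel]
    epCondition <- epCondition[sel]
    epSubject <- epSubject[sel]
    epClock <- epClock[sel]
    epCount <- epCount[sel]
    epAttrDate <- epAttrDate[sel]
    subjLev <- sort(unique(epSubject))
    subjIdx <- match(epSubject, subjLev)
    nC <- length(conditions)
    ki <- (subjIdx - 1L) * nC + condIdx
    nK <- length(subjLev) * nC
    subj <- rep(subjLev, each = nC)
    second <- rep(conditions, times = length(subjLev))
  } else {
    subjLev <- sort(unique(epSubject))
    subjIdx <- match(epSubject, subjLev)
    dayLev <- sort(unique(ep$day))
    dayIdx <- match(ep$day, dayLev)
    nD <- length(dayLev)
    ki <- (subjIdx - 1L) * nD + dayIdx
    nK <- length(subjLev) * nD
    subj <- rep(subjLev, each = nD)
    fi <- !duplicated(ep$day)
    dayDates <- as.Date(ep$timestamp[fi],
                        tz = "UTC")[match(dayLev, ep$day[fi])]
    second <- format(rep(dayDates, times = length(subjLev)))
  }
  cell <- epClock %/% w                    # 0-based cell index
  slot <- (ki - 1L) * G + cell + 1L

  minutes <- tabulate(slot, nbins = nK * G)
  sums <- numeric(nK * G)
  rs <- rowsum(as.numeric(epCount), slot)
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  act <- sums / minutes
  act[minutes == 0L] <- NA_real_

  actMat <- matrix(act, nrow = G, ncol = nK)
  minMat <- matrix(as.numeric(minutes), nrow = G, ncol = nK)

  ## days aggregated per profile (a profile's member minutes can span
  ## several attribution dates)
  attrDayInt <- as.integer(unclass(epAttrDate))
  pairId <- (ki - 1L) * (diff(range(attrDayInt)) + 2L) +
    (attrDayInt - min(attrDayInt)) + 1L
  nDays <- tabulate(ki[!duplicated(pairId)], nbins = nK)

  ## drop key combinations never observed (e.g. a subject with no days
  ## in one of the requested conditions)
  present <- colSums(minMat) > 0
  if (!all(present)) {
    actMat <- actMat[, present, drop = FALSE]
    minMat <- minMat[, present, drop = FALSE]
    subj <- subj[present]; second <- second[present]
    nDays <- nDays[present]
    presentKi <- which(present)
  } else presentKi <- seq_len(nK)
  nK <- length(presentKi)

  coverage <- colMeans(!is.na(actMat))
  cd <- if (aggregation == "per_condition_mean") {
    S4Vectors::DataFrame(subject_id = subj, condition = second,
                         n_days = nDays, coverage = coverage)
  } else {
    ## a calendar day's epochs can mix conditions at period boundaries
    ## (night epochs keep their onset evening's condition); label the
    ## day profile with its modal condition
    modal <- vapply(split(epCondition, factor(ki, presentKi)),
                    function(v) names(which.max(table(v))), character(1))
    S4Vectors::DataFrame(subject_id = subj, date = as.Date(second),
                         condition = unname(modal),
                         n_days = nDays, coverage = coverage)
  }
  rd <- S4Vectors::DataFrame(minute_start = (seq_len(G) - 1L) * w,
                             minute_mid = (seq_len(G) - 0.5) * w)
  colnames(actMat) <- colnames(minMat) <- paste(subj, second, sep = ".")
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(activity = actMat, minutes = minMat),
    rowData = rd, colData = cd)
  out <- new("DailyProfiles", se)
  if (!is.null(maxMissing)) {
    keep <- (1 - coverage) <= maxMissing
    if (!all(keep)) {
      warning(sum(!keep), " profile(s) dropped: > ",
              round(100 * maxMissing), "% missing cells", call. = FALSE)
      out <- out[, keep]
    }
  }
  out
}

#' Profile accessors
#'
#' \code{profileMatrix} returns the G x N activity assay;
#' \code{profileGrid} the clock-minute midpoints of the grid cells;
#' \code{profileInfo} the column metadata as a data.frame.
#'
#' @param x a [DailyProfiles-class].
#' @return see above.
#' @export
profileMatrix <- function(x) {
  stopifnot(is(x, "DailyProfiles"))
  assay(x, "activity")
}

#' @rdname profileMatrix
#' @export
profileGrid <- function(x) {
  stopifnot(is(x, "DailyProfiles"))
  rowData(x)$minute_mid
}

#' @rdname profileMatrix
#' @export
profileInfo <- function(x) {
  stopifnot(is(x, "DailyProfiles"))
  as.data.frame(colData(x))
}

#' Re-bin profiles to a coarser clock grid
#'
#' Cell values are member-minute-weighted means, so re-binning commutes
#' with profile building: building at G = 1440 and re-binning to G = 144
#' equals building directly at G = 144.
#'
#' @param x a [DailyProfiles-class].
#' @param gridSize target number of cells; must divide the current grid
#'   size.
#' @return A [DailyProfiles-class] on the coarser grid.
#' @export
rebinProfiles <- function(x, gridSize) {
  stopifnot(is(x, "DailyProfiles"))
  G <- nrow(x)
  newG <- as.integer(gridSize)
  if (newG < 1L || G %% newG != 0L)
    stop("gridSize must divide the current grid size ", G, call. = FALSE)
  fold <- G %/% newG
  grp <- rep(seq_len(newG), each = fold)
  a <- assay(x, "activity")
  m <- assay(x, "minutes")
  s <- a * m
  s[is.na(s)] <- 0
  newS <- rowsum(s, grp, reorder = TRUE)
  newM <- rowsum(m, grp, reorder = TRUE)
  newA <- newS / newM
  newA[newM == 0] <- NA_real_
  rownames(newA) <- rownames(newM) <- NULL
  w <- 1440L %/% newG
  rd <- S4Vectors::DataFrame(minute_start = (seq_len(newG) - 1L) * w,
                             minute_mid = (seq_len(newG) - 0.5) * w)
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(activity = newA, minutes = newM),
    rowData = rd, colData = colData(x))
  new("DailyProfiles", se)
}
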