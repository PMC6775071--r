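#' Simulate questionnaire responses over the assessment schedule
#'
#' Produces one row per subject per assessment day (default days 0, 14,
#' 21, 28, 35) with one score per item. A subject's score on item j at
#' an assessment is \code{baselineMean[j] + subject effect + shift[j] +
#' noise}, where the shift is the item's drug or placebo shift if the
#' assessment day falls in the corresponding treatment period (mapped
#' through the subject's randomized sequence) and 0 at baseline or in
#' washout. The subject effect is shared across items and days and
#' carries \code{withinSubjectCor} of the item variance. Scores are
#' rounded and clamped to the item scale unless
#' \code{integerScores = FALSE}.
#'
#' @param cohort data.frame from [simulateCohort()].
#' @param design a [TrialDesign-class].
#' @param effects a [SnoreEffectSpec-class].
#' @param seed integer seed.
#' @param days assessment days (0 = baseline; defaults to the day-0/14/
#'   21/28/35 schedule implied by 14-day periods and a 7-day washout).
#' @param integerScores round and clamp scores to the item scale
#'   (default TRUE).
#' @return data.frame with columns \code{subject_id}, \code{day},
#'   \code{condition}, and \code{item1} ... \code{item6}.
#' @examples
#' cohort <- simulateCohort(CohortSpec(), seed = 1)
#' design <- TrialDesign(cohort, seed = 1)
#' head(simulateSnore(cohort, design, SnoreEffectSpec(), seed = 1))
#' @export
simulateSnore <- function(cohort, design, effects = SnoreEffectSpec(),
                          seed = 1, days = NULL, integerScores = TRUE) {
  stopifnot(is.data.frame(cohort), is(design, "TrialDesign"),
            is(effects, "SnoreEffectSpec"))
  validObject(design); validObject(effects)
  if (is.null(days)) {
    p <- design@periodLength; w <- design@washoutLength
    days <- c(0L, p, p + w, p + w + p %/% 2L, 2L * p + w)
  }
  set.seed(as.integer(seed))
  subjects <- cohort$subject_id
  nS <- length(subjects)
  nI <- length(effects@itemNames)
  rho <- effects@withinSubjectCor

  ## shared subject effect carries rho of each item's variance
  subjEff <- stats::rnorm(nS, 0, sqrt(rho))
  out <- vector("list", nS)
  for (i in seq_len(nS)) {
    cond <- assessmentCondition(design, subjects[i], days)
    scores <- matrix(NA_real_, length(days), nI)
    for (j in seq_len(nI)) {
      shift <- ifelse(cond == "drug", effects@drugShift[j],
                      ifelse(cond == "placebo", effects@placeboShift[j], 0))
      sdItem <- effects@baselineSd[j]
      noise <- stats::rnorm(length(days), 0, sdItem * sqrt(1 - rho))
      scores[, j] <- effects@baselineMean[j] + sdItem * subjEff[i] +
        shift + noise
    }
    if (integerScores)
      scores <- pmin(pmax(round(scores), effects@scaleMin),
                     effects@scaleMax)
    df <- data.frame(subject_id = subjects[i], day = days,
                     condition = cond, stringsAsFactors = FALSE)
    colnames(scores) <- paste0("item", seq_len(nI))
    out[[i]] <- cbind(df, as.data.frame(scores))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
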