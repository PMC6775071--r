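#' Construct a cohort specification
#'
#' Defaults parameterize a cohort of 15 client-owned dogs with
#' osteoarthritis (10 spayed females, 5 neutered males; age
#' 10.29 +/- 2.48 years; weight 31.53 +/- 5.39 kg; baseline CBPI pain
#' sub-score 3.85 +/- 1.5), the population the simulator emulates.
#'
#' @param nSubjects total number of subjects.
#' @param ageMean,ageSd age distribution, years.
#' @param weightMean,weightSd weight distribution, kg.
#' @param cbpiMean,cbpiSd baseline CBPI pain sub-score distribution.
#' @param nFemale,nMale sex split; must sum to \code{nSubjects}.
#' @return A [CohortSpec-class] object.
#' @examples
#' CohortSpec()
#' CohortSpec(nSubjects = 6, nFemale = 3, nMale = 3)
#' @export
CohortSpec <- function(nSubjects = 15, ageMean = 10.29, ageSd = 2.48,
                       weightMean = 31.53, weightSd = 5.39,
                       cbpiMean = 3.85, cbpiSd = 1.5,
                       nFemale = NULL, nMale = NULL) {
  nSubjects <- as.integer(nSubjects)
  if (is.null(nFemale) && is.null(nMale)) {
    nFemale <- as.integer(ceiling(nSubjects * 2 / 3))  # default 2:1 F:M
    nMale <- nSubjects - nFemale
  } else if (is.null(nMale)) {
    nMale <- nSubjects - as.integer(nFemale)
  } else if (is.null(nFemale)) {
    nFemale <- nSubjects - as.integer(nMale)
  }
  new("CohortSpec", nSubjects = nSubjects,
      ageMean = ageMean, ageSd = ageSd,
      weightMean = weightMean, weightSd = weightSd,
      cbpiMean = cbpiMean, cbpiSd = cbpiSd,
      nFemale = as.integer(nFemale), nMale = as.integer(nMale))
}

#' Simulate subject covariates
#'
#' Draws one covariate row per subject: age, weight and baseline CBPI
#' pain sub-score from normal distributions (truncated below at a small
#' positive value so covariates stay physical), and sex assigned to match
#' the spec's counts exactly.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return data.frame with columns \code{subject_id}, \code{age},
#'   \code{weight}, \code{sex} (\code{"F"}/\code{"M"}), \code{cbpi}.
#' @examples
#' head(simulateCohort(CohortSpec(), seed = 1))
#' @export
simulateCohort <- function(spec = CohortSpec(), seed = 1) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(as.integer(seed))
  n <- spec@nSubjects
  ids <- sprintf("dog%02d", seq_len(n))
  age <- pmax(stats::rnorm(n, spec@ageMean, spec@ageSd), 0.5)
  weight <- pmax(stats::rnorm(n, spec@weightMean, spec@weightSd), 1)
  cbpi <- pmin(pmax(stats::rnorm(n, spec@cbpiMean, spec@cbpiSd), 0), 10)
  sex <- sample(c(rep("F", spec@nFemale), rep("M", spec@nMale)))
  data.frame(subject_id = ids, age = age, weight = weight,
             sex = sex, cbpi = cbpi, stringsAsFactors = FALSE)
}
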