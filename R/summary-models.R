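#' Night/day summary table of mean activity
#'
#' The traditional summary the functional analysis is contrasted with:
#' one row per subject x date x segment with the mean count/min over
#' that segment's minutes. Night rows are keyed by the night's
#' evening-onset date and carry its condition and Friday/Saturday
#' weekend flag; day rows are keyed by calendar date.
#'
#' @param labeled a [LabeledEpochs-class].
#' @param covariates optional covariate data.frame
#'   ([readCovariates()] schema) merged onto the rows.
#' @return data.frame with columns \code{subject_id}, \code{date},
#'   \code{segment} (\code{"NTA"}/\code{"DTA"}), \code{mean_count},
#'   \code{n_minutes}, \code{weekend}, \code{condition} and, if
#'   supplied, the covariates.
#' @examples
#' cohort <- simulateCohort(CohortSpec(nSubjects = 2, nFemale = 1), seed = 1)
#' design <- TrialDesign(cohort, periodLength = 2, washoutLength = 1)
#' sim <- simulateActivity(cohort, design, seed = 1)
#' lab <- classifyEpochs(sim$activity, sim$diary, design)
#' head(summarizeDayNight(lab, cohort))
#' @export
summarizeDayNight <- function(labeled, covariates = NULL) {
  stopifnot(is(labeled, "LabeledEpochs"))
  ep <- labeled@epochs
  key <- paste(ep$subject_id, ep$attr_date, ep$label, sep = "\r")
  keyLev <- unique(key)
  ki <- match(key, keyLev)
  nK <- length(keyLev)
  n <- tabulate(ki, nbins = nK)
  s <- numeric(nK)
  rs <- rowsum(as.numeric(ep$count), ki)
  s[as.integer(rownames(rs))] <- rs[, 1L]
  first <- !duplicated(ki)
  out <- data.frame(
    subject_id = ep$subject_id[first],
    date = ep$attr_date[first],
    segment = ep$label[first],
    mean_count = (s / n)[ki[first]],
    n_minutes = n[ki[first]],
    weekend = ep$weekend[first],
    condition = ep$condition[first],
    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$date, out$segment), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(covariates))
    out <- merge(out, covariates, by = "subject_id", sort = FALSE)
  out
}

## Prepare the model frame for the mixed-model arm: filter to one
## segment and the treatment conditions, transform and optionally
## z-score the response, z-score continuous covariates.
lmmFrame <- function(table, segment, transform, standardize) {
  need <- c("subject_id", "segment", "mean_count", "weekend",
            "condition", "age", "weight", "sex", "cbpi")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("summary table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- table[table$segment == segment &
               table$condition %in% c("drug", "placebo"), , drop = FALSE]
  if (length(unique(d$subject_id)) < 2L ||
      length(unique(d$condition)) < 2L)
    stop("need >= 2 subjects and both conditions in segment ", segment,
         call. = FALSE)
  y <- switch(transform, log1p = log1p(d$mean_count),
              none = d$mean_count,
              stop("unknown transform: ", transform, call. = FALSE))
  z <- function(v) if (standardize && stats::sd(v) > 0)
    (v - mean(v)) / stats::sd(v) else v
  data.frame(
    response = z(y),
    age = z(d$age), weight = z(d$weight),
    sex = as.numeric(d$sex == "M"),
    cbpi = z(d$cbpi),
    weekend = as.numeric(d$weekend),
    treatment = as.numeric(d$condition == "drug"),
    subject_id = d$subject_id,
    stringsAsFactors = FALSE)
}

lmmCoefTable <- function(fit) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  z <- abs(est) / se
  data.frame(`Estimate` = est, `Std. Error` = se, `z value` = z,
             `P(>|z|)` = 2 * stats::pnorm(-z),
             check.names = FALSE)
}

#' Fit the night/day summary linear mixed-effects model
#'
#' The comparison arm: response is the (log1p-transformed, z-scored)
#' per-night or per-day mean activity; fixed effects are age, weight,
#' sex, baseline CBPI pain sub-score, weekend and treatment (continuous
#' covariates z-scored); random intercept per subject; REML fitting.
#' Wald z-tests (normal reference) give the p-values.
#'
#' @param table a summary table from [summarizeDayNight()] including
#'   covariates.
#' @param segment \code{"NTA"} (default) or \code{"DTA"}.
#' @param transform response transform, \code{"log1p"} (default) or
#'   \code{"none"}.
#' @param standardize z-score the response and continuous covariates
#'   (default TRUE).
#' @return list of class \code{"activityLMM"}: \code{fit} (the lme4
#'   model), \code{coefficients} (data.frame with columns
#'   \code{Estimate}, \code{Std. Error}, \code{z value},
#'   \code{P(>|z|)}), \code{segment}, \code{singular}.
#' @export
fitActivityLMM <- function(table, segment = c("NTA", "DTA"),
                           transform = c("log1p", "none"),
                           standardize = TRUE) {
  segment <- match.arg(segment)
  transform <- match.arg(transform)
  d <- lmmFrame(table, segment, transform, standardize)
  fit <- lme4::lmer(
    response ~ age + weight + sex + cbpi + weekend + treatment +
      (1 | subject_id),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: subject random-intercept variance ",
            "estimated as 0", call. = FALSE)
  coefs <- lmmCoefTable(fit)
  coefs <- coefs[rownames(coefs) != "(Intercept)", , drop = FALSE]
  structure(list(fit = fit, coefficients = coefs, segment = segment,
                 singular = singular),
            class = "activityLMM")
}

#' @export
print.activityLMM <- function(x, ...) {
  cat("Summary-activity linear mixed model (", x$segment, " segment )\n",
      sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

aiccOf <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Model-averaged coefficients over fixed-effect subsets
#'
#' Fits every candidate fixed-effect subset by maximum likelihood (all
#' subsets of \{age, weight, sex, cbpi, weekend, treatment\} by
#' default, always with the subject random intercept), weights
#' candidates by small-sample AICc, and reports full (zero-substitution)
#' model-averaged estimates with unconditional standard errors
#' (each candidate contributes its estimate, or 0 when the term is
#' absent, weighted by its AICc weight; the SE combines within-model
#' variance and between-model spread). z = |estimate| / SE with
#' two-sided normal p-values.
#'
#' @param table,segment,transform,standardize as in [fitActivityLMM()].
#' @param candidates list of character vectors of fixed-effect names, or
#'   \code{NULL} for all subsets of the six standard effects.
#' @return list of class \code{"averagedCoefficients"}:
#'   \code{coefficients} (data.frame, columns \code{Estimate},
#'   \code{Std. Error}, \code{z value}, \code{P(>|z|)}),
#'   \code{models} (candidate table with \code{formula}, \code{df},
#'   \code{AICc}, \code{delta}, \code{weight}), \code{segment}.
#' @export
modelAverage <- function(table, segment = c("NTA", "DTA"),
                         transform = c("log1p", "none"),
                         standardize = TRUE, candidates = NULL) {
  segment <- match.arg(segment)
  transform <- match.arg(transform)
  d <- lmmFrame(table, segment, transform, standardize)
  terms <- c("age", "weight", "sex", "cbpi", "weekend", "treatment")
  if (is.null(candidates)) {
    candidates <- unlist(lapply(0:length(terms), function(k)
      utils::combn(terms, k, simplify = FALSE)), recursive = FALSE)
  }
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)

  fits <- vector("list", length(candidates))
  aicc <- rep(NA_real_, length(candidates))
  forms <- character(length(candidates))
  for (i in seq_along(candidates)) {
    rhs <- if (length(candidates[[i]]))
      paste(candidates[[i]], collapse = " + ") else "1"
    forms[i] <- paste("response ~", rhs, "+ (1 | subject_id)")
    fit <- tryCatch(
      lme4::lmer(stats::as.formula(forms[i]), data = d, REML = FALSE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   calc.derivs = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate '", forms[i], "' failed (",
              conditionMessage(fit), "); dropped", call. = FALSE)
      next
    }
    fits[[i]] <- fit
    aicc[i] <- aiccOf(fit)
  }
  ok <- !is.na(aicc)
  if (!any(ok)) stop("all candidate fits failed", call. = FALSE)
  delta <- aicc - min(aicc[ok])
  wt <- ifelse(ok, exp(-delta / 2), 0)
  wt <- wt / sum(wt)

  ## only terms that appear in at least one candidate are averaged
  terms <- terms[terms %in% unique(unlist(candidates))]
  est <- se <- stats::setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    b <- v <- numeric(length(candidates))
    for (i in which(ok)) {
      cf <- lme4::fixef(fits[[i]])
      if (tm %in% names(cf)) {
        b[i] <- cf[[tm]]
        v[i] <- stats::vcov(fits[[i]])[tm, tm]
      }
    }
    est[tm] <- sum(wt * b)
    se[tm] <- sum(wt * sqrt(v + (b - est[tm])^2))
  }
  z <- abs(est) / se
  coefs <- data.frame(`Estimate` = est, `Std. Error` = se,
                      `z value` = z, `P(>|z|)` = 2 * stats::pnorm(-z),
                      check.names = FALSE)
  models <- data.frame(formula = forms, df = vapply(fits, function(f)
    if (is.null(f)) NA_real_ else attr(stats::logLik(f), "df"),
    numeric(1)), AICc = aicc, delta = delta, weight = wt,
    stringsAsFactors = FALSE)
  models <- models[order(models$delta), , drop = FALSE]
  rownames(models) <- NULL
  structure(list(coefficients = coefs, models = models,
                 segment = segment),
            class = "averagedCoefficients")
}

#' @export
print.averagedCoefficients <- function(x, ...) {
  cat("Model-averaged coefficients (", x$segment, " segment, ",
      nrow(x$models), " candidates )\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}
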