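#' Construct a circadian activity model
#'
#' Defaults produce a realistic companion-dog rest-activity rhythm:
#' a mesor of ~25 counts/min, a 24-h harmonic peaking mid-afternoon
#' (day ~120 counts/min, night trough ~5 counts/min), a small 12-h
#' harmonic sharpening the daytime plateau, moderate between-dog
#' variation, 20% higher weekend activity, and overdispersed counts
#' (variance about 3x the mean at the mesor). The default drug effect
#' reduces activity by half overnight (23:00-06:00) and raises it by 30%
#' in the morning (07:00-12:00) — the qualitative pattern an effective
#' nighttime analgesic is expected to produce.
#'
#' @param intercept log mean counts/min at the cosinor mesor.
#' @param amp24,phase24 24-h harmonic amplitude (log scale) and acrophase
#'   (clock minute of the peak; default 14:30).
#' @param amp12,phase12 12-h harmonic amplitude and acrophase.
#' @param subjectSd SD of the per-subject log intercept.
#' @param weekendMultiplier multiplier on the mean for Saturday/Sunday
#'   calendar dates.
#' @param dispersion negative binomial size; variance = mu + mu^2 /
#'   dispersion.
#' @param effectWindows data.frame(start, end, multiplier): clock-minute
#'   windows (wrapping across midnight when start > end) where the mean
#'   is multiplied under the drug condition. Use
#'   \code{nullEffectWindows()} for a no-effect model.
#' @param bedMean,bedSd,riseMean,riseSd diary time distributions, clock
#'   minutes (defaults: bed 23:00 +/- 30 min, rise 06:30 +/- 30 min,
#'   truncated at +/- 2 h).
#' @param doseRamp if TRUE, the drug multiplier decays toward 1 in the
#'   hour before evening dosing (18:00). Default FALSE.
#' @return An [ActivityModel-class] object.
#' @examples
#' ActivityModel()
#' ActivityModel(effectWindows = nullEffectWindows())
#' @export
ActivityModel <- function(intercept = log(25),
                          amp24 = 1.6, phase24 = 870,
                          amp12 = 0.35, phase12 = 600,
                          subjectSd = 0.3,
                          weekendMultiplier = 1.2,
                          dispersion = 12,
                          effectWindows = defaultEffectWindows(),
                          bedMean = 1380, bedSd = 30,
                          riseMean = 390, riseSd = 30,
                          doseRamp = FALSE) {
  new("ActivityModel", intercept = intercept,
      amp24 = amp24, phase24 = phase24,
      amp12 = amp12, phase12 = phase12,
      subjectSd = subjectSd,
      weekendMultiplier = weekendMultiplier,
      dispersion = dispersion,
      effectWindows = as.data.frame(effectWindows),
      bedMean = bedMean, bedSd = bedSd,
      riseMean = riseMean, riseSd = riseSd,
      doseRamp = doseRamp)
}

#' Default and null drug-effect windows
#'
#' The default windows encode the qualitative treatment effect the
#' analysis is built to detect: halved activity overnight (23:00-06:00,
#' wrapping midnight) and 30% higher activity in the morning
#' (07:00-12:00). \code{nullEffectWindows()} returns an empty window
#' table (no treatment effect; drug and placebo exchangeable).
#'
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{multiplier}.
#' @export
defaultEffectWindows <- function() {
  data.frame(start = c(1380, 420), end = c(360, 720),
             multiplier = c(0.5, 1.3))
}

#' @rdname defaultEffectWindows
#' @export
nullEffectWindows <- function() {
  data.frame(start = numeric(0), end = numeric(0),
             multiplier = numeric(0))
}

#' Deterministic mean activity intensity
#'
#' Evaluates the model's expected counts/min at given clock minutes,
#' before subject effects: \code{exp(intercept + amp24 *
#' cos(2 pi (t - phase24) / 1440) + amp12 * cos(2 pi (t - phase12) /
#' 720))}, times the weekend multiplier if \code{weekend}, times the
#' window multiplier if \code{condition == "drug"}.
#'
#' @param model an [ActivityModel-class].
#' @param minute numeric vector of clock minutes in [0, 1440).
#' @param weekend logical scalar.
#' @param condition \code{"placebo"} (default) or \code{"drug"}.
#' @return numeric vector of expected counts/min.
#' @examples
#' m <- ActivityModel()
#' activityIntensity(m, c(0, 360, 870))
#' @export
activityIntensity <- function(model, minute, weekend = FALSE,
                              condition = c("placebo", "drug")) {
  condition <- match.arg(condition)
  lp <- model@intercept +
    model@amp24 * cos(2 * pi * (minute - model@phase24) / 1440) +
    model@amp12 * cos(2 * pi * (minute - model@phase12) / 720)
  mu <- exp(lp)
  if (weekend) mu <- mu * model@weekendMultiplier
  if (condition == "drug") {
    wm <- windowMultiplierByMinute(model@effectWindows, model@doseRamp)
    mu <- mu * wm[as.integer(floor(minute)) %% 1440L + 1L]
  }
  mu
}

#' Construct a questionnaire effect specification
#'
#' Defaults describe a 6-item sleep-quality instrument on an integer
#' 0-10 scale (the response scale is an assumption; the instrument's
#' published description does not state it). Default shifts reproduce the
#' direction and size of the treatment responses an effective analgesic
#' produced on this instrument: the largest drug improvements on the
#' twitching and dreaming items, near-null placebo responses, and a
#' slightly positive pacing item.
#'
#' @param itemNames character(6) item labels.
#' @param baselineMean,baselineSd per-item baseline score distribution.
#' @param drugShift,placeboShift per-item additive shifts while in the
#'   corresponding condition (negative = improvement for items 1-5).
#' @param withinSubjectCor fraction of score variance from a shared
#'   subject effect, in [0, 1].
#' @param scaleMin,scaleMax the item scale; scores are rounded and
#'   clamped to it.
#' @return A [SnoreEffectSpec-class] object.
#' @examples
#' SnoreEffectSpec()
#' @export
SnoreEffectSpec <- function(itemNames = c("movement", "twitching",
                                          "dreaming", "shifting",
                                          "vocalizing", "pacing"),
                            baselineMean = c(5, 5, 5, 5, 5, 3),
                            baselineSd = rep(1.5, 6),
                            drugShift = c(-1.00, -1.20, -1.80,
                                          -1.13, -1.07, 0.27),
                            placeboShift = c(-0.33, -0.20, -0.40,
                                             -0.13, -0.60, 0.33),
                            withinSubjectCor = 0.5,
                            scaleMin = 0, scaleMax = 10) {
  new("SnoreEffectSpec", itemNames = itemNames,
      baselineMean = baselineMean, baselineSd = baselineSd,
      drugShift = drugShift, placeboShift = placeboShift,
      withinSubjectCor = withinSubjectCor,
      scaleMin = scaleMin, scaleMax = scaleMax)
}
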