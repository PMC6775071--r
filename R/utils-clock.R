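## Clock / calendar helpers. All clock arithmetic is on minutes of the
## circular 1440-minute day; timestamps are naive local time kept in UTC
## so no DST arithmetic can occur.

#' Format clock minutes as HH:MM
#'
#' @param minute numeric vector of clock minutes in [0, 1440).
#' @return character vector, \code{"HH:MM"}.
#' @examples
#' formatClock(c(0, 390, 1380))
#' @export
formatClock <- function(minute) {
  minute <- as.integer(round(minute)) %% 1440L
  sprintf("%02d:%02d", minute %/% 60L, minute %% 60L)
}

#' Parse HH:MM clock strings to minutes
#'
#' @param x character vector of \code{"HH:MM"} or \code{"HH:MM:SS"} times.
#' @return numeric vector of clock minutes in [0, 1440).
#' @examples
#' parseClock(c("23:00", "06:30"))
#' @export
parseClock <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L ||
                  anyNA(suppressWarnings(as.numeric(p[1:2]))), logical(1))
  if (any(bad))
    stop("malformed clock time(s): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  h <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  m <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  if (any(h < 0 | h > 23 | m < 0 | m > 59))
    stop("clock time out of range: ",
         paste(x[h < 0 | h > 23 | m < 0 | m > 59], collapse = ", "),
         call. = FALSE)
  h * 60 + m
}

#' Clock-window membership
#'
#' Tests whether clock minutes fall inside the half-open window
#' \code{[start, end)} on the circular 1440-minute clock; the window
#' wraps past midnight when \code{start > end}, and \code{start == end}
#' denotes the empty window.
#'
#' @param minute numeric vector of clock minutes.
#' @param start,end window bounds in clock minutes, each in [0, 1440).
#' @return logical vector.
#' @examples
#' inClockWindow(c(1400, 100, 500), 1380, 360)
#' @export
inClockWindow <- function(minute, start, end) {
  minute <- minute %% 1440
  if (start == end) return(rep(FALSE, length(minute)))
  if (start < end) minute >= start & minute < end
  else minute >= start | minute < end
}

## TRUE if any two half-open circular windows overlap.
circularWindowsOverlap <- function(start, end) {
  n <- length(start)
  if (n < 2L) return(FALSE)
  covered <- rep(0L, 1440L)
  for (i in seq_len(n)) {
    idx <- which(inClockWindow(0:1439, start[i], end[i]))
    covered[idx] <- covered[idx] + 1L
  }
  any(covered > 1L)
}

## Per-window multipliers evaluated at clock minutes: a vector of 1440
## multipliers (minute 0 .. 1439) under the drug condition.
windowMultiplierByMinute <- function(windows, doseRamp = FALSE,
                                     doseMinute = 1080) {
  mult <- rep(1, 1440L)
  if (nrow(windows)) {
    for (i in seq_len(nrow(windows))) {
      idx <- inClockWindow(0:1439, windows$start[i], windows$end[i])
      mult[idx] <- mult[idx] * windows$multiplier[i]
    }
  }
  if (doseRamp) {
    ramp <- (doseMinute - 60):(doseMinute - 1) %% 1440 + 1
    w <- seq(1, 0, length.out = 61)[-61]  # 1 at ramp start -> 0 at dosing
    mult[ramp] <- exp(w * log(mult[ramp]))
  }
  mult
}

## Deterministic child-seed spawning so pipeline arms are independently
## replayable from one master seed. Lehmer-style step, kept below 2^31.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 113 * as.numeric(stream)) %% 2147483647
}

## Truncated normal draw (mean, sd, +/- bound), by rejection; bound is in
## the same units as sd. Vectorized over n.
rtruncnorm <- function(n, mean, sd, bound) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(abs(x - mean) > bound)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[abs(x[bad] - mean) > bound]
  }
  x
}

## Weekend helpers. weekdayIndex: 1 = Monday ... 7 = Sunday.
weekdayIndex <- function(date) {
  (as.integer(unclass(date)) + 3L) %% 7L + 1L  # 1970-01-01 was a Thursday
}

isWeekendDate <- function(date) weekdayIndex(date) >= 6L        # Sat/Sun
isWeekendNightOnset <- function(date) {
  wd <- weekdayIndex(date)
  wd == 5L | wd == 6L                                            # Fri/Sat
}
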