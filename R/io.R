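## CSV readers/writers for the pipeline's tabular dialects. All schemas
## are plain headers; timestamps are ISO-8601 local clock time (either
## "YYYY-MM-DDTHH:MM:SS" or with a space separator). Malformed rows are
## reported with their file line number (header = line 1).

stopRows <- function(path, what, rows) {
  rows <- utils::head(sort(unique(rows)), 10L)
  stop(sprintf("%s: %s at line%s %s", path, what,
               if (length(rows) > 1L) "s" else "",
               paste(rows + 1L, collapse = ", ")), call. = FALSE)
}

requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

parseTimestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

#' Read and write minute-epoch activity CSV
#'
#' Schema: \code{subject_id,timestamp,count} with ISO-8601 timestamps.
#' Rows must be unique per (subject, timestamp), monotone in time within
#' subject, and carry non-negative integer counts; violations raise an
#' error naming the offending file line.
#'
#' @param path CSV file path.
#' @return \code{readActivity}: an [EpochData-class].
#' @examples
#' cohort <- simulateCohort(CohortSpec(nSubjects = 2, nFemale = 1), seed = 1)
#' design <- TrialDesign(cohort, periodLength = 1, washoutLength = 0)
#' sim <- simulateActivity(cohort, design, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeActivity(sim$activity, f)
#' identical(epochTable(readActivity(f)), epochTable(sim$activity))
#' @export
readActivity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  requireColumns(df, c("subject_id", "timestamp", "count"), path)
  n <- nrow(df)
  ts <- parseTimestamp(df$timestamp)
  if (anyNA(ts))
    stopRows(path, "malformed timestamp", which(is.na(ts)))
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(cnt) | cnt < 0 | cnt != round(cnt)
  if (any(bad))
    stopRows(path, "count is not a non-negative integer", which(bad))
  if (n > 1L) {
    sameSubj <- df$subject_id[-1L] == df$subject_id[-n]
    dt <- diff(as.numeric(ts))
    if (any(sameSubj & dt == 0))
      stopRows(path, "duplicate (subject_id, timestamp)",
               which(sameSubj & dt == 0) + 1L)
    if (any(sameSubj & dt < 0))
      stopRows(path, "non-monotone timestamps within subject",
               which(sameSubj & dt < 0) + 1L)
  }
  EpochData(data.frame(subject_id = df$subject_id, timestamp = ts,
                       count = as.integer(cnt), stringsAsFactors = FALSE))
}

#' @param x an [EpochData-class].
#' @rdname readActivity
#' @return \code{writeActivity}: the path, invisibly.
#' @export
writeActivity <- function(x, path) {
  stopifnot(is(x, "EpochData"))
  ep <- x@epochs
  out <- data.frame(
    subject_id = ep$subject_id,
    timestamp = format(ep$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    count = ep$count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sleep-diary CSV
#'
#' Schema: \code{subject_id,date,bed_time,rise_time}; \code{date} is the
#' night's evening-onset date, times are \code{"HH:MM"}. The night spans
#' \code{[bed, rise)} on the circular clock: if \code{rise_time} is not
#' after \code{bed_time} on linear same-day time the night wraps past
#' midnight (bed 23:00 / rise 06:30 is the usual wrapped night; bed
#' 13:00 / rise 14:00 is a same-day rest). Equal bed and rise times are
#' ambiguous and rejected.
#'
#' @param path CSV file path.
#' @return \code{readDiary}: data.frame with \code{subject_id},
#'   \code{date} (Date), \code{bed_time}, \code{rise_time}.
#' @export
readDiary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  requireColumns(df, c("subject_id", "date", "bed_time", "rise_time"),
                 path)
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date)) stopRows(path, "malformed date", which(is.na(date)))
  bed <- parseClock(df$bed_time)
  rise <- parseClock(df$rise_time)
  if (any(bed == rise))
    stopRows(path, "bed_time equal to rise_time (empty/ambiguous night)",
             which(bed == rise))
  dup <- duplicated(paste(df$subject_id, df$date))
  if (any(dup)) stopRows(path, "duplicate (subject_id, date)", which(dup))
  data.frame(subject_id = df$subject_id, date = date,
             bed_time = df$bed_time, rise_time = df$rise_time,
             stringsAsFactors = FALSE)
}

#' @param x a diary data.frame.
#' @rdname readDiary
#' @export
writeDiary <- function(x, path) {
  out <- data.frame(subject_id = x$subject_id,
                    date = format(x$date, "%Y-%m-%d"),
                    bed_time = x$bed_time, rise_time = x$rise_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write subject covariates CSV
#'
#' Schema: \code{subject_id,age,weight,sex,cbpi}; \code{sex} must be
#' \code{"F"} or \code{"M"}.
#'
#' @param path CSV file path.
#' @return \code{readCovariates}: data.frame matching the schema.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  requireColumns(df, c("subject_id", "age", "weight", "sex", "cbpi"),
                 path)
  bad <- !(df$sex %in% c("F", "M"))
  if (any(bad)) stopRows(path, "unknown sex code", which(bad))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stopRows(path, paste("malformed", col), which(is.na(v)))
    v
  }
  dup <- duplicated(df$subject_id)
  if (any(dup)) stopRows(path, "duplicate subject_id", which(dup))
  data.frame(subject_id = df$subject_id, age = num("age"),
             weight = num("weight"), sex = df$sex, cbpi = num("cbpi"),
             stringsAsFactors = FALSE)
}

#' @param x a covariates data.frame.
#' @rdname readCovariates
#' @export
writeCovariates <- function(x, path) {
  utils::write.csv(x[c("subject_id", "age", "weight", "sex", "cbpi")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write questionnaire CSV
#'
#' Schema: \code{subject_id,day,item1..item6} (6 item-score columns; a
#' \code{condition} column is accepted and ignored on read).
#'
#' @param path CSV file path.
#' @param nItems number of item columns expected (default 6).
#' @return \code{readSnore}: data.frame with \code{subject_id},
#'   \code{day} and the item columns.
#' @export
readSnore <- function(path, nItems = 6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  items <- paste0("item", seq_len(nItems))
  requireColumns(df, c("subject_id", "day", items), path)
  day <- suppressWarnings(as.integer(df$day))
  if (anyNA(day)) stopRows(path, "malformed day", which(is.na(day)))
  out <- data.frame(subject_id = df$subject_id, day = day,
                    stringsAsFactors = FALSE)
  for (it in items) {
    v <- suppressWarnings(as.numeric(df[[it]]))
    if (anyNA(v)) stopRows(path, paste("malformed", it), which(is.na(v)))
    out[[it]] <- v
  }
  dup <- duplicated(paste(out$subject_id, out$day))
  if (any(dup)) stopRows(path, "duplicate (subject_id, day)", which(dup))
  out
}

#' @param x a questionnaire data.frame.
#' @rdname readSnore
#' @export
writeSnore <- function(x, path) {
  items <- grep("^item", names(x), value = TRUE)
  utils::write.csv(x[c("subject_id", "day", items)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
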