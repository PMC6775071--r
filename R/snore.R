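## Questionnaire change-score analysis: per-item and total change from
## baseline under each condition, compared with matched-pairs t-tests
## at a fixed multiplicity-adjusted threshold (default p < 0.016).

snoreMeasures <- function(nItems = 6) {
  c(paste0("item", seq_len(nItems)), "total_5q", "total_6q")
}

#' Per-subject paired change scores for each contrast
#'
#' Maps each subject's end-of-period assessments to conditions through
#' the randomized sequence (the drug assessment is day
#' \code{periodLength} for drug-first subjects and the final day for
#' placebo-first subjects, and vice versa), derives the 5-item and
#' 6-item totals, and returns within-subject differences for the three
#' contrasts: drug - baseline, placebo - baseline, drug - placebo.
#' Subjects missing an assessment are dropped from the affected
#' contrasts with a message. Intermediate assessment days (e.g. 21, 28)
#' are ingested but unused.
#'
#' @param responses questionnaire data.frame ([readSnore()] schema:
#'   \code{subject_id}, \code{day}, \code{item1..item6}).
#' @param design a [TrialDesign-class].
#' @return data.frame with columns \code{subject_id}, \code{measure},
#'   \code{contrast} (\code{"drug_vs_baseline"},
#'   \code{"placebo_vs_baseline"}, \code{"drug_vs_placebo"}),
#'   \code{difference}.
#' @export
changeScores <- function(responses, design) {
  stopifnot(is(design, "TrialDesign"))
  items <- grep("^item[0-9]+$", names(responses), value = TRUE)
  if (length(items) < 1L)
    stop("no item columns in responses", call. = FALSE)
  r <- responses
  r$total_5q <- rowSums(r[items[seq_len(min(5L, length(items)))]])
  r$total_6q <- rowSums(r[items])
  measures <- c(items, "total_5q", "total_6q")

  p <- design@periodLength; w <- design@washoutLength
  endP1 <- p; endP2 <- 2L * p + w
  subjects <- names(design@sequence)
  rows <- list(); dropped <- 0L
  for (s in subjects) {
    rs <- r[r$subject_id == s, , drop = FALSE]
    base <- rs[rs$day == 0L, , drop = FALSE]
    drugDay <- if (design@sequence[[s]] == "drug") endP1 else endP2
    placDay <- if (design@sequence[[s]] == "drug") endP2 else endP1
    drug <- rs[rs$day == drugDay, , drop = FALSE]
    plac <- rs[rs$day == placDay, , drop = FALSE]
    have <- c(base = nrow(base) == 1L, drug = nrow(drug) == 1L,
              plac = nrow(plac) == 1L)
    if (!all(have)) dropped <- dropped + 1L
    for (m in measures) {
      if (have["drug"] && have["base"])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, measure = m, contrast = "drug_vs_baseline",
          difference = drug[[m]] - base[[m]], stringsAsFactors = FALSE)
      if (have["plac"] && have["base"])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, measure = m, contrast = "placebo_vs_baseline",
          difference = plac[[m]] - base[[m]], stringsAsFactors = FALSE)
      if (have["drug"] && have["plac"])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, measure = m, contrast = "drug_vs_placebo",
          difference = drug[[m]] - plac[[m]], stringsAsFactors = FALSE)
    }
  }
  if (dropped)
    message(dropped, " subject(s) missing assessments; dropped from ",
            "affected contrasts")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Matched-pairs t-test on within-subject differences
#'
#' One-sample t-test of the paired differences against 0 with a
#' two-sided p from the t distribution on n - 1 df. Degenerate cases:
#' zero variance with zero mean gives t = 0, p = 1; zero variance with
#' non-zero mean gives an infinite t sentinel and p = 0 with a warning.
#'
#' @param differences numeric vector of paired differences (n >= 2).
#' @return named list: \code{mean}, \code{t}, \code{p}, \code{n}.
#' @examples
#' pairedT(c(-3, -2, -1, -2, -2))
#' @export
pairedT <- function(differences) {
  differences <- differences[is.finite(differences)]
  n <- length(differences)
  if (n < 2L) stop("need >= 2 paired differences", call. = FALSE)
  m <- mean(differences)
  s <- stats::sd(differences)
  if (s == 0) {
    if (m == 0) return(list(mean = 0, t = 0, p = 1, n = n))
    warning("zero variance with non-zero mean difference; p = 0 sentinel",
            call. = FALSE)
    return(list(mean = m, t = sign(m) * Inf, p = 0, n = n))
  }
  tt <- stats::t.test(differences, mu = 0)
  list(mean = m, t = unname(tt$statistic), p = tt$p.value, n = n)
}

flagSignificant <- function(p, threshold = 0.016) {
  p < threshold  # strictly below: p == threshold is not significant
}

#' Questionnaire results table
#'
#' One row per measure (each item plus the 5-item and 6-item totals),
#' with the paired mean difference, t statistic and p-value for each of
#' the three contrasts, flagged significant where p is strictly below
#' the multiplicity-adjusted threshold.
#'
#' @param changes change-score data.frame from [changeScores()].
#' @param threshold significance threshold (default 0.016).
#' @return data.frame with one row per measure and, per contrast
#'   \code{drug_vs_baseline} / \code{placebo_vs_baseline} /
#'   \code{drug_vs_placebo}, columns \code{<contrast>_mean},
#'   \code{<contrast>_t}, \code{<contrast>_p},
#'   \code{<contrast>_significant}.
#' @export
snoreTable <- function(changes, threshold = 0.016) {
  measures <- unique(changes$measure)
  contrasts <- c("drug_vs_baseline", "placebo_vs_baseline",
                 "drug_vs_placebo")
  out <- data.frame(measure = measures, stringsAsFactors = FALSE)
  for (ct in contrasts) {
    res <- lapply(measures, function(m) {
      d <- changes$difference[changes$measure == m &
                                changes$contrast == ct]
      if (length(d) < 2L)
        return(list(mean = NA_real_, t = NA_real_, p = NA_real_))
      pairedT(d)
    })
    out[[paste0(ct, "_mean")]] <- vapply(res, `[[`, numeric(1), "mean")
    out[[paste0(ct, "_t")]] <- vapply(res, `[[`, numeric(1), "t")
    p <- vapply(res, `[[`, numeric(1), "p")
    out[[paste0(ct, "_p")]] <- p
    out[[paste0(ct, "_significant")]] <- flagSignificant(p, threshold)
  }
  out
}
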