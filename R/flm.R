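#' Point-wise two-group functional F statistic
#'
#' At each grid point t, the one-way ANOVA F statistic between the two
#' groups of curve evaluations: F(t) = [between-group SS / (k - 1)] /
#' [within-group SS / (N - k)] with k = 2 groups and N total curves.
#' Where the within-group SS is zero with non-zero between-group SS the
#' statistic is \code{Inf}; where both are zero it is 0.
#'
#' @param curvesA,curvesB matrices of evaluated curves (curves in rows,
#'   grid points in columns); both groups need >= 2 curves and equal
#'   grids.
#' @return numeric vector of F values, one per grid point.
#' @examples
#' A <- matrix(rep(1:3, 4), 3, 4)
#' B <- matrix(rep(4:6, 4), 3, 4)
#' pointwiseF(A, B)  # 13.5 everywhere
#' @export
pointwiseF <- function(curvesA, curvesB) {
  curvesA <- as.matrix(curvesA); curvesB <- as.matrix(curvesB)
  nA <- nrow(curvesA); nB <- nrow(curvesB)
  if (nA < 2L || nB < 2L)
    stop("both groups need at least 2 curves", call. = FALSE)
  if (ncol(curvesA) != ncol(curvesB))
    stop("curve grids differ between groups", call. = FALSE)
  N <- nA + nB
  mA <- colMeans(curvesA); mB <- colMeans(curvesB)
  grand <- (nA * mA + nB * mB) / N
  bss <- nA * (mA - grand)^2 + nB * (mB - grand)^2
  wss <- colSums((curvesA - rep(mA, each = nA))^2) +
    colSums((curvesB - rep(mB, each = nB))^2)
  f <- (bss / 1) / (wss / (N - 2))
  zero <- wss == 0
  f[zero & bss > 0] <- Inf
  f[zero & bss == 0] <- 0
  f
}

#' Generate permuted condition labelings
#'
#' For the paired scheme each subject's two condition labels are
#' independently swapped or kept (2^n possible assignments for n
#' subjects), respecting the crossover's within-subject exchangeability.
#' For the unpaired scheme all labels are shuffled preserving group
#' sizes. Returned as a logical matrix (permutations in rows): for
#' paired, TRUE means "swap this subject"; for unpaired, TRUE marks the
#' curves assigned to group A.
#'
#' @param n number of subjects (paired) or total curves (unpaired).
#' @param nPerm number of permutations to draw.
#' @param scheme \code{"paired"} or \code{"unpaired"}.
#' @param nA group-A size (unpaired scheme only).
#' @param exact paired scheme: enumerate all 2^n assignments instead of
#'   sampling (n <= 20; overrides \code{nPerm}).
#' @param unique paired scheme: sample assignments without replacement.
#' @return logical matrix, one permutation per row. The identity
#'   assignment (no swaps) is always part of the exact enumeration.
#' @examples
#' nrow(permuteLabels(4, exact = TRUE))  # 16
#' @export
permuteLabels <- function(n, nPerm = 500, scheme = c("paired", "unpaired"),
                          nA = NULL, exact = FALSE, unique = FALSE) {
  scheme <- match.arg(scheme)
  if (scheme == "paired") {
    if (exact) {
      if (n > 20L) stop("exact enumeration limited to n <= 20 subjects",
                        call. = FALSE)
      codes <- 0:(2^n - 1)
    } else if (unique) {
      if (n > 30L) stop("unique sampling limited to n <= 30 subjects",
                        call. = FALSE)
      if (nPerm > 2^n)
        stop("nPerm exceeds the number of distinct assignments 2^", n,
             call. = FALSE)
      codes <- sample.int(2^n, nPerm) - 1
    } else {
      return(matrix(sample(c(TRUE, FALSE), n * nPerm, replace = TRUE),
                    nrow = nPerm, ncol = n))
    }
    bits <- vapply(seq_len(n) - 1L,
                   function(b) bitwAnd(codes, bitwShiftL(1, b)) > 0,
                   logical(length(codes)))
    matrix(bits, nrow = length(codes), ncol = n)
  } else {
    if (is.null(nA)) stop("unpaired scheme needs nA", call. = FALSE)
    t(vapply(seq_len(nPerm), function(i) {
      idx <- sample.int(n, nA)
      seq_len(n) %in% idx
    }, logical(n)))
  }
}

#' Point-wise permutation F-test between condition curves
#'
#' The central analysis: per-subject daily profiles are smoothed into
#' functional curves (penalized cyclic B-splines, log1p transform by
#' default), and at each clock grid point the observed two-group F
#' statistic is compared with its permutation distribution. Under the
#' default paired scheme permutations swap the drug/placebo labels
#' within subject, the exchangeable unit of a crossover. The point-wise
#' p-value is the proportion of permutation F values strictly larger
#' than the observed F (set \code{pRule = "plusone"} for the
#' (1+b)/(1+n) convention); the critical curve is the nearest-rank
#' empirical (1-alpha) quantile of the permutation F values, and grid
#' points with observed F strictly above it are significant.
#'
#' @param profiles a [DailyProfiles-class] with one profile per subject
#'   x condition (paired scheme) or any two-group profile set.
#' @param nPerm number of permutations (default 500).
#' @param alpha significance level (default 0.05); a warning is issued
#'   if \code{nPerm < 1/alpha}.
#' @param scheme \code{"paired"} (within-subject label swaps, default)
#'   or \code{"unpaired"} (label shuffle preserving group sizes).
#' @param transform,nBasis,sp passed to the smoother (see
#'   [smoothProfile()]).
#' @param seed integer seed governing the permutation stream.
#' @param exact paired scheme: enumerate all 2^n assignments.
#' @param uniquePerms paired scheme: sample assignments without
#'   replacement.
#' @param pRule \code{"greater"} (default) or \code{"plusone"}.
#' @param conditions the two condition labels to compare (default: the
#'   two present).
#' @return An [FLMResult-class] object.
#' @examples
#' cohort <- simulateCohort(CohortSpec(nSubjects = 4, nFemale = 2), seed = 1)
#' design <- TrialDesign(cohort, periodLength = 3, washoutLength = 1)
#' sim <- simulateActivity(cohort, design, seed = 1)
#' lab <- classifyEpochs(sim$activity, sim$diary, design)
#' prof <- buildDailyProfiles(lab, gridSize = 48)
#' pointwisePermutationTest(prof, nPerm = 50, seed = 1)
#' @export
pointwisePermutationTest <- function(profiles, nPerm = 500, alpha = 0.05,
                                     scheme = c("paired", "unpaired"),
                                     transform = "log1p", nBasis = 24,
                                     sp = NULL, seed = 1, exact = FALSE,
                                     uniquePerms = FALSE,
                                     pRule = c("greater", "plusone"),
                                     conditions = NULL) {
  stopifnot(is(profiles, "DailyProfiles"))
  scheme <- match.arg(scheme)
  pRule <- match.arg(pRule)
  info <- profileInfo(profiles)
  if (is.null(conditions)) {
    conditions <- sort(unique(info$condition))
  }
  if (length(conditions) != 2L)
    stop("exactly two conditions are required, got: ",
         paste(conditions, collapse = ", "), call. = FALSE)
  keep <- info$condition %in% conditions
  profiles <- profiles[, keep]
  info <- info[keep, , drop = FALSE]
  if (nPerm < 1 / alpha)
    warning("nPerm < 1/alpha: the critical quantile is unstable",
            call. = FALSE)

  E <- smoothProfileMatrix(profiles, nBasis = nBasis,
                           transform = transform, sp = sp)
  G <- ncol(E)
  grid <- profileGrid(profiles)

  iA <- which(info$condition == conditions[1])
  iB <- which(info$condition == conditions[2])

  set.seed(as.integer(seed))
  if (scheme == "paired") {
    subj <- sort(unique(info$subject_id))
    rowA <- match(paste(subj, conditions[1]),
                  paste(info$subject_id, info$condition))
    rowB <- match(paste(subj, conditions[2]),
                  paste(info$subject_id, info$condition))
    if (anyNA(rowA) || anyNA(rowB))
      stop("paired scheme requires exactly one curve per subject and ",
           "condition", call. = FALSE)
    A <- E[rowA, , drop = FALSE]
    B <- E[rowB, , drop = FALSE]
    n <- length(subj)
    masks <- permuteLabels(n, nPerm, "paired", exact = exact,
                           unique = uniquePerms)
    nPerm <- nrow(masks)
    Fobs <- pointwiseF(A, B)
    Fperm <- pairedPermutationF(A, B, masks)
  } else {
    A <- E[iA, , drop = FALSE]
    B <- E[iB, , drop = FALSE]
    all <- rbind(A, B)
    nA <- nrow(A); N <- nrow(all)
    Fobs <- pointwiseF(A, B)
    masks <- permuteLabels(N, nPerm, "unpaired", nA = nA)
    Fperm <- matrix(0, nPerm, G)
    for (p in seq_len(nPerm)) {
      sel <- masks[p, ]
      Fperm[p, ] <- pointwiseF(all[sel, , drop = FALSE],
                               all[!sel, , drop = FALSE])
    }
  }

  pCurve <- if (pRule == "greater") {
    colMeans(Fperm > rep(Fobs, each = nPerm))
  } else {
    (1 + colSums(Fperm > rep(Fobs, each = nPerm))) / (1 + nPerm)
  }
  rank <- ceiling((1 - alpha) * nPerm)
  critCurve <- apply(Fperm, 2L, function(col) sort(col)[rank])

  meanCurves <- rbind(colMeans(E[iA, , drop = FALSE]),
                      colMeans(E[iB, , drop = FALSE]))
  rownames(meanCurves) <- conditions

  intervals <- significantIntervalsCore(Fobs > critCurve, grid,
                                        meanCurves, conditions,
                                        minLength = 0)
  new("FLMResult", grid = as.numeric(grid), Fobs = Fobs, Fperm = Fperm,
      critCurve = critCurve, pCurve = pCurve, alpha = alpha,
      nPerm = as.integer(nPerm), scheme = scheme, pRule = pRule,
      seed = as.integer(seed), groupLevels = conditions,
      meanCurves = meanCurves, intervals = intervals)
}

## F curves for a batch of within-pair label swaps. Swapping the two
## values of a pair leaves the pooled total sum of squares at each grid
## point unchanged, and with equal groups the between-group SS is
## (n/2) * mean(s_i * d_i)^2 with d_i = A_i - B_i and s_i = -1 for
## swapped pairs, so the whole batch reduces to one matrix product.
## Algebraically identical to calling pointwiseF on each relabeling.
pairedPermutationF <- function(A, B, masks) {
  n <- nrow(A)
  G <- ncol(A)
  V <- rbind(A, B)
  grand <- colMeans(V)
  tss <- colSums((V - rep(grand, each = 2L * n))^2)
  S <- matrix(1, nrow(masks), n)
  S[masks] <- -1
  M <- (S %*% (A - B)) / n
  bss <- (n / 2) * M^2
  wss <- rep(tss, each = nrow(masks)) - bss
  wss[wss < 0] <- 0
  f <- bss / (wss / (2L * n - 2L))
  zero <- wss == 0
  f[zero & bss > 0] <- Inf
  f[zero & bss == 0] <- 0
  f
}

## Maximal runs of significant grid cells, merged across midnight, as
## clock-time intervals with direction.
significantIntervalsCore <- function(mask, grid, meanCurves, groupLevels,
                                     minLength = 0) {
  G <- length(mask)
  w <- 1440 / G
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), higher = character(0),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  if (all(mask)) {
    runs <- list(seq_len(G))
  } else {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- Map(seq, starts[r$values], ends[r$values])
    if (mask[1L] && mask[G] && length(runs) > 1L) {
      runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
      runs[[length(runs)]] <- NULL
    }
  }
  out <- lapply(runs, function(cells) {
    len <- length(cells) * w
    startMin <- (cells[1L] - 1L) * w
    endMin <- (startMin + len) %% 1440
    if (endMin == 0) endMin <- 1440
    diffMean <- mean(meanCurves[1L, cells]) - mean(meanCurves[2L, cells])
    data.frame(start = startMin, end = endMin, length = len,
               higher = if (diffMean >= 0) groupLevels[1L] else
                 groupLevels[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$length >= minLength & out$length > 0, , drop = FALSE]
  if (!is.null(minLength) && minLength > 0)
    out <- out[out$length >= minLength, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) empty else out
}

#' Extract significant clock-time intervals
#'
#' Maximal runs of consecutive grid points where the observed F curve
#' strictly exceeds the point-wise critical curve, merged across the
#' midnight wrap, dropped when shorter than \code{minLength} minutes,
#' and annotated with which group's mean curve is higher.
#'
#' @param result an [FLMResult-class].
#' @param minLength minimum interval length in minutes (default 0).
#' @return data.frame with columns \code{start}, \code{end} (clock
#'   minutes; \code{start > end} denotes a midnight wrap), \code{length}
#'   and \code{higher}.
#' @export
extractSignificantIntervals <- function(result, minLength = 0) {
  stopifnot(is(result, "FLMResult"))
  significantIntervalsCore(result@Fobs > result@critCurve, result@grid,
                           result@meanCurves, result@groupLevels,
                           minLength = minLength)
}

#' Minute-membership mask of clock intervals
#'
#' Utility for interval overlap computations (e.g. Jaccard between
#' detected and injected windows): marks every clock minute covered by
#' any of the given half-open intervals, with midnight wrap when
#' \code{start > end}.
#'
#' @param intervals data.frame with \code{start} and \code{end} clock
#'   minutes (as produced by [extractSignificantIntervals()]).
#' @return logical vector of length 1440 (minute 0 .. 1439).
#' @examples
#' sum(intervalsToMask(data.frame(start = 1380, end = 360)))  # 420
#' @export
intervalsToMask <- function(intervals) {
  mask <- rep(FALSE, 1440L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e == 1440 && s == 0) { mask[] <- TRUE; next }
    mask <- mask | inClockWindow(0:1439, s %% 1440, e %% 1440)
  }
  mask
}

#' Plot a point-wise permutation test result
#'
#' Two panels in the canonical layout: the group mean curves (top) and
#' the observed F curve (solid) against the point-wise critical curve
#' (dotted) with significant intervals shaded (bottom).
#'
#' @param result an [FLMResult-class].
#' @param file optional path; if given, a PNG is written there.
#' @param width,height,res PNG device settings.
#' @return \code{file} (or \code{NULL}), invisibly.
#' @export
plotFLM <- function(result, file = NULL, width = 900, height = 700,
                    res = 110) {
  stopifnot(is(result, "FLMResult"))
  if (!is.null(file)) grDevices::png(file, width = width, height = height,
                                     res = res)
  op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1),
                      mgp = c(2.2, 0.7, 0))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() },
          add = TRUE)
  at <- seq(0, 1440, by = 240)
  ylim <- range(result@meanCurves)
  graphics::plot(result@grid, result@meanCurves[1, ], type = "l",
                 col = "red", lwd = 2, ylim = ylim, xaxt = "n",
                 xlab = "clock time", ylab = "mean activity (smoothed)",
                 main = "Group mean circadian activity")
  graphics::lines(result@grid, result@meanCurves[2, ], col = "black",
                  lwd = 2)
  graphics::axis(1, at = at, labels = formatClock(at %% 1440))
  graphics::legend("topleft", legend = result@groupLevels,
                   col = c("red", "black"), lwd = 2, bty = "n")
  fin <- is.finite(result@Fobs)
  ymax <- max(result@Fobs[fin], result@critCurve, 1)
  graphics::plot(result@grid, pmin(result@Fobs, ymax * 1.05), type = "l",
                 lwd = 2, ylim = c(0, ymax * 1.05), xaxt = "n",
                 xlab = "clock time", ylab = "F statistic",
                 main = sprintf("Point-wise permutation F (alpha = %.2f)",
                                result@alpha))
  sig <- result@intervals
  for (i in seq_len(nrow(sig))) {
    s <- sig$start[i]; e <- sig$end[i]
    segs <- if (s < e) list(c(s, e)) else list(c(s, 1440), c(0, e))
    for (sg in segs)
      graphics::rect(sg[1], 0, sg[2], ymax * 1.05,
                     col = grDevices::adjustcolor("grey", 0.4),
                     border = NA)
  }
  graphics::lines(result@grid, pmin(result@Fobs, ymax * 1.05), lwd = 2)
  graphics::lines(result@grid, result@critCurve, lty = 3, lwd = 2)
  graphics::axis(1, at = at, labels = formatClock(at %% 1440))
  invisible(file)
}

#' @describeIn plotFLM plot method for FLMResult
#' @param x,y see \code{plot}; \code{y} is ignored.
#' @param ... passed to \code{plotFLM}.
#' @export
setMethod("plot", signature(x = "FLMResult", y = "missing"),
          function(x, y, ...) plotFLM(x, ...))
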