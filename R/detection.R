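#' Detection-call parameters
#'
#' Parameters of the Wilcoxon signed-rank presence/absence detection call:
#' the discrimination-score offset \code{tau} and the two p-value thresholds
#' separating Present, Marginal and Absent.  Defaults are the published
#' Affymetrix values (tau = 0.015, alpha1 = 0.04, alpha2 = 0.06).
#'
#' @param tau discrimination-score offset tested against (>= 0).
#' @param alpha1 Present threshold: call is P when p < alpha1.
#' @param alpha2 Marginal threshold: M when alpha1 <= p < alpha2, else A.
#'   Must satisfy 0 < alpha1 < alpha2 < 0.5.
#' @return A validated list of class \code{DetectionParams}.
#' @export
detectionParams <- function(tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  if (tau < 0) .cfgStop("tau", "must be >= 0")
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 0.5))
    .cfgStop("alpha1/alpha2", "must satisfy 0 < alpha1 < alpha2 < 0.5")
  structure(list(tau = tau, alpha1 = alpha1, alpha2 = alpha2),
            class = "DetectionParams")
}

## cache of 2^n x n subset-indicator matrices for exact enumeration
.signRankCache <- new.env(parent = emptyenv())

.subsetMatrix <- function(n) {
  key <- as.character(n)
  m <- .signRankCache[[key]]
  if (is.null(m)) {
    m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    .signRankCache[[key]] <- m
  }
  m
}

#' One-sided Wilcoxon signed-rank p-value
#'
#' Tests whether the median of \code{x} exceeds zero: computes the positive
#' rank sum \eqn{W^+} on mid-ranks of \eqn{|x|} (exact zeros dropped) and
#' returns \eqn{P(W^+ \ge w)} under the null of random signs.  For
#' \code{n <= maxExact} non-zero values the null distribution is obtained by
#' exhaustive enumeration of all \eqn{2^n} sign assignments (so mid-ranks
#' from ties are handled exactly); above that a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x numeric vector of differences.
#' @param maxExact largest n for which the exact enumeration is used.
#' @return One-sided p-value in (0, 1]; 0.5 when all values are zero.
#' @seealso [detectionCall()]
#' @export
signedRankP <- function(x, maxExact = 12L) {
  x <- x[abs(x) > 1e-12]
  n <- length(x)
  if (n == 0) return(0.5)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= maxExact) {
    dist <- drop(.subsetMatrix(n) %*% r)
    mean(dist >= w - 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
}

#' Present/Marginal/Absent detection call for one probe set
#'
#' Computes discrimination scores \eqn{R_i = (PM_i - MM_i)/(PM_i + MM_i)}
#' and applies a one-sided Wilcoxon signed-rank test of
#' \eqn{\mathrm{median}(R - \tau) > 0}; the call is P if
#' \code{p < alpha1}, M if \code{alpha1 <= p < alpha2}, A otherwise.
#'
#' @param pm,mm positive intensity vectors of equal length >= 3.
#' @param params a [detectionParams()] object.
#' @return A list with \code{call} (factor level "P", "M" or "A") and
#'   \code{p} (the one-sided signed-rank p-value).
#' @examples
#' detectionCall(pm = c(800, 900, 1000, 1200), mm = c(100, 90, 120, 110))
#' @export
detectionCall <- function(pm, mm, params = detectionParams()) {
  if (length(pm) != length(mm))
    stop("pm and mm must have the same length", call. = FALSE)
  if (length(pm) < 3)
    stop("at least 3 probe pairs are required", call. = FALSE)
  if (any(pm <= 0) || any(mm <= 0))
    stop("all intensities must be strictly positive", call. = FALSE)
  R <- (pm - mm) / (pm + mm)
  p <- signedRankP(R - params$tau)
  call <- if (p < params$alpha1) "P" else if (p < params$alpha2) "M" else "A"
  list(call = call, p = p)
}

#' Detection-call matrix for a probe-level experiment
#'
#' Applies [detectionCall()] to every probe set on every array.
#'
#' @param experiment a \linkS4class{ProbeLevelExperiment}.
#' @param params a [detectionParams()] object.
#' @return A list with \code{calls} (character matrix, probe sets x arrays,
#'   values "P"/"M"/"A") and \code{pvalues} (matching numeric matrix).
#' @export
callMatrix <- function(experiment, params = detectionParams()) {
  pm <- SummarizedExperiment::assay(experiment, "pm")
  mm <- SummarizedExperiment::assay(experiment, "mm")
  ps <- SummarizedExperiment::rowData(experiment)$probeset_id
  idx <- split(seq_along(ps), factor(ps, levels = unique(ps)))
  psIds <- names(idx)
  calls <- matrix(NA_character_, length(idx), ncol(pm),
                  dimnames = list(psIds, colnames(pm)))
  pvals <- matrix(NA_real_, length(idx), ncol(pm),
                  dimnames = list(psIds, colnames(pm)))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    for (a in seq_len(ncol(pm))) {
      res <- tryCatch(detectionCall(pm[rows, a], mm[rows, a], params),
                      error = function(e)
                        stop(sprintf("probe set %s, array %s: %s",
                                     psIds[i], colnames(pm)[a],
                                     conditionMessage(e)), call. = FALSE))
      calls[i, a] <- res$call
      pvals[i, a] <- res$p
    }
  }
  list(calls = calls, pvalues = pvals)
}
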