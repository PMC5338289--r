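#' Quantile normalization
#'
#' Forces every column of a matrix onto the same distribution: the row-wise
#' mean of the sorted columns.  Within-column ranks are preserved and ties
#' share the mean of the values they would have occupied.  This is the
#' surrogate normalization used ahead of probe-set summarization (the
#' sequence-dependent background model of gcrma needs chip probe sequences
#' and is out of scope); delegated to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param values numeric matrix (probes x samples) with no missing values.
#' @return A matrix of the same dimension and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' @export
quantileNormalize <- function(values) {
  values <- as.matrix(values)
  if (length(values) == 0) stop("empty matrix", call. = FALSE)
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Median-polish probe-set summarization
#'
#' Fits the additive decomposition value = overall + probe effect + sample
#' effect by median polish (tolerance 1e-6, at most 20 iterations) and
#' returns overall + sample effects as the per-sample probe-set expression
#' value, as in MAS-style summarization.
#'
#' @param log2ProbeValues numeric matrix, probes x samples, finite.
#' @return Named numeric vector of per-sample summary values.
#' @examples
#' m <- outer(c(0, 1, -1), c(5, 6, 7, 8), `+`)
#' summarizeProbeset(m)
#' @export
summarizeProbeset <- function(log2ProbeValues) {
  m <- as.matrix(log2ProbeValues)
  if (!all(is.finite(m))) stop("non-finite probe values", call. = FALSE)
  if (nrow(m) == 1L) return(setNames(drop(m), colnames(m)))
  ## the 20-iteration cap is part of the procedure, not a failure
  mp <- suppressWarnings(medpolish(m, eps = 1e-6, maxiter = 20,
                                   trace.iter = FALSE))
  setNames(mp$overall + mp$col, colnames(m))
}

#' Filter probe sets by detection calls and a minimum maximum value
#'
#' Drops probe sets whose call is Absent on every array, then probe sets
#' whose maximum log2 expression does not exceed \code{minMaxLog2}
#' (default log2(100), read strictly: a probe set survives only if its max
#' is above the threshold).  The counts removed by each rule are recorded in
#' \code{metadata(x)$filtered}.
#'
#' @param x \code{SummarizedExperiment} with assays \code{exprs} and
#'   \code{calls} (as produced by [preprocessExperiment()]).
#' @param minMaxLog2 threshold on the per-probe-set maximum log2 value.
#' @return The row-subset \code{SummarizedExperiment}.
#' @export
filterProbesets <- function(x, minMaxLog2 = log2(100)) {
  calls <- SummarizedExperiment::assay(x, "calls")
  exprs <- SummarizedExperiment::assay(x, "exprs")
  allAbsent <- apply(calls == "A", 1, all)
  lowMax <- apply(exprs, 1, max) <= minMaxLog2
  keep <- !allAbsent & !lowMax
  out <- x[keep, ]
  S4Vectors::metadata(out)$filtered <-
    list(all_absent = sum(allAbsent),
         below_min_max = sum(lowMax & !allAbsent),
         kept = sum(keep), minMaxLog2 = minMaxLog2)
  out
}

#' Probe-level intensities to filtered probe-set expression values
#'
#' The preprocessing pipeline: Present/Marginal/Absent detection calls on
#' the raw PM/MM probe pairs, log2 transformation and quantile
#' normalization of the PM intensities, median-polish summarization to one
#' value per probe set per array, and (optionally) the detection-call /
#' minimum-maximum filter.
#'
#' @param experiment a \linkS4class{ProbeLevelExperiment}.
#' @param params detection-call parameters, see [detectionParams()].
#' @param minMaxLog2 threshold for [filterProbesets()].
#' @param filter apply the probe-set filter (default TRUE).
#' @return A \code{SummarizedExperiment} with assays \code{exprs} (probe-set
#'   x array log2 expression), \code{calls} and \code{pvalues}; colData is
#'   carried over from the input experiment.
#' @examples
#' sim <- simulateArrayExperiment(arraySimConfig(nProbesets = 40,
#'   nSharedResponders = 3, nSpecificRespondersPerLine = 1,
#'   nAbsentProbesets = 4, seed = 11))
#' se <- preprocessExperiment(sim$experiment)
#' dim(se)
#' @export
preprocessExperiment <- function(experiment, params = detectionParams(),
                                 minMaxLog2 = log2(100), filter = TRUE) {
  cm <- callMatrix(experiment, params)
  pm <- SummarizedExperiment::assay(experiment, "pm")
  norm <- quantileNormalize(log2(pm))
  ps <- SummarizedExperiment::rowData(experiment)$probeset_id
  idx <- split(seq_along(ps), factor(ps, levels = unique(ps)))
  exprs <- t(vapply(idx, function(rows)
    summarizeProbeset(norm[rows, , drop = FALSE]),
    numeric(ncol(norm))))
  dimnames(exprs) <- list(names(idx), colnames(pm))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs, calls = cm$calls[rownames(exprs), ],
                  pvalues = cm$pvalues[rownames(exprs), ]),
    colData = SummarizedExperiment::colData(experiment))
  if (filter) filterProbesets(se, minMaxLog2) else se
}
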