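#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats median na.omit pnorm qnorm phyper rnorm runif rexp rlnorm
#'   sd cor rank dist hclust chisq.test pchisq medpolish setNames rbinom
#' @importFrom utils read.delim write.table read.csv head
NULL

setOldClass("igraph")

#' Probe-level microarray experiment
#'
#' Container for perfect-match (PM) and mismatch (MM) probe-pair intensities
#' across arrays, extending \linkS4class{SummarizedExperiment}.  Rows are
#' probe pairs (annotated by \code{probeset_id} and \code{probe_idx} in
#' \code{rowData}); columns are arrays, with \code{cell_line} and
#' \code{condition} in \code{colData}.  The two assays are \code{pm} and
#' \code{mm}, both strictly positive linear-scale intensities.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [simulateArrayExperiment()], [callMatrix()],
#'   [preprocessExperiment()]
#' @export
setClass("ProbeLevelExperiment", contains = "SummarizedExperiment")

setValidity("ProbeLevelExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("pm", "mm") %in% an))
    msg <- c(msg, "assays 'pm' and 'mm' are required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("probeset_id", "probe_idx") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'probeset_id' and 'probe_idx'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("cell_line", "condition") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'cell_line' and 'condition'")
  if (all(c("pm", "mm") %in% an)) {
    if (any(SummarizedExperiment::assay(object, "pm") <= 0) ||
        any(SummarizedExperiment::assay(object, "mm") <= 0))
      msg <- c(msg, "all pm and mm intensities must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeLevelExperiment
#'
#' @param pm,mm numeric matrices of identical dimension (probe pairs x
#'   arrays) of strictly positive intensities.
#' @param probesetId character vector, one probe-set id per row.
#' @param probeIdx integer vector, probe index within its probe set.
#' @param sampleData data.frame with one row per array and at least columns
#'   \code{cell_line} and \code{condition}.
#' @return A \linkS4class{ProbeLevelExperiment}.
#' @examples
#' pm <- matrix(2^rnorm(12, 8), 3, 4)
#' ple <- ProbeLevelExperiment(pm, pm * 0.3, rep("ps1", 3), 1:3,
#'   data.frame(cell_line = rep(c("lineA", "lineB"), each = 2),
#'              condition = rep(c("control", "knockdown"), 2)))
#' @export
ProbeLevelExperiment <- function(pm, mm, probesetId, probeIdx, sampleData) {
  pm <- as.matrix(pm); mm <- as.matrix(mm)
  stopifnot(identical(dim(pm), dim(mm)))
  if (is.null(colnames(pm)))
    colnames(pm) <- colnames(mm) <- rownames(sampleData) %||%
      paste0("array", seq_len(ncol(pm)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pm = pm, mm = mm),
    rowData = S4Vectors::DataFrame(probeset_id = probesetId,
                                   probe_idx = as.integer(probeIdx)),
    colData = S4Vectors::DataFrame(sampleData))
  new("ProbeLevelExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "ProbeLevelExperiment", function(object) {
  cat("ProbeLevelExperiment with",
      length(unique(SummarizedExperiment::rowData(object)$probeset_id)),
      "probe sets /", nrow(object), "probe pairs on", ncol(object),
      "arrays\n")
  cd <- SummarizedExperiment::colData(object)
  cat("arrays:", paste(sprintf("%s (%s/%s)", rownames(cd), cd$cell_line,
                               cd$condition), collapse = ", "), "\n")
})

#' Paired expression differences with z-scores for one cell line
#'
#' Holds, for a single cell line, the per-probe-set expression difference
#' \eqn{d = \mathrm{control} - \mathrm{knockdown}} (log2 units), its mean and
#' sample standard deviation, and the standardized scores
#' \eqn{z = (d - \mu)/\sigma}.  A positive \eqn{d} means expression fell upon
#' knockdown.
#'
#' @slot line cell-line identifier.
#' @slot d named numeric vector of differences (one per probe set).
#' @slot mu,sigma mean and sample SD (denominator n-1) of \code{d}.
#' @slot z named numeric vector of z-scores.
#' @seealso [computeDiff()], [extractHits()]
#' @export
setClass("DiffData", representation(line = "character", d = "numeric",
                                    mu = "numeric", sigma = "numeric",
                                    z = "numeric"))

setValidity("DiffData", function(object) {
  msg <- character()
  if (length(object@sigma) != 1L || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive value")
  if (!identical(names(object@d), names(object@z)))
    msg <- c(msg, "d and z must share names")
  if (length(object@z) > 1L) {
    if (abs(mean(object@z)) > 1e-9)
      msg <- c(msg, "z-scores must have mean 0 (within 1e-9)")
    if (abs(sd(object@z) - 1) > 1e-9)
      msg <- c(msg, "z-scores must have SD 1 (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiffData", function(object) {
  cat("DiffData for cell line", object@line, ":", length(object@d),
      "probe sets\n  mu =", signif(object@mu, 4), ", sigma =",
      signif(object@sigma, 4), "\n  |z| >= 3 for",
      sum(abs(object@z) >= 3), "probe sets\n")
})

#' Seed-enriched subnetwork
#'
#' A connected gene subnetwork extracted from an interaction graph, scored by
#' the hypergeometric tail probability of containing as many seed genes as it
#' does.  Carries the induced subgraph, the parent graph (so merges can
#' re-induce edges), and the seed set used for scoring.
#'
#' @slot graph induced \code{igraph} subgraph.
#' @slot nodes character vector of member gene ids.
#' @slot seeds seed genes present anywhere in the parent graph.
#' @slot seedCount number of seeds inside this subnetwork.
#' @slot enrichmentP hypergeometric \eqn{P(X \ge \mathrm{seedCount})}.
#' @slot population number of nodes in the parent graph.
#' @slot parent the parent \code{igraph}.
#' @slot anchor anchor gene recorded by [selectContaining()] (may be empty).
#' @seealso [buildSeedSubnetworks()], [mergeSubnetworks()],
#'   [rankCentralNodes()]
#' @export
setClass("ScoredSubnetwork",
         representation(graph = "igraph", nodes = "character",
                        seeds = "character", seedCount = "integer",
                        enrichmentP = "numeric", population = "integer",
                        parent = "igraph", anchor = "character"))

setValidity("ScoredSubnetwork", function(object) {
  msg <- character()
  if (object@seedCount > length(object@nodes))
    msg <- c(msg, "seedCount cannot exceed the number of nodes")
  if (object@enrichmentP <= 0 || object@enrichmentP > 1)
    msg <- c(msg, "enrichmentP must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoredSubnetwork", function(object) {
  cat("ScoredSubnetwork:", length(object@nodes), "nodes,",
      igraph::ecount(object@graph), "edges;", object@seedCount,
      "seeds; enrichment p =", signif(object@enrichmentP, 3), "\n")
  if (length(object@anchor))
    cat("  anchored on:", object@anchor, "\n")
})

#' @describeIn ScoredSubnetwork-class member gene ids.
#' @param x a \code{ScoredSubnetwork}.
#' @export
subnetworkNodes <- function(x) x@nodes

#' @describeIn ScoredSubnetwork-class hypergeometric enrichment p-value.
#' @export
enrichmentP <- function(x) x@enrichmentP

#' @describeIn ScoredSubnetwork-class number of seed genes inside.
#' @export
seedCount <- function(x) x@seedCount

#' @describeIn ScoredSubnetwork-class does the subnetwork contain a gene?
#' @param anchor gene id to look up.
#' @export
containsAnchor <- function(x, anchor) anchor %in% x@nodes

#' @describeIn DiffData-class the difference vector \code{d}.
#' @param x a \code{DiffData}.
#' @export
diffValues <- function(x) x@d

#' @describeIn DiffData-class the z-score vector.
#' @export
zScores <- function(x) x@z
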