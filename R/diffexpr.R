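#' Paired expression differences and z-scores for one cell line
#'
#' Builds the per-probe-set difference vector d = control - knockdown (log2
#' units; a positive d means expression fell upon knockdown), standardizes
#' it to z-scores with the sample mean and SD (denominator n-1), and
#' returns a \linkS4class{DiffData}.
#'
#' @param se \code{SummarizedExperiment} from [preprocessExperiment()] whose
#'   colData identifies exactly one knockdown and one control array for the
#'   requested line.
#' @param line cell-line id (a value of \code{colData(se)$cell_line}).
#' @return A \linkS4class{DiffData}.
#' @examples
#' \dontrun{diff <- computeDiff(se, "lineA")}
#' @export
computeDiff <- function(se, line) {
  cd <- SummarizedExperiment::colData(se)
  ctl <- which(cd$cell_line == line & cd$condition == "control")
  kd <- which(cd$cell_line == line & cd$condition == "knockdown")
  if (length(ctl) != 1L || length(kd) != 1L)
    stop(sprintf(paste("cell line '%s' must have exactly one control and",
                       "one knockdown sample"), line), call. = FALSE)
  exprs <- SummarizedExperiment::assay(se, "exprs")
  d <- exprs[, ctl] - exprs[, kd]
  names(d) <- rownames(exprs)
  mu <- mean(d)
  sigma <- sd(d)
  if (!is.finite(sigma) || sigma == 0)
    stop("difference vector has zero variance; z-scores undefined",
         call. = FALSE)
  new("DiffData", line = line, d = d, mu = mu, sigma = sigma,
      z = (d - mu) / sigma)
}

#' Select differential-expression hits by z-score threshold
#'
#' Extracts probe sets with |z| >= threshold (inclusive by default; set
#' \code{strict = TRUE} for a strictly-greater reading), annotates them
#' with gene symbols and the direction implied by the sign of d, and sorts
#' by |z| descending.
#'
#' @param diff a \linkS4class{DiffData}.
#' @param threshold positive z cutoff (default 3).
#' @param annotation data.frame with columns \code{probeset_id} and
#'   \code{gene_symbol}; probe sets missing from it are kept with an NA
#'   symbol and a warning.
#' @param strict use |z| > threshold instead of >=.
#' @return data.frame with columns \code{probeset_id}, \code{gene_symbol},
#'   \code{d}, \code{z}, \code{direction} ("up_in_knockdown" when d < 0,
#'   "down_in_knockdown" when d > 0) and attribute \code{threshold}.
#' @export
extractHits <- function(diff, threshold = 3, annotation, strict = FALSE) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  z <- diff@z
  keep <- if (strict) abs(z) > threshold else abs(z) >= threshold
  ids <- names(z)[keep]
  sym <- rep(NA_character_, length(ids))
  if (!missing(annotation) && !is.null(annotation)) {
    m <- match(ids, annotation$probeset_id)
    sym <- annotation$gene_symbol[m]
    if (anyNA(m))
      warning(sprintf("%d hit probe set(s) missing from annotation",
                      sum(is.na(m))))
  }
  hits <- data.frame(probeset_id = ids, gene_symbol = sym,
                     d = unname(diff@d[ids]), z = unname(z[ids]),
                     direction = ifelse(diff@d[ids] > 0, "down_in_knockdown",
                                        "up_in_knockdown"))
  hits <- hits[order(-abs(hits$z), hits$probeset_id), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "threshold") <- threshold
  attr(hits, "line") <- diff@line
  hits
}

#' Intersect two per-line hit lists into the common gene set
#'
#' Genes (matched by symbol, regardless of direction) present in both hit
#' lists; when several probe sets of one gene are hits in a line, their d
#' values are averaged.  Genes whose direction disagrees between the lines
#' are retained and flagged \code{concordant = FALSE}.
#'
#' @param a,b annotated hit lists from [extractHits()]; probe sets with an
#'   NA gene symbol cannot enter the intersection.
#' @return data.frame with columns \code{gene_symbol}, \code{value_a},
#'   \code{value_b} (mean d per line), \code{concordant},
#'   \code{probesets_a}, \code{probesets_b} (comma-separated provenance),
#'   sorted by gene symbol.
#' @export
intersectHits <- function(a, b) {
  genes <- sort(intersect(na.omit(a$gene_symbol), na.omit(b$gene_symbol)))
  perGene <- function(h, g) {
    rows <- h[!is.na(h$gene_symbol) & h$gene_symbol == g, , drop = FALSE]
    list(value = mean(rows$d),
         probesets = paste(sort(rows$probeset_id), collapse = ","))
  }
  out <- lapply(genes, function(g) {
    ga <- perGene(a, g); gb <- perGene(b, g)
    data.frame(gene_symbol = g, value_a = ga$value, value_b = gb$value,
               concordant = sign(ga$value) == sign(gb$value),
               probesets_a = ga$probesets, probesets_b = gb$probesets)
  })
  if (length(out) == 0)
    return(data.frame(gene_symbol = character(), value_a = numeric(),
                      value_b = numeric(), concordant = logical(),
                      probesets_a = character(),
                      probesets_b = character()))
  do.call(rbind, out)
}

#' Hierarchically cluster common-hit genes for heatmap display
#'
#' Average-linkage agglomerative clustering on Euclidean row distances of
#' the gene x line value matrix.  Rows are pre-sorted lexicographically by
#' gene id so the result does not depend on input order (deterministic
#' tie-breaking).
#'
#' @param values numeric matrix with genes as rownames (e.g. the
#'   \code{value_a}/\code{value_b} columns of [intersectHits()] output).
#' @return A list with \code{order} (gene ids in display order) and
#'   \code{tree} (the \code{hclust} object).
#' @export
clusterHits <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 genes", call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite values", call. = FALSE)
  values <- values[order(rownames(values)), , drop = FALSE]
  hc <- hclust(dist(values, method = "euclidean"), method = "average")
  list(order = rownames(values)[hc$order], tree = hc)
}
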