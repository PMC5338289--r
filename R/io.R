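## Plain-text readers/writers for the pipeline's stage files.  All writers
## accept optional comment-header lines (prefixed "#", used to record the
## seed and config hash); all readers skip them.

.writeTable <- function(df, file, header = character(), sep = "\t") {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write / read a probe-level experiment as TSV
#'
#' The probe table is long format with columns \code{array_id},
#' \code{probeset_id}, \code{probe_idx}, \code{pm}, \code{mm}; the sample
#' sheet has \code{array_id}, \code{cell_line}, \code{condition}.  Lines
#' starting with \code{#} are comments.
#'
#' @param experiment a \linkS4class{ProbeLevelExperiment}.
#' @param probesFile,samplesFile file paths.
#' @param header optional comment-header lines.
#' @return \code{writeProbeTable} invisibly returns the file paths;
#'   \code{readProbeTable} returns a \linkS4class{ProbeLevelExperiment}.
#' @export
writeProbeTable <- function(experiment, probesFile, samplesFile,
                            header = character()) {
  pm <- SummarizedExperiment::assay(experiment, "pm")
  mm <- SummarizedExperiment::assay(experiment, "mm")
  rd <- SummarizedExperiment::rowData(experiment)
  long <- do.call(rbind, lapply(colnames(pm), function(a)
    data.frame(array_id = a, probeset_id = rd$probeset_id,
               probe_idx = rd$probe_idx, pm = pm[, a], mm = mm[, a])))
  .writeTable(long, probesFile, header)
  cd <- SummarizedExperiment::colData(experiment)
  .writeTable(data.frame(array_id = rownames(cd),
                         cell_line = cd$cell_line,
                         condition = cd$condition),
              samplesFile, header)
  invisible(c(probesFile, samplesFile))
}

#' @rdname writeProbeTable
#' @export
readProbeTable <- function(probesFile, samplesFile) {
  long <- read.delim(probesFile, comment.char = "#")
  samples <- read.delim(samplesFile, comment.char = "#")
  arrays <- samples$array_id
  key <- paste(long$probeset_id, long$probe_idx)
  first <- long[long$array_id == arrays[1], ]
  pm <- mm <- matrix(NA_real_, nrow(first), length(arrays),
                     dimnames = list(NULL, arrays))
  for (a in arrays) {
    sub <- long[long$array_id == a, ]
    m <- match(paste(first$probeset_id, first$probe_idx),
               paste(sub$probeset_id, sub$probe_idx))
    pm[, a] <- sub$pm[m]
    mm[, a] <- sub$mm[m]
  }
  ProbeLevelExperiment(pm, mm, first$probeset_id, first$probe_idx,
                       data.frame(cell_line = samples$cell_line,
                                  condition = samples$condition,
                                  row.names = arrays))
}

#' Write / read an expression matrix with calls as TSV
#'
#' @param se \code{SummarizedExperiment} from [preprocessExperiment()].
#' @param file file path.
#' @param header optional comment-header lines.
#' @export
writeExpressionMatrix <- function(se, file, header = character()) {
  exprs <- SummarizedExperiment::assay(se, "exprs")
  calls <- SummarizedExperiment::assay(se, "calls")
  df <- data.frame(probeset_id = rownames(exprs), exprs,
                   setNames(as.data.frame(calls),
                            paste0("call_", colnames(calls))),
                   check.names = FALSE)
  .writeTable(df, file, header)
  invisible(file)
}

#' Write / read a TMA cohort as CSV
#'
#' Missing values are written as \code{NA}.
#'
#' @param cohort cohort data.frame (see [simulateTMACohort()]).
#' @param file file path.
#' @param header optional comment-header lines.
#' @export
writeCohort <- function(cohort, file, header = character()) {
  .writeTable(cohort, file, header, sep = ",")
  invisible(file)
}

#' @rdname writeCohort
#' @export
readCohort <- function(file) {
  read.csv(file, comment.char = "#")
}

#' Write / read a gene-interaction graph as edge-list + node-tag TSVs
#'
#' @param graph an \code{igraph} with named vertices and a \code{tags}
#'   attribute.
#' @param edgesFile,tagsFile file paths.
#' @param header optional comment-header lines.
#' @export
writeGraph <- function(graph, edgesFile, tagsFile, header = character()) {
  el <- igraph::as_edgelist(graph)
  .writeTable(data.frame(node_a = el[, 1], node_b = el[, 2]), edgesFile,
              header)
  .writeTable(data.frame(node = igraph::V(graph)$name,
                         tags = igraph::vertex_attr(graph, "tags") %||%
                           ""),
              tagsFile, header)
  invisible(c(edgesFile, tagsFile))
}

#' @rdname writeGraph
#' @export
readGraph <- function(edgesFile, tagsFile = NULL) {
  el <- read.delim(edgesFile, comment.char = "#")
  g <- igraph::graph_from_edgelist(as.matrix(el[, 1:2]), directed = FALSE)
  g <- igraph::simplify(g)
  if (!is.null(tagsFile)) {
    tags <- read.delim(tagsFile, comment.char = "#")
    m <- match(igraph::V(g)$name, tags$node)
    g <- igraph::set_vertex_attr(g, "tags",
                                 value = ifelse(is.na(m), "",
                                                tags$tags[m]))
  }
  g
}
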