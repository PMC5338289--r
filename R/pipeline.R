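#' Configuration for the end-to-end pipeline
#'
#' Bundles per-stage configurations.  The global \code{seed} re-seeds each
#' stage deterministically (stage seeds are derived as seed, seed+1,
#' seed+2), so a single integer reproduces the whole run.
#'
#' @param array an [arraySimConfig()].
#' @param detection a [detectionParams()].
#' @param zThreshold hit-selection z cutoff.
#' @param graph a [graphSimConfig()].
#' @param allowedTags annotation tags kept by the network filter.
#' @param cohort a [cohortSimConfig()].
#' @param cutoff staining dichotomization cutoff.
#' @param minMaxLog2 probe-set filter threshold.
#' @param seed global seed; \code{NULL} keeps each stage's own seed.
#' @return List of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(array = arraySimConfig(),
                           detection = detectionParams(), zThreshold = 3,
                           graph = graphSimConfig(),
                           allowedTags = c("bone", "neoplasm"),
                           cohort = cohortSimConfig(), cutoff = 2L,
                           minMaxLog2 = log2(100), seed = 1L) {
  if (zThreshold <= 0) .cfgStop("zThreshold", "must be positive")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    array$seed <- seed
    graph$seed <- seed + 1L
    cohort$seed <- seed + 2L
  }
  structure(list(array = array, detection = detection,
                 zThreshold = zThreshold, graph = graph,
                 allowedTags = allowedTags, cohort = cohort,
                 cutoff = as.integer(cutoff), minMaxLog2 = minMaxLog2,
                 seed = seed),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys \code{array}, \code{detection}, \code{graph},
#' \code{cohort}, \code{zThreshold}, \code{allowedTags}, \code{cutoff},
#' \code{minMaxLog2}, \code{seed}; each stage key holds arguments for the
#' corresponding config constructor.
#'
#' @param file path to a YAML file.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(file) {
  y <- yaml::read_yaml(file)
  args <- list()
  if (!is.null(y$array)) args$array <- do.call(arraySimConfig, y$array)
  if (!is.null(y$detection))
    args$detection <- do.call(detectionParams, y$detection)
  if (!is.null(y$graph)) args$graph <- do.call(graphSimConfig, y$graph)
  if (!is.null(y$cohort)) args$cohort <- do.call(cohortSimConfig, y$cohort)
  for (k in c("zThreshold", "allowedTags", "cutoff", "minMaxLog2", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipelineConfig, args)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Simulate (arrays, interaction graph, cohort), preprocess, run the
#' differential-expression and intersection step, reconstruct the network,
#' and run the TMA/survival statistics.  Stage boundaries are files in
#' \code{outDir}, so each stage is independently inspectable and
#' replaceable by real data; every numeric output carries the seed and
#' config hash in a comment header.  A JSON run manifest with per-file MD5
#' checksums is written last.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return The run manifest (invisibly also written to
#'   \code{manifest.json}): config hash, seed, per-stage files and
#'   checksums, headline results, warnings.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  hdr <- c(sprintf("seed=%s", config$seed %||% "stage-local"),
           sprintf("config_hash=%s", hash))
  stageFiles <- list()
  path <- function(f) file.path(outDir, f)

  ## stage 1: simulate
  sim <- simulateArrayExperiment(config$array)
  writeProbeTable(sim$experiment, path("probes.tsv"), path("samples.tsv"),
                  hdr)
  .writeTable(sim$annotation, path("annotation.tsv"), hdr)
  jsonlite::write_json(
    list(responders = sim$truth$responders,
         sharedResponders = sim$truth$sharedResponders,
         sharedResponderGenes = sim$truth$sharedResponderGenes,
         absent = sim$truth$absent),
    path("truth_array.json"), auto_unbox = TRUE, digits = NA)
  stageFiles$simulate <- c("probes.tsv", "samples.tsv", "annotation.tsv",
                           "truth_array.json")

  ## stage 2: preprocess
  se <- preprocessExperiment(sim$experiment, config$detection,
                             config$minMaxLog2)
  writeExpressionMatrix(se, path("expression.tsv"), hdr)
  stageFiles$preprocess <- "expression.tsv"

  ## stage 3: differential expression + intersection
  lines <- unique(SummarizedExperiment::colData(se)$cell_line)
  hits <- lapply(lines, function(ln)
    extractHits(computeDiff(se, ln), config$zThreshold, sim$annotation))
  names(hits) <- lines
  for (ln in lines)
    .writeTable(hits[[ln]], path(sprintf("hits_%s.tsv", ln)), hdr)
  common <- intersectHits(hits[[1]], hits[[2]])
  .writeTable(common, path("common_hits.tsv"), hdr)
  if (nrow(common) >= 2) {
    vals <- as.matrix(common[, c("value_a", "value_b")])
    rownames(vals) <- common$gene_symbol
    ord <- clusterHits(vals)
    .writeTable(data.frame(gene_symbol = ord$order,
                           vals[ord$order, , drop = FALSE]),
                path("common_hits_ordered.tsv"), hdr)
  }
  stageFiles$diffexpr <- c(sprintf("hits_%s.tsv", lines), "common_hits.tsv")

  ## stage 4: network reconstruction
  seeds <- common$gene_symbol
  if (length(seeds) < 3)
    stop("stage network failed: too few common genes to seed the graph",
         call. = FALSE)
  gsim <- simulateInteractionGraph(config$graph, seeds)
  writeGraph(gsim$graph, path("edges.tsv"), path("node_tags.tsv"), hdr)
  net <- reconstructNetwork(gsim$graph, seeds,
                            anchor = config$graph$anchorName,
                            allowedTags = config$allowedTags)
  .writeTable(net$centrality, path("centrality.tsv"), hdr)
  writeGraph(net$filtered@graph, path("final_network_edges.tsv"),
             path("final_network_tags.tsv"), hdr)
  jsonlite::write_json(list(hub = gsim$truth$hub,
                            anchor = gsim$truth$anchor),
                       path("truth_graph.json"), auto_unbox = TRUE)
  stageFiles$network <- c("edges.tsv", "node_tags.tsv", "centrality.tsv",
                          "final_network_edges.tsv",
                          "final_network_tags.tsv", "truth_graph.json")

  ## stage 5: TMA / survival
  csim <- simulateTMACohort(config$cohort)
  writeCohort(csim$cohort, path("cohort.csv"), hdr)
  summ <- cohortSummary(csim$cohort, config$cutoff)
  .writeTable(summ$features, path("cohort_summary.tsv"), hdr)
  arGrp <- dichotomize(csim$cohort$ar_category, config$cutoff)
  cdkGrp <- dichotomize(csim$cohort$cdk11_category, config$cutoff)
  assoc <- chiSquare(table(arGrp, cdkGrp))
  rho <- spearmanRho(csim$cohort$ar_category, csim$cohort$cdk11_category)
  lr <- logRank(arGrp, csim$cohort$followup_months, csim$cohort$event)
  km <- lapply(split(csim$cohort, arGrp), function(d)
    kaplanMeier(d$followup_months, d$event))
  for (g in names(km))
    .writeTable(km[[g]], path(sprintf("km_ar_%s.tsv", g)), hdr)
  cox <- coxFit(data.frame(ar_high = as.integer(arGrp == "high")),
                csim$cohort$followup_months, csim$cohort$event)
  stats <- list(chi_square = assoc, spearman_rho = rho, log_rank = lr,
                cox_ar_hr = unname(cox$hr[1]))
  jsonlite::write_json(stats, path("tma_stats.json"), auto_unbox = TRUE,
                       digits = NA)
  stageFiles$tma <- c("cohort.csv", "cohort_summary.tsv",
                      sprintf("km_ar_%s.tsv", names(km)), "tma_stats.json")

  files <- unlist(stageFiles, use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cdk11net")),
    seed = config$seed, config_hash = hash,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = lapply(stageFiles, function(fs)
      list(files = fs,
           checksums = as.list(tools::md5sum(file.path(outDir, fs))))),
    results = list(
      hits_per_line = as.list(setNames(vapply(hits, nrow, integer(1)),
                                       lines)),
      common_genes = nrow(common), central_node = net$centralNode,
      planted_hub = gsim$truth$hub, tma = stats),
    out_dir = outDir)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Assemble a plain-text run report
#'
#' Collates a completed [runPipeline()] run into a single markdown
#' document: hit counts per line, the common-gene table, the nominated
#' central node with its planted-truth comparison, the cohort summary and
#' survival statistics, and the recovered-vs-planted responder confusion
#' counts.  Missing stage outputs are flagged rather than fatal.
#'
#' @param outDir directory written by [runPipeline()].
#' @param file report path (default \code{report.md} inside
#'   \code{outDir}).
#' @return The report path, invisibly; the report body is deterministic
#'   apart from the single \code{generated:} timestamp line.
#' @export
makeReport <- function(outDir, file = file.path(outDir, "report.md")) {
  manifestFile <- file.path(outDir, "manifest.json")
  if (!file.exists(manifestFile))
    stop("no manifest.json in ", outDir, call. = FALSE)
  man <- jsonlite::read_json(manifestFile, simplifyVector = TRUE)
  lines <- c("# Knockdown network pipeline report", "",
             sprintf("generated: %s", format(Sys.time())),
             sprintf("seed: %s | config hash: %s", man$seed,
                     man$config_hash), "")

  lines <- c(lines, "## Differential expression", "")
  hp <- man$results$hits_per_line
  for (ln in names(hp))
    lines <- c(lines, sprintf("- %s: %d hit probe sets", ln, hp[[ln]]))
  lines <- c(lines, sprintf("- common genes across lines: %d",
                            man$results$common_genes), "")

  commonFile <- file.path(outDir, "common_hits.tsv")
  truthFile <- file.path(outDir, "truth_array.json")
  if (file.exists(commonFile) && file.exists(truthFile)) {
    common <- read.delim(commonFile, comment.char = "#")
    truth <- jsonlite::read_json(truthFile, simplifyVector = TRUE)
    planted <- truth$sharedResponderGenes
    recovered <- intersect(common$gene_symbol, planted)
    lines <- c(lines, "### Recovered vs planted shared responders", "",
               sprintf("- planted: %d, recovered: %d, missed: %d, false: %d",
                       length(planted), length(recovered),
                       length(setdiff(planted, common$gene_symbol)),
                       length(setdiff(common$gene_symbol, planted))), "")
  } else {
    lines <- c(lines, "_(ground truth or common-hit table missing)_", "")
  }

  lines <- c(lines, "## Network reconstruction", "",
             sprintf("- nominated central node: %s",
                     man$results$central_node),
             sprintf("- planted hub: %s (%s)", man$results$planted_hub,
                     if (identical(man$results$central_node,
                                   man$results$planted_hub))
                       "recovered" else "not recovered"), "")

  statsFile <- file.path(outDir, "tma_stats.json")
  if (file.exists(statsFile)) {
    st <- jsonlite::read_json(statsFile, simplifyVector = TRUE)
    lines <- c(lines, "## TMA cohort and survival", "",
               sprintf("- AR vs CDK11 staining chi-square: %.3f (p = %.3g)",
                       st$chi_square$statistic, st$chi_square$p),
               sprintf("- Spearman rho (AR vs CDK11 categories): %.3f",
                       st$spearman_rho),
               sprintf("- log-rank AR high vs low: %.3f (p = %.3g)",
                       st$log_rank$statistic, st$log_rank$p),
               sprintf("- Cox HR, AR high vs low: %.3f", st$cox_ar_hr), "")
  } else {
    lines <- c(lines, "## TMA cohort and survival", "",
               "_(cohort stage output missing; section omitted)_", "")
  }

  writeLines(lines, file)
  invisible(file)
}
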