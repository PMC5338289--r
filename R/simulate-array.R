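#' Configuration for the synthetic knockdown microarray experiment
#'
#' Defines the generative model for a two-cell-line siRNA knockdown
#' experiment: each cell line contributes one knockdown and one control
#' array (the single-comparison design), probe sets carry log-normal
#' probe-pair intensities, and a planted subset of probe sets responds to
#' the knockdown by a fixed log2 shift.
#'
#' The probe-level model for an expressed probe set s, probe j, array a is
#' \deqn{PM_{ja} = 2^{b_s + f_{sj} + \delta_{sa} + \epsilon},\quad
#'       MM_{ja} = m \cdot PM_{ja} \cdot 2^{\epsilon'}}
#' with baseline \eqn{b_s \sim U(\mathrm{baselineLog2Range})}, probe affinity
#' \eqn{f_{sj} \sim N(0, \mathrm{probeAffinitySd}^2)}, knockdown effect
#' \eqn{\delta_{sa} = \pm\mathrm{effectLog2}} when s is a responder in that
#' array's cell line and the array is the knockdown, 0 otherwise, and
#' \eqn{\epsilon, \epsilon' \sim N(0, \mathrm{noiseSd}^2)}.  Absent probe
#' sets sit at a fixed low background with MM at the PM level, so their
#' discrimination scores hover around zero and they draw Absent calls.
#'
#' @param nProbesets total probe sets per array.
#' @param probesPerSet probe pairs per probe set.
#' @param nSharedResponders probe sets responding in both cell lines.
#' @param nSpecificRespondersPerLine probe sets responding in only one line.
#' @param nDiscordantShared how many shared responders flip direction between
#'   the two lines (emulating discordant hits such as HELLS).
#' @param effectLog2 magnitude of the knockdown-induced log2 shift.
#' @param baselineLog2Range length-2 interval for probe-set baseline means.
#' @param probeAffinitySd log2 SD of per-probe affinity offsets.
#' @param noiseSd log2 SD of measurement noise.
#' @param mmFraction expected MM/PM ratio for expressed probe sets, in (0,1).
#' @param nAbsentProbesets probe sets simulated at background on all arrays.
#' @param backgroundLog2 log2 level of absent probe sets.
#' @param duplicateGeneFraction fraction of non-responder probe sets that
#'   share a gene symbol with another probe set (exercises per-gene probe
#'   averaging downstream).
#' @param seed RNG seed; identical configs give byte-identical output.
#' @return A validated list of class \code{ArraySimConfig}.
#' @seealso [simulateArrayExperiment()]
#' @export
arraySimConfig <- function(nProbesets = 500L, probesPerSet = 11L,
                           nSharedResponders = 20L,
                           nSpecificRespondersPerLine = 10L,
                           nDiscordantShared = 1L,
                           effectLog2 = 1.5,
                           baselineLog2Range = c(7, 12),
                           probeAffinitySd = 0.5, noiseSd = 0.15,
                           mmFraction = 0.3, nAbsentProbesets = 50L,
                           backgroundLog2 = 4, duplicateGeneFraction = 0.05,
                           seed = 1L) {
  cfg <- list(nProbesets = as.integer(nProbesets),
              probesPerSet = as.integer(probesPerSet),
              nSharedResponders = as.integer(nSharedResponders),
              nSpecificRespondersPerLine =
                as.integer(nSpecificRespondersPerLine),
              nDiscordantShared = as.integer(nDiscordantShared),
              effectLog2 = effectLog2,
              baselineLog2Range = baselineLog2Range,
              probeAffinitySd = probeAffinitySd, noiseSd = noiseSd,
              mmFraction = mmFraction,
              nAbsentProbesets = as.integer(nAbsentProbesets),
              backgroundLog2 = backgroundLog2,
              duplicateGeneFraction = duplicateGeneFraction,
              seed = as.integer(seed))
  class(cfg) <- "ArraySimConfig"
  .validateArraySimConfig(cfg)
  cfg
}

.cfgStop <- function(field, why)
  stop(sprintf("invalid configuration: field '%s' %s", field, why),
       call. = FALSE)

.validateArraySimConfig <- function(cfg) {
  with(cfg, {
    if (nProbesets < 1) .cfgStop("nProbesets", "must be >= 1")
    if (probesPerSet < 3) .cfgStop("probesPerSet", "must be >= 3")
    if (nSharedResponders + 2L * nSpecificRespondersPerLine +
        nAbsentProbesets > nProbesets)
      .cfgStop("nProbesets", paste("must accommodate shared + 2*specific",
                                   "responders + absent probe sets"))
    if (nDiscordantShared > nSharedResponders)
      .cfgStop("nDiscordantShared", "cannot exceed nSharedResponders")
    if (mmFraction <= 0 || mmFraction >= 1)
      .cfgStop("mmFraction", "must lie in (0, 1)")
    if (probeAffinitySd < 0) .cfgStop("probeAffinitySd", "must be >= 0")
    if (noiseSd < 0) .cfgStop("noiseSd", "must be >= 0")
    if (length(baselineLog2Range) != 2 ||
        baselineLog2Range[1] > baselineLog2Range[2])
      .cfgStop("baselineLog2Range", "must be an ordered interval")
    if (duplicateGeneFraction < 0 || duplicateGeneFraction >= 1)
      .cfgStop("duplicateGeneFraction", "must lie in [0, 1)")
  })
  invisible(cfg)
}

#' Simulate a two-line knockdown/control probe-level experiment
#'
#' Generates four arrays (lineA and lineB, each with a knockdown and a
#' control array), a probe-set to gene-symbol annotation table, and the
#' planted ground truth (responder probe sets with directions, absent probe
#' sets).  See [arraySimConfig()] for the generative model.
#'
#' @param cfg an \code{ArraySimConfig}.
#' @return A list with elements \code{experiment}
#'   (\linkS4class{ProbeLevelExperiment}), \code{annotation} (data.frame
#'   with columns \code{probeset_id}, \code{gene_symbol}) and \code{truth}
#'   (list: \code{responders} data.frame of line/probeset/gene/direction,
#'   \code{sharedResponders}, \code{absent}, \code{config}).
#' @examples
#' sim <- simulateArrayExperiment(arraySimConfig(nProbesets = 60,
#'   nSharedResponders = 4, nSpecificRespondersPerLine = 2,
#'   nAbsentProbesets = 5, seed = 7))
#' sim$experiment
#' @export
simulateArrayExperiment <- function(cfg = arraySimConfig()) {
  .validateArraySimConfig(cfg)
  set.seed(cfg$seed)
  n <- cfg$nProbesets
  J <- cfg$probesPerSet
  psIds <- sprintf("PS%05d_at", seq_len(n))

  ## role assignment
  special <- sample(n, cfg$nAbsentProbesets + cfg$nSharedResponders +
                      2L * cfg$nSpecificRespondersPerLine)
  absentIdx <- special[seq_len(cfg$nAbsentProbesets)]
  rest <- special[-seq_len(cfg$nAbsentProbesets)]
  sharedIdx <- rest[seq_len(cfg$nSharedResponders)]
  rest <- rest[-seq_len(cfg$nSharedResponders)]
  specAIdx <- rest[seq_len(cfg$nSpecificRespondersPerLine)]
  specBIdx <- rest[-seq_len(cfg$nSpecificRespondersPerLine)]

  ## planted directions (+1: knockdown raises expression, -1: lowers)
  dirShared <- sample(c(-1, 1), length(sharedIdx), replace = TRUE)
  dirSharedB <- dirShared
  if (cfg$nDiscordantShared > 0 && length(sharedIdx) > 0) {
    flip <- seq_len(cfg$nDiscordantShared)
    dirSharedB[flip] <- -dirSharedB[flip]
  }
  dirA <- sample(c(-1, 1), length(specAIdx), replace = TRUE)
  dirB <- sample(c(-1, 1), length(specBIdx), replace = TRUE)

  effectByLine <- list(lineA = numeric(n), lineB = numeric(n))
  effectByLine$lineA[sharedIdx] <- dirShared * cfg$effectLog2
  effectByLine$lineA[specAIdx] <- dirA * cfg$effectLog2
  effectByLine$lineB[sharedIdx] <- dirSharedB * cfg$effectLog2
  effectByLine$lineB[specBIdx] <- dirB * cfg$effectLog2

  baseline <- runif(n, cfg$baselineLog2Range[1], cfg$baselineLog2Range[2])
  baseline[absentIdx] <- cfg$backgroundLog2
  affinity <- matrix(rnorm(n * J, 0, cfg$probeAffinitySd), n, J)
  isAbsent <- logical(n); isAbsent[absentIdx] <- TRUE

  samples <- data.frame(
    cell_line = rep(c("lineA", "lineB"), each = 2),
    condition = rep(c("control", "knockdown"), 2),
    row.names = c("lineA_control", "lineA_knockdown",
                  "lineB_control", "lineB_knockdown"))

  nProbes <- n * J
  pm <- mm <- matrix(NA_real_, nProbes, nrow(samples),
                     dimnames = list(NULL, rownames(samples)))
  probesetCol <- rep(psIds, each = J)
  probeIdxCol <- rep(seq_len(J), n)
  baseMat <- matrix(rep(baseline, each = J) + as.vector(t(affinity)),
                    nProbes, 1)[, 1]
  mmFrac <- ifelse(rep(isAbsent, each = J), 1, cfg$mmFraction)

  for (a in seq_len(nrow(samples))) {
    eff <- if (samples$condition[a] == "knockdown")
      effectByLine[[samples$cell_line[a]]] else numeric(n)
    log2pm <- baseMat + rep(eff, each = J) + rnorm(nProbes, 0, cfg$noiseSd)
    pm[, a] <- 2^log2pm
    mm[, a] <- mmFrac * pm[, a] * 2^rnorm(nProbes, 0, cfg$noiseSd)
  }

  annotation <- .makeAnnotation(psIds, absentIdx,
                                c(sharedIdx, specAIdx, specBIdx),
                                cfg$duplicateGeneFraction)
  sym <- setNames(annotation$gene_symbol, annotation$probeset_id)

  responders <- rbind(
    data.frame(line = "lineA",
               probeset_id = psIds[c(sharedIdx, specAIdx)],
               gene_symbol = unname(sym[psIds[c(sharedIdx, specAIdx)]]),
               direction = ifelse(c(dirShared, dirA) > 0,
                                  "up_in_knockdown", "down_in_knockdown"),
               shared = c(rep(TRUE, length(sharedIdx)),
                          rep(FALSE, length(specAIdx)))),
    data.frame(line = "lineB",
               probeset_id = psIds[c(sharedIdx, specBIdx)],
               gene_symbol = unname(sym[psIds[c(sharedIdx, specBIdx)]]),
               direction = ifelse(c(dirSharedB, dirB) > 0,
                                  "up_in_knockdown", "down_in_knockdown"),
               shared = c(rep(TRUE, length(sharedIdx)),
                          rep(FALSE, length(specBIdx)))))

  truth <- list(responders = responders,
                sharedResponders = psIds[sharedIdx],
                sharedResponderGenes = unname(sym[psIds[sharedIdx]]),
                absent = psIds[absentIdx],
                config = cfg)

  list(experiment = ProbeLevelExperiment(pm, mm, probesetCol, probeIdxCol,
                                         samples),
       annotation = annotation, truth = truth)
}

## gene symbols: responders and absent sets always get their own symbol;
## a fraction of the remaining probe sets pair up to share one.
.makeAnnotation <- function(psIds, absentIdx, responderIdx, dupFraction) {
  n <- length(psIds)
  gene <- sprintf("GENE%05d", seq_len(n))
  plain <- setdiff(seq_len(n), c(absentIdx, responderIdx))
  nDup <- floor(length(plain) * dupFraction / 2) * 2
  if (nDup >= 2) {
    dup <- sample(plain, nDup)
    firsts <- dup[seq_len(nDup / 2)]
    seconds <- dup[-seq_len(nDup / 2)]
    gene[seconds] <- gene[firsts]
  }
  data.frame(probeset_id = psIds, gene_symbol = gene)
}
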