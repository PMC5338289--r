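#' Configuration for the synthetic gene-interaction graph
#'
#' A transparent stand-in for a curated interaction database: a
#' preferential-attachment (scale-free) base graph over \code{nNodes} genes,
#' into which one designated hub gene is additionally wired to
#' \code{ceiling(hubSeedFraction * |seeds|)} of the seed genes and tagged
#' \{bone, neoplasm\}.  An optional anchor gene (the knocked-down kinase in
#' the motivating application) is wired to the hub and to a few seeds so
#' that anchor-containing subnetworks exist.
#'
#' @param nNodes number of genes in the graph.
#' @param edgesPerNewNode edges added per node in the preferential-attachment
#'   base graph.
#' @param hubSeedFraction fraction of seed genes wired directly to the
#'   planted hub, in (0, 1].
#' @param tagProbs named probabilities for drawing each node's annotation
#'   tag from \{bone, neoplasm, other\}.
#' @param hubName gene id of the planted hub.
#' @param anchorName gene id of the anchor wired near the hub, or
#'   \code{NULL} for none.
#' @param anchorSeedLinks how many seeds the anchor is wired to.
#' @param seed RNG seed.
#' @return A validated list of class \code{GraphSimConfig}.
#' @seealso [simulateInteractionGraph()]
#' @export
graphSimConfig <- function(nNodes = 200L, edgesPerNewNode = 2L,
                           hubSeedFraction = 0.7,
                           tagProbs = c(bone = 0.3, neoplasm = 0.3,
                                        other = 0.4),
                           hubName = "AR", anchorName = "CDK11",
                           anchorSeedLinks = 2L, seed = 1L) {
  cfg <- list(nNodes = as.integer(nNodes),
              edgesPerNewNode = as.integer(edgesPerNewNode),
              hubSeedFraction = hubSeedFraction, tagProbs = tagProbs,
              hubName = hubName, anchorName = anchorName,
              anchorSeedLinks = as.integer(anchorSeedLinks),
              seed = as.integer(seed))
  class(cfg) <- "GraphSimConfig"
  .validateGraphSimConfig(cfg)
  cfg
}

.validateGraphSimConfig <- function(cfg) {
  with(cfg, {
    if (nNodes < 3) .cfgStop("nNodes", "must be >= 3")
    if (edgesPerNewNode < 1) .cfgStop("edgesPerNewNode", "must be >= 1")
    if (hubSeedFraction <= 0 || hubSeedFraction > 1)
      .cfgStop("hubSeedFraction", "must lie in (0, 1]")
    if (abs(sum(tagProbs) - 1) > 1e-6)
      .cfgStop("tagProbs", "probabilities must sum to 1")
  })
  invisible(cfg)
}

#' Simulate a gene-interaction graph with a planted hub
#'
#' Builds an undirected, simple (no self-loops, no multi-edges), connected
#' preferential-attachment graph; places the given seed genes on randomly
#' chosen nodes; wires the planted hub to \code{ceiling(hubSeedFraction *
#' |seeds|)} seeds and tags it \{bone, neoplasm\}; optionally wires an
#' anchor gene to the hub and a few seeds.  Node tags live in the vertex
#' attribute \code{tags} (comma-separated).
#'
#' @param cfg a \code{GraphSimConfig}.
#' @param seeds character vector of seed gene ids (>= 2 must be wired to
#'   the hub, so \code{ceiling(hubSeedFraction * length(seeds)) >= 2}).
#' @return A list with \code{graph} (an \code{igraph}) and \code{truth}
#'   (hub gene, the seeds wired to it, anchor).
#' @examples
#' sim <- simulateInteractionGraph(graphSimConfig(nNodes = 60, seed = 2),
#'                                 seeds = sprintf("GENE%05d", 1:10))
#' sim$truth$hub
#' @export
simulateInteractionGraph <- function(cfg = graphSimConfig(), seeds) {
  .validateGraphSimConfig(cfg)
  seeds <- unique(as.character(seeds))
  nHubLinks <- ceiling(cfg$hubSeedFraction * length(seeds))
  if (nHubLinks < 2)
    .cfgStop("hubSeedFraction",
             "must wire the hub to at least 2 seeds")
  reserved <- c(cfg$hubName, cfg$anchorName)
  if (cfg$nNodes < length(seeds) + length(reserved))
    .cfgStop("nNodes", "must exceed the number of seed/hub/anchor genes")

  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$nNodes, m = cfg$edgesPerNewNode,
                         directed = FALSE)

  ## name nodes: seeds and reserved genes on random distinct vertices,
  ## background genes elsewhere
  nm <- sprintf("NODE%04d", seq_len(cfg$nNodes))
  special <- sample(cfg$nNodes, length(seeds) + length(reserved))
  nm[special] <- c(seeds, reserved)
  igraph::V(g)$name <- nm
  hub <- cfg$hubName

  hubSeeds <- sample(seeds, nHubLinks)
  g <- igraph::add_edges(g, as.vector(rbind(hub, hubSeeds)))
  if (!is.null(cfg$anchorName)) {
    anchorSeeds <- sample(seeds, min(cfg$anchorSeedLinks, length(seeds)))
    g <- igraph::add_edges(g, as.vector(rbind(cfg$anchorName,
                                              c(hub, anchorSeeds))))
  }
  g <- igraph::simplify(g)

  tags <- sample(names(cfg$tagProbs), cfg$nNodes, replace = TRUE,
                 prob = cfg$tagProbs)
  names(tags) <- nm
  tags[hub] <- "bone,neoplasm"
  if (!is.null(cfg$anchorName)) tags[cfg$anchorName] <- "bone,neoplasm"
  g <- igraph::set_vertex_attr(g, "tags", value = unname(tags[
    igraph::V(g)$name]))

  list(graph = g,
       truth = list(hub = hub, hubSeeds = hubSeeds,
                    anchor = cfg$anchorName, config = cfg))
}
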