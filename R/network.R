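#' Build seed-enriched candidate subnetworks
#'
#' A transparent reconstruction heuristic standing in for proprietary
#' pathway-database tools: the subgraph induced by the seed genes together
#' with all linker nodes (non-seed nodes adjacent to at least two seeds) is
#' split into connected components, and each component is scored by the
#' hypergeometric tail probability of containing at least its number of
#' seeds (population = all graph nodes, successes = seeds present in the
#' graph, draws = component size).
#'
#' @param g an undirected \code{igraph} with named vertices (and optionally
#'   a \code{tags} vertex attribute).
#' @param seeds character vector of seed gene ids; at least one must be a
#'   node of \code{g}.
#' @param maxLinkerDegreeCap optional cap: linkers with total degree above
#'   it are excluded (guards against promiscuous nodes); \code{NULL}
#'   disables the cap.
#' @return List of \linkS4class{ScoredSubnetwork}, sorted by enrichment
#'   p-value ascending.
#' @export
buildSeedSubnetworks <- function(g, seeds, maxLinkerDegreeCap = NULL) {
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0)
    stop("no seed gene is present in the graph", call. = FALSE)
  nodes <- igraph::V(g)$name
  nonSeed <- setdiff(nodes, present)
  seedAdj <- vapply(nonSeed, function(v)
    sum(names(igraph::neighbors(g, v)) %in% present), integer(1))
  linkers <- nonSeed[seedAdj >= 2]
  if (!is.null(maxLinkerDegreeCap)) {
    deg <- igraph::degree(g, linkers)
    linkers <- linkers[deg <= maxLinkerDegreeCap]
  }
  sub <- igraph::induced_subgraph(g, c(present, linkers))
  comp <- igraph::components(sub)
  subnets <- lapply(seq_len(comp$no), function(i) {
    members <- igraph::V(sub)$name[comp$membership == i]
    .scoreSubnetwork(g, members, present)
  })
  subnets[order(vapply(subnets, enrichmentP, numeric(1)))]
}

## hypergeometric upper tail P(X >= k): k seeds among m drawn nodes, from a
## population of N nodes containing K seeds
.hyperTail <- function(k, K, N, m) phyper(k - 1, K, N - K, m,
                                          lower.tail = FALSE)

.scoreSubnetwork <- function(parent, members, seeds, anchor = character()) {
  k <- sum(members %in% seeds)
  N <- igraph::vcount(parent)
  new("ScoredSubnetwork",
      graph = igraph::induced_subgraph(parent, members),
      nodes = members, seeds = seeds, seedCount = as.integer(k),
      enrichmentP = .hyperTail(k, length(seeds), N, length(members)),
      population = as.integer(N), parent = parent, anchor = anchor)
}

#' Keep only subnetworks containing an anchor gene
#'
#' @param subnets list of \linkS4class{ScoredSubnetwork}.
#' @param anchor gene id that must be a member.
#' @return The matching subnetworks (order preserved, anchor recorded);
#'   an empty list (with a message) when none match.
#' @export
selectContaining <- function(subnets, anchor) {
  keep <- Filter(function(s) containsAnchor(s, anchor), subnets)
  if (length(keep) == 0)
    message(sprintf("no subnetwork contains anchor '%s'", anchor))
  lapply(keep, function(s) { s@anchor <- anchor; s })
}

#' Merge subnetworks into one
#'
#' Union of the node sets, with edges re-induced from the parent graph and
#' the enrichment p-value recomputed on the merged node set.
#'
#' @param subnets nonempty list of \linkS4class{ScoredSubnetwork} sharing a
#'   parent graph.
#' @return A single \linkS4class{ScoredSubnetwork}.
#' @export
mergeSubnetworks <- function(subnets) {
  if (length(subnets) == 0)
    stop("cannot merge an empty list of subnetworks", call. = FALSE)
  members <- sort(unique(unlist(lapply(subnets, subnetworkNodes))))
  first <- subnets[[1]]
  .scoreSubnetwork(first@parent, members, first@seeds, first@anchor)
}

#' Filter a subnetwork by annotation tags and trim isolated nodes
#'
#' Keeps nodes whose tag set intersects \code{allowedTags} or that are
#' whitelisted (the subnetwork's seeds and anchor always are), then drops
#' non-whitelisted nodes left without any edge (the trim step).  Edges are
#' re-induced from the parent graph.
#'
#' @param subnet a \linkS4class{ScoredSubnetwork} whose parent graph has a
#'   \code{tags} vertex attribute (comma-separated tag sets).
#' @param allowedTags tags to keep, e.g. \code{c("bone", "neoplasm")}.
#' @param anchorWhitelist additional genes never removed.
#' @return The filtered \linkS4class{ScoredSubnetwork}.
#' @export
filterByAnnotation <- function(subnet, allowedTags = c("bone", "neoplasm"),
                               anchorWhitelist = character()) {
  parent <- subnet@parent
  white <- unique(c(subnet@seeds, subnet@anchor, anchorWhitelist))
  tags <- strsplit(igraph::vertex_attr(parent, "tags",
                                       index = subnet@nodes) %||%
                     rep("", length(subnet@nodes)), ",")
  tagged <- vapply(tags, function(t) any(t %in% allowedTags), logical(1))
  keep <- subnet@nodes[tagged | subnet@nodes %in% white]
  sub <- igraph::induced_subgraph(parent, keep)
  isolated <- igraph::V(sub)$name[igraph::degree(sub) == 0]
  keep <- setdiff(keep, setdiff(isolated, white))
  .scoreSubnetwork(parent, keep, subnet@seeds, subnet@anchor)
}

#' Rank subnetwork nodes by composite centrality
#'
#' Computes degree and betweenness centrality on the subnetwork (betweenness
#' is computed within components for disconnected subnetworks), ranks each,
#' and combines them as the mean of the two rank positions, with ties broken
#' lexicographically by gene id.  The top composite rank is the central-node
#' nomination.
#'
#' @param subnet a \linkS4class{ScoredSubnetwork} with >= 2 nodes.
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{betweenness}, \code{degree_rank}, \code{betweenness_rank},
#'   \code{composite_rank} (a permutation of 1..n), sorted by composite
#'   rank; the nominated central node is row 1.
#' @export
rankCentralNodes <- function(subnet) {
  g <- subnet@graph
  if (igraph::vcount(g) < 2)
    stop("need at least 2 nodes to rank", call. = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  degRank <- rank(-deg, ties.method = "average")
  btwRank <- rank(-btw, ties.method = "average")
  composite <- (degRank + btwRank) / 2
  nodes <- igraph::V(g)$name
  ord <- order(composite, nodes)
  data.frame(node = nodes[ord], degree = unname(deg[ord]),
             betweenness = unname(btw[ord]),
             degree_rank = unname(degRank[ord]),
             betweenness_rank = unname(btwRank[ord]),
             composite_rank = seq_along(ord), row.names = NULL)
}

#' Run the full network-reconstruction stage
#'
#' Convenience wrapper: build seed subnetworks, keep the ones containing
#' the anchor, merge, filter by annotation, rank central nodes.
#'
#' @inheritParams buildSeedSubnetworks
#' @param anchor anchor gene id selecting which subnetworks are merged.
#' @param allowedTags tags for [filterByAnnotation()].
#' @return A list with \code{subnetworks} (all candidates),
#'   \code{selected}, \code{merged}, \code{filtered} and
#'   \code{centrality}; \code{centralNode} is the nominated node.
#' @export
reconstructNetwork <- function(g, seeds, anchor,
                               allowedTags = c("bone", "neoplasm"),
                               maxLinkerDegreeCap = NULL) {
  subnets <- buildSeedSubnetworks(g, seeds, maxLinkerDegreeCap)
  selected <- selectContaining(subnets, anchor)
  if (length(selected) == 0)
    return(list(subnetworks = subnets, selected = selected,
                merged = NULL, filtered = NULL, centrality = NULL,
                centralNode = NA_character_))
  merged <- mergeSubnetworks(selected)
  filtered <- filterByAnnotation(merged, allowedTags)
  cent <- rankCentralNodes(filtered)
  list(subnetworks = subnets, selected = selected, merged = merged,
       filtered = filtered, centrality = cent,
       centralNode = cent$node[1])
}
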