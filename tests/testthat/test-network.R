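## small named graph from an edge list
mkGraph <- function(..., tags = NULL) {
  g <- igraph::graph_from_edgelist(matrix(c(...), ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (!is.null(tags))
    g <- igraph::set_vertex_attr(g, "tags",
                                 value = unname(tags[igraph::V(g)$name]))
  g
}

test_that("seed subnetworks are the components of the seed+linker subgraph", {
  ## star: hub adjacent to five seeds -> a single 6-node subnetwork
  g <- mkGraph("h", "s1", "h", "s2", "h", "s3", "h", "s4", "h", "s5")
  subnets <- buildSeedSubnetworks(g, paste0("s", 1:5))
  expect_length(subnets, 1)
  expect_setequal(subnetworkNodes(subnets[[1]]),
                  c("h", paste0("s", 1:5)))
  expect_equal(seedCount(subnets[[1]]), 5L)
  ## pairwise non-adjacent seeds with no shared neighbours: singletons
  g2 <- mkGraph("s1", "x1", "s2", "x2", "s3", "x3", "x1", "x2")
  subnets2 <- buildSeedSubnetworks(g2, c("s1", "s2", "s3"))
  expect_length(subnets2, 3)
  expect_true(all(vapply(subnets2, function(s)
    length(subnetworkNodes(s)), integer(1)) == 1L))
  ## a node adjacent to only one seed is not a linker
  expect_false("x1" %in% unlist(lapply(subnets2, subnetworkNodes)))
  expect_error(buildSeedSubnetworks(g, c("nope")), "no seed")
})

test_that("hypergeometric enrichment matches hand and enumeration oracles", {
  ## population 20, 5 seeds, subnetwork of 6 holding all 5 seeds:
  ## P = C(5,5) C(15,1) / C(20,6) = 15/38760
  g <- igraph::make_ring(20)
  igraph::V(g)$name <- paste0("n", 1:20)
  ## wire n6 to the five seeds n1..n5 so they form one component
  g <- igraph::add_edges(g, as.vector(rbind("n6", paste0("n", 1:5))))
  g <- igraph::simplify(g)
  subnets <- buildSeedSubnetworks(g, paste0("n", 1:5))
  top <- subnets[[1]]
  expect_equal(seedCount(top), 5L)
  expect_length(subnetworkNodes(top), 6)
  expect_equal(enrichmentP(top), 15 / 38760, tolerance = 1e-12)
  ## scorer equals exhaustive subset enumeration on small populations
  for (case in list(c(k = 2, K = 4, N = 10, m = 5),
                    c(k = 3, K = 5, N = 12, m = 6),
                    c(k = 1, K = 3, N = 15, m = 4))) {
    expect_equal(
      phyper(case["k"] - 1, case["K"], case["N"] - case["K"], case["m"],
             lower.tail = FALSE),
      enumHyperTail(case["k"], case["K"], case["N"], case["m"]),
      tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("anchor selection preserves order and handles empty results", {
  ## "a" touches two seeds, so it is a linker and lands in one component
  g <- mkGraph("h", "s1", "h", "s2", "a", "s3", "a", "s4", "x", "y")
  subnets <- buildSeedSubnetworks(g, c("s1", "s2", "s3", "s4"))
  withAnchor <- selectContaining(subnets, "a")
  expect_true(all(vapply(withAnchor, containsAnchor, logical(1),
                         anchor = "a")))
  expect_length(withAnchor, 1)
  expect_message(none <- selectContaining(subnets, "zzz"), "no subnetwork")
  expect_length(none, 0)
  all_ <- selectContaining(subnets, "s1")
  expect_length(all_, sum(vapply(subnets, containsAnchor, logical(1),
                                 anchor = "s1")))
})

test_that("merging unions node sets, re-induces edges, recomputes enrichment", {
  g <- mkGraph("a", "b", "c", "d", "b", "c")
  seeds <- c("a", "b", "c", "d")
  subnets <- buildSeedSubnetworks(g, seeds)
  expect_length(subnets, 1)  # all connected through b-c
  ## split pieces by hand and merge
  s1 <- buildSeedSubnetworks(mkGraph("a", "b"), c("a", "b"))[[1]]
  merged <- mergeSubnetworks(list(s1, s1))
  expect_setequal(subnetworkNodes(merged), c("a", "b"))
  ## overlapping sets: 6 + 6 sharing 2 -> 10 nodes
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("r", 1:10)
  sA <- cdk11net:::.scoreSubnetwork(ring, paste0("r", 1:6), paste0("r", 1:6))
  sB <- cdk11net:::.scoreSubnetwork(ring, paste0("r", 5:10), paste0("r", 1:6))
  m <- mergeSubnetworks(list(sA, sB))
  expect_length(subnetworkNodes(m), 10)
  ## edges re-induced from the parent
  expect_equal(igraph::ecount(m@graph), 10)
  expect_error(mergeSubnetworks(list()), "empty")
})

test_that("annotation filter keeps tagged or whitelisted nodes and trims isolates", {
  tags <- c(h = "bone,neoplasm", s1 = "other", s2 = "other",
            k1 = "bone", k2 = "other", iso = "bone")
  g <- mkGraph("h", "s1", "h", "s2", "h", "k1", "h", "k2", "s1", "iso",
               tags = tags)
  sub <- cdk11net:::.scoreSubnetwork(g, igraph::V(g)$name, c("s1", "s2"),
                                     anchor = "h")
  filt <- filterByAnnotation(sub, c("bone", "neoplasm"))
  ## seeds and anchor always survive; bone-tagged k1 kept; other-tagged k2 out
  expect_true(all(c("h", "s1", "s2", "k1") %in% subnetworkNodes(filt)))
  expect_false("k2" %in% subnetworkNodes(filt))
  ## iso is bone-tagged but isolated after s1's other edges vanish? it still
  ## touches s1, so it stays; remove the tag to see the trim
  tags2 <- tags; tags2["iso"] <- "other"
  g2 <- mkGraph("h", "s1", "h", "s2", "h", "k1", "iso", "k3",
                tags = c(tags2, k3 = "bone"))
  sub2 <- cdk11net:::.scoreSubnetwork(g2, igraph::V(g2)$name, c("s1", "s2"),
                                      anchor = "h")
  filt2 <- filterByAnnotation(sub2, c("bone", "neoplasm"))
  ## k3 is tag-kept but its only neighbour iso is dropped -> trimmed
  expect_false("k3" %in% subnetworkNodes(filt2))
  ## all-other tags with no whitelist hits: only whitelisted nodes remain
  sub3 <- cdk11net:::.scoreSubnetwork(g, igraph::V(g)$name, c("s1", "s2"),
                                      anchor = character())
  filt3 <- filterByAnnotation(sub3, "nosuchtag")
  expect_setequal(subnetworkNodes(filt3), c("s1", "s2"))
})

test_that("centrality ranking matches structure and a brute-force oracle", {
  ## star: centre is rank 1
  star <- mkGraph("c", "l1", "c", "l2", "c", "l3", "c", "l4")
  subStar <- cdk11net:::.scoreSubnetwork(star, igraph::V(star)$name, "l1")
  expect_identical(rankCentralNodes(subStar)$node[1], "c")
  ## path a-b-c: middle is rank 1
  path <- mkGraph("a", "b", "b", "c")
  subPath <- cdk11net:::.scoreSubnetwork(path, igraph::V(path)$name, "a")
  expect_identical(rankCentralNodes(subPath)$node[1], "b")
  ## 6-node graph: betweenness equals exhaustive path enumeration
  g6 <- mkGraph("a", "b", "b", "c", "c", "d", "d", "a", "b", "e", "e", "f")
  nodes <- igraph::V(g6)$name
  adj <- as.matrix(igraph::as_adjacency_matrix(g6))
  oracle <- bruteBetweenness(adj)
  sub6 <- cdk11net:::.scoreSubnetwork(g6, nodes, "a")
  rep6 <- rankCentralNodes(sub6)
  expect_equal(rep6$betweenness[match(nodes, rep6$node)], oracle,
               tolerance = 1e-12)
  ## ranks form a permutation
  expect_setequal(rep6$composite_rank, seq_along(nodes))
  expect_error(rankCentralNodes(
    cdk11net:::.scoreSubnetwork(g6, "a", "a")), "at least 2")
})

test_that("the planted hub is nominated central across simulated graphs", {
  seeds <- sprintf("G%03d", 1:30)
  ok <- 0
  for (s in 1:10) {
    gs <- simulateInteractionGraph(
      graphSimConfig(nNodes = 200, hubSeedFraction = 0.7, seed = s,
                     anchorName = NULL), seeds)
    net <- reconstructNetwork(gs$graph, seeds,
                              anchor = gs$truth$hubSeeds[1])
    ok <- ok + identical(net$centralNode, gs$truth$hub)
    ## the filter never removes seeds present in the merged set or anchor
    expect_true(all(intersect(subnetworkNodes(net$merged), seeds) %in%
                      c(subnetworkNodes(net$filtered))))
  }
  expect_gte(ok, 9)
})
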