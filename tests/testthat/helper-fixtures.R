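## shared fixtures and independent oracles used across test files

suppressPackageStartupMessages(library(SummarizedExperiment))

## a small but fully featured array simulation for module tests
## keeps the responder fraction near the default config's (planted shifts
## dominate sigma when too large a share of probe sets responds)
smallArrayCfg <- function(seed = 1L, ...) {
  arraySimConfig(nProbesets = 150L, nSharedResponders = 6L,
                 nSpecificRespondersPerLine = 2L, nAbsentProbesets = 12L,
                 seed = seed, ...)
}

smallPipelineCfg <- function(seed = 1L) {
  pipelineConfig(array = smallArrayCfg(),
                 graph = graphSimConfig(nNodes = 80L),
                 cohort = cohortSimConfig(nPatients = 60L),
                 seed = seed)
}

## independent brute-force oracle for the one-sided signed-rank p-value:
## walks every sign assignment explicitly, one at a time
enumSignedRankP <- function(x) {
  x <- x[abs(x) > 1e-12]
  n <- length(x)
  if (n == 0) return(0.5)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  hits <- 0L
  for (code in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (sum(r[bits]) >= w - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

## brute-force betweenness: enumerate all simple paths per pair, keep the
## shortest, count pass-throughs (small graphs only)
bruteBetweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  allPaths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nxt in which(adj[from, ] == 1))
      if (!(nxt %in% visited))
        out <- c(out, allPaths(nxt, to, c(visited, nxt)))
    out
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- allPaths(s, t, s)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (v in setdiff(seq_len(n), c(s, t))) {
      onPath <- vapply(shortest, function(p) v %in% p, logical(1))
      btw[v] <- btw[v] + sum(onPath) / length(shortest)
    }
  }
  btw
}

## hypergeometric upper tail by explicit subset enumeration
enumHyperTail <- function(k, K, N, m) {
  seeds <- seq_len(K)
  subsets <- utils::combn(N, m)
  mean(apply(subsets, 2, function(s) sum(s %in% seeds) >= k))
}
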