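#' Split a network once by greedy modularity maximization
#'
#' Runs one level of Clauset-Newman-Moore greedy agglomerative modularity
#' clustering on the unweighted graph and returns the vertex-induced
#' subnetworks of the resulting communities. Disconnected components are
#' separated first (modularity never merges them profitably, and treating
#' them separately keeps the dendrogram well-defined). The dendrogram is
#' cut at its modularity maximum; for graphs with no modularity-improving
#' split (e.g. complete graphs) the component is returned whole.
#'
#' @param net a [PPINetwork].
#' @return list of [PPINetwork] subnetworks that partition the node set.
#' @export
modularitySplit <- function(net) {
  if (numNodes(net) == 0L) stop("empty network")
  g <- asIgraph(net)
  comp <- igraph::components(g)
  parts <- list()
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::vcount(sub) <= 2L || igraph::ecount(sub) == 0L) {
      parts <- c(parts, list(fromIgraph(sub)))
      next
    }
    fc <- igraph::cluster_fast_greedy(sub)
    # cut at the modularity maximum ourselves: igraph's membership() can
    # return a worse cut when the maximum is numerically ~0 (ties)
    qs <- fc$modularity
    best <- which.max(qs)
    memb <- igraph::cut_at(fc, steps = best - 1L)
    for (k in sort(unique(memb))) {
      parts <- c(parts,
                 list(fromIgraph(igraph::induced_subgraph(sub, memb == k))))
    }
  }
  # deterministic order: by lexicographically smallest node ID
  first <- vapply(parts, function(p) nodeIDs(p)[1L], "")
  parts[order(first)]
}

#' Recursively decompose a network into bounded-size subnetworks
#'
#' Estimating propensities directly on a genome-scale PPI network is
#' prohibitively expensive, so the network is first broken into
#' subnetworks of at most `maxSize` proteins by recursive greedy
#' modularity clustering; complexes are then detected per subnetwork.
#' A part that greedy modularity cannot split (a single community) is
#' returned as-is with a warning even when it exceeds `maxSize`; forcing a
#' bisection would invent structure the clustering does not support.
#' Cross-subnetwork edges are discarded by vertex-induced subgraphing, so
#' complexes spanning subnetworks cannot be detected — the price of the
#' speed-up.
#'
#' @param net a [PPINetwork].
#' @param maxSize largest allowed subnetwork size N_s (default 200; must be
#'   at least 4 since a complex needs at least 3 proteins).
#' @return list of node-disjoint [PPINetwork] parts covering the input
#'   node set.
#' @export
decomposeNetwork <- function(net, maxSize = 200) {
  if (maxSize < 4) stop("maxSize must be at least 4")
  if (numNodes(net) == 0L) stop("empty network")
  out <- list()
  queue <- list(net)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    if (numNodes(cur) <= maxSize) {
      out <- c(out, list(cur))
      next
    }
    parts <- modularitySplit(cur)
    if (length(parts) == 1L) {
      warning("unsplittable subnetwork of ", numNodes(cur),
              " nodes exceeds maxSize = ", maxSize, "; processed whole")
      out <- c(out, list(cur))
    } else {
      queue <- c(parts, queue)
    }
  }
  first <- vapply(out, function(p) nodeIDs(p)[1L], "")
  out[order(first)]
}
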