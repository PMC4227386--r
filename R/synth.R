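#' Simulate a PPI network with planted protein complexes
#'
#' Planted-partition construction mirroring the modelling premise that
#' co-complexed proteins are likely to interact: proteins are allocated to
#' `nComplexes` complexes (optionally sharing proteins with earlier
#' complexes), every pair of proteins that shares a complex is connected
#' with probability `pIn`, and every remaining pair with the background
#' probability `pOut`. Background proteins belong to no complex. The
#' planted complexes are returned as the gold standard, so the full
#' detection pipeline and its evaluation metrics can be exercised without
#' external data.
#'
#' The defaults (10 complexes of 5-10 proteins, dense `pIn = 0.9`
#' intra-complex wiring, sparse `pOut = 0.005` background, no overlap, no
#' background proteins) give compact dense modules of the size range
#' typical of curated complex catalogues, embedded in weak noise.
#'
#' @param nComplexes number of planted complexes.
#' @param sizeRange integer vector `c(min, max)` of complex sizes; min >= 3.
#' @param overlapProb probability that a complex member is reused from an
#'   earlier complex rather than being a new protein.
#' @param pIn intra-complex edge probability.
#' @param pOut edge probability between pairs not sharing a complex;
#'   must satisfy 0 <= pOut < pIn <= 1.
#' @param nBackground number of proteins belonging to no complex.
#' @param seed integer seed; the output is fully determined by it.
#' @return list with elements `network` (a [PPINetwork]) and `gold`
#'   (a [ComplexSet] of the planted complexes).
#' @examples
#' sim <- simulateComplexNetwork(nComplexes = 3, seed = 7)
#' sim$network
#' sim$gold
#' @export
simulateComplexNetwork <- function(nComplexes = 10, sizeRange = c(5, 10),
                                   overlapProb = 0, pIn = 0.9,
                                   pOut = 0.005, nBackground = 0,
                                   seed = 1) {
  stopifnot(nComplexes >= 0, nBackground >= 0,
            length(sizeRange) == 2L, sizeRange[1] >= 3,
            sizeRange[1] <= sizeRange[2],
            overlapProb >= 0, overlapProb <= 1)
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  withSeed(seed, {
    nProt <- 0L
    newID <- function() {
      nProt <<- nProt + 1L
      sprintf("P%04d", nProt)
    }
    gold <- vector("list", nComplexes)
    allIDs <- character(0)
    for (ci in seq_len(nComplexes)) {
      size <- sizeRange[1] + sample.int(sizeRange[2] - sizeRange[1] + 1L, 1L) - 1L
      members <- character(0)
      for (m in seq_len(size)) {
        pool <- setdiff(allIDs, members)
        if (length(pool) && stats::runif(1) < overlapProb) {
          members <- c(members, pool[sample.int(length(pool), 1L)])
        } else {
          id <- newID()
          allIDs <- c(allIDs, id)
          members <- c(members, id)
        }
      }
      gold[[ci]] <- sort(members)
    }
    allIDs <- c(allIDs,
                vapply(seq_len(nBackground), function(i) newID(), ""))
    n <- length(allIDs)
    # pairs sharing >= 1 complex
    intra <- character(0)
    for (cx in gold) {
      if (length(cx) >= 2L) {
        prs <- utils::combn(sort(cx), 2L)
        intra <- c(intra, paste(prs[1L, ], prs[2L, ], sep = "\t"))
      }
    }
    intra <- unique(intra)
    edgeKeys <- character(0)
    if (n >= 2L) {
      ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      x <- allIDs[ij[, 1L]]
      y <- allIDs[ij[, 2L]]
      a <- ifelse(x < y, x, y)
      b <- ifelse(x < y, y, x)
      key <- paste(a, b, sep = "\t")
      isIntra <- key %in% intra
      p <- ifelse(isIntra, pIn, pOut)
      # draw in a fixed (sorted-key) order so the result is seed-stable
      ord <- order(key)
      keep <- logical(length(key))
      keep[ord] <- stats::runif(length(key)) < p[ord]
      edgeKeys <- key[keep]
    }
    em <- if (length(edgeKeys)) {
      do.call(rbind, strsplit(edgeKeys, "\t", fixed = TRUE))
    } else NULL
    list(network = PPINetwork(edges = em, nodes = allIDs),
         gold = ComplexSet(gold, source = "planted"))
  })
}
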