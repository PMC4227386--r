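#' Turn estimated propensities into complexes
#'
#' Protein i joins candidate complex k when `theta[i, k] >= tau`. Empty
#' columns are dropped, exact-duplicate sets are collapsed to one, and
#' complexes smaller than `minSize` are removed. A protein may appear in
#' several complexes: overlap is permitted by construction.
#'
#' @param fit a [PropensityFit] (rownames carry the protein IDs), or a
#'   plain propensity matrix with rownames.
#' @param tau propensity threshold (default 0.2; typical scans cover
#'   0.05-0.5).
#' @param minSize smallest complex size kept (default 3).
#' @return a [ComplexSet].
#' @export
thresholdComplexes <- function(fit, tau = 0.2, minSize = 3) {
  stopifnot(tau > 0, minSize >= 1)
  theta <- if (is(fit, "PropensityFit")) fit@theta else as.matrix(fit)
  ids <- rownames(theta)
  if (is.null(ids)) stop("propensity matrix must carry protein IDs as rownames")
  sets <- lapply(seq_len(ncol(theta)), function(k) ids[theta[, k] >= tau])
  sets <- sets[lengths(sets) > 0L]
  cs <- dedupComplexes(ComplexSet(sets, source = "plsmc"))
  filterMinSize(cs, minSize)
}

#' Merge per-subnetwork predictions
#'
#' Concatenates the complex sets detected in node-disjoint subnetworks,
#' preserving subnetwork order. Disjointness is asserted: overlapping node
#' sets would mean the parts did not come from a decomposition and
#' duplicate complexes could slip through.
#'
#' @param parts list of [ComplexSet] objects from node-disjoint
#'   subnetworks.
#' @return a single [ComplexSet].
#' @export
mergeComplexSets <- function(parts) {
  seen <- character(0)
  all <- list()
  for (cs in parts) {
    members <- unique(unlist(cs@complexes))
    if (any(members %in% seen))
      stop("subnetwork predictions share proteins; parts must be node-disjoint")
    seen <- c(seen, members)
    all <- c(all, cs@complexes)
  }
  new("ComplexSet", complexes = all, source = "plsmc")
}
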