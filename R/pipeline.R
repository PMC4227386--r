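#' Fit propensities on every subnetwork of a decomposition
#'
#' Decomposes the network (unless `parts` is supplied), computes the
#' neighborhood-overlap weights per subnetwork from that subnetwork's own
#' topology, and runs the restarted optimizer on each part with at least 3
#' proteins. Per-part seeds are derived deterministically from `seed` and
#' the part index.
#'
#' @param net a [PPINetwork].
#' @param lambda ridge penalty weight.
#' @param K candidate complexes per subnetwork; `NULL` (default) applies
#'   the ceiling(n/3) rule per part.
#' @param maxSize decomposition size cap N_s (default 200).
#' @param restarts random restarts per part.
#' @param seed base seed.
#' @param variant weighting variant, see [computeWeights()].
#' @param maxIter,relTol,eps optimizer controls, see [plsmcEstimate()].
#' @param parts optional precomputed decomposition (list of node-disjoint
#'   [PPINetwork]s), e.g. to reuse across a lambda grid.
#' @return list with `parts` (the decomposition), `fits` (a
#'   [PropensityFit] per part, or NULL for parts too small to host a
#'   complex) and `summary` (a data.frame of per-part sizes, objectives,
#'   iteration counts and seeds).
#' @export
fitSubnetworks <- function(net, lambda = 1, K = NULL, maxSize = 200,
                           restarts = 100, seed = 1,
                           variant = c("product", "geometric"),
                           maxIter = 1000, relTol = 1e-6, eps = 1e-12,
                           parts = NULL) {
  variant <- match.arg(variant)
  if (is.null(parts)) parts <- decomposeNetwork(net, maxSize = maxSize)
  fits <- vector("list", length(parts))
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    n <- numNodes(p)
    partSeed <- deriveSeed(seed, 100000 + i)
    if (n < 3L) {
      rows[[i]] <- data.frame(part = i, nodes = n, edges = numEdges(p),
                              K = 0L, objective = NA_real_,
                              iterations = NA_integer_, converged = NA,
                              seed = partSeed)
      next
    }
    W <- computeWeights(p, variant = variant)
    Kp <- if (is.null(K)) max(1L, ceiling(n / 3)) else K
    fit <- plsmcFit(W, K = Kp, lambda = lambda, restarts = restarts,
                    seed = partSeed, maxIter = maxIter, relTol = relTol,
                    eps = eps)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(part = i, nodes = n, edges = numEdges(p),
                            K = Kp, objective = fit@objective,
                            iterations = fit@iterations,
                            converged = fit@converged, seed = partSeed)
  }
  list(parts = parts, fits = fits, summary = do.call(rbind, rows))
}

# threshold every fitted part and merge
thresholdAll <- function(fitted, tau, minSize) {
  sets <- lapply(fitted$fits, function(f) {
    if (is.null(f)) ComplexSet() else thresholdComplexes(f, tau = tau,
                                                         minSize = minSize)
  })
  mergeComplexSets(sets)
}

#' Detect protein complexes in a PPI network
#'
#' The full pipeline: decompose the network into subnetworks of at most
#' `maxSize` proteins by recursive greedy modularity clustering, compute
#' neighborhood-overlap weights per subnetwork, estimate nonnegative
#' propensities by restarted penalized least squares, threshold them at
#' `tau`, and merge the per-subnetwork predictions.
#'
#' @inheritParams fitSubnetworks
#' @param tau propensity threshold for complex membership (default 0.2).
#' @param minSize smallest reported complex (default 3).
#' @return list with `complexes` (a [ComplexSet]), `summary` (per-part
#'   diagnostics) and `params` (all effective parameters).
#' @examples
#' sim <- simulateComplexNetwork(nComplexes = 3, pIn = 1, pOut = 0, seed = 2)
#' res <- detectComplexes(sim$network, lambda = 0.1, restarts = 3, seed = 2)
#' res$complexes
#' @export
detectComplexes <- function(net, lambda = 1, tau = 0.2, K = NULL,
                            maxSize = 200, restarts = 100, seed = 1,
                            variant = c("product", "geometric"),
                            minSize = 3, maxIter = 1000, relTol = 1e-6,
                            eps = 1e-12) {
  variant <- match.arg(variant)
  fitted <- fitSubnetworks(net, lambda = lambda, K = K, maxSize = maxSize,
                           restarts = restarts, seed = seed,
                           variant = variant, maxIter = maxIter,
                           relTol = relTol, eps = eps)
  cs <- thresholdAll(fitted, tau = tau, minSize = minSize)
  list(complexes = cs,
       summary = fitted$summary,
       params = list(lambda = lambda, tau = tau,
                     K = if (is.null(K)) "ceil(n/3)" else K,
                     maxSize = maxSize, restarts = restarts, seed = seed,
                     variant = variant, minSize = minSize,
                     maxIter = maxIter, relTol = relTol))
}

#' Select lambda and tau by composite score against a gold standard
#'
#' Sweeps the penalty weight over `lambdas` and the propensity threshold
#' over `taus`, evaluating each pair's predictions against the supplied
#' gold standard, and returns the pair maximizing the composite score
#' (f-measure + Acc + MMR). This mirrors the standard selection protocol
#' for this method: restart the optimizer per lambda, then scan tau on the
#' winning fit. The decomposition and per-lambda fits are computed once
#' and shared across the tau scan.
#'
#' @inheritParams detectComplexes
#' @param gold reference [ComplexSet]; it is size-filtered with
#'   `minRefSize` before evaluation.
#' @param lambdas penalty grid (default 2^-5 ... 2^5).
#' @param taus threshold grid (default 0.05 to 0.5 in steps of 0.05).
#' @param ov overlap threshold for the f-measure matching.
#' @param minRefSize reference complexes smaller than this are dropped
#'   before evaluation (default 3).
#' @return list with `grid` (a data.frame of lambda, tau and all metric
#'   values), `best` (the composite-maximizing row), `complexes` (the
#'   winning prediction) and `report` (its [EvalReport]).
#' @export
paramGrid <- function(net, gold, lambdas = 2^(-5:5),
                      taus = seq(0.05, 0.5, by = 0.05), ov = 0.25,
                      K = NULL, maxSize = 200, restarts = 10, seed = 1,
                      variant = c("product", "geometric"), minSize = 3,
                      maxIter = 1000, relTol = 1e-6, minRefSize = 3) {
  variant <- match.arg(variant)
  gold <- filterMinSize(gold, minRefSize)
  if (!length(gold@complexes)) stop("gold standard empty after size filter")
  parts <- decomposeNetwork(net, maxSize = maxSize)
  rows <- list()
  best <- NULL
  for (lam in lambdas) {
    fitted <- fitSubnetworks(net, lambda = lam, K = K, maxSize = maxSize,
                             restarts = restarts, seed = seed,
                             variant = variant, maxIter = maxIter,
                             relTol = relTol, parts = parts)
    for (tau in taus) {
      cs <- thresholdAll(fitted, tau = tau, minSize = minSize)
      rep <- suppressWarnings(evaluateComplexes(cs, gold, ov = ov))
      rows[[length(rows) + 1L]] <- data.frame(
        lambda = lam, tau = tau, nPred = rep@nPred,
        precision = rep@precision, recall = rep@recall,
        fMeasure = rep@fMeasure, acc = rep@acc, mmr = rep@mmr,
        composite = rep@composite)
      if (is.null(best) || rep@composite > best$report@composite) {
        best <- list(lambda = lam, tau = tau, complexes = cs, report = rep)
      }
    }
  }
  grid <- do.call(rbind, rows)
  list(grid = grid,
       best = grid[which.max(grid$composite), , drop = FALSE],
       complexes = best$complexes,
       report = best$report)
}
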