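#' @import methods
NULL

#' PPINetwork: an undirected simple protein-protein interaction graph
#'
#' Stores a PPI network as a lexicographically sorted node vector and a
#' canonical two-column edge matrix. The graph is simple: no self-loops,
#' no duplicate edges, and every edge endpoint is a known node. Each edge
#' row is ordered so that the first endpoint sorts before the second, and
#' rows are sorted, which makes equal networks byte-identical on disk.
#'
#' @slot nodes character vector of unique protein IDs, sorted.
#' @slot edges character matrix with two columns; each row an unordered
#'   interaction written in canonical (sorted) order.
#'
#' @seealso [readEdgeList()], [computeWeights()], [decomposeNetwork()]
#' @export
setClass("PPINetwork",
  representation(nodes = "character", edges = "matrix"),
  prototype(nodes = character(0),
            edges = matrix(character(0), ncol = 2))
)

setValidity("PPINetwork", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node IDs")
  if (is.unsorted(object@nodes))
    msg <- c(msg, "nodes must be sorted")
  e <- object@edges
  if (ncol(e) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (!is.character(e)) msg <- c(msg, "edges must be character")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) msg <- c(msg, "edge rows must be in canonical order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\t")))
      msg <- c(msg, "duplicate edges")
    if (!all(c(e) %in% object@nodes))
      msg <- c(msg, "edge endpoint not in node set")
  }
  if (length(msg)) msg else TRUE
})

#' WeightMatrix: neighborhood-overlap interaction weights
#'
#' A symmetric nonnegative N x N matrix of interaction weights aligned to a
#' [PPINetwork]'s node order. Weights are supported exactly on the edge set
#' (zero on non-edges and on the diagonal). See [computeWeights()] for the
#' two weighting variants.
#'
#' @slot values numeric matrix of weights.
#' @slot nodes character vector naming the rows/columns.
#' @slot variant "product" or "geometric" (denominator convention).
#' @export
setClass("WeightMatrix",
  representation(values = "matrix", nodes = "character", variant = "character")
)

setValidity("WeightMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) != length(object@nodes))
    msg <- c(msg, "nodes length must match matrix dimension")
  if (nrow(v) > 0L) {
    if (any(v < 0)) msg <- c(msg, "weights must be nonnegative")
    if (!isTRUE(all.equal(v, t(v)))) msg <- c(msg, "weights must be symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
  }
  if (!object@variant %in% c("product", "geometric"))
    msg <- c(msg, "variant must be 'product' or 'geometric'")
  if (length(msg)) msg else TRUE
})

#' ComplexSet: an ordered collection of protein complexes
#'
#' A list of protein-ID sets, used both for predictions and for gold
#' standards (e.g. CYC2008-style catalogues). Members within a complex are
#' unique; complexes are nonempty.
#'
#' @slot complexes list of character vectors (protein-ID sets).
#' @slot source free-text label recording where the set came from.
#' @seealso [readComplexes()], [filterMinSize()], [evaluateComplexes()]
#' @export
setClass("ComplexSet",
  representation(complexes = "list", source = "character"),
  prototype(complexes = list(), source = "")
)

setValidity("ComplexSet", function(object) {
  msg <- character(0)
  for (cx in object@complexes) {
    if (!is.character(cx)) { msg <- c(msg, "complex members must be character"); break }
    if (length(cx) == 0L) { msg <- c(msg, "empty complex"); break }
    if (anyDuplicated(cx)) { msg <- c(msg, "duplicate member within a complex"); break }
  }
  if (length(msg)) msg else TRUE
})

#' PropensityFit: result of the penalized least-squares optimization
#'
#' Holds the estimated nonnegative propensity matrix Theta (rows = proteins
#' of the fitted subnetwork, columns = candidate complexes), the final value
#' of the objective L, and the objective trajectory across iterations.
#'
#' @slot theta numeric N x K matrix of nonnegative propensities, with
#'   rownames set to the subnetwork's node IDs.
#' @slot objective final value of the penalized objective.
#' @slot trajectory objective values, starting at the initial Theta; the
#'   last entry equals `objective`.
#' @slot iterations number of multiplicative updates performed.
#' @slot converged TRUE when the relative-change stopping rule fired before
#'   the iteration cap.
#' @slot lambda penalty weight used.
#' @slot seedUsed seed of the (winning) random initialization.
#' @export
setClass("PropensityFit",
  representation(theta = "matrix", objective = "numeric",
                 trajectory = "numeric", iterations = "integer",
                 converged = "logical", lambda = "numeric",
                 seedUsed = "integer")
)

setValidity("PropensityFit", function(object) {
  msg <- character(0)
  if (any(object@theta < 0)) msg <- c(msg, "theta must be nonnegative")
  if (length(object@trajectory) &&
      abs(object@objective - object@trajectory[length(object@trajectory)]) >
        1e-8 * (1 + abs(object@objective)))
    msg <- c(msg, "objective must equal the last trajectory entry")
  if (length(msg)) msg else TRUE
})

#' EvalReport: complex-prediction evaluation metrics
#'
#' Gathers the match-based metrics (precision, recall, f-measure at overlap
#' threshold `ov`), the protein-level Sn/PPV/Acc, the maximum matching
#' ratio, their composite score, and the raw match counts.
#'
#' @slot precision,recall,fMeasure match-based rates in \[0, 1\].
#' @slot sn,ppv,acc protein-level rates in \[0, 1\].
#' @slot mmr maximum matching ratio in \[0, 1\].
#' @slot composite fMeasure + acc + mmr, in \[0, 3\].
#' @slot nMatchedPred number of predicted complexes matching some reference
#'   complex (N_cp); at most the number of predictions.
#' @slot nMatchedRef number of reference complexes matched by some
#'   prediction (N_cb); at most the number of references.
#' @slot perfectMatches reference complexes reproduced exactly (overlap
#'   score 1).
#' @slot nPred,nRef sizes of the predicted and reference sets.
#' @slot ov overlap-score matching threshold used.
#' @export
setClass("EvalReport",
  representation(precision = "numeric", recall = "numeric",
                 fMeasure = "numeric", sn = "numeric", ppv = "numeric",
                 acc = "numeric", mmr = "numeric", composite = "numeric",
                 nMatchedPred = "integer", nMatchedRef = "integer",
                 perfectMatches = "integer", nPred = "integer",
                 nRef = "integer", ov = "numeric")
)

setValidity("EvalReport", function(object) {
  rates <- c(object@precision, object@recall, object@fMeasure,
             object@sn, object@ppv, object@acc, object@mmr)
  msg <- character(0)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must lie in [0, 1]")
  if (object@nMatchedPred > object@nPred)
    msg <- c(msg, "nMatchedPred exceeds nPred")
  if (object@nMatchedRef > object@nRef)
    msg <- c(msg, "nMatchedRef exceeds nRef")
  if (length(msg)) msg else TRUE
})
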