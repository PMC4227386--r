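#' Node IDs of an object
#'
#' @param x a [PPINetwork] or [WeightMatrix].
#' @return character vector of protein IDs in the object's canonical order.
#' @export
setGeneric("nodeIDs", function(x) standardGeneric("nodeIDs"))

#' Number of nodes
#'
#' @param x a [PPINetwork].
#' @return integer node count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#'
#' @param x a [PPINetwork].
#' @return integer edge count.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Edge matrix
#'
#' @param x a [PPINetwork].
#' @return two-column character matrix of edges in canonical order.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Weight values
#'
#' @param x a [WeightMatrix].
#' @return the symmetric numeric matrix of interaction weights, with
#'   dimnames set to the node IDs.
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' Complex membership lists
#'
#' @param x a [ComplexSet].
#' @return list of character vectors, one per complex.
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' Estimated propensity matrix
#'
#' @param x a [PropensityFit].
#' @return numeric matrix Theta with node IDs as rownames.
#' @export
setGeneric("propensities", function(x) standardGeneric("propensities"))
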