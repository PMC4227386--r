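#' Construct a PPINetwork from an edge table
#'
#' Builds a simple undirected network from a two-column character matrix (or
#' nothing, for an edgeless network). Duplicate edges, reversed duplicates
#' and self-loops are removed; self-loop removal is reported with a warning
#' because it usually signals an upstream data problem.
#'
#' @param edges two-column character matrix (or data.frame) of interactions;
#'   may be NULL or zero-row.
#' @param nodes optional character vector of node IDs; isolated nodes (in
#'   `nodes` but in no edge) are retained. Endpoints missing from `nodes`
#'   are added.
#' @return a [PPINetwork].
#' @examples
#' PPINetwork(rbind(c("A", "B"), c("B", "C")))
#' @export
PPINetwork <- function(edges = NULL, nodes = character(0)) {
  if (is.null(edges)) {
    e <- matrix(character(0), ncol = 2)
  } else {
    e <- as.matrix(edges)
    storage.mode(e) <- "character"
    if (ncol(e) != 2L) stop("edges must have exactly two columns")
  }
  if (nrow(e) > 0L) {
    loops <- e[, 1L] == e[, 2L]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      e <- e[!loops, , drop = FALSE]
    }
    # canonical order within each edge, then dedup
    flip <- e[, 1L] > e[, 2L]
    e[flip, ] <- e[flip, c(2L, 1L), drop = FALSE]
    key <- paste(e[, 1L], e[, 2L], sep = "\t")
    e <- e[!duplicated(key), , drop = FALSE]
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  nodes <- sort(unique(c(as.character(nodes), c(e))))
  new("PPINetwork", nodes = nodes, edges = e)
}

#' @rdname nodeIDs
setMethod("nodeIDs", "PPINetwork", function(x) x@nodes)
#' @rdname numNodes
setMethod("numNodes", "PPINetwork", function(x) length(x@nodes))
#' @rdname numEdges
setMethod("numEdges", "PPINetwork", function(x) nrow(x@edges))
#' @rdname edges
setMethod("edges", "PPINetwork", function(x) x@edges)

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (length(object@nodes)) {
    shown <- utils::head(object@nodes, 6L)
    cat("  nodes:", paste(shown, collapse = " "),
        if (length(object@nodes) > 6L) "..." else "", "\n")
  }
})

# internal: igraph round-trips (vertex names preserved)
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(net@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net@nodes, stringsAsFactors = FALSE))
}

fromIgraph <- function(g) {
  e <- igraph::as_edgelist(g, names = TRUE)
  storage.mode(e) <- "character"
  PPINetwork(edges = e, nodes = igraph::V(g)$name)
}

#' Read a PPI network from an edge-list or SIF file
#'
#' Edge-list files carry one interaction per line as two (or more)
#' whitespace-separated tokens; tokens past the second (e.g. a confidence
#' weight) are ignored and the network is recomputed as unweighted topology.
#' SIF files use the Cytoscape convention `node relation node [node ...]`.
#' Duplicate lines, reversed duplicates and self-loops are collapsed or
#' dropped (the latter with a warning); nodes are sorted lexicographically.
#'
#' @param path file to read.
#' @param format "tsv" (generic whitespace edge list, default) or "sif".
#' @param comment lines starting with this character are skipped.
#' @return a [PPINetwork].
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B C"), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path, format = c("tsv", "sif"), comment = "#") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  data <- which(keep)
  if (!length(data)) stop("no network data in ", path)
  pairs <- vector("list", length(data))
  for (idx in seq_along(data)) {
    ln <- data[idx]
    tok <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (format == "tsv") {
      if (length(tok) < 2L)
        stop("malformed edge line ", ln, " in ", path, ": ", lines[ln])
      pairs[[idx]] <- matrix(tok[1:2], ncol = 2)
    } else {
      # SIF: source relation target1 [target2 ...]; a lone node is isolated
      if (length(tok) == 1L) {
        pairs[[idx]] <- matrix(c(tok, NA_character_), ncol = 2)
      } else if (length(tok) >= 3L) {
        pairs[[idx]] <- cbind(tok[1L], tok[-(1:2)])
      } else {
        stop("malformed SIF line ", ln, " in ", path, ": ", lines[ln])
      }
    }
  }
  mat <- do.call(rbind, pairs)
  isolated <- is.na(mat[, 2L])
  PPINetwork(edges = mat[!isolated, , drop = FALSE],
             nodes = mat[isolated, 1L])
}

#' Write a PPI network as a tab-separated edge list
#'
#' Isolated nodes cannot be represented in a plain edge list and are
#' appended as comment lines so that [readEdgeList()] round-trips modulo
#' isolated nodes; use the returned path in pipelines.
#'
#' @param net a [PPINetwork].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- net@edges
  lines <- if (nrow(e)) paste(e[, 1L], e[, 2L], sep = "\t") else character(0)
  iso <- setdiff(net@nodes, c(e))
  if (length(iso)) lines <- c(lines, paste0("#isolated\t", iso))
  writeLines(lines, path)
  invisible(path)
}

#' Compute neighborhood-overlap interaction weights
#'
#' For every interacting pair (i, j) the weight is the number of shared
#' members of the closed neighborhoods N(i) and N(j) — each containing the
#' protein itself and its interaction partners — scaled by the neighborhood
#' sizes:
#' \deqn{S_{ij} = |N(i) \cap N(j)| / (|N(i)| \cdot |N(j)|)}
#' for `variant = "product"` (the default), or with
#' \eqn{\sqrt{|N(i)| |N(j)|}} in the denominator for
#' `variant = "geometric"`, which keeps the weights in (0, 1]. Non-edges
#' (including the diagonal) get weight 0, so a low weight flags an
#' interaction whose endpoints share few partners — a likely false
#' positive.
#'
#' @param net a [PPINetwork].
#' @param variant denominator convention, "product" or "geometric".
#' @return a [WeightMatrix] aligned to `nodeIDs(net)`.
#' @examples
#' net <- PPINetwork(rbind(c("A", "B"), c("B", "C")))
#' weightValues(computeWeights(net))["A", "B"]  # 2 / (2 * 3)
#' @export
computeWeights <- function(net, variant = c("product", "geometric")) {
  variant <- match.arg(variant)
  if (numNodes(net) == 0L) stop("empty network")
  n <- numNodes(net)
  A <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
  if (nrow(net@edges)) {
    i <- match(net@edges[, 1L], net@nodes)
    j <- match(net@edges[, 2L], net@nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  Ac <- A + diag(n)                       # closed neighborhoods
  common <- Ac %*% Ac                     # |N(i) n N(j)| for all pairs
  size <- rowSums(Ac)                     # |N(i)|
  denom <- outer(size, size)
  if (variant == "geometric") denom <- sqrt(denom)
  S <- (common / denom) * A               # supported on edges only
  new("WeightMatrix", values = S, nodes = net@nodes, variant = variant)
}

#' @rdname weightValues
setMethod("weightValues", "WeightMatrix", function(x) x@values)
#' @rdname nodeIDs
setMethod("nodeIDs", "WeightMatrix", function(x) x@nodes)

setMethod("show", "WeightMatrix", function(object) {
  nz <- sum(object@values > 0) / 2
  cat("WeightMatrix (", object@variant, ") over ", length(object@nodes),
      " nodes, ", nz, " weighted edges\n", sep = "")
})

#' Construct a ComplexSet
#'
#' @param complexes list of character vectors of protein IDs; duplicate
#'   members within a complex are dropped.
#' @param source free-text provenance label.
#' @return a [ComplexSet].
#' @export
ComplexSet <- function(complexes = list(), source = "") {
  complexes <- lapply(complexes, function(cx) unique(as.character(cx)))
  new("ComplexSet", complexes = complexes, source = source)
}

#' @rdname complexes
setMethod("complexes", "ComplexSet", function(x) x@complexes)

#' @describeIn ComplexSet number of complexes.
#' @param x a ComplexSet.
#' @export
setMethod("length", "ComplexSet", function(x) length(x@complexes))

#' @describeIn ComplexSet extract the i-th complex as a character vector.
#' @param i index.
#' @export
setMethod("[[", "ComplexSet", function(x, i) x@complexes[[i]])

setMethod("show", "ComplexSet", function(object) {
  sizes <- lengths(object@complexes)
  cat("ComplexSet with", length(sizes), "complexes")
  if (nzchar(object@source)) cat(" [", object@source, "]", sep = "")
  cat("\n")
  if (length(sizes))
    cat("  sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
})

#' Read a complex catalogue (one complex per line)
#'
#' The de facto exchange format of complex-prediction tools and of
#' CYC2008-style catalogues: each line lists the whitespace-separated
#' protein IDs of one complex. Duplicate IDs within a line are dropped;
#' empty lines are skipped with a warning.
#'
#' @param path file to read.
#' @param source provenance label stored on the result (defaults to the
#'   file name).
#' @return a [ComplexSet].
#' @export
readComplexes <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  empty <- !nzchar(trimws(lines))
  if (any(empty)) warning(sum(empty), " empty line(s) skipped in ", path)
  lines <- lines[!empty]
  ComplexSet(lapply(lines, function(ln) strsplit(trimws(ln), "[ \t]+")[[1]]),
             source = source)
}

#' Write a complex catalogue (one complex per line)
#'
#' @param cs a [ComplexSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeComplexes <- function(cs, path) {
  writeLines(vapply(cs@complexes, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Drop complexes below a minimum size
#'
#' Complex catalogues are conventionally restricted to complexes of at
#' least 3 proteins, both on the prediction side and for the gold standard.
#'
#' @param cs a [ComplexSet].
#' @param minSize smallest complex size kept (default 3).
#' @return a [ComplexSet] with the surviving complexes in their original
#'   order.
#' @export
filterMinSize <- function(cs, minSize = 3) {
  stopifnot(minSize >= 1)
  keep <- lengths(cs@complexes) >= minSize
  new("ComplexSet", complexes = cs@complexes[keep], source = cs@source)
}

# internal: canonical string key of a protein set
complexKey <- function(members) paste(sort(members), collapse = "\t")

#' Remove exact-duplicate complexes
#'
#' @param cs a [ComplexSet].
#' @return a [ComplexSet] keeping the first occurrence of each distinct set.
#' @export
dedupComplexes <- function(cs) {
  keys <- vapply(cs@complexes, complexKey, "")
  new("ComplexSet", complexes = cs@complexes[!duplicated(keys)],
      source = cs@source)
}
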