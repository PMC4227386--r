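# ---- penalized least-squares propensity estimation -------------------------
#
# Model: each protein i carries a nonnegative propensity theta[i, z] for each
# of K candidate complexes; the cocomplex coefficient sum_z theta[i,z]
# theta[j,z] is fitted toward the interaction weight S[i, j] by minimizing
#
#   L(Theta) = sum_{i,j} 0.5 * (sum_z theta_iz theta_jz - S_ij)^2
#              + lambda * sum_{i,z} theta_iz^2 ,   Theta >= 0,
#
# the double sum running over all ordered pairs including i = j (S_ii = 0).
# The ridge penalty controls how many complexes a protein can join; without
# it a protein accumulates many large propensities and predictions overlap
# pervasively.

# accept a WeightMatrix or a plain symmetric matrix
weightInput <- function(S) {
  if (is(S, "WeightMatrix")) list(values = S@values, nodes = S@nodes)
  else {
    S <- as.matrix(S)
    nd <- rownames(S)
    if (is.null(nd)) nd <- as.character(seq_len(nrow(S)))
    list(values = S, nodes = nd)
  }
}

# run expr with the global RNG seeded, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# order-independent substream seed for (seed, index); stays below 2^31
deriveSeed <- function(seed, index) {
  s <- as.numeric(seed) %% 2147483647
  if (s < 0) s <- s + 2147483647
  as.integer((s * 69069 + as.numeric(index) * 40503 + 1) %% 2147483647)
}

#' Penalized least-squares objective
#'
#' Value of the fit-plus-ridge objective
#' \deqn{L(\Theta) = \sum_{i,j} \tfrac12 (\sum_z \theta_{iz}\theta_{jz} -
#'   S_{ij})^2 + \lambda \sum_{i,z} \theta_{iz}^2}
#' with the first sum over all ordered pairs (i, j) including i = j.
#'
#' @param theta nonnegative N x K propensity matrix.
#' @param S a [WeightMatrix] or symmetric numeric matrix of interaction
#'   weights with zero diagonal.
#' @param lambda ridge penalty weight (> 0 for the penalized method; 0
#'   gives the unpenalized least-squares variant).
#' @return the scalar objective value.
#' @export
plsmcObjective <- function(theta, S, lambda = 1) {
  w <- weightInput(S)
  if (nrow(theta) != nrow(w$values)) stop("theta rows must match S dimension")
  C <- tcrossprod(theta)
  0.5 * sum((C - w$values)^2) + lambda * sum(theta^2)
}

#' Gradient of the penalized objective
#'
#' \eqn{\partial L/\partial\theta_{ik} = 2\sum_j \theta_{jk}(\sum_z
#' \theta_{iz}\theta_{jz}) - 2\sum_j \theta_{jk} S_{ij} + 2\lambda
#' \theta_{ik}}. Exposed mainly for optimality (KKT) diagnostics.
#'
#' @inheritParams plsmcObjective
#' @return N x K matrix of partial derivatives.
#' @export
plsmcGradient <- function(theta, S, lambda = 1) {
  w <- weightInput(S)
  2 * (theta %*% crossprod(theta)) - 2 * (w$values %*% theta) + 2 * lambda * theta
}

#' One multiplicative update of the propensity matrix
#'
#' Updates every entry simultaneously by
#' \deqn{\theta_{ik} \leftarrow \frac{\theta_{ik}}{2} +
#'   \frac{\theta_{ik}}{2} \cdot
#'   \frac{\sum_j \theta_{jk} S_{ij}}
#'        {\sum_j \theta_{jk} \sum_z \theta_{iz}\theta_{jz} +
#'         \lambda\theta_{ik} + \epsilon}.}
#' The averaged multiplicative form is a gradient step with an adaptive,
#' entrywise step length: it preserves nonnegativity, leaves exact zeros at
#' zero, and does not increase the objective. `eps` guards the denominator
#' when an entire column has decayed to zero.
#'
#' @inheritParams plsmcObjective
#' @param eps small positive denominator guard.
#' @return the updated N x K matrix.
#' @export
plsmcUpdate <- function(theta, S, lambda = 1, eps = 1e-12) {
  if (any(theta < 0)) stop("theta must be nonnegative")
  w <- weightInput(S)
  numer <- w$values %*% theta
  denom <- theta %*% crossprod(theta) + lambda * theta + eps
  0.5 * theta + 0.5 * theta * numer / denom
}

#' Estimate propensities from a fixed initialization
#'
#' Iterates [plsmcUpdate()] until the relative objective change
#' |L_t - L_(t-1)| / (1 + L_(t-1)) drops below `relTol` or `maxIter` is
#' reached. Deterministic given `init`.
#'
#' @param S a [WeightMatrix] or symmetric numeric matrix.
#' @param init nonnegative N x K starting matrix.
#' @param lambda ridge penalty weight.
#' @param maxIter iteration cap (default 1000).
#' @param relTol relative-change stopping tolerance (default 1e-6).
#' @param eps denominator guard passed to [plsmcUpdate()].
#' @param seedUsed seed recorded on the result (bookkeeping only; the
#'   routine itself draws no random numbers).
#' @return a [PropensityFit].
#' @export
plsmcEstimate <- function(S, init, lambda = 1, maxIter = 1000,
                          relTol = 1e-6, eps = 1e-12,
                          seedUsed = NA_integer_) {
  w <- weightInput(S)
  theta <- as.matrix(init)
  if (any(theta < 0)) stop("init must be nonnegative")
  if (nrow(theta) != nrow(w$values)) stop("init rows must match S dimension")
  traj <- numeric(maxIter + 1L)
  traj[1L] <- plsmcObjective(theta, w$values, lambda)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    theta <- plsmcUpdate(theta, w$values, lambda, eps)
    traj[iter + 1L] <- plsmcObjective(theta, w$values, lambda)
    if (abs(traj[iter + 1L] - traj[iter]) / (1 + traj[iter]) < relTol) {
      converged <- TRUE
      break
    }
  }
  rownames(theta) <- w$nodes
  new("PropensityFit", theta = theta, objective = traj[iter + 1L],
      trajectory = traj[seq_len(iter + 1L)], iterations = iter,
      converged = converged, lambda = lambda,
      seedUsed = as.integer(seedUsed))
}

# random start: entries uniform on (0, s] with s = sqrt(mean(S)/K), placing
# the initial Theta Theta' on the scale of S
randomInit <- function(Svalues, K, seed) {
  n <- nrow(Svalues)
  s <- sqrt(mean(Svalues) / K)
  if (!is.finite(s) || s <= 0) s <- 1e-3
  withSeed(seed, matrix(stats::runif(n * K, min = 0, max = s), n, K))
}

#' Estimate propensities with random restarts
#'
#' Runs [plsmcEstimate()] from `restarts` independent random
#' initializations and keeps the run with the smallest final objective
#' (ties broken by lowest restart index). Each restart's RNG stream is
#' derived deterministically from `(seed, restart index)`, so the winner is
#' reproducible and independent of execution order. The default of 100
#' restarts matches the standard protocol for this optimizer; reduce it
#' for interactive work.
#'
#' @inheritParams plsmcEstimate
#' @param K number of candidate complexes (columns of Theta). `NULL`
#'   applies the ceiling(n/3) rule: complexes have at least 3 members, so
#'   at most n/3 disjoint complexes fit in an n-protein subnetwork.
#' @param restarts number of random initializations (default 100).
#' @param seed base seed for the restart streams.
#' @return the winning [PropensityFit]; its `seedUsed` slot records the
#'   derived seed of the winning restart.
#' @export
plsmcFit <- function(S, K = NULL, lambda = 1, restarts = 100, seed = 1,
                     maxIter = 1000, relTol = 1e-6, eps = 1e-12) {
  stopifnot(restarts >= 1)
  w <- weightInput(S)
  n <- nrow(w$values)
  if (is.null(K)) K <- max(1L, ceiling(n / 3))
  stopifnot(K >= 1)
  best <- NULL
  for (r in seq_len(restarts)) {
    sr <- deriveSeed(seed, r)
    init <- randomInit(w$values, K, sr)
    fit <- plsmcEstimate(w$values, init, lambda = lambda, maxIter = maxIter,
                         relTol = relTol, eps = eps, seedUsed = sr)
    if (is.null(best) || fit@objective < best@objective) best <- fit
  }
  rownames(best@theta) <- w$nodes
  best
}

#' @rdname propensities
setMethod("propensities", "PropensityFit", function(x) x@theta)

setMethod("show", "PropensityFit", function(object) {
  cat("PropensityFit: ", nrow(object@theta), " proteins x ",
      ncol(object@theta), " candidate complexes\n", sep = "")
  cat("  objective ", format(object@objective), " after ",
      object@iterations, " iterations (",
      if (object@converged) "converged" else "iteration cap", ")\n",
      sep = "")
  cat("  lambda ", object@lambda, ", init seed ", object@seedUsed, "\n",
      sep = "")
})
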