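# Independent oracles: literal loop-by-loop transcriptions of the model
# formulas, kept free of the package's vectorized code paths.

# multiplicative update, one entry at a time
naiveUpdate <- function(theta, S, lambda, eps = 1e-12) {
  N <- nrow(theta); K <- ncol(theta)
  out <- theta
  for (i in seq_len(N)) {
    for (k in seq_len(K)) {
      num <- 0
      for (j in seq_len(N)) num <- num + theta[j, k] * S[i, j]
      den <- 0
      for (j in seq_len(N)) {
        cij <- 0
        for (z in seq_len(K)) cij <- cij + theta[i, z] * theta[j, z]
        den <- den + theta[j, k] * cij
      }
      den <- den + lambda * theta[i, k] + eps
      out[i, k] <- theta[i, k] / 2 + theta[i, k] / 2 * num / den
    }
  }
  out
}

# objective by explicit double loop over ordered pairs (including i = j)
naiveObjective <- function(theta, S, lambda) {
  N <- nrow(theta)
  L <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      cij <- sum(theta[i, ] * theta[j, ])
      L <- L + 0.5 * (cij - S[i, j])^2
    }
  }
  L + lambda * sum(theta^2)
}

# central finite-difference gradient of the objective
fdGradient <- function(theta, S, lambda, h = 1e-6) {
  g <- theta * 0
  for (i in seq_len(nrow(theta))) {
    for (k in seq_len(ncol(theta))) {
      tp <- theta; tp[i, k] <- tp[i, k] + h
      tm <- theta; tm[i, k] <- tm[i, k] - h
      g[i, k] <- (naiveObjective(tp, S, lambda) -
                  naiveObjective(tm, S, lambda)) / (2 * h)
    }
  }
  g
}

# brute-force recomputation of every evaluation metric from first
# principles (plain double loops over all (p, b) pairs)
naiveEvaluate <- function(Plist, Blist, ov = 0.25) {
  os <- function(p, b) length(intersect(p, b))^2 / (length(p) * length(b))
  nP <- length(Plist); nB <- length(Blist)
  hitP <- logical(nP); hitB <- logical(nB); perfect <- logical(nB)
  bestForB <- numeric(nB)
  for (bi in seq_len(nB)) {
    for (pi in seq_len(nP)) {
      s <- os(Plist[[pi]], Blist[[bi]])
      if (s >= ov) { hitP[pi] <- TRUE; hitB[bi] <- TRUE }
      if (s == 1) perfect[bi] <- TRUE
      if (s > bestForB[bi]) bestForB[bi] <- s
    }
  }
  prec <- if (nP) sum(hitP) / nP else 0
  rec <- if (nB) sum(hitB) / nB else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  Tm <- matrix(0, nB, nP)
  for (bi in seq_len(nB)) for (pi in seq_len(nP))
    Tm[bi, pi] <- length(intersect(Blist[[bi]], Plist[[pi]]))
  sn <- sum(apply(Tm, 1, max)) / sum(lengths(Blist))
  tot <- sum(Tm)
  ppv <- if (tot > 0) sum(apply(Tm, 2, max)) / tot else 0
  acc <- sqrt(sn * ppv)
  mmr <- if (nP) mean(bestForB) else 0
  list(precision = prec, recall = rec, fMeasure = f, sn = sn, ppv = ppv,
       acc = acc, mmr = mmr, composite = f + acc + mmr,
       nMatchedPred = sum(hitP), nMatchedRef = sum(hitB),
       perfectMatches = sum(perfect))
}

# random nonnegative problem instance on a symmetric zero-diagonal S
randomInstance <- function(n, K, density = 0.4) {
  S <- matrix(0, n, n)
  up <- which(upper.tri(S))
  on <- sample(up, max(1, round(density * length(up))))
  S[on] <- runif(length(on))
  S <- S + t(S)
  theta <- matrix(runif(n * K, 0, 0.8), n, K)
  list(S = S, theta = theta)
}

# random complex set over a small protein universe
randomComplexSet <- function(universe, nComplexes, maxSize = 6) {
  ComplexSet(lapply(seq_len(nComplexes), function(i) {
    sample(universe, sample(2:maxSize, 1))
  }))
}

# bridged pair of 4-cliques: the canonical two-community graph
bridgedDoubleK4 <- function() {
  cliq <- function(ids) t(utils::combn(ids, 2))
  PPINetwork(rbind(cliq(c("a1", "a2", "a3", "a4")),
                   cliq(c("b1", "b2", "b3", "b4")),
                   c("a1", "b1")))
}

completeNetwork <- function(ids) PPINetwork(t(utils::combn(ids, 2)))

randomNetwork <- function(n, p, seed) {
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  e <- igraph::as_edgelist(g, names = TRUE)
  storage.mode(e) <- "character"
  PPINetwork(edges = e, nodes = igraph::V(g)$name)
}
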