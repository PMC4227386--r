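# ---- complex-prediction evaluation metrics ---------------------------------

#' Overlap score between two protein sets
#'
#' \eqn{os(p, b) = |p \cap b|^2 / (|p| \cdot |b|)}, in \[0, 1\]; equal to 1
#' exactly when the sets are identical.
#'
#' @param p,b nonempty character vectors of protein IDs.
#' @return the overlap score.
#' @export
overlapScore <- function(p, b) {
  if (!length(p) || !length(b)) stop("overlap score of an empty set")
  length(intersect(p, b))^2 / (length(p) * length(b))
}

# all pairwise overlap scores, |P| x |B|
overlapMatrix <- function(P, B) {
  outer(seq_along(P@complexes), seq_along(B@complexes),
        Vectorize(function(i, j) overlapScore(P@complexes[[i]],
                                              B@complexes[[j]])))
}

#' Match-based precision, recall and f-measure
#'
#' A predicted complex p and a reference complex b match when their
#' [overlapScore()] reaches the threshold `ov`. Precision is the fraction
#' of predictions matching at least one reference complex, recall the
#' fraction of reference complexes matched by at least one prediction, and
#' the f-measure their harmonic mean (0 when both are 0).
#'
#' @param P predicted [ComplexSet].
#' @param B reference (gold standard) [ComplexSet].
#' @param ov matching threshold on the overlap score (default 0.25, the
#'   conventional choice in this literature).
#' @param strict if TRUE, require overlap strictly greater than `ov`
#'   instead of the conventional >=.
#' @return named numeric vector with elements `precision`, `recall`,
#'   `fMeasure`, `nMatchedPred` (N_cp) and `nMatchedRef` (N_cb).
#' @export
precisionRecallF <- function(P, B, ov = 0.25, strict = FALSE) {
  stopifnot(ov > 0, ov <= 1)
  if (!length(P@complexes) || !length(B@complexes)) {
    warning("empty complex set; precision/recall/f set to 0")
    return(c(precision = 0, recall = 0, fMeasure = 0,
             nMatchedPred = 0, nMatchedRef = 0))
  }
  os <- overlapMatrix(P, B)
  hit <- if (strict) os > ov else os >= ov
  ncp <- sum(apply(hit, 1L, any))
  ncb <- sum(apply(hit, 2L, any))
  prec <- ncp / length(P@complexes)
  rec <- ncb / length(B@complexes)
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, fMeasure = f,
    nMatchedPred = ncp, nMatchedRef = ncb)
}

#' Protein-level sensitivity, positive predictive value and accuracy
#'
#' Built from the confusion matrix T with T\[i, j\] the number of proteins
#' shared by reference complex i and predicted complex j:
#' Sn = sum_i max_j T_ij / sum_i |b_i| and
#' PPV = sum_j max_i T_ij / sum_ij T_ij (0 when no prediction touches the
#' reference). Acc is their geometric mean sqrt(Sn * PPV) as defined by
#' the metric's originators; `accVariant = "product"` gives the plain
#' product instead.
#'
#' @inheritParams precisionRecallF
#' @param accVariant "geometric" (default) or "product".
#' @return named numeric vector with elements `sn`, `ppv`, `acc`.
#' @export
snPpvAcc <- function(P, B, accVariant = c("geometric", "product")) {
  accVariant <- match.arg(accVariant)
  if (!length(P@complexes) || !length(B@complexes)) {
    warning("empty complex set; Sn/PPV/Acc set to 0")
    return(c(sn = 0, ppv = 0, acc = 0))
  }
  Tm <- outer(seq_along(B@complexes), seq_along(P@complexes),
              Vectorize(function(i, j)
                length(intersect(B@complexes[[i]], P@complexes[[j]]))))
  sn <- sum(apply(Tm, 1L, max)) / sum(lengths(B@complexes))
  tot <- sum(Tm)
  ppv <- if (tot > 0) sum(apply(Tm, 2L, max)) / tot else 0
  acc <- if (accVariant == "geometric") sqrt(sn * ppv) else sn * ppv
  c(sn = sn, ppv = ppv, acc = acc)
}

#' Maximum matching ratio
#'
#' Mean, over reference complexes, of the best overlap score any predicted
#' complex achieves against them: a prediction set scores well only by
#' reproducing each reference complex closely with some prediction.
#'
#' @inheritParams precisionRecallF
#' @return the MMR in \[0, 1\]; 0 when P is empty.
#' @export
maxMatchingRatio <- function(P, B) {
  if (!length(B@complexes)) stop("reference set is empty")
  if (!length(P@complexes)) return(0)
  os <- overlapMatrix(P, B)
  mean(apply(os, 2L, max))
}

#' Evaluate predicted complexes against a gold standard
#'
#' Computes every metric in one pass: precision/recall/f-measure at
#' overlap threshold `ov`, Sn/PPV/Acc, the maximum matching ratio, the
#' composite score (fMeasure + Acc + MMR, the usual model-selection
#' criterion), and the number of reference complexes reproduced exactly
#' (overlap score 1, i.e. set equality). The reference set is expected to
#' be size-filtered beforehand (see [filterMinSize()]).
#'
#' @inheritParams precisionRecallF
#' @inheritParams snPpvAcc
#' @return an [EvalReport].
#' @export
evaluateComplexes <- function(P, B, ov = 0.25, strict = FALSE,
                              accVariant = c("geometric", "product")) {
  accVariant <- match.arg(accVariant)
  if (!length(B@complexes)) stop("reference set is empty")
  nP <- length(P@complexes)
  nB <- length(B@complexes)
  if (nP == 0L) {
    warning("no predicted complexes; all metrics are 0")
    return(new("EvalReport", precision = 0, recall = 0, fMeasure = 0,
               sn = 0, ppv = 0, acc = 0, mmr = 0, composite = 0,
               nMatchedPred = 0L, nMatchedRef = 0L, perfectMatches = 0L,
               nPred = 0L, nRef = as.integer(nB), ov = ov))
  }
  prf <- precisionRecallF(P, B, ov = ov, strict = strict)
  spa <- snPpvAcc(P, B, accVariant = accVariant)
  mmr <- maxMatchingRatio(P, B)
  os <- overlapMatrix(P, B)
  perfect <- sum(apply(os, 2L, function(col) any(col == 1)))
  new("EvalReport",
      precision = unname(prf["precision"]), recall = unname(prf["recall"]),
      fMeasure = unname(prf["fMeasure"]),
      sn = unname(spa["sn"]), ppv = unname(spa["ppv"]),
      acc = unname(spa["acc"]), mmr = mmr,
      composite = unname(prf["fMeasure"] + spa["acc"] + mmr),
      nMatchedPred = as.integer(prf["nMatchedPred"]),
      nMatchedRef = as.integer(prf["nMatchedRef"]),
      perfectMatches = as.integer(perfect),
      nPred = as.integer(nP), nRef = as.integer(nB), ov = ov)
}

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (", object@nPred, " predicted vs ", object@nRef,
      " reference complexes, ov = ", object@ov, ")\n", sep = "")
  cat(sprintf("  precision %.4f  recall %.4f  f-measure %.4f\n",
              object@precision, object@recall, object@fMeasure))
  cat(sprintf("  Sn %.4f  PPV %.4f  Acc %.4f\n",
              object@sn, object@ppv, object@acc))
  cat(sprintf("  MMR %.4f  composite %.4f  perfect matches %d\n",
              object@mmr, object@composite, object@perfectMatches))
})

#' Flatten an EvalReport to a named list
#'
#' @param report an [EvalReport].
#' @return named list of all metric fields, suitable for JSON output.
#' @export
reportAsList <- function(report) {
  list(precision = report@precision, recall = report@recall,
       f_measure = report@fMeasure, sn = report@sn, ppv = report@ppv,
       acc = report@acc, mmr = report@mmr, composite = report@composite,
       n_matched_pred = report@nMatchedPred,
       n_matched_ref = report@nMatchedRef,
       perfect_matches = report@perfectMatches,
       n_pred = report@nPred, n_ref = report@nRef, ov = report@ov)
}
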