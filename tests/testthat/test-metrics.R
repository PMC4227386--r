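test_that("overlap score matches its definition on hand cases", {
  expect_equal(overlapScore(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(overlapScore(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlapScore(c("a", "b", "x", "y"), c("a", "b", "u", "v")),
               0.25)  # 2^2 / (4*4)
  expect_error(overlapScore(character(0), "a"), "empty")
})

test_that("precision/recall/f reproduce worked examples", {
  B <- ComplexSet(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(unname(precisionRecallF(B, B)[1:3]), c(1, 1, 1))

  P <- ComplexSet(list(c("a", "b", "c")))
  Bbig <- ComplexSet(list(c("a", "b", "c", "d")))
  # os = 9/12 = 0.75 >= 0.25: full match
  expect_equal(unname(precisionRecallF(P, Bbig)[1:3]), c(1, 1, 1))

  # one of two reference complexes matched: harmonic mean of 1 and 0.5
  r <- precisionRecallF(ComplexSet(list(c("a", "b", "c"))), B)
  expect_equal(unname(r[1:3]), c(1, 0.5, 2 / 3))

  expect_warning(z <- precisionRecallF(ComplexSet(), B), "empty")
  expect_equal(unname(z[1:3]), c(0, 0, 0))
})

test_that("Sn/PPV/Acc reproduce worked examples and variants", {
  B <- ComplexSet(list(c("a", "b", "c", "d")))
  P <- ComplexSet(list(c("a", "b", "c")))
  r <- snPpvAcc(P, B)
  expect_equal(unname(r["sn"]), 0.75)
  expect_equal(unname(r["ppv"]), 1)
  expect_equal(unname(r["acc"]), sqrt(0.75))
  expect_equal(unname(snPpvAcc(P, B, accVariant = "product")["acc"]), 0.75)

  Bdisj <- ComplexSet(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(unname(snPpvAcc(Bdisj, Bdisj)), c(1, 1, 1))
  expect_equal(unname(snPpvAcc(ComplexSet(list(c("x", "y", "z"))), Bdisj)),
               c(0, 0, 0))
})

test_that("maximum matching ratio reproduces worked examples", {
  B <- ComplexSet(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(maxMatchingRatio(B, B), 1)
  B1 <- ComplexSet(list(c("a", "b", "x", "y")))
  P1 <- ComplexSet(list(c("a", "b", "u", "v")))  # os = 0.25
  expect_equal(maxMatchingRatio(P1, B1), 0.25)
  # one reference matched perfectly, the other untouched
  expect_equal(maxMatchingRatio(ComplexSet(list(c("a", "b", "c"))), B), 0.5)
  expect_equal(maxMatchingRatio(ComplexSet(), B), 0)
  expect_error(maxMatchingRatio(B, ComplexSet()), "empty")
})

test_that("the full report agrees with brute-force recomputation", {
  set.seed(101)
  universe <- sprintf("u%02d", 1:30)
  for (rep in 1:50) {
    P <- randomComplexSet(universe, sample(1:8, 1))
    B <- randomComplexSet(universe, sample(1:8, 1))
    got <- evaluateComplexes(P, B)
    want <- naiveEvaluate(complexes(P), complexes(B))
    expect_equal(got@precision, want$precision)
    expect_equal(got@recall, want$recall)
    expect_equal(got@fMeasure, want$fMeasure)
    expect_equal(got@sn, want$sn)
    expect_equal(got@ppv, want$ppv)
    expect_equal(got@acc, want$acc)
    expect_equal(got@mmr, want$mmr)
    expect_equal(got@composite, want$composite)
    expect_equal(got@nMatchedPred, as.integer(want$nMatchedPred))
    expect_equal(got@nMatchedRef, as.integer(want$nMatchedRef))
    expect_equal(got@perfectMatches, as.integer(want$perfectMatches))
  }
})

test_that("metrics are permutation invariant and bounded", {
  set.seed(7)
  universe <- sprintf("u%02d", 1:25)
  for (rep in 1:10) {
    P <- randomComplexSet(universe, 5)
    B <- randomComplexSet(universe, 4)
    r1 <- evaluateComplexes(P, B)
    Pp <- ComplexSet(complexes(P)[sample(5)])
    Bp <- ComplexSet(complexes(B)[sample(4)])
    r2 <- evaluateComplexes(Pp, Bp)
    expect_equal(reportAsList(r1)[1:11], reportAsList(r2)[1:11])
    expect_true(all(c(r1@fMeasure, r1@acc, r1@mmr) >= 0))
    expect_true(all(c(r1@fMeasure, r1@acc, r1@mmr) <= 1))
    expect_true(r1@composite >= 0 && r1@composite <= 3)
  }
})

test_that("MMR and recall never decrease when predictions are added", {
  set.seed(19)
  universe <- sprintf("u%02d", 1:25)
  B <- randomComplexSet(universe, 4)
  P <- randomComplexSet(universe, 3)
  extra <- randomComplexSet(universe, 2)
  Pplus <- ComplexSet(c(complexes(P), complexes(extra)))
  expect_gte(maxMatchingRatio(Pplus, B), maxMatchingRatio(P, B))
  expect_gte(unname(precisionRecallF(Pplus, B)["recall"]),
             unname(precisionRecallF(P, B)["recall"]))
})

test_that("self-evaluation of a disjoint catalogue is perfect", {
  B <- ComplexSet(list(c("a", "b", "c"), c("d", "e", "f"), c("g", "h", "i")))
  r <- evaluateComplexes(B, B)
  expect_equal(r@composite, 3)
  expect_equal(r@perfectMatches, 3L)
  expect_warning(r0 <- evaluateComplexes(ComplexSet(), B), "no predicted")
  expect_equal(r0@composite, 0)
})
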