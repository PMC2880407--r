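test_that("composition counts pool sequences and exclude ambiguity codes", {
  ca <- composition("AAAA")
  expect_equal(unname(aaFrequencies(ca)["A"]), 1)
  expect_equal(sum(aaFrequencies(ca)), 1)
  cu <- composition("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(unname(aaFrequencies(cu)), rep(0.05, 20))
  cx <- composition("AXA")
  expect_equal(unname(aaCounts(cx)["A"]), 2)
  expect_equal(sum(aaCounts(cx)), 2)
  expect_error(composition("XXX"), "empty composition")
  # order-invariance over sequences and residues
  expect_equal(aaFrequencies(composition(c("MKV", "EEK"))),
               aaFrequencies(composition(c("KEE", "VKM"))))
})

test_that("fractional difference is relative to the reference with
           undefined flags", {
  cr <- compositionVector(stats::setNames(rep(5, 20), standardResidues()))
  d0 <- fractionalDifference(cr, cr)
  expect_equal(d0$delta, rep(0, 20))
  expect_false(any(d0$undefined))
  # doubling one residue relative to the reference gives delta +1
  cts <- stats::setNames(rep(10, 20), standardResidues())
  cts["K"] <- 20
  dq <- fractionalDifference(compositionVector(cts),
                             compositionVector(stats::setNames(
                               rep(10, 20), standardResidues())))
  fx <- aaFrequencies(compositionVector(cts))
  expect_equal(dq$delta[dq$residue == "K"], (fx[["K"]] - 0.05) / 0.05)
  # zero reference frequency is flagged, not zeroed
  ref0 <- stats::setNames(rep(3, 20), standardResidues())
  ref0["W"] <- 0
  dz <- fractionalDifference(cr, compositionVector(ref0))
  expect_true(dz$undefined[dz$residue == "W"])
  expect_true(is.na(dz$delta[dz$residue == "W"]))
})

test_that("residues are ordered by increasing disorder propensity", {
  cr <- compositionVector(stats::setNames(rep(1, 20), standardResidues()))
  d <- fractionalDifference(cr, cr)
  expect_equal(d$residue[1], "W")
  expect_equal(d$residue[20], "P")
  v <- scaleValues(topIDPScale())
  expect_equal(d$residue, names(sort(v)))
})

test_that("an order-residue-enriched set shows the structure-promoting
           sign pattern", {
  set.seed(61)
  thermo <- biasedComposition(orderPromotingResidues(), 2)
  seqs <- vapply(1:50, function(i) paste(
    sample(standardResidues(), 500, TRUE, prob = thermo), collapse = ""), "")
  cx <- composition(seqs)
  ref <- compositionVector(stats::setNames(rep(100, 20), standardResidues()))
  d <- fractionalDifference(cx, ref)
  ordSet <- d$delta[d$residue %in% orderPromotingResidues()]
  disSet <- d$delta[d$residue %in% disorderPromotingResidues()]
  expect_true(all(ordSet > 0))
  expect_true(all(disSet < 0))
})

test_that("symmetrized KL divergence has its closed-form toy value and
           metric-like properties", {
  expect_lt(abs(klDivergence(c(0.5, 0.5), c(0.25, 0.75)) - 0.1373), 1e-4)
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_error(klDivergence(c(0.5, 0.5, 0), c(0.3, 0.3, 0.4)),
               "unsupported composition")
  set.seed(62)
  for (i in 1:50) {
    p <- randomSimplex(); q <- randomSimplex()
    expect_equal(klDivergence(p, q), klDivergence(q, p), tolerance = 1e-12)
    expect_gte(klDivergence(p, q), 0)
  }
})

test_that("zero counts are pseudocount-regularized with stable results", {
  set.seed(63)
  mkCounts <- function(bias) {
    cts <- stats::setNames(
      as.numeric(rmultinom(1, 15000, biasedComposition(bias))),
      standardResidues())
    cts["W"] <- 0
    compositionVector(cts)
  }
  p <- mkCounts(orderPromotingResidues())
  q <- mkCounts(disorderPromotingResidues())
  d1 <- klDivergence(p, q, pseudocount = 0.5)
  d2 <- klDivergence(p, q, pseudocount = 0.25)
  expect_lt(abs(d1 - d2), 1e-3)
  expect_gte(d1, 0)
})

test_that("similarity bands partition the divergence scale", {
  expect_equal(similarityClass(0.005), "similar")
  expect_equal(similarityClass(0.07), "unlikely_similar")
  expect_equal(similarityClass(0.15), "non_similar")
  expect_equal(similarityClass(c(0.01, 0.05, 0.1)),
               c("gray", "gray", "unlikely_similar"))
  expect_error(similarityClass(-0.1), "invalid divergence")
})

test_that("KL matrices are symmetric with zero diagonal and match the
           scalar operation", {
  u <- compositionVector(stats::setNames(rep(7, 20), standardResidues()))
  m0 <- klMatrix(list(a = u, b = u))
  expect_equal(m0["a", "b"], 0)
  expect_equal(attr(m0, "bands")["a", "b"], "similar")
  set.seed(64)
  comps <- lapply(1:3, function(i) compositionVector(
    stats::setNames(as.numeric(rmultinom(1, 5000, randomSimplex())) + 1,
                    standardResidues())))
  names(comps) <- c("x", "y", "z")
  m <- klMatrix(comps)
  expect_equal(m, t(m), ignore_attr = TRUE)
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m["x", "y"], klDivergence(comps$x, comps$y))
  expect_equal(m["y", "z"], klDivergence(comps$y, comps$z))
  expect_equal(m["x", "z"], klDivergence(comps$x, comps$z))
  expect_error(klMatrix(list(a = u)), "need at least two datasets")
})
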