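test_that("CDF curves saturate for structured and stay low for disordered
           score profiles", {
  c0 <- cdfCurve(rep(0, 30))
  expect_equal(c0@values, rep(1, 20))
  c1 <- cdfCurve(rep(1, 30))
  expect_equal(c1@values, c(rep(0, 19), 1))
  # uniform scores on a fine grid give an identity ramp
  cu <- cdfCurve((seq_len(1000) - 0.5) / 1000)
  expect_equal(cu@values, cu@thresholds, tolerance = 1e-3)
  expect_error(cdfCurve(numeric(0)), "no residues")
})

test_that("CDF curves are non-decreasing and end at 1 for random profiles", {
  set.seed(51)
  for (i in 1:100) {
    cv <- cdfCurve(runif(sample(1:300, 1)))
    expect_true(all(diff(cv@values) >= 0))
    expect_equal(cv@values[20], 1)
    expect_true(all(cv@values >= 0 & cv@values <= 1))
  }
})

test_that("boundary calibration takes class midpoints and flags
           inseparable classes", {
  thr <- cdfThresholds()
  mk <- function(v) new("CDFCurve", thresholds = thr,
                        values = pmin(1, pmax(0, c(rep(v, 19), 1))))
  b <- calibrateCDFBoundary(list(mk(0.9)), list(mk(0.1)))
  expect_equal(b@values[1:19], rep(0.5, 19))
  expect_true(all(b@activeBins[1:19]))
  expect_equal(b@accuracy, 1)
  expect_error(calibrateCDFBoundary(list(), list(mk(0.1))),
               "need both classes")
  expect_error(calibrateCDFBoundary(list(mk(0.5)), list(mk(0.5))),
               "classes inseparable")
})

test_that("CDF distance is a signed mean over active bins and
           antisymmetric", {
  thr <- cdfThresholds()
  mk <- function(v) new("CDFCurve", thresholds = thr, values = v)
  bd <- function(v, act = rep(TRUE, 20))
    new("CDFBoundary", thresholds = thr, values = v, activeBins = act,
        accuracy = NA_real_)
  v1 <- sort(runif(20)); v1[20] <- 1
  expect_equal(cdfDistance(mk(v1), bd(v1)), 0)
  v2 <- pmin(1, v1 + 0.1)
  act <- v2 < 1  # bins where the +0.1 shift is not clipped
  expect_equal(cdfDistance(mk(v2), bd(v1, act)), 0.1, tolerance = 1e-12)
  set.seed(52)
  for (i in 1:20) {
    a <- sort(runif(20)); b2 <- sort(runif(20))
    expect_equal(cdfDistance(mk(a), bd(b2)), -cdfDistance(mk(b2), bd(a)),
                 tolerance = 1e-12)
  }
  # an all-zero-score protein sits strictly above any boundary below 1
  v3 <- rep(0.8, 20)
  expect_gt(cdfDistance(cdfCurve(rep(0, 25)), bd(v3)), 0)
  expect_error(cdfDistance(mk(v1), new("CDFBoundary", thresholds = thr / 2,
                                       values = v1,
                                       activeBins = rep(TRUE, 20),
                                       accuracy = NA_real_)),
               "incompatible grids")
})

test_that("CH coordinates match hand-computed values", {
  expect_equal(chPoint("DDKK")[["mean_net_charge"]], 0, tolerance = 1e-12)
  pe <- chPoint(strrep("E", 12))
  expect_equal(pe[["mean_net_charge"]], 1, tolerance = 1e-12)
  expect_equal(pe[["mean_hydropathy"]], (-3.5 + 4.5) / 9, tolerance = 1e-12)
  pg <- chPoint(strrep("G", 9))
  expect_equal(pg[["mean_net_charge"]], 0, tolerance = 1e-12)
  expect_equal(pg[["mean_hydropathy"]], (-0.4 + 4.5) / 9, tolerance = 1e-12)
  expect_error(chPoint("XXB"), "no scorable residues")
})

test_that("CH point is composition-determined (permutation-invariant)", {
  set.seed(53)
  for (i in 1:15) {
    sq <- randomAASequence(sample(10:100, 1))
    perm <- paste(sample(strsplit(sq, "")[[1]]), collapse = "")
    expect_equal(chPoint(sq), chPoint(perm), tolerance = 1e-12)
  }
})

test_that("CH distance is the vertical offset from the boundary line", {
  sl <- 2.785; ic <- -1.151
  onLine <- c(mean_hydropathy = 0.6, mean_net_charge = sl * 0.6 + ic)
  expect_equal(chDistance(onLine), 0, tolerance = 1e-12)
  expect_equal(chDistance(c(mean_hydropathy = 0.5, mean_net_charge = 0.5)),
               0.2585, tolerance = 1e-12)
  expect_equal(chDistance(chPoint(strrep("G", 9))), -0.1177222,
               tolerance = 1e-6)
})

test_that("CH calls agree with sequence construction", {
  set.seed(54)
  # extended-disordered-like: highly charged (E-rich), low hydropathy
  charged <- biasedComposition(c("E", "D"), 8)
  hydrophobic <- biasedComposition(c("I", "L", "V", "F"), 8)
  for (i in 1:10) {
    sqd <- randomAASequence(200)
    chd <- chDistance(chPoint(paste(
      sample(standardResidues(), 200, TRUE, prob = charged),
      collapse = "")))
    cho <- chDistance(chPoint(paste(
      sample(standardResidues(), 200, TRUE, prob = hydrophobic),
      collapse = "")))
    expect_gt(chd, 0)   # disordered side
    expect_lt(cho, 0)   # ordered side
  }
})

test_that("quadrant labels follow the sign conventions with >= ties", {
  expect_equal(classifyCHCDF(-0.1, -0.1), "molten_globule_like")
  expect_equal(classifyCHCDF(-0.1, 0.1), "extended_disordered")
  expect_equal(classifyCHCDF(0.2, -0.3), "ordered")
  expect_equal(classifyCHCDF(0.2, 0.3), "ch_disordered_cdf_ordered")
  expect_equal(classifyCHCDF(0, 0), "ch_disordered_cdf_ordered")
  expect_equal(classifyCHCDF(0, -1e-9), "ordered")
  expect_equal(classifyCHCDF(-1e-9, 0), "extended_disordered")
})

test_that("CH-CDF summary partitions calls and reports RMSD about the mean", {
  one <- data.frame(protein_id = "a", mean_hydropathy = 0.4,
                    mean_net_charge = 0.1, ch_distance = 0.2,
                    cdf_distance = -0.1, quadrant = "extended_disordered")
  s1 <- chcdfSummary(one)
  expect_equal(s1$rmsd_cdf, 0)
  expect_equal(unname(s1$counts["extended_disordered"]), 1L)
  two <- data.frame(protein_id = c("a", "b"),
                    mean_hydropathy = 0.4, mean_net_charge = 0.1,
                    ch_distance = c(0.2, 0.2),
                    cdf_distance = c(0.3, -0.3),
                    quadrant = c("ch_disordered_cdf_ordered",
                                 "extended_disordered"))
  s2 <- chcdfSummary(two)
  expect_equal(s2$mean_cdf, 0)
  expect_equal(s2$rmsd_cdf, 0.3)
  expect_error(chcdfSummary(NULL), "no calls")
  set.seed(55)
  for (i in 1:10) {
    n <- sample(1:50, 1)
    calls <- data.frame(protein_id = as.character(seq_len(n)),
                        mean_hydropathy = runif(n), mean_net_charge = runif(n),
                        ch_distance = rnorm(n), cdf_distance = rnorm(n))
    calls$quadrant <- classifyCHCDF(calls$cdf_distance, calls$ch_distance)
    expect_equal(sum(chcdfSummary(calls)$counts), n)
  }
})

test_that("whole-proteome classification ties sequences, profiles and
           boundary together", {
  set.seed(56)
  ord <- generateProteome(archetypeConfig("o", 0), 40, seed = 561)
  dis <- generateProteome(archetypeConfig("d", 1), 40, seed = 562)
  b <- calibrateCDFBoundary(cdfCurves(scoreProteome(ord$proteome)),
                            cdfCurves(scoreProteome(dis$proteome)))
  calls <- classifyProteome(dis$proteome, scoreProteome(dis$proteome), b)
  expect_equal(nrow(calls), 40L)
  expect_true(all(calls$cdf_distance < 0))
  expect_true(all(calls$quadrant %in% chcdfQuadrants()))
})
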