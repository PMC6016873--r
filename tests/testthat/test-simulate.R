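test_that("generators are bit-stable under a fixed seed", {
  p <- decidSimParams(seed = 77)
  expect_identical(simulateDecid(p), simulateDecid(p))
  cp <- cytoSimParams(seed = 77)
  expect_identical(simulateCytometry(cp), simulateCytometry(cp))
  expect_identical(simulateQPCR(seed = 77), simulateQPCR(seed = 77))
  ## different seeds differ
  expect_false(identical(measurements(simulateDecid(decidSimParams(seed = 1))),
                         measurements(simulateDecid(decidSimParams(seed = 2)))))
})

test_that("generated data always satisfies the data-model invariants", {
  for (s in 1:5) {
    expect_s4_class(simulateCytometry(cytoSimParams(seed = s,
                                                    concentration = 2)),
                    "CytometryExperiment")
    expect_s4_class(simulateDecid(decidSimParams(seed = s)), "DecidDataset")
    expect_s4_class(simulateQPCR(seed = s, replicates = 2), "QPCRTable")
  }
})

test_that("noise-free limit reproduces the cell means exactly", {
  p <- decidSimParams(sigmaSubject = 0, sigmaResid = 1e-12, delta = 0,
                      seed = 5)
  m <- measurements(simulateDecid(p))
  expected <- p$mu[cbind(m$treatment, as.character(m$time_h))]
  expect_equal(log(m$igfbp1), unname(expected), tolerance = 1e-9)
})

test_that("equal variance components are accepted", {
  p <- decidSimParams(sigmaSubject = 0.3, sigmaResid = 0.3, seed = 1)
  expect_s4_class(simulateDecid(p), "DecidDataset")
})

test_that("case-minus-control log difference recovers the generating delta", {
  p <- decidSimParams(delta = -0.9, seed = 4)
  m <- measurements(simulateDecid(p))
  m$logy <- log(m$igfbp1)
  diffs <- sapply(split(m, list(m$treatment, m$time_h)), function(d)
    mean(d$logy[d$group == "endometriosis"]) -
      mean(d$logy[d$group == "control"]))
  ## SE of the across-cell mean difference from the generating variances
  se <- sqrt((p$sigmaSubject^2 + p$sigmaResid^2) * (2 / 7) / 12)
  expect_lt(abs(mean(diffs) - (-0.9)), 3 * se)
})

test_that("generating-model moments are recovered at large n", {
  p <- decidSimParams(nControl = 250, nCase = 250, delta = -0.9, seed = 9)
  m <- measurements(simulateDecid(p))
  m$logy <- log(m$igfbp1)
  cell <- m$treatment == "cAMP" & m$time_h == 48
  ctrl <- m$logy[cell & m$group == "control"]
  expect_equal(mean(ctrl), p$mu["cAMP", "48"], tolerance = 0.05)
  expect_equal(sd(ctrl), sqrt(p$sigmaSubject^2 + p$sigmaResid^2),
               tolerance = 0.05)
})

test_that("huge Dirichlet concentration pins compositions at the base", {
  p <- cytoSimParams(unkCaseMultiplier = 1, concentration = 1e9,
                     totalCellsMean = 2e5, seed = 3)
  fr <- normalizeSubsets(simulateCytometry(p))
  baseUnk <- p$baseComposition[["uNK"]] /
    sum(p$baseComposition[c("Mono", "Tcell", "Bcell", "uNK",
                            "otherCD66bNeg")])
  expect_equal(mean(fr$fraction_uNK), baseUnk, tolerance = 0.01)
  expect_lt(sd(fr$fraction_uNK), 0.005)
})

test_that("null uNK multiplier gives overlapping case/control fractions", {
  ## two-sided Mann-Whitney on the uNK fraction at alpha = .05 over 200
  ## null simulations: rejection rate must be within [0.02, 0.09]
  rej <- vapply(1:200, function(s) {
    fr <- normalizeSubsets(simulateCytometry(
      cytoSimParams(unkCaseMultiplier = 1, totalCellsMean = 2000,
                    seed = 5000 + s)))
    mannWhitneyExact(fr$fraction_uNK[fr$group == "endometriosis"],
                     fr$fraction_uNK[fr$group == "control"])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("qPCR generator honours its noise-free contracts", {
  q0 <- wells(simulateQPCR(deltaCtShift = 0, noiseSd = 0, seed = 1))
  expect_true(all(q0$ct_target - q0$ct_reference == 8))
  q2 <- simulateQPCR(deltaCtShift = 2, noiseSd = 0, seed = 1)
  fc <- deltaDeltaCt(q2)
  smp <- samples(fc)
  expect_true(all(smp$fold_change[smp$group == "endometriosis"] == 0.25))
  expect_true(all(smp$fold_change[smp$group == "control"] == 1))
})

test_that("a +2 delta-Ct shift is detected in most small-sample studies", {
  ## power of the Mann-Whitney test on delta-Ct at n = 7 vs 7, 100 sims
  rej <- vapply(1:100, function(s) {
    q <- wells(simulateQPCR(deltaCtShift = 2, noiseSd = 0.3,
                            seed = 9000 + s))
    q <- q[q$condition == "vehicle", ]
    dct <- q$ct_target - q$ct_reference
    mannWhitneyExact(dct[q$group == "endometriosis"],
                     dct[q$group == "control"])$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("parameter constructors validate their invariants", {
  expect_error(decidSimParams(nControl = 1), "at least 2")
  expect_error(decidSimParams(sigmaResid = 0), "sigmaResid")
  expect_error(cytoSimParams(unkCaseMultiplier = 0), "unkCaseMultiplier")
  expect_error(cytoSimParams(concentration = -1), "concentration")
  bad <- rep(0.1, 10)
  expect_error(cytoSimParams(baseComposition = bad), "named over the leaf")
})
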