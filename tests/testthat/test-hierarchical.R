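test_that("buildHierarchy counts observations, cells and strata", {
  d <- simulateDecid(decidSimParams(seed = 11))
  st <- buildHierarchy(d)
  expect_identical(st$n, 168L)
  expect_identical(nrow(st$cells), 12L)
  expect_identical(st$nStrata, 168L)           # nested coding
  expect_identical(length(unique(st$stratum)), 168L)
  st2 <- buildHierarchy(d, coding = "shared")
  expect_identical(st2$nStrata, 14L)
  expect_identical(length(unique(st2$stratum)), 14L)
})

test_that("incomplete designs are rejected with the missing keys named", {
  d <- measurements(simulateDecid(decidSimParams(seed = 11)))
  drop <- !(d$subject_id == "ctrl_01" & d$treatment == "cAMP" & d$time_h == 24)
  expect_error(buildHierarchy(DecidDataset(d[drop, ])),
               "missing.*ctrl_01\\|cAMP\\|24")
  oneGroup <- d[d$group == "control", ]
  expect_error(buildHierarchy(DecidDataset(oneGroup)), "both groups")
})

test_that("posterior summaries are invariant to input row order", {
  d <- measurements(simulateDecid(decidSimParams(seed = 21)))
  cfg <- RunConfig(seed = 9, chains = 2, iterations = 400, burnin = 200)
  f1 <- suppressWarnings(fitHierarchical(buildHierarchy(DecidDataset(d)), cfg))
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  f2 <- suppressWarnings(fitHierarchical(buildHierarchy(DecidDataset(d2)),
                                         cfg))
  expect_equal(cellSummary(f1), cellSummary(f2))
  expect_equal(posteriorDraws(f1), posteriorDraws(f2))
})

test_that("adding a constant to the response shifts mu and nothing else", {
  d <- measurements(simulateDecid(decidSimParams(seed = 23)))
  cfg <- RunConfig(seed = 4, chains = 2, iterations = 400, burnin = 200,
                   priorFixedSd = Inf)  # flat fixed-effect priors
  f1 <- suppressWarnings(fitHierarchical(buildHierarchy(DecidDataset(d)),
                                         cfg))
  d2 <- d
  d2$igfbp1 <- d2$igfbp1 * exp(2)       # +2 on the log scale
  f2 <- suppressWarnings(fitHierarchical(buildHierarchy(DecidDataset(d2)),
                                         cfg))
  a1 <- posteriorDraws(f1)
  a2 <- posteriorDraws(f2)
  muN <- grep("^mu", dimnames(a1)[[3]], value = TRUE)
  dN <- grep("^delta", dimnames(a1)[[3]], value = TRUE)
  expect_equal(a2[, , muN], a1[, , muN] + 2, tolerance = 1e-8)
  expect_equal(a2[, , dN], a1[, , dN], tolerance = 1e-8)
  expect_equal(a2[, , "sigma_e"], a1[, , "sigma_e"], tolerance = 1e-8)
  expect_equal(a2[, , "sigma_b"], a1[, , "sigma_b"], tolerance = 1e-8)
})

test_that("identical responses concentrate the group effect at zero", {
  d <- DecidDataset(makeDecidDF(nPerGroup = 4, treatments = "cAMP",
                                times = 6, value = 10))
  fit <- suppressWarnings(fitHierarchical(
    buildHierarchy(d), RunConfig(seed = 2, chains = 2, iterations = 2000,
                                 burnin = 1000)))
  s <- cellSummary(fit)
  expect_lt(abs(s$mean), 0.1)
  expect_gte(s$pr_ge_0, 0.45)
  expect_lte(s$pr_ge_0, 0.55)
  expect_gte(s$pr_ge_0 + s$pr_le_0, 1)
})

test_that("tail probabilities are fractions of draws on each side of zero", {
  d <- simulateDecid(decidSimParams(seed = 31))
  cfg <- RunConfig(seed = 3, chains = 2, iterations = 500, burnin = 250)
  fit <- suppressWarnings(fitHierarchical(buildHierarchy(d), cfg))
  pr <- posteriorGroupProb(fit, "cAMP", 24)
  dr <- as.vector(posteriorDraws(fit)[, , "delta[cAMP,24]"])
  expect_equal(unname(pr[["pr_ge_0"]]), mean(dr >= 0))
  expect_equal(unname(pr[["pr_le_0"]]), mean(dr <= 0))
  if (all(dr < 0)) expect_identical(unname(pr[["pr_ge_0"]]), 0)
  expect_error(posteriorGroupProb(fit, "cAMP", 12), "no such")
})

test_that("pooled group effect reduces to a single delta parameter", {
  d <- simulateDecid(decidSimParams(seed = 41))
  cfg <- RunConfig(seed = 5, chains = 2, iterations = 400, burnin = 200)
  fit <- suppressWarnings(fitHierarchical(buildHierarchy(d), cfg,
                                          pooledDelta = TRUE))
  expect_identical(nrow(cellSummary(fit)), 1L)
  expect_true("delta" %in% dimnames(posteriorDraws(fit))[[3]])
  pr <- posteriorGroupProb(fit, "cAMP", 6)
  expect_true(pr[["pr_le_0"]] > 0.5)  # impaired decidualization
})

test_that("generated quantities: one replicate per kept draw, calibrated means", {
  d <- simulateDecid(decidSimParams(seed = 51))
  cfg <- RunConfig(seed = 6, chains = 2, iterations = 700, burnin = 200)
  fit <- suppressWarnings(fitHierarchical(buildHierarchy(d), cfg))
  gq <- generatedQuantities(fit)
  expect_identical(nrow(gq$yrep), 2L * 500L)   # kept draws x chains
  expect_identical(ncol(gq$yrep), 168L)
  expect_identical(nrow(gq$checks), 24L)       # 12 cells x 2 groups
  ## well-specified fit: most observed cell means inside the 95% band
  expect_gte(mean(gq$checks$covered), 0.9)
  ## deterministic given the fit seed
  gq2 <- generatedQuantities(fit)
  expect_identical(gq$yrep, gq2$yrep)
})

test_that("near-noise-free fits reproduce observed cell means in replicates", {
  p <- decidSimParams(sigmaSubject = 0, sigmaResid = 0.01, seed = 61)
  d <- simulateDecid(p)
  cfg <- RunConfig(seed = 7, chains = 2, iterations = 600, burnin = 300,
                   priorFixedSd = Inf)
  fit <- suppressWarnings(fitHierarchical(buildHierarchy(d), cfg,
                                          fixSigmaB = 0, fixSigmaE = 0.01))
  gq <- generatedQuantities(fit)
  expect_lt(max(abs(gq$checks$observed_mean -
                      (gq$checks$rep_lower + gq$checks$rep_upper) / 2)), 0.05)
})

test_that("non-convergence is flagged loudly, never silently", {
  d <- simulateDecid(decidSimParams(seed = 71))
  cfg <- RunConfig(seed = 8, chains = 3, iterations = 30, burnin = 10)
  expect_warning(fit <- fitHierarchical(buildHierarchy(d), cfg),
                 "NOT converged")
  expect_false(isConverged(fit))
  expect_true(all(c("rhat", "ess") %in% names(mcmcDiagnostics(fit))))
  expect_identical(nrow(mcmcDiagnostics(fit)), 26L)  # 12 mu, 12 delta, 2 SDs
})
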