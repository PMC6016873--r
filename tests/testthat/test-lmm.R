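## one sample per subject, subject variance constrained to 0, no covariates:
## the model must collapse exactly to the classical pooled two-sample t test
test_that("constrained model collapses to the pooled-variance t test", {
  set.seed(42)
  d <- data.frame(subject_id = sprintf("s%d", 1:12),
                  group = rep(c("control", "endometriosis"), each = 6),
                  response = c(rnorm(6, 0.3, 0.1), rnorm(6, 0.25, 0.1)))
  fit <- fitLMM(d, covariates = character(), constrainSubjectVar = TRUE)
  tt <- t.test(response ~ group, data = d, var.equal = TRUE)
  gt <- groupTest(fit)
  expect_equal(unname(gt[["estimate"]]),
               unname(diff(rev(tt$estimate))) * -1, tolerance = 1e-12)
  expect_equal(unname(gt[["p"]]), tt$p.value, tolerance = 1e-12)
  expect_equal(unname(gt[["statistic"]]), -unname(tt$statistic),
               tolerance = 1e-12)
  expect_equal(unname(varComp(fit)[["subject"]]), 0)
})

test_that("REML optimum matches a brute-force error-contrast grid search", {
  ## tiny data: 4 subjects, 8 samples
  set.seed(7)
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:4), each = 2),
                  group = rep(c("control", "endometriosis"), each = 4),
                  response = c(1.1, 1.3, 0.9, 1.0, 0.4, 0.6, 0.8, 0.7))
  fit <- fitLMM(d, covariates = character())
  X <- cbind(1, as.numeric(d$group == "endometriosis"))
  grid <- remlGridOracle(d$response, X, d$subject_id)
  vc <- varComp(fit)
  expect_equal(unname(vc[["subject"]]), unname(grid[["sb2"]]),
               tolerance = 2e-3)
  expect_equal(unname(vc[["residual"]]), unname(grid[["se2"]]),
               tolerance = 2e-3)
  ## the implementation's optimum is not beaten anywhere on the grid
  implLL <- remlContrastLik(d$response, X, d$subject_id,
                            vc[["subject"]], vc[["residual"]])
  expect_gte(implLL, grid[["ll"]] - 1e-6)
})

test_that("REML agrees with lme4 on balanced repeated-measures data", {
  skip_if_not_installed("lme4")
  set.seed(11)
  n <- 10
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:n), each = 3),
                  group = rep(rep(c("control", "endometriosis"), each = 5),
                              each = 3),
                  collection_day = sample(c("day0", "day1_2"), 3 * n, TRUE))
  b <- rnorm(n, 0, 0.3)
  d$response <- 0.5 - 0.2 * (d$group == "endometriosis") +
    0.1 * (d$collection_day == "day1_2") + b[rep(1:n, each = 3)] +
    rnorm(3 * n, 0, 0.2)
  fit <- fitLMM(d, covariates = "collection_day")
  lf <- lme4::lmer(response ~ group + collection_day + (1 | subject_id),
                   data = d, REML = TRUE)
  vcL <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(varComp(fit)[["subject"]]), vcL$vcov[1],
               tolerance = 1e-4)
  expect_equal(unname(varComp(fit)[["residual"]]), vcL$vcov[2],
               tolerance = 1e-4)
  co <- lme4::fixef(lf)
  expect_equal(unname(groupTest(fit)[["estimate"]]),
               unname(co[["groupendometriosis"]]), tolerance = 1e-5)
  seL <- sqrt(diag(as.matrix(vcov(lf))))[2]
  expect_equal(unname(groupTest(fit)[["se"]]), unname(seL), tolerance = 1e-4)
})

test_that("REML variance components are recovered on average", {
  ## 100 balanced datasets, subject SD 0.3, residual SD 0.2
  set.seed(2024)
  est <- t(replicate(100, {
    n <- 10
    b <- rnorm(n, 0, 0.3)
    d <- data.frame(subject_id = rep(sprintf("s%d", 1:n), each = 4),
                    group = rep(rep(c("control", "endometriosis"),
                                    each = 5), each = 4))
    d$response <- 1 - 0.3 * (d$group == "endometriosis") +
      b[rep(1:n, each = 4)] + rnorm(4 * n, 0, 0.2)
    varComp(fitLMM(d, covariates = character()))[c("subject", "residual")]
  }))
  expect_lt(abs(mean(est[, "subject"]) - 0.09), 0.15 * 0.09)
  expect_lt(abs(mean(est[, "residual"]) - 0.04), 0.15 * 0.04)
})

test_that("REML estimates are invariant to subject relabeling", {
  set.seed(3)
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:8), each = 2),
                  group = rep(c("control", "endometriosis"), each = 8),
                  response = rnorm(16))
  perm <- setNames(sprintf("z%d", sample(8)), sprintf("s%d", 1:8))
  d2 <- d
  d2$subject_id <- unname(perm[d$subject_id])
  f1 <- fitLMM(d, covariates = character())
  f2 <- fitLMM(d2, covariates = character())
  expect_equal(varComp(f1), varComp(f2), tolerance = 1e-9)
  expect_equal(groupTest(f1), groupTest(f2), tolerance = 1e-9)
})

test_that("degenerate designs raise informative errors", {
  set.seed(1)
  d <- data.frame(subject_id = sprintf("s%d", 1:8),
                  group = rep(c("control", "endometriosis"), each = 4),
                  response = rnorm(8))
  d$dup <- as.numeric(d$group == "endometriosis")  # collinear with group
  expect_error(fitLMM(d, covariates = "dup"), "collinear.*dup")
  expect_error(fitLMM(d[1:3, ], covariates = character()), "at least 2")
  d3 <- d
  d3$response[1:2] <- NA
  expect_error(fitLMM(data.frame(response = 1), covariates = character()),
               "lacks column")
  ## single-level covariate is dropped, not fatal
  d$flat <- "evening"
  expect_message(fit <- fitLMM(d, covariates = "flat"),
                 "single observed level")
  expect_s4_class(fit, "MixedModelFit")
})
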