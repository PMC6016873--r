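test_that("the powers-of-two worked example holds exactly", {
  tab <- QPCRTable(data.frame(
    sample_id = c("ctl", "cse"), subject_id = c("c1", "e1"),
    group = c("control", "endometriosis"), condition = "vehicle",
    replicate = 1L, ct_target = c(30, 28), ct_reference = c(20, 20)))
  fc <- deltaDeltaCt(tab)
  smp <- samples(fc)
  expect_identical(smp$delta_ct[smp$group == "control"], 10)
  expect_identical(smp$delta_delta_ct[smp$group == "endometriosis"], -2)
  expect_identical(smp$fold_change[smp$group == "endometriosis"], 4)
  ## single calibrator sample: its own fold change is exactly 1
  expect_identical(smp$fold_change[smp$group == "control"], 1)
})

test_that("fold changes equal an independent per-sample re-derivation", {
  set.seed(19)
  n <- 20
  tab <- QPCRTable(data.frame(
    sample_id = sprintf("s%02d", 1:n), subject_id = sprintf("p%02d", 1:n),
    group = sample(c("control", "endometriosis"), n, TRUE),
    condition = sample(c("vehicle", "cAMP"), n, TRUE),
    replicate = 1L,
    ct_target = runif(n, 24, 34), ct_reference = runif(n, 18, 22)))
  w <- wells(tab)
  if (!any(w$group == "control" & w$condition == "vehicle"))
    w$group[1] <- "control"
  tab <- QPCRTable(w)
  fc <- deltaDeltaCt(tab)
  smp <- samples(fc)
  ## brute-force re-computation straight from the well table
  dct <- setNames(w$ct_target - w$ct_reference, w$sample_id)
  cal <- mean(dct[w$group == "control" & w$condition == "vehicle"])
  expect_equal(smp$fold_change,
               unname(2^(-(dct[smp$sample_id] - cal))), tolerance = 1e-12)
})

test_that("replicates are averaged per sample before delta-Ct", {
  tab <- QPCRTable(data.frame(
    sample_id = rep(c("a", "b"), each = 2),
    subject_id = rep(c("c1", "e1"), each = 2),
    group = rep(c("control", "endometriosis"), each = 2),
    condition = "vehicle", replicate = c(1L, 2L),
    ct_target = c(29, 31, 27, 29), ct_reference = c(19.5, 20.5, 20, 20)))
  smp <- samples(deltaDeltaCt(tab))
  expect_equal(smp$delta_ct, c(10, 8))
})

test_that("plate shift invariance: adding c to every Ct changes nothing", {
  tab <- simulateQPCR(seed = 33)
  w <- wells(tab)
  w$ct_target <- w$ct_target + 3.7
  w$ct_reference <- w$ct_reference + 3.7
  fc1 <- deltaDeltaCt(tab)
  fc2 <- deltaDeltaCt(QPCRTable(w))
  expect_equal(samples(fc1), samples(fc2))
  expect_equal(foldChangeTests(fc1), foldChangeTests(fc2))
})

test_that("missing Ct values exclude the sample with a warning", {
  w <- wells(simulateQPCR(nPerGroup = 3, seed = 2))
  w$ct_reference[1] <- NA
  expect_message(fc <- deltaDeltaCt(QPCRTable(w)), "excluding 1 sample")
  expect_false(w$sample_id[1] %in% samples(fc)$sample_id)
  expect_error(deltaDeltaCt(QPCRTable(w), calibratorGroup = "control",
                            calibratorCondition = "nonexistent"),
               "unknown level|empty calibrator")
})

test_that("exact Mann-Whitney matches hand-enumerable cases", {
  r <- mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$statistic, 0)
  expect_identical(r$p.value, 2 * (1 / 20))
  ## all-tied data carries no information
  expect_identical(mannWhitneyExact(c(5, 5), c(5, 5, 5))$p.value, 1)
  expect_error(mannWhitneyExact(numeric(0), 1), "non-empty")
})

test_that("exact p equals the label-enumeration oracle at n = 7 vs 7", {
  set.seed(8)
  for (rep in 1:3) {
    x <- round(rnorm(7, 0.3), 1)  # rounding induces occasional ties
    y <- round(rnorm(7), 1)
    got <- mannWhitneyExact(x, y)
    ora <- mwLabelOracle(x, y)
    expect_identical(got$statistic, ora$U)
    expect_identical(got$p.value, ora$p)
    expect_true(got$exact)
  }
})

test_that("U_x + U_y = nx * ny without ties, and p agrees with wilcox.test", {
  set.seed(12)
  x <- rnorm(6)
  y <- rnorm(8)
  rx <- mannWhitneyExact(x, y)
  ry <- mannWhitneyExact(y, x)
  expect_equal(rx$statistic + ry$statistic, 6 * 8)
  wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
  expect_equal(rx$statistic, unname(wt$statistic))
  expect_equal(rx$p.value, wt$p.value, tolerance = 1e-12)
})

test_that("p is invariant under strictly monotone transforms", {
  set.seed(14)
  x <- rexp(5)
  y <- rexp(6)
  r1 <- mannWhitneyExact(x, y)
  r2 <- mannWhitneyExact(log(x), log(y))
  r3 <- mannWhitneyExact(x^3, y^3)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(r1$p.value, r3$p.value)
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(15)
  x <- round(rnorm(12), 1)
  y <- round(rnorm(12, 0.8), 1)
  got <- mannWhitneyExact(x, y)
  expect_false(got$exact)
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$p.value, wt$p.value, tolerance = 1e-10)
})
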