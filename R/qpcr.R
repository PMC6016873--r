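## Comparative Ct (delta-delta-Ct) relative quantification and the exact
## Mann-Whitney test. The Mann-Whitney implementation enumerates the full
## permutation distribution of U for small samples (ties handled by
## mid-ranks, with the distribution enumerated over the observed tied
## data); larger samples use the normal approximation with tie and
## continuity corrections. The same test serves any two-group continuous
## comparison (e.g. gMFI values).

#' Exact Mann-Whitney U test
#'
#' U is the rank-sum statistic of \code{x} (mid-ranks under ties):
#' U = sum of pooled ranks of x minus nx(nx+1)/2. When
#' nx + ny <= \code{exactLimit} the permutation distribution of U over all
#' choose(nx+ny, nx) group assignments of the observed (possibly tied)
#' values is enumerated exactly; otherwise a normal approximation with
#' tie correction and continuity correction is used. The two-sided
#' p-value is min(1, 2 * min(tail probabilities)); mid-p is not used.
#'
#' @param x,y non-empty numeric vectors.
#' @param exactLimit largest nx + ny for which the exact distribution is
#'   enumerated; default 14.
#' @return list with \code{statistic} (U for \code{x}), \code{p.value},
#'   \code{exact} (logical) and \code{method}.
#' @export
#' @examples
#' mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mannWhitneyExact <- function(x, y, exactLimit = 14L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("inputs must be finite")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  eps <- 1e-9
  if (n <= exactLimit) {
    idx <- combn(n, nx)
    rs <- colSums(matrix(r[idx], nrow = nx))
    Us <- rs - nx * (nx + 1) / 2
    pLow <- mean(Us <= U + eps)
    pHigh <- mean(Us >= U - eps)
    p <- min(1, 2 * min(pLow, pHigh))
    method <- "exact permutation distribution of U"
    exact <- TRUE
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tieAdj)
    if (v <= 0) {
      p <- 1
    } else {
      zLow <- (U - mu + 0.5) / sqrt(v)
      zHigh <- (U - mu - 0.5) / sqrt(v)
      p <- min(1, 2 * min(pnorm(zLow), pnorm(zHigh, lower.tail = FALSE)))
    }
    method <- "normal approximation with tie and continuity correction"
    exact <- FALSE
  }
  list(statistic = U, p.value = p, exact = exact, method = method)
}

#' Comparative Ct relative quantification
#'
#' Technical replicates are averaged (arithmetic mean of Ct) per sample
#' first. Per sample, delta-Ct = Ct(target) - Ct(reference); the
#' calibrator baseline is the mean delta-Ct of the calibrator samples
#' (default: control-group vehicle condition); delta-delta-Ct is the
#' sample delta-Ct minus that baseline and the fold change is
#' 2^(-delta-delta-Ct), assuming exact base-2 amplification efficiency.
#' Per condition, case and control fold changes are compared with
#' \code{\link{mannWhitneyExact}} (x = endometriosis, y = control).
#' Samples with a missing target or reference Ct are excluded with a
#' warning.
#'
#' @param table a \code{\link{QPCRTable}}.
#' @param calibratorGroup,calibratorCondition selector of the calibrator
#'   samples; defaults \code{"control"} and \code{"vehicle"}.
#' @return A \code{\link{FoldChangeResult}}.
#' @export
#' @examples
#' tab <- simulateQPCR(seed = 4)
#' deltaDeltaCt(tab)
deltaDeltaCt <- function(table, calibratorGroup = "control",
                         calibratorCondition = "vehicle") {
  stopifnot(is(table, "QPCRTable"))
  df <- wells(table)
  if (!nrow(df)) stop("empty qPCR table")
  drop <- is.na(df$ct_target) | is.na(df$ct_reference)
  if (any(drop)) {
    bad <- unique(df$sample_id[drop])
    .dlLog("WARN", "excluding %d sample(s) with missing Ct: %s", length(bad),
           paste(bad, collapse = ", "))
    df <- df[!df$sample_id %in% bad, , drop = FALSE]
    if (!nrow(df)) stop("no samples left after excluding missing Ct values")
  }
  agg <- aggregate(df[, c("ct_target", "ct_reference")],
                   by = list(sample_id = df$sample_id), FUN = mean)
  meta <- df[!duplicated(df$sample_id),
             c("sample_id", "subject_id", "group", "condition")]
  smp <- merge(meta, agg, by = "sample_id", sort = TRUE)
  smp$delta_ct <- smp$ct_target - smp$ct_reference
  isCal <- smp$group == calibratorGroup & smp$condition == calibratorCondition
  if (!any(isCal))
    stop(sprintf("empty calibrator: no sample with group=%s, condition=%s",
                 calibratorGroup, calibratorCondition))
  baseline <- mean(smp$delta_ct[isCal])
  smp$delta_delta_ct <- smp$delta_ct - baseline
  smp$fold_change <- 2^(-smp$delta_delta_ct)
  gm <- aggregate(list(mean_delta_ct = smp$delta_ct),
                  by = list(group = smp$group, condition = smp$condition),
                  FUN = mean)
  tests <- do.call(rbind, lapply(sort(unique(smp$condition)), function(cond) {
    cs <- smp$fold_change[smp$condition == cond &
                            smp$group == "endometriosis"]
    ct <- smp$fold_change[smp$condition == cond & smp$group == "control"]
    if (!length(cs) || !length(ct)) return(NULL)
    mw <- mannWhitneyExact(cs, ct)
    data.frame(condition = cond, n_case = length(cs), n_control = length(ct),
               U = mw$statistic, p = mw$p.value, exact = mw$exact,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tests))
    tests <- data.frame(condition = character(), n_case = integer(),
                        n_control = integer(), U = numeric(), p = numeric(),
                        exact = logical())
  smp <- smp[, c("sample_id", "subject_id", "group", "condition", "delta_ct",
                 "delta_delta_ct", "fold_change")]
  rownames(smp) <- NULL
  new("FoldChangeResult", samples = smp, groupMeans = gm, tests = tests,
      calibrator = list(group = calibratorGroup,
                        condition = calibratorCondition))
}
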