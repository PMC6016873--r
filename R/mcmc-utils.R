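## MCMC primitives: a univariate slice sampler (used inside the Gibbs scan
## for the SD components, whose half-Normal priors are not conditionally
## conjugate) and convergence diagnostics (split R-hat, effective sample
## size from combined split chains with Geyer's initial-positive-sequence
## truncation).

#' @importFrom stats rexp
.sliceSample <- function(x0, logf, w = 1, maxSteps = 50L) {
  ## Neal (2003) stepping-out + shrinkage on an unbounded coordinate
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started outside the support")
  z <- f0 - rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(runif(1) * maxSteps)
  k <- (maxSteps - 1) - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

.splitChains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[seq.int(n - half + 1, n), , drop = FALSE])
}

#' Split-R-hat convergence diagnostic
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' factor is computed over the resulting 2m sequences, so that trending
#' single chains are also flagged. Returns \code{NA} for degenerate
#' (constant) parameters.
#'
#' @param mat numeric matrix, iterations x chains.
#' @return Scalar R-hat (>= 1 up to Monte-Carlo noise), or \code{NA}.
#' @export
#' @examples
#' set.seed(1)
#' splitRhat(matrix(rnorm(4000), 1000, 4))  # ~1
splitRhat <- function(mat) {
  mat <- as.matrix(mat)
  seqs <- .splitChains(mat)
  nn <- nrow(seqs)
  if (nn < 4L) return(NA_real_)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of an MCMC parameter
#'
#' Combined-chain estimate: split chains as in \code{\link{splitRhat}},
#' estimate lag autocorrelations from the within-chain autocovariances
#' relative to the pooled variance, and truncate the sum with Geyer's
#' initial positive sequence rule.
#'
#' @param mat numeric matrix, iterations x chains.
#' @return Scalar effective sample size, or \code{NA} for constant input.
#' @export
effectiveSize <- function(mat) {
  mat <- as.matrix(mat)
  seqs <- .splitChains(mat)
  nn <- nrow(seqs)
  mm <- ncol(seqs)
  if (nn < 4L) return(NA_real_)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  varPlus <- (nn - 1) / nn * W + B / nn
  if (!is.finite(varPlus) || varPlus <= 0) return(NA_real_)
  maxLag <- nn - 1L
  acovs <- vapply(seq_len(mm), function(j) {
    a <- acf(seqs[, j], lag.max = maxLag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (nn - 1) / nn * nn / (nn - 1)  # acf already ~ biased; keep as-is
  }, numeric(maxLag + 1L))
  rho <- 1 - (W - rowMeans(acovs)[-1]) / varPlus   # lags 1..maxLag
  ## Geyer: sum consecutive pairs while positive
  tauSum <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair <= 0) break
    tauSum <- tauSum + pair
    t <- t + 2L
  }
  ess <- nn * mm / (1 + 2 * tauSum)
  min(ess, nn * mm)
}
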