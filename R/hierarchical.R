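## Bayesian hierarchical model of the decidualization time course.
##
## Observation model (log scale), for measurement i in cell c(i) =
## (treatment, time) with case indicator g_i and subject stratum s(i):
##
##   log y_i = mu[c(i)] + delta[c(i)] * g_i + b_{s(i)} + e_i
##   b_s ~ Normal(0, sigma_b^2),  e_i ~ Normal(0, sigma_e^2)
##   mu_c, delta_c ~ Normal(0, sFixed^2)   (flat when sFixed = Inf)
##   sigma_b, sigma_e ~ half-Normal(sSd)
##
## Under the nested coding the subject effects are indexed per (subject,
## treatment, time) stratum; under the shared coding one intercept per
## subject is reused in every cell. The sampler is a Gibbs scan over the
## conditionally conjugate normal blocks (mu, delta, b), with a univariate
## slice step on log sigma for the two SD components (whose half-Normal
## priors are not conjugate). All updates are deterministic given the seed.

#' Build the design structure of the hierarchical model
#'
#' Validates completeness (every (subject, treatment, time) cell present
#' exactly once, both groups represented), log-transforms the response,
#' and constructs the index maps the sampler uses. Rows are put in a
#' canonical order (treatment, time, subject) so results are invariant to
#' the input row order.
#'
#' @param dataset a \code{\link{DecidDataset}}.
#' @param coding \code{"nested"} (default): independent subject effects
#'   per (subject, treatment, time) stratum; \code{"shared"}: one
#'   intercept per subject across all cells.
#' @return A list with the log response \code{y}, the cell table
#'   \code{cells} (treatment x time), per-observation indices
#'   \code{cell}, \code{stratum}, \code{isCase}, stratum and subject
#'   bookkeeping, and the coding.
#' @export
#' @examples
#' d <- simulateDecid(decidSimParams(seed = 11))
#' str(buildHierarchy(d), max.level = 1)
buildHierarchy <- function(dataset, coding = c("nested", "shared")) {
  coding <- match.arg(coding)
  stopifnot(is(dataset, "DecidDataset"))
  df <- measurements(dataset)
  if (!nrow(df)) stop("empty dataset")
  if (length(unique(df$group)) < 2L)
    stop("both groups (control, endometriosis) must be represented")
  treatments <- .treatmentLevels[.treatmentLevels %in% df$treatment]
  times <- .timeLevels[.timeLevels %in% df$time_h]
  subjects <- sort(unique(df$subject_id))
  cells <- expand.grid(time_h = times, treatment = treatments,
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, c("treatment", "time_h")]
  key <- function(s, t, tau) paste(s, t, tau, sep = "|")
  have <- key(df$subject_id, df$treatment, df$time_h)
  wanted <- as.vector(outer(subjects, seq_len(nrow(cells)), function(s, ci)
    key(s, cells$treatment[ci], cells$time_h[ci])))
  missing <- setdiff(wanted, have)
  if (length(missing))
    stop("incomplete design; missing (subject, treatment, time) cell(s): ",
         paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" ... and %d more",
                                            length(missing) - 10L))
  ## canonical row order: by treatment, time, subject
  ord <- order(match(df$treatment, treatments), match(df$time_h, times),
               df$subject_id)
  df <- df[ord, , drop = FALSE]
  cellOf <- match(key("", df$treatment, df$time_h),
                  key("", cells$treatment, cells$time_h))
  subjOf <- match(df$subject_id, subjects)
  ## nested coding: one stratum per (subject, cell) pair; shared: per subject
  stratum <- if (coding == "nested")
    (cellOf - 1L) * length(subjects) + subjOf else subjOf
  grpOfSubject <- vapply(subjects, function(s)
    unique(df$group[df$subject_id == s]), character(1))
  list(y = log(df$igfbp1), n = nrow(df), cells = cells, cell = cellOf,
       stratum = as.integer(stratum),
       nStrata = if (coding == "nested")
         nrow(cells) * length(subjects) else length(subjects),
       subject = subjOf,
       subjects = data.frame(subject_id = subjects, group = grpOfSubject,
                             stringsAsFactors = FALSE),
       isCase = as.numeric(df$group == "endometriosis"), coding = coding,
       data = df)
}

.gibbsChain <- function(structure, nIter, prec0, sSd, pooledDelta,
                        fixSigmaB, fixSigmaE, chainSeed, burnin, thin) {
  ## Under the nested coding every stratum holds the observations of one
  ## (subject, cell) pair, so the marginal covariance after integrating the
  ## subject effects out stays diagonal; (mu, delta) are therefore drawn
  ## from that marginal and b is redrawn conditionally afterwards — a joint
  ## exact draw of (mu, delta, b) that avoids the ridge between cell
  ## parameters and per-stratum effects. The shared coding (one intercept
  ## reused across cells) conditions on b instead.
  nested <- identical(structure$coding, "nested") &&
    all(tabulate(structure$stratum, structure$nStrata) == 1L)
  y <- structure$y
  n <- structure$n
  C <- nrow(structure$cells)
  cell <- structure$cell
  g <- structure$isCase
  stratum <- structure$stratum
  S <- structure$nStrata
  dIdx <- if (pooledDelta) rep(1L, n) else cell
  D <- if (pooledDelta) 1L else C
  caseObs <- which(g == 1)
  nC <- tabulate(cell, C)
  mCell <- tabulate(cell[caseObs], C)
  nS <- tabulate(stratum, S)
  set.seed(chainSeed)
  ## dispersed starts around data summaries
  ctrlMean <- as.numeric(rowsum(y * (1 - g), cell)) / pmax(1, nC - mCell)
  caseMean <- as.numeric(rowsum(y * g, cell)) / pmax(1, mCell)
  mu <- ctrlMean + rnorm(C, 0, 0.5)
  dHat <- caseMean - ctrlMean
  delta <- (if (pooledDelta) mean(dHat) else dHat) + rnorm(D, 0, 0.5)
  sdY <- max(sd(y), 0.1)
  sigB <- if (!is.null(fixSigmaB)) fixSigmaB else
    max(0.05, 0.5 * sdY * exp(runif(1, -0.7, 0.7)))
  sigE <- if (!is.null(fixSigmaE)) fixSigmaE else
    max(0.05, 0.5 * sdY * exp(runif(1, -0.7, 0.7)))
  b <- if (!is.null(fixSigmaB) && fixSigmaB == 0) numeric(S) else
    rnorm(S, 0, max(sigB, 0.05))
  nKeep <- length(seq.int(burnin + 1L, nIter, by = thin))
  out <- matrix(NA_real_, nKeep, C + D + 2L)
  kept <- 0L
  for (it in seq_len(nIter)) {
    sigE2 <- sigE^2
    ## marginal observation variance for the (mu, delta) draw: subject
    ## effects integrated out under the nested coding
    sigM2 <- if (nested) sigE2 + sigB^2 else sigE2
    r <- if (nested) y else y - b[stratum]
    if (!pooledDelta) {
      ## joint conjugate draw of (mu_c, delta_c) per cell
      S0 <- as.numeric(rowsum(r, cell))
      S1 <- as.numeric(rowsum(r * g, cell))
      P11 <- nC / sigM2 + prec0
      P12 <- mCell / sigM2
      P22 <- mCell / sigM2 + prec0
      det <- P11 * P22 - P12^2
      rhs0 <- S0 / sigM2
      rhs1 <- S1 / sigM2
      mMu <- (P22 * rhs0 - P12 * rhs1) / det
      mDe <- (P11 * rhs1 - P12 * rhs0) / det
      ## Cholesky of the 2x2 posterior covariance, vectorized over cells
      s11 <- P22 / det
      s12 <- -P12 / det
      s22 <- P11 / det
      L11 <- sqrt(s11)
      L21 <- s12 / L11
      L22 <- sqrt(pmax(s22 - L21^2, 0))
      z1 <- rnorm(C)
      z2 <- rnorm(C)
      mu <- mMu + L11 * z1
      delta <- mDe + L21 * z1 + L22 * z2
    } else {
      ## cell means given the shared group effect
      pr <- r - delta[dIdx] * g
      sums <- as.numeric(rowsum(pr, cell))
      prec <- nC / sigM2 + prec0
      mu <- rnorm(C, (sums / sigM2) / prec, sqrt(1 / prec))
      ## shared group effect
      prc <- (r - mu[cell])[caseObs]
      prec <- length(caseObs) / sigM2 + prec0
      delta <- rnorm(1L, (sum(prc) / sigM2) / prec, sqrt(1 / prec))
    }
    ## lower bound keeps the sampler off the numerically degenerate spike
    ## at sigma = 0 that zero-variation data would otherwise induce
    lb <- log(1e-8)
    if (nested && is.null(fixSigmaB) && is.null(fixSigmaE)) {
      ## Exact joint block for (sigma_b, sigma_e, b) under the nested
      ## coding: with b integrated out the likelihood depends on the SDs
      ## only through sigma_M^2 = sigma_b^2 + sigma_e^2, and so do the
      ## equal-scale half-Normal priors; in polar coordinates sigma_M has
      ## a univariate marginal posterior (slice-sampled on log sigma_M,
      ## the +2u term being the area element sigma_M dsigma_M dphi) and
      ## the angle is uniform on (0, pi/2). b is then redrawn from its
      ## conditional. This removes the ridge walk between the two SDs,
      ## which the data separate only weakly (one well per stratum).
      rs <- y - mu[cell] - delta[dIdx] * g
      SSR <- sum(rs^2)
      u <- .sliceSample(max(log(sqrt(sigB^2 + sigE^2)), lb), function(u)
        if (u < lb) -Inf else
          (2 - n) * u - SSR / (2 * exp(2 * u)) - exp(2 * u) / (2 * sSd^2))
      sigM <- exp(u)
      phi <- runif(1, 0, pi / 2)
      sigB <- sigM * sin(phi)
      sigE <- sigM * cos(phi)
      prec <- nS / sigE^2 + 1 / sigB^2
      b <- rnorm(S, (as.numeric(rowsum(rs, stratum)) / sigE^2) / prec,
                 sqrt(1 / prec))
    } else {
      ## subject-stratum effects given (mu, delta)
      if (is.null(fixSigmaB) || fixSigmaB > 0) {
        rs <- y - mu[cell] - delta[dIdx] * g
        sumR <- as.numeric(rowsum(rs, stratum))
        prec <- nS / sigE2 + 1 / sigB^2
        b <- rnorm(S, (sumR / sigE2) / prec, sqrt(1 / prec))
      }
      ## SD components: slice on log sigma; log target of u = log sigma is
      ## (1 - k) u - SS / (2 e^{2u}) - e^{2u} / (2 sSd^2)  (k = #terms)
      if (is.null(fixSigmaB)) {
        Sb <- sum(b^2)
        sigB <- exp(.sliceSample(max(log(sigB), lb), function(u)
          if (u < lb) -Inf else
            (1 - S) * u - Sb / (2 * exp(2 * u)) - exp(2 * u) / (2 * sSd^2)))
      }
      if (is.null(fixSigmaE)) {
        e <- y - mu[cell] - delta[dIdx] * g - b[stratum]
        RSS <- sum(e^2)
        sigE <- exp(.sliceSample(max(log(sigE), lb), function(u)
          if (u < lb) -Inf else
            (1 - n) * u - RSS / (2 * exp(2 * u)) - exp(2 * u) / (2 * sSd^2)))
      }
    }
    if (it > burnin && (it - burnin - 1L) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- c(mu, delta, sigB, sigE)
    }
  }
  out
}

#' Fit the hierarchical decidualization model by Gibbs sampling
#'
#' Runs \code{config@chains} chains from dispersed starts; draws after
#' burn-in (thinned) are kept. Non-convergence (any split-R-hat above
#' \code{rhatThreshold}) triggers a prominent warning and is recorded in
#' the \code{converged} slot — the fit is still returned.
#'
#' @param structure from \code{\link{buildHierarchy}}.
#' @param config a \code{\link{RunConfig}} (seed, chains, iterations,
#'   burn-in, thinning, prior hyperparameters).
#' @param pooledDelta if TRUE a single group effect is shared by all
#'   (treatment, time) cells instead of one per cell.
#' @param fixSigmaB,fixSigmaE optionally fix a SD component at a known
#'   value (e.g. \code{fixSigmaB = 0} removes the subject effects); NULL
#'   (default) samples it.
#' @param rhatThreshold convergence threshold for split-R-hat;
#'   default 1.05.
#' @return A \code{\link{HierarchicalFit}}.
#' @export
#' @examples
#' d <- simulateDecid(decidSimParams(seed = 11))
#' fit <- fitHierarchical(buildHierarchy(d),
#'                        RunConfig(seed = 1, chains = 2, iterations = 600,
#'                                  burnin = 300))
#' cellSummary(fit)
fitHierarchical <- function(structure, config = RunConfig(),
                            pooledDelta = FALSE, fixSigmaB = NULL,
                            fixSigmaE = NULL, rhatThreshold = 1.05) {
  stopifnot(is(config, "RunConfig"))
  C <- nrow(structure$cells)
  D <- if (pooledDelta) 1L else C
  sFixed <- config@priorFixedSd
  prec0 <- if (is.na(sFixed) || !is.finite(sFixed)) 0 else 1 / sFixed^2
  chainSeeds <- .withSeed(config@seed,
                          sample.int(.Machine$integer.max - 1L,
                                     config@chains))
  draws <- lapply(seq_len(config@chains), function(k)
    .gibbsChain(structure, config@iterations, prec0, config@priorSdScale,
                pooledDelta, fixSigmaB, fixSigmaE, chainSeeds[k],
                config@burnin, config@thin))
  nKeep <- nrow(draws[[1]])
  cellLab <- sprintf("%s,%d", structure$cells$treatment,
                     structure$cells$time_h)
  pNames <- c(sprintf("mu[%s]", cellLab),
              if (pooledDelta) "delta" else sprintf("delta[%s]", cellLab),
              "sigma_b", "sigma_e")
  arr <- array(NA_real_, dim = c(nKeep, config@chains, length(pNames)),
               dimnames = list(NULL, sprintf("chain%d",
                                             seq_len(config@chains)), pNames))
  for (k in seq_len(config@chains)) arr[, k, ] <- draws[[k]]
  diag <- data.frame(
    parameter = pNames,
    rhat = vapply(pNames, function(p) splitRhat(arr[, , p]), numeric(1)),
    ess = vapply(pNames, function(p) effectiveSize(arr[, , p]), numeric(1)),
    row.names = NULL)
  converged <- all(is.na(diag$rhat) | diag$rhat <= rhatThreshold)
  dNames <- pNames[seq.int(C + 1L, C + D)]
  summ <- do.call(rbind, lapply(seq_along(dNames), function(j) {
    d <- as.vector(arr[, , dNames[j]])
    q <- unname(quantile(d, c(0.025, 0.975)))
    data.frame(
      treatment = if (pooledDelta) "pooled" else structure$cells$treatment[j],
      time_h = if (pooledDelta) NA_integer_ else structure$cells$time_h[j],
      mean = mean(d), sd = sd(d), lower95 = q[1], upper95 = q[2],
      pr_ge_0 = mean(d >= 0), pr_le_0 = mean(d <= 0),
      rhat = diag$rhat[diag$parameter == dNames[j]],
      ess = diag$ess[diag$parameter == dNames[j]],
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  if (!converged) {
    badp <- diag$parameter[!is.na(diag$rhat) & diag$rhat > rhatThreshold]
    warning(sprintf(
      "hierarchical fit has NOT converged: split-Rhat > %.2f for %s",
      rhatThreshold, paste(badp, collapse = ", ")), call. = FALSE)
  }
  new("HierarchicalFit", draws = arr, cells = structure$cells,
      summary = summ, diagnostics = diag, converged = converged,
      rhatThreshold = rhatThreshold, structure = structure, config = config,
      model = list(pooledDelta = pooledDelta, fixSigmaB = fixSigmaB,
                   fixSigmaE = fixSigmaE, priorFixedSd = sFixed,
                   priorSdScale = config@priorSdScale))
}

#' Posterior tail probabilities of the group effect
#'
#' The "posterior probability of the group effect being zero" is
#' operationalized as the two tail probabilities Pr(delta >= 0) and
#' Pr(delta <= 0), computed as the fraction of kept draws on each side of
#' zero (draws exactly at zero count in both, so the two sum to >= 1).
#'
#' @param fit a \code{\link{HierarchicalFit}}.
#' @param treatment,time the (treatment, time) cell; ignored when the fit
#'   used a pooled group effect.
#' @return Named numeric \code{c(pr_ge_0, pr_le_0)}.
#' @export
posteriorGroupProb <- function(fit, treatment, time) {
  stopifnot(is(fit, "HierarchicalFit"))
  if (isTRUE(fit@model$pooledDelta)) {
    d <- as.vector(fit@draws[, , "delta"])
  } else {
    lab <- sprintf("delta[%s,%d]", treatment, as.integer(time))
    if (!lab %in% dimnames(fit@draws)[[3]])
      stop("no such (treatment, time) cell: ", treatment, ", ", time)
    d <- as.vector(fit@draws[, , lab])
  }
  c(pr_ge_0 = mean(d >= 0), pr_le_0 = mean(d <= 0))
}

#' Posterior-predictive generated quantities
#'
#' For every kept draw, a full replicate dataset is simulated from the
#' model at that draw (fresh subject-stratum effects and residuals).
#' Replicate cell-by-group means are compared with the observed ones:
#' the central 95\% band of replicate means, a posterior-predictive
#' p-style value (fraction of replicate means at or above the observed
#' mean) and a coverage flag are reported per (treatment, time, group).
#'
#' @param fit a \code{\link{HierarchicalFit}}.
#' @param seed seed for the replicate simulations; defaults to the fit's
#'   configured seed offset by 777.
#' @return list with \code{yrep} (kept-draws x observations matrix of
#'   replicate log responses, observations in the canonical order of the
#'   fitted structure) and \code{checks} (the per-cell comparison table).
#' @export
generatedQuantities <- function(fit, seed = NULL) {
  stopifnot(is(fit, "HierarchicalFit"))
  st <- fit@structure
  if (is.null(seed)) seed <- fit@config@seed + 777L
  C <- nrow(st$cells)
  pooled <- isTRUE(fit@model$pooledDelta)
  dIdx <- if (pooled) rep(1L, st$n) else st$cell
  arr <- fit@draws
  nKeep <- dim(arr)[1] * dim(arr)[2]
  flat <- function(p) as.vector(arr[, , p])
  muM <- vapply(seq_len(C), function(c0) flat(sprintf("mu[%s,%d]",
                                                      st$cells$treatment[c0],
                                                      st$cells$time_h[c0])),
                numeric(nKeep))
  dN <- if (pooled) "delta" else sprintf("delta[%s,%d]", st$cells$treatment,
                                         st$cells$time_h)
  dM <- vapply(dN, flat, numeric(nKeep))
  sigB <- flat("sigma_b")
  sigE <- flat("sigma_e")
  yrep <- .withSeed(seed, {
    bNew <- matrix(rnorm(nKeep * st$nStrata), nKeep) * sigB
    eps <- matrix(rnorm(nKeep * st$n), nKeep) * sigE
    muM[, st$cell, drop = FALSE] +
      dM[, dIdx, drop = FALSE] * rep(st$isCase, each = nKeep) +
      bNew[, st$stratum, drop = FALSE] + eps
  })
  ## cell x group means
  gc <- st$cell + C * st$isCase
  counts <- tabulate(gc, 2L * C)
  M <- matrix(0, st$n, 2L * C)
  M[cbind(seq_len(st$n), gc)] <- 1 / counts[gc]
  repMeans <- yrep %*% M
  obsMeans <- as.numeric(crossprod(st$y, M))
  present <- counts > 0
  checks <- data.frame(
    treatment = rep(st$cells$treatment, 2L),
    time_h = rep(st$cells$time_h, 2L),
    group = rep(.groupLevels, each = C),
    observed_mean = obsMeans,
    rep_lower = apply(repMeans, 2, function(v) quantile(v, 0.025)),
    rep_upper = apply(repMeans, 2, function(v) quantile(v, 0.975)),
    ppp = colMeans(repMeans >= rep(obsMeans, each = nKeep)),
    stringsAsFactors = FALSE)[present, ]
  checks$covered <- checks$observed_mean >= checks$rep_lower &
    checks$observed_mean <= checks$rep_upper
  rownames(checks) <- NULL
  list(yrep = yrep, checks = checks)
}
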