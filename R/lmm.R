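## Random-intercept linear mixed models estimated by REML.
##
## The restricted likelihood is profiled over the fixed effects and the
## residual variance, leaving a 1-D (subject) or 2-D (subject + cycle)
## optimization over the variance ratio(s) theta_j = sigma_j^2 / sigma_e^2.
## Group-effect inference is a Wald t test with residual degrees of freedom
## n - rank(X); with the subject variance constrained to zero and no
## covariates this collapses exactly to the classical two-sample
## pooled-variance t test.

.remlProfile <- function(theta, y, X, Zs) {
  ## restricted log-likelihood at variance ratios theta (profiled over
  ## beta and sigma_e^2), plus the profiled estimates
  n <- length(y); p <- ncol(X)
  V <- diag(n)
  for (j in seq_along(Zs))
    if (theta[j] > 0) V <- V + theta[j] * tcrossprod(Zs[[j]])
  R <- chol(V)
  logDetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  XtViy <- crossprod(X, Vi_y)
  cR <- chol(XtViX)
  beta <- backsolve(cR, forwardsolve(t(cR), XtViy))
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  rss <- drop(crossprod(r, Vi_r))
  sigma2 <- rss / (n - p)
  logDetXtViX <- 2 * sum(log(diag(cR)))
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + logDetV + logDetXtViX)
  covBeta <- chol2inv(cR) * sigma2
  list(logLik = ll, beta = drop(beta), sigma2 = sigma2, covBeta = covBeta,
       theta = theta)
}

.remlFit <- function(y, X, Zs, constrain = rep(FALSE, length(Zs))) {
  nz <- length(Zs)
  free <- which(!constrain)
  evalAt <- function(thFree) {
    th <- numeric(nz)
    th[free] <- thFree
    .remlProfile(th, y, X, Zs)
  }
  if (!length(free)) return(evalAt(numeric(0)))
  best <- evalAt(rep(0, length(free)))        # boundary: all free ratios 0
  if (length(free) == 1L) {
    opt <- optimize(function(s) evalAt(exp(s))$logLik,
                    interval = c(-12, 12), maximum = TRUE, tol = 1e-9)
    cand <- evalAt(exp(opt$maximum))
    if (cand$logLik > best$logLik) best <- cand
  } else {
    opt <- optim(rep(-1, length(free)),
                 function(s) -evalAt(exp(s))$logLik, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
    cand <- evalAt(exp(opt$par))
    if (cand$logLik > best$logLik) best <- cand
    ## check each single-component boundary too
    for (j in seq_along(free)) {
      o1 <- optimize(function(s) {
        th <- rep(0, length(free)); th[j] <- exp(s)
        evalAt(th)$logLik
      }, interval = c(-12, 12), maximum = TRUE, tol = 1e-9)
      th <- rep(0, length(free)); th[j] <- exp(o1$maximum)
      cand <- evalAt(th)
      if (cand$logLik > best$logLik) best <- cand
    }
  }
  best
}

.indicator <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Fit a random-intercept mixed model for one cell population
#'
#' Estimates \code{response ~ group + covariates + (1 | subject)} (and
#' optionally a cycle-within-subject intercept) by REML, profiling the
#' restricted likelihood over the fixed effects and residual variance and
#' maximizing over the variance ratio(s), including the boundary at zero.
#' The group effect (endometriosis vs control) is tested with a Wald t
#' statistic on residual degrees of freedom.
#'
#' @param data data.frame with columns \code{response}, \code{group},
#'   \code{subject_id}, optionally \code{cycle_id} and covariate columns.
#' @param covariates character vector of covariate column names to adjust
#'   for (factors or numeric). Covariate factors with fewer than two
#'   observed levels are dropped as unestimable, with a log note.
#' @param randomEffects \code{"subject"} (default) or
#'   \code{"subject_cycle"} to add a cycle-within-subject intercept.
#' @param constrainSubjectVar if TRUE the subject variance is fixed at
#'   exactly zero (the model collapses to ordinary least squares).
#' @param population label stored in the result.
#' @param transform label of the transform already applied to
#'   \code{response}.
#' @return A \code{\link{MixedModelFit}}.
#' @export
#' @examples
#' d <- measurements(simulateDecid(decidSimParams(seed = 3)))
#' d <- d[d$treatment == "cAMP" & d$time_h == 24, ]
#' d$response <- log(d$igfbp1)
#' fitLMM(d, covariates = character())
fitLMM <- function(data, covariates = intersect(
                     c("collection_day", "collection_time"), names(data)),
                   randomEffects = c("subject", "subject_cycle"),
                   constrainSubjectVar = FALSE, population = "response",
                   transform = "none") {
  randomEffects <- match.arg(randomEffects)
  need <- c("response", "group", "subject_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  data <- data[complete.cases(data[, c(need, covariates), drop = FALSE]), ,
               drop = FALSE]
  n <- nrow(data)
  grp <- factor(data$group, levels = .groupLevels)
  nPerGroup <- tapply(data$subject_id, grp, function(s) length(unique(s)))
  if (any(is.na(nPerGroup)) || any(nPerGroup < 2))
    stop("need at least 2 subjects in each group")
  ## fixed-effect design: intercept + group + covariates
  X <- cbind(`(Intercept)` = rep(1, n),
             group = as.numeric(grp == "endometriosis"))
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (nlevels(droplevels(v)) < 2L) {
        .dlLog("INFO", "covariate %s has a single observed level; dropped", cv)
        next
      }
      v <- droplevels(v)
      for (lv in levels(v)[-1])
        X <- cbind(X, setNames(matrix(as.numeric(v == lv)), NULL))
      colnames(X)[(ncol(X) - nlevels(v) + 2):ncol(X)] <-
        paste0(cv, levels(v)[-1])
    } else {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    }
  }
  if (n <= ncol(X))
    stop(sprintf("fewer samples (%d) than needed for %d fixed effects", n,
                 ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Zs <- list(subject = .indicator(data$subject_id))
  constrain <- c(subject = isTRUE(constrainSubjectVar))
  if (randomEffects == "subject_cycle") {
    if (!"cycle_id" %in% names(data))
      stop("randomEffects = 'subject_cycle' requires a cycle_id column")
    Zs$cycle <- .indicator(paste(data$subject_id, data$cycle_id, sep = "|"))
    constrain <- c(constrain, cycle = FALSE)
  }
  fit <- .remlFit(data$response, X, Zs, constrain = constrain)
  se <- sqrt(diag(fit$covBeta))
  df <- n - ncol(X)
  stat <- fit$beta / se
  pvals <- 2 * pt(-abs(stat), df)
  coefs <- data.frame(estimate = fit$beta, se = se, statistic = stat,
                      p = pvals, row.names = colnames(X))
  vc <- setNames(fit$theta * fit$sigma2, names(Zs))
  vc <- c(vc, residual = fit$sigma2)
  gi <- which(colnames(X) == "group")
  new("MixedModelFit", population = population, transform = transform,
      coefficients = coefs, varComp = vc,
      groupTest = c(estimate = fit$beta[gi], se = se[gi],
                    statistic = stat[gi], df = df, p = pvals[gi]),
      nSamples = as.integer(n),
      nSubjects = length(unique(data$subject_id)),
      logRestrictedLik = fit$logLik)
}
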