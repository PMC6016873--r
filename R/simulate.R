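## Synthetic-data generators. Each emits a validated data container with the
## generating-model structure the downstream analyses assume:
##   - decidualization: log-normal IGFBP-1 with cell means, an additive case
##     effect on the log scale, subject and residual variance components;
##   - cytometry: Dirichlet-multinomial leaf-gate compositions with a
##     case-specific uNK proportion shift, internal gates as sums of leaves;
##   - qPCR: target Ct = reference Ct + base dCt + case shift + noise.
## All generators are bit-stable given their seed.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

.defaultMu <- function() {
  ## control-group log IGFBP-1 means (illustrative): cAMP-driven induction
  ## rising over 6 -> 48 h above near-flat vehicles
  m <- rbind(cAMP        = c(2.0, 3.0, 4.0),
             vehicle_PBS = c(1.0, 1.2, 1.4),
             vehicle_EtOH = c(1.0, 1.2, 1.4),
             cAMP_MPA_E2 = c(2.2, 3.3, 4.4))
  colnames(m) <- as.character(.timeLevels)
  m
}

.cellMatrix <- function(x, what) {
  if (is.null(dim(x))) {
    if (length(x) != 1L)
      stop(what, " must be a scalar or a treatment x time matrix")
    x <- matrix(x, nrow = length(.treatmentLevels), ncol = length(.timeLevels),
                dimnames = list(.treatmentLevels, as.character(.timeLevels)))
  }
  x <- as.matrix(x)
  if (!all(.treatmentLevels %in% rownames(x)) ||
      !all(as.character(.timeLevels) %in% colnames(x)))
    stop(what, " must have rows ", paste(.treatmentLevels, collapse = ", "),
         " and columns ", paste(.timeLevels, collapse = ", "))
  x[.treatmentLevels, as.character(.timeLevels), drop = FALSE]
}

#' Parameters of the decidualization time-course generator
#'
#' @param nControl,nCase subjects per group (>= 2 each); defaults 7 and 7.
#' @param mu control-group mean of log IGFBP-1, either a scalar or a
#'   4 treatment x 3 time matrix; default an illustrative cAMP induction
#'   profile rising over 6-48 h above flat vehicles.
#' @param delta additive case effect on the log scale (negative = impaired
#'   decidualization), scalar or matrix like \code{mu}; default -0.9.
#' @param sigmaSubject SD of subject random intercepts (>= 0); default 0.4.
#' @param sigmaResid residual SD on the log scale (> 0); default 0.3.
#' @param subjectCoding \code{"nested"} draws an independent subject effect
#'   per (subject, treatment, time) stratum; \code{"shared"} draws one
#'   effect per subject used in every cell.
#' @param seed integer seed.
#' @return Validated parameter list for \code{\link{simulateDecid}}.
#' @export
#' @examples
#' p <- decidSimParams(seed = 7)
#' d <- simulateDecid(p)
#' d
decidSimParams <- function(nControl = 7L, nCase = 7L, mu = .defaultMu(),
                           delta = -0.9, sigmaSubject = 0.4, sigmaResid = 0.3,
                           subjectCoding = c("nested", "shared"), seed = 1L) {
  subjectCoding <- match.arg(subjectCoding)
  nControl <- as.integer(nControl); nCase <- as.integer(nCase)
  if (nControl < 2L || nCase < 2L) stop("need at least 2 subjects per group")
  if (sigmaSubject < 0) stop("sigmaSubject must be >= 0")
  if (sigmaResid <= 0) stop("sigmaResid must be > 0")
  list(nControl = nControl, nCase = nCase, mu = .cellMatrix(mu, "mu"),
       delta = .cellMatrix(delta, "delta"), sigmaSubject = sigmaSubject,
       sigmaResid = sigmaResid, subjectCoding = subjectCoding,
       seed = as.integer(seed))
}

#' Simulate a decidualization time-course dataset
#'
#' For subject s in cell (treatment t, time tau):
#' log igfbp1 = mu[t, tau] + delta[t, tau] * case + b + eps, with
#' b ~ Normal(0, sigmaSubject^2) drawn per (subject, t, tau) stratum under
#' the nested coding (or once per subject under the shared coding) and
#' eps ~ Normal(0, sigmaResid^2).
#'
#' @param params from \code{\link{decidSimParams}}.
#' @return A \code{\link{DecidDataset}} with one measurement per
#'   (subject, treatment, time) cell.
#' @export
simulateDecid <- function(params) {
  .withSeed(params$seed, {
    subjects <- c(sprintf("ctrl_%02d", seq_len(params$nControl)),
                  sprintf("case_%02d", seq_len(params$nCase)))
    isCase <- rep(c(0, 1), c(params$nControl, params$nCase))
    grid <- expand.grid(subject = seq_along(subjects),
                        time_h = .timeLevels, treatment = .treatmentLevels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- params$mu[cbind(grid$treatment, as.character(grid$time_h))]
    delta <- params$delta[cbind(grid$treatment, as.character(grid$time_h))]
    if (params$subjectCoding == "nested") {
      b <- rnorm(nrow(grid), 0, params$sigmaSubject)
    } else {
      bSubj <- rnorm(length(subjects), 0, params$sigmaSubject)
      b <- bSubj[grid$subject]
    }
    eps <- rnorm(nrow(grid), 0, params$sigmaResid)
    logY <- mu + delta * isCase[grid$subject] + b + eps
    DecidDataset(data.frame(
      subject_id = subjects[grid$subject],
      group = .groupLevels[1 + isCase[grid$subject]],
      treatment = grid$treatment, time_h = grid$time_h,
      igfbp1 = exp(logY), stringsAsFactors = FALSE))
  })
}

.leafGates <- c("CD66b_pos", "Mono", "Tcell", "Bcell", "uNK", "otherCD66bNeg",
                "Epith", "Endo", "SFC", "otherDoubleNeg")

.defaultBaseComposition <- function() {
  ## CD45+ ~ 98% of viable cells, granulocytes ~ 55% of CD45+, T cells the
  ## largest CD66b- subset followed by uNK, monocytes and B cells; CD45-
  ## ~ 2%, mostly double-negative cells of which SFCs are a subset
  c(CD66b_pos = 0.540, Mono = 0.066, Tcell = 0.198, Bcell = 0.022,
    uNK = 0.088, otherCD66bNeg = 0.066, Epith = 0.003, Endo = 0.002,
    SFC = 0.008, otherDoubleNeg = 0.007)
}

#' Parameters of the cytometry composition generator
#'
#' @param nControl,nCase subjects per group; defaults 14 and 8.
#' @param totalCellsMean Poisson mean of viable cells per sample;
#'   default 20000.
#' @param baseComposition probability vector over the ten leaf gates
#'   (\code{CD66b_pos}, \code{Mono}, \code{Tcell}, \code{Bcell},
#'   \code{uNK}, \code{otherCD66bNeg}, \code{Epith}, \code{Endo},
#'   \code{SFC}, \code{otherDoubleNeg}); must sum to 1.
#' @param unkCaseMultiplier factor (> 0) applied to the uNK leaf
#'   proportion in cases before renormalization; default 0.5 (uNK
#'   deficit). Set to 1 for a null generator.
#' @param concentration Dirichlet concentration scalar (> 0) controlling
#'   between-sample overdispersion; default 50.
#' @param dayEffect,todEffect named numeric log-odds shifts per leaf gate
#'   applied for collection_day = day1_2 and collection_time = overnight;
#'   default none.
#' @param samplesPerSubject repeated collections (cycles) per subject;
#'   default 1.
#' @param seed integer seed.
#' @return Validated parameter list for \code{\link{simulateCytometry}}.
#' @export
cytoSimParams <- function(nControl = 14L, nCase = 8L, totalCellsMean = 20000,
                          baseComposition = .defaultBaseComposition(),
                          unkCaseMultiplier = 0.5, concentration = 50,
                          dayEffect = NULL, todEffect = NULL,
                          samplesPerSubject = 1L, seed = 1L) {
  nControl <- as.integer(nControl); nCase <- as.integer(nCase)
  if (nControl < 2L || nCase < 2L) stop("need at least 2 subjects per group")
  if (!all(.leafGates %in% names(baseComposition)))
    stop("baseComposition must be named over the leaf gates: ",
         paste(.leafGates, collapse = ", "))
  baseComposition <- baseComposition[.leafGates]
  if (any(baseComposition < 0) || abs(sum(baseComposition) - 1) > 1e-6)
    stop("baseComposition must be non-negative and sum to 1")
  if (unkCaseMultiplier <= 0) stop("unkCaseMultiplier must be > 0")
  if (concentration <= 0) stop("concentration must be > 0")
  asEffect <- function(e) {
    out <- setNames(numeric(length(.leafGates)), .leafGates)
    if (!is.null(e)) {
      bad <- setdiff(names(e), .leafGates)
      if (length(bad)) stop("unknown leaf gate(s): ", paste(bad, collapse = ", "))
      out[names(e)] <- e
    }
    out
  }
  list(nControl = nControl, nCase = nCase, totalCellsMean = totalCellsMean,
       baseComposition = baseComposition,
       unkCaseMultiplier = unkCaseMultiplier, concentration = concentration,
       dayEffect = asEffect(dayEffect), todEffect = asEffect(todEffect),
       samplesPerSubject = as.integer(samplesPerSubject),
       seed = as.integer(seed))
}

#' Simulate a cytometry gate-count dataset
#'
#' Per sample, the expected leaf composition is the base composition with
#' the case uNK proportion scaled by \code{unkCaseMultiplier} and
#' collection-covariate log-odds shifts applied, renormalized; the
#' realized composition is Dirichlet(concentration x expected) and leaf
#' counts are multinomial given a Poisson total. Internal gates are sums
#' of their leaves, so every gate-tree invariant holds by construction.
#'
#' @param params from \code{\link{cytoSimParams}}.
#' @return A \code{\link{CytometryExperiment}}.
#' @export
simulateCytometry <- function(params) {
  .withSeed(params$seed, {
    nSubj <- params$nControl + params$nCase
    subjects <- c(sprintf("ctrl_%02d", seq_len(params$nControl)),
                  sprintf("case_%02d", seq_len(params$nCase)))
    isCase <- rep(c(FALSE, TRUE), c(params$nControl, params$nCase))
    rows <- vector("list", nSubj * params$samplesPerSubject)
    k <- 0L
    for (s in seq_len(nSubj)) {
      for (cyc in seq_len(params$samplesPerSubject)) {
        k <- k + 1L
        day <- sample(.dayLevels, 1L)
        tod <- sample(.todLevels, 1L)
        pi <- params$baseComposition
        if (isCase[s]) pi["uNK"] <- pi["uNK"] * params$unkCaseMultiplier
        w <- log(pi) +
          (day == "day1_2") * params$dayEffect +
          (tod == "overnight") * params$todEffect
        pi <- exp(w - max(w)); pi <- pi / sum(pi)
        g <- rgamma(length(pi), shape = params$concentration * pi)
        if (sum(g) <= 0) g <- pi
        p <- g / sum(g)
        total <- rpois(1L, params$totalCellsMean)
        cnt <- setNames(as.numeric(rmultinom(1L, total, p)), .leafGates)
        rows[[k]] <- data.frame(
          subject_id = subjects[s], group = .groupLevels[1 + isCase[s]],
          cycle_id = sprintf("%s_cyc%d", subjects[s], cyc),
          collection_day = day, collection_time = tod,
          CD45pos = cnt[["CD66b_pos"]] + cnt[["Mono"]] + cnt[["Tcell"]] +
            cnt[["Bcell"]] + cnt[["uNK"]] + cnt[["otherCD66bNeg"]],
          CD66b_pos = cnt[["CD66b_pos"]],
          CD66b_neg = cnt[["Mono"]] + cnt[["Tcell"]] + cnt[["Bcell"]] +
            cnt[["uNK"]] + cnt[["otherCD66bNeg"]],
          Mono = cnt[["Mono"]], Tcell = cnt[["Tcell"]],
          Bcell = cnt[["Bcell"]], uNK = cnt[["uNK"]],
          CD45neg = cnt[["Epith"]] + cnt[["Endo"]] + cnt[["SFC"]] +
            cnt[["otherDoubleNeg"]],
          Epith = cnt[["Epith"]], Endo = cnt[["Endo"]],
          DoubleNeg = cnt[["SFC"]] + cnt[["otherDoubleNeg"]],
          SFC = cnt[["SFC"]], stringsAsFactors = FALSE)
      }
    }
    CytometryExperiment(do.call(rbind, rows))
  })
}

#' Simulate a qPCR Ct table
#'
#' Target Ct = reference Ct + \code{baseDeltaCt} + \code{deltaCtShift} for
#' cases + Normal(0, \code{noiseSd}) noise; the reference gene Ct is held
#' at \code{ctReference}. A positive shift means lower target expression
#' in cases (fold change 2^-shift relative to controls).
#'
#' @param nPerGroup subjects per group; default 7.
#' @param deltaCtShift additive case shift of the target delta-Ct;
#'   default 2 (four-fold reduction).
#' @param noiseSd SD of the per-well delta-Ct noise; default 0.3.
#' @param baseDeltaCt control-group delta-Ct; default 8.
#' @param conditionEffect additive delta-Ct effect of the cAMP condition;
#'   default 0.
#' @param replicates technical replicates per sample; default 1.
#' @param ctReference constant reference-gene Ct; default 20.
#' @param seed integer seed.
#' @return A \code{\link{QPCRTable}} with one sample per
#'   (subject, condition).
#' @export
simulateQPCR <- function(nPerGroup = 7L, deltaCtShift = 2, noiseSd = 0.3,
                         baseDeltaCt = 8, conditionEffect = 0,
                         replicates = 1L, ctReference = 20, seed = 1L) {
  nPerGroup <- as.integer(nPerGroup)
  if (nPerGroup < 2L) stop("need at least 2 subjects per group")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  .withSeed(seed, {
    subjects <- c(sprintf("ctrl_%02d", seq_len(nPerGroup)),
                  sprintf("case_%02d", seq_len(nPerGroup)))
    isCase <- rep(c(0, 1), each = nPerGroup)
    grid <- expand.grid(rep = seq_len(as.integer(replicates)),
                        condition = .conditionLevels,
                        subject = seq_along(subjects),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    dct <- baseDeltaCt + deltaCtShift * isCase[grid$subject] +
      conditionEffect * (grid$condition == "cAMP") +
      rnorm(nrow(grid), 0, noiseSd)
    QPCRTable(data.frame(
      sample_id = sprintf("%s_%s", subjects[grid$subject], grid$condition),
      subject_id = subjects[grid$subject],
      group = .groupLevels[1 + isCase[grid$subject]],
      condition = grid$condition, replicate = grid$rep,
      ct_target = ctReference + dct, ct_reference = ctReference,
      stringsAsFactors = FALSE))
  })
}
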