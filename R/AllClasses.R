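## S4 containers for the study data and fitted results.
## All tabular slots are validated data.frames; validity methods enforce the
## invariants of the data model so malformed rows can never reach a fit.

.checkEnum <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    sprintf("%s contains unknown level(s): %s (allowed: %s)", what,
            paste(unique(x[bad]), collapse = ", "),
            paste(levels, collapse = ", "))
  } else NULL
}

## ---------------------------------------------------------------------------
## CytometryExperiment

#' @title Per-sample viable cell counts on the fixed gating tree
#'
#' @description One row per collected sample; columns \code{subject_id},
#' \code{group}, \code{cycle_id}, \code{collection_day},
#' \code{collection_time} and one count column per gate in
#' \code{\link{cytometryGates}}. Gate counts may be \code{NA} (population
#' not acquired for that sample); present counts must be non-negative
#' integers and respect the gate tree:
#' CD66b+ + CD66b- <= CD45+, Mono + T + B + uNK <= CD66b-,
#' Epith + Endo + DoubleNeg <= CD45-, SFC <= DoubleNeg.
#'
#' @slot samples validated data.frame as described above.
#' @seealso \code{\link{readCytometry}}, \code{\link{simulateCytometry}},
#'   \code{\link{normalizeSubsets}}
#' @export
setClass("CytometryExperiment", slots = c(samples = "data.frame"))

.cytoCovariates <- c("subject_id", "group", "cycle_id", "collection_day",
                     "collection_time")

.validateCytoRow <- function(row) {
  msgs <- character()
  cnt <- function(g) {
    v <- row[[g]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  for (g in cytometryGates()) {
    v <- cnt(g)
    if (!is.na(v) && (v < 0 || abs(v - round(v)) > 1e-8))
      msgs <- c(msgs, sprintf("gate %s: count %s is not a non-negative integer",
                              g, format(v)))
  }
  sumOk <- function(children, parent) {
    p <- cnt(parent)
    if (is.na(p)) return(NULL)
    s <- sum(vapply(children, cnt, numeric(1)), na.rm = TRUE)
    if (s > p + 1e-8)
      sprintf("child gates {%s} sum to %s > parent %s = %s",
              paste(children, collapse = "+"), format(s), parent, format(p))
    else NULL
  }
  msgs <- c(msgs,
            sumOk(c("CD66b_pos", "CD66b_neg"), "CD45pos"),
            sumOk(c("Mono", "Tcell", "Bcell", "uNK"), "CD66b_neg"),
            sumOk(c("Epith", "Endo", "DoubleNeg"), "CD45neg"),
            sumOk("SFC", "DoubleNeg"))
  msgs
}

setValidity("CytometryExperiment", function(object) {
  df <- object@samples
  need <- c(.cytoCovariates, cytometryGates())
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  msgs <- .checkEnum(df$group, .groupLevels, "group")
  msgs <- c(msgs, .checkEnum(df$collection_day, .dayLevels, "collection_day"),
            .checkEnum(df$collection_time, .todLevels, "collection_time"))
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      rowMsgs <- .validateCytoRow(df[i, ])
      if (length(rowMsgs))
        msgs <- c(msgs, sprintf("row %d: %s", i, rowMsgs))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a CytometryExperiment
#'
#' @param samples data.frame with covariate and gate-count columns (see the
#'   class description). Gate columns absent from \code{samples} are added
#'   as all-\code{NA}.
#' @return A validated \code{CytometryExperiment}.
#' @export
#' @examples
#' df <- data.frame(subject_id = "s1", group = "control", cycle_id = "c1",
#'                  collection_day = "day0", collection_time = "evening",
#'                  CD45pos = 1000, CD66b_pos = 600, CD66b_neg = 400,
#'                  Mono = 100, Tcell = 150, Bcell = 30, uNK = 50,
#'                  CD45neg = 20, Epith = 5, Endo = 3, DoubleNeg = 10, SFC = 4)
#' CytometryExperiment(df)
CytometryExperiment <- function(samples) {
  samples <- as.data.frame(samples)
  for (g in setdiff(cytometryGates(), names(samples)))
    samples[[g]] <- NA_real_
  for (col in c("subject_id", "cycle_id"))
    samples[[col]] <- as.character(samples[[col]])
  samples <- samples[, c(.cytoCovariates, cytometryGates()), drop = FALSE]
  rownames(samples) <- NULL
  new("CytometryExperiment", samples = samples)
}

## ---------------------------------------------------------------------------
## DecidDataset

#' @title Protein-normalized IGFBP-1 decidualization measurements
#'
#' @description One row per (subject, treatment, time) cell of the
#' decidualization assay: \code{subject_id}, \code{group}, \code{treatment}
#' (cAMP; PBS vehicle for cAMP; ethanol vehicle; cAMP+MPA+E2),
#' \code{time_h} (6, 24, 48) and \code{igfbp1}, the IGFBP-1 ELISA readout
#' normalized to cell-lysate protein. Values must be strictly positive so
#' the log transform of the hierarchical model is defined, and the
#' (subject, treatment, time) key must be unique.
#'
#' @slot measurements validated data.frame as described above.
#' @seealso \code{\link{readDecid}}, \code{\link{simulateDecid}},
#'   \code{\link{buildHierarchy}}
#' @export
setClass("DecidDataset", slots = c(measurements = "data.frame"))

setValidity("DecidDataset", function(object) {
  df <- object@measurements
  need <- c("subject_id", "group", "treatment", "time_h", "igfbp1")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  msgs <- c(.checkEnum(df$group, .groupLevels, "group"),
            .checkEnum(df$treatment, .treatmentLevels, "treatment"),
            .checkEnum(df$time_h, .timeLevels, "time_h"))
  bad <- which(!is.finite(df$igfbp1) | df$igfbp1 <= 0)
  if (length(bad))
    msgs <- c(msgs, sprintf(
      "row %d: igfbp1 must be a positive finite number (log transform undefined)",
      bad))
  key <- paste(df$subject_id, df$treatment, df$time_h, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup))
    msgs <- c(msgs, sprintf("duplicate (subject, treatment, time) key: %s",
                            unique(dup)))
  grpBySubj <- tapply(as.character(df$group), df$subject_id,
                      function(g) length(unique(g)))
  if (any(grpBySubj > 1))
    msgs <- c(msgs, sprintf("subject %s assigned to more than one group",
                            names(grpBySubj)[grpBySubj > 1]))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a DecidDataset
#'
#' @param measurements data.frame with columns \code{subject_id},
#'   \code{group}, \code{treatment}, \code{time_h}, \code{igfbp1}.
#' @return A validated \code{DecidDataset}.
#' @export
DecidDataset <- function(measurements) {
  measurements <- as.data.frame(measurements)
  measurements$subject_id <- as.character(measurements$subject_id)
  measurements$group <- as.character(measurements$group)
  measurements$treatment <- as.character(measurements$treatment)
  measurements$time_h <- as.integer(measurements$time_h)
  measurements$igfbp1 <- as.numeric(measurements$igfbp1)
  keep <- c("subject_id", "group", "treatment", "time_h", "igfbp1")
  measurements <- measurements[, intersect(c(keep, names(measurements)),
                                           names(measurements)), drop = FALSE]
  rownames(measurements) <- NULL
  new("DecidDataset", measurements = measurements)
}

## ---------------------------------------------------------------------------
## QPCRTable

#' @title qPCR Ct records for a target and a reference gene
#'
#' @description One row per well: \code{sample_id}, \code{subject_id},
#' \code{group}, \code{condition} (vehicle or cAMP), \code{replicate},
#' \code{ct_target}, \code{ct_reference}. Ct values must be finite and all
#' replicates of a sample must share the same (subject, group, condition).
#'
#' @slot wells validated data.frame as described above.
#' @seealso \code{\link{readQPCR}}, \code{\link{simulateQPCR}},
#'   \code{\link{deltaDeltaCt}}
#' @export
setClass("QPCRTable", slots = c(wells = "data.frame"))

setValidity("QPCRTable", function(object) {
  df <- object@wells
  need <- c("sample_id", "subject_id", "group", "condition", "replicate",
            "ct_target", "ct_reference")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  msgs <- c(.checkEnum(df$group, .groupLevels, "group"),
            .checkEnum(df$condition, .conditionLevels, "condition"))
  ## NA marks a missing well (excluded with a warning downstream);
  ## non-finite numbers are rejected outright
  badT <- which(!is.na(df$ct_target) & !is.finite(df$ct_target))
  if (length(badT)) msgs <- c(msgs, sprintf("row %d: ct_target not finite", badT))
  badR <- which(!is.na(df$ct_reference) & !is.finite(df$ct_reference))
  if (length(badR))
    msgs <- c(msgs, sprintf("row %d: ct_reference not finite", badR))
  if (nrow(df)) {
    meta <- tapply(paste(df$subject_id, df$group, df$condition, sep = "|"),
                   df$sample_id, function(m) length(unique(m)))
    if (any(meta > 1))
      msgs <- c(msgs, sprintf(
        "sample %s: replicates disagree on (subject, group, condition)",
        names(meta)[meta > 1]))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a QPCRTable
#'
#' @param wells data.frame of per-well Ct records (see class description).
#' @return A validated \code{QPCRTable}.
#' @export
QPCRTable <- function(wells) {
  wells <- as.data.frame(wells)
  for (col in c("sample_id", "subject_id", "group", "condition"))
    wells[[col]] <- as.character(wells[[col]])
  wells$replicate <- as.integer(wells$replicate)
  wells$ct_target <- as.numeric(wells$ct_target)
  wells$ct_reference <- as.numeric(wells$ct_reference)
  keep <- c("sample_id", "subject_id", "group", "condition", "replicate",
            "ct_target", "ct_reference")
  wells <- wells[, keep, drop = FALSE]
  rownames(wells) <- NULL
  new("QPCRTable", wells = wells)
}

## ---------------------------------------------------------------------------
## RunConfig

#' @title Run configuration: seed, sampler settings, priors, transform
#'
#' @description Bundles everything that parameterizes a pipeline run:
#' the random seed, Gibbs sampler settings (chains, iterations, burn-in,
#' thinning), prior hyperparameters (Normal SD for cell means and group
#' effects; half-Normal scale for the SD components), the cytometry
#' fraction transform, and the output directory.
#'
#' @slot seed integer random seed.
#' @slot chains number of MCMC chains (>= 1).
#' @slot iterations total iterations per chain (> burnin).
#' @slot burnin burn-in iterations discarded per chain (>= 0).
#' @slot thin thinning interval (>= 1).
#' @slot priorFixedSd prior SD of cell means and group effects (log scale).
#' @slot priorSdScale half-Normal scale of the SD components.
#' @slot transform cytometry transform: none, log or arcsine_sqrt.
#' @slot outDir output directory for pipeline stages.
#' @export
setClass("RunConfig",
         slots = c(seed = "integer", chains = "integer", iterations = "integer",
                   burnin = "integer", thin = "integer",
                   priorFixedSd = "numeric", priorSdScale = "numeric",
                   transform = "character", outDir = "character"))

setValidity("RunConfig", function(object) {
  msgs <- character()
  if (object@chains < 1L) msgs <- c(msgs, "chains must be >= 1")
  if (object@burnin < 0L) msgs <- c(msgs, "burnin must be >= 0")
  if (object@iterations <= object@burnin)
    msgs <- c(msgs, "iterations must exceed burnin")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  if (!is.na(object@priorFixedSd) && object@priorFixedSd <= 0)
    msgs <- c(msgs, "priorFixedSd must be positive (NA/Inf for flat)")
  if (object@priorSdScale <= 0) msgs <- c(msgs, "priorSdScale must be positive")
  if (!(object@transform %in% c("none", "log", "arcsine_sqrt")))
    msgs <- c(msgs, "transform must be one of none, log, arcsine_sqrt")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a RunConfig
#'
#' @param seed integer random seed.
#' @param chains MCMC chains; default 4.
#' @param iterations total iterations per chain; default 4000.
#' @param burnin discarded iterations per chain; default 2000.
#' @param thin thinning interval; default 1 (no thinning).
#' @param priorFixedSd prior SD of cell-mean and group-effect parameters on
#'   the log scale; default 10 (weakly informative for log-scale data).
#' @param priorSdScale half-Normal scale of the subject and residual SDs;
#'   default 5.
#' @param transform cytometry fraction transform; default \code{"none"}.
#' @param outDir output directory; default \code{"decidlab-out"}.
#' @return A validated \code{RunConfig}.
#' @export
#' @examples
#' RunConfig(seed = 1)
RunConfig <- function(seed = 1L, chains = 4L, iterations = 4000L,
                      burnin = 2000L, thin = 1L, priorFixedSd = 10,
                      priorSdScale = 5, transform = "none",
                      outDir = "decidlab-out") {
  new("RunConfig", seed = as.integer(seed), chains = as.integer(chains),
      iterations = as.integer(iterations), burnin = as.integer(burnin),
      thin = as.integer(thin), priorFixedSd = as.numeric(priorFixedSd),
      priorSdScale = as.numeric(priorSdScale),
      transform = as.character(transform), outDir = as.character(outDir))
}

## ---------------------------------------------------------------------------
## Fit containers (constructed by the fitting functions, not by users)

#' @title REML fit of a random-intercept mixed model for one population
#'
#' @description Returned by \code{\link{fitLMM}}. Holds the fixed-effect
#' table (estimate, SE, t statistic, p-value), the REML variance
#' components, the group-effect test, and bookkeeping (transform, sample
#' and subject counts, restricted log-likelihood).
#'
#' @slot population population name (or "response").
#' @slot transform transform applied to the response.
#' @slot coefficients data.frame: estimate, se, statistic, p per fixed effect.
#' @slot varComp named numeric: subject (optionally cycle) and residual
#'   variances.
#' @slot groupTest named numeric: estimate, se, statistic, df, p for the
#'   group effect.
#' @slot nSamples,nSubjects integer counts.
#' @slot logRestrictedLik maximized restricted log-likelihood.
#' @export
setClass("MixedModelFit",
         slots = c(population = "character", transform = "character",
                   coefficients = "data.frame", varComp = "numeric",
                   groupTest = "numeric", nSamples = "integer",
                   nSubjects = "integer", logRestrictedLik = "numeric"))

setValidity("MixedModelFit", function(object) {
  msgs <- character()
  if (any(object@varComp < -1e-8)) msgs <- c(msgs, "variances must be >= 0")
  se <- object@coefficients$se
  if (length(se) && any(is.finite(se) & se <= 0))
    msgs <- c(msgs, "standard errors must be positive when estimable")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @title Posterior sample from the hierarchical decidualization model
#'
#' @description Returned by \code{\link{fitHierarchical}}. Draws are stored
#' as an iterations x chains x parameters array (after burn-in and
#' thinning). Cell-level group effects are summarized with posterior mean,
#' SD, central 95\% credible interval and the two tail probabilities
#' Pr(delta >= 0) and Pr(delta <= 0); split-R-hat and effective sample
#' size are reported for every parameter.
#'
#' @slot draws numeric array, kept-iterations x chains x parameters.
#' @slot cells data.frame mapping cell index to (treatment, time_h).
#' @slot summary per-cell data.frame of group-effect summaries.
#' @slot diagnostics data.frame: parameter, rhat, ess.
#' @slot converged TRUE if all R-hat <= threshold.
#' @slot rhatThreshold the threshold used (default 1.05).
#' @slot structure the design structure the model was fitted to.
#' @slot config the \code{RunConfig} used.
#' @slot model list of fixed/prior settings actually used.
#' @export
setClass("HierarchicalFit",
         slots = c(draws = "array", cells = "data.frame",
                   summary = "data.frame", diagnostics = "data.frame",
                   converged = "logical", rhatThreshold = "numeric",
                   structure = "list", config = "RunConfig", model = "list"))

setValidity("HierarchicalFit", function(object) {
  msgs <- character()
  if (length(dim(object@draws)) != 3L)
    msgs <- c(msgs, "draws must be an iterations x chains x parameters array")
  s <- object@summary
  if (nrow(s) && any(s$pr_ge_0 + s$pr_le_0 < 1 - 1e-12))
    msgs <- c(msgs, "tail probabilities must satisfy Pr(>=0) + Pr(<=0) >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @title Comparative Ct (delta-delta-Ct) fold-change result
#'
#' @description Returned by \code{\link{deltaDeltaCt}}. Per-sample
#' delta-Ct, delta-delta-Ct against the calibrator mean and fold change
#' 2^(-ddCt); per (group, condition) mean delta-Ct; and, per condition, a
#' Mann-Whitney comparison of case vs control fold changes.
#'
#' @slot samples per-sample data.frame (sample_id, subject_id, group,
#'   condition, delta_ct, delta_delta_ct, fold_change).
#' @slot groupMeans per-(group, condition) mean delta-Ct.
#' @slot tests per-condition data.frame: U statistic, two-sided p, method.
#' @slot calibrator list(group, condition) defining the baseline.
#' @export
setClass("FoldChangeResult",
         slots = c(samples = "data.frame", groupMeans = "data.frame",
                   tests = "data.frame", calibrator = "list"))

setValidity("FoldChangeResult", function(object) {
  if (nrow(object@samples) && any(object@samples$fold_change <= 0))
    "fold changes must be positive" else TRUE
})

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "CytometryExperiment", function(object) {
  df <- object@samples
  cat(sprintf("CytometryExperiment: %d sample(s), %d subject(s)\n", nrow(df),
              length(unique(df$subject_id))))
  if (nrow(df)) {
    tab <- table(factor(df$group, levels = .groupLevels))
    cat(sprintf("  samples by group: control=%d, endometriosis=%d\n",
                tab[["control"]], tab[["endometriosis"]]))
    absent <- vapply(cytometryGates(), function(g) sum(is.na(df[[g]])),
                     integer(1))
    if (any(absent > 0))
      cat("  absent counts:",
          paste(sprintf("%s(%d)", names(absent)[absent > 0],
                        absent[absent > 0]), collapse = " "), "\n")
  }
})

setMethod("show", "DecidDataset", function(object) {
  df <- object@measurements
  cat(sprintf(
    "DecidDataset: %d measurement(s), %d subject(s), %d treatment(s) x %d time(s)\n",
    nrow(df), length(unique(df$subject_id)), length(unique(df$treatment)),
    length(unique(df$time_h))))
})

setMethod("show", "QPCRTable", function(object) {
  df <- object@wells
  cat(sprintf("QPCRTable: %d well(s), %d sample(s), %d subject(s)\n",
              nrow(df), length(unique(df$sample_id)),
              length(unique(df$subject_id))))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: seed=%d, %d chain(s) x %d iter (burnin %d, thin %d)\n",
    object@seed, object@chains, object@iterations, object@burnin, object@thin))
  cat(sprintf("  priors: fixed ~ Normal(0, %s^2), SDs ~ half-Normal(%s)\n",
              format(object@priorFixedSd), format(object@priorSdScale)))
  cat(sprintf("  cytometry transform: %s; outDir: %s\n", object@transform,
              object@outDir))
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("MixedModelFit for population '%s' (transform: %s)\n",
              object@population, object@transform))
  cat(sprintf("  %d samples from %d subjects\n", object@nSamples,
              object@nSubjects))
  vc <- object@varComp
  cat("  variance components:",
      paste(sprintf("%s=%.4g", names(vc), vc), collapse = ", "), "\n")
  gt <- object@groupTest
  cat(sprintf("  group effect: %.4g (SE %.4g), t=%.3f on df=%.0f, p=%.4g\n",
              gt[["estimate"]], gt[["se"]], gt[["statistic"]], gt[["df"]],
              gt[["p"]]))
})

setMethod("show", "HierarchicalFit", function(object) {
  d <- dim(object@draws)
  cat(sprintf("HierarchicalFit: %d kept draws x %d chain(s), %d parameter(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  converged (all split-Rhat <= %.2f): %s\n",
              object@rhatThreshold, object@converged))
  cat("  group-effect summary (per treatment x time cell):\n")
  print(object@summary, digits = 3, row.names = FALSE)
})

setMethod("show", "FoldChangeResult", function(object) {
  cat(sprintf("FoldChangeResult: %d sample(s); calibrator group=%s, condition=%s\n",
              nrow(object@samples), object@calibrator$group,
              object@calibrator$condition))
  if (nrow(object@tests)) {
    cat("  case vs control fold-change tests:\n")
    print(object@tests, digits = 4, row.names = FALSE)
  }
})

## ---------------------------------------------------------------------------
## accessors

#' Accessors for decidlab containers
#'
#' \code{samples} returns the per-sample table of a
#' \code{CytometryExperiment} or \code{FoldChangeResult};
#' \code{measurements} the table of a \code{DecidDataset}; \code{wells}
#' the well table of a \code{QPCRTable}; \code{gateCounts} the numeric
#' gate-count matrix; \code{varComp}, \code{fixedEffects} and
#' \code{groupTest} the components of a \code{MixedModelFit};
#' \code{posteriorDraws}, \code{cellSummary}, \code{mcmcDiagnostics} and
#' \code{isConverged} the components of a \code{HierarchicalFit}.
#'
#' @param object a decidlab S4 object.
#' @return The corresponding slot, as a data.frame, matrix or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "CytometryExperiment", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("samples", "FoldChangeResult", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setMethod("measurements", "DecidDataset", function(object) object@measurements)

#' @rdname accessors
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))
#' @rdname accessors
#' @export
setMethod("wells", "QPCRTable", function(object) object@wells)

#' @rdname accessors
#' @export
setGeneric("gateCounts", function(object) standardGeneric("gateCounts"))
#' @rdname accessors
#' @export
setMethod("gateCounts", "CytometryExperiment", function(object) {
  m <- as.matrix(object@samples[, cytometryGates(), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
})

#' @rdname accessors
#' @export
setGeneric("varComp", function(object) standardGeneric("varComp"))
#' @rdname accessors
#' @export
setMethod("varComp", "MixedModelFit", function(object) object@varComp)

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setMethod("fixedEffects", "MixedModelFit", function(object) object@coefficients)

#' @rdname accessors
#' @export
setGeneric("groupTest", function(object) standardGeneric("groupTest"))
#' @rdname accessors
#' @export
setMethod("groupTest", "MixedModelFit", function(object) object@groupTest)

#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))
#' @rdname accessors
#' @export
setMethod("posteriorDraws", "HierarchicalFit", function(object) object@draws)

#' @rdname accessors
#' @export
setGeneric("cellSummary", function(object) standardGeneric("cellSummary"))
#' @rdname accessors
#' @export
setMethod("cellSummary", "HierarchicalFit", function(object) object@summary)

#' @rdname accessors
#' @export
setGeneric("mcmcDiagnostics", function(object) standardGeneric("mcmcDiagnostics"))
#' @rdname accessors
#' @export
setMethod("mcmcDiagnostics", "HierarchicalFit",
          function(object) object@diagnostics)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "HierarchicalFit", function(object) object@converged)

#' @rdname accessors
#' @export
setGeneric("foldChangeTests", function(object) standardGeneric("foldChangeTests"))
#' @rdname accessors
#' @export
setMethod("foldChangeTests", "FoldChangeResult", function(object) object@tests)
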