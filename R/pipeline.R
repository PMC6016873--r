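## Pipeline driver: chains simulate -> cytometry -> decid -> qpcr with a
## shared configuration and seed, writing per-stage CSV outputs and one
## reproducibility manifest per output directory.

.dlStop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

.pipelineStages <- c("simulate", "cytometry", "decid", "qpcr")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order. The
#' \code{simulate} stage writes the three input CSVs (cytometry, decid,
#' qPCR) into \code{config@outDir} using the synthetic-data generators
#' seeded from \code{config@seed}; the analysis stages read either those
#' files or the paths supplied in \code{inputs}. Each analysis stage
#' writes its report CSV(s); a JSON manifest (tool version, configuration
#' snapshot, seed, input file digests, per-stage outputs and wall times)
#' is written last. The whole run is deterministic given the seed, except
#' for the manifest timestamps.
#'
#' @param config a \code{\link{RunConfig}}; \code{config@outDir} receives
#'   all outputs.
#' @param stages subset of \code{c("simulate", "cytometry", "decid",
#'   "qpcr")}, or \code{"all"}.
#' @param inputs optional named list of input CSV paths
#'   (\code{cytometry}, \code{decid}, \code{qpcr}) for analysis stages
#'   run without the simulate stage.
#' @param coding,pooledDelta passed to \code{\link{buildHierarchy}} /
#'   \code{\link{fitHierarchical}}.
#' @param decidParams,cytoParams optional generator parameter lists
#'   (defaults: \code{decidSimParams(seed = config@seed)} and
#'   \code{cytoSimParams(seed = config@seed + 1)}).
#' @param qpcrArgs optional list of arguments to
#'   \code{\link{simulateQPCR}} (seed defaults to \code{config@seed + 2}).
#' @param strict if TRUE a non-converged hierarchical fit is an error
#'   (condition class \code{decidlab_convergence_error}) instead of a
#'   warning.
#' @return The manifest, invisibly (also written to
#'   \code{decidlab_manifest.json}).
#' @export
#' @examples
#' cfg <- RunConfig(seed = 1, chains = 2, iterations = 400, burnin = 200,
#'                  outDir = file.path(tempdir(), "decidlab-example"))
#' m <- runPipeline(cfg, stages = c("simulate", "qpcr"))
#' names(m$stages)
runPipeline <- function(config = RunConfig(), stages = "all",
                        inputs = list(), coding = c("nested", "shared"),
                        pooledDelta = FALSE, decidParams = NULL,
                        cytoParams = NULL, qpcrArgs = list(),
                        strict = FALSE) {
  stopifnot(is(config, "RunConfig"))
  coding <- match.arg(coding)
  if (identical(stages, "all")) stages <- .pipelineStages
  unknown <- setdiff(stages, .pipelineStages)
  if (length(unknown))
    .dlStop(paste0("unknown stage name(s): ", paste(unknown, collapse = ", "),
                   " (known: ", paste(.pipelineStages, collapse = ", "), ")"),
            "decidlab_usage_error")
  stages <- .pipelineStages[.pipelineStages %in% stages]
  outDir <- config@outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "decidlab",
                   version = as.character(packageVersion("decidlab")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config@seed, config = configAsList(config),
                   inputs = list(), stages = list())
  paths <- list(cytometry = inputs$cytometry, decid = inputs$decid,
                qpcr = inputs$qpcr)
  timeIt <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    list(result = res, wall = proc.time()[["elapsed"]] - t0)
  }
  needInput <- function(stage, kind) {
    if (is.null(paths[[kind]]))
      .dlStop(sprintf(
        "stage '%s' needs a %s input: supply inputs$%s or run the simulate stage first",
        stage, kind, kind), "decidlab_usage_error")
    if (!file.exists(paths[[kind]]))
      .dlStop(sprintf("input file for stage '%s' not found: %s", stage,
                      paths[[kind]]), "decidlab_usage_error")
    manifest$inputs[[kind]] <<- list(
      path = paths[[kind]],
      md5 = unname(tools::md5sum(paths[[kind]])))
    paths[[kind]]
  }

  for (stage in stages) {
    .dlLog("INFO", "stage %s started", stage)
    st <- switch(stage,
      simulate = timeIt({
        dp <- if (is.null(decidParams))
          decidSimParams(seed = config@seed) else decidParams
        cp <- if (is.null(cytoParams))
          cytoSimParams(seed = config@seed + 1L) else cytoParams
        qa <- qpcrArgs
        if (is.null(qa$seed)) qa$seed <- config@seed + 2L
        fCyto <- file.path(outDir, "cytometry.csv")
        fDecid <- file.path(outDir, "decid.csv")
        fQpcr <- file.path(outDir, "qpcr.csv")
        writeCytometry(simulateCytometry(cp), fCyto)
        writeDecid(simulateDecid(dp), fDecid)
        writeQPCR(do.call(simulateQPCR, qa), fQpcr)
        paths$cytometry <- fCyto
        paths$decid <- fDecid
        paths$qpcr <- fQpcr
        c(cytometry = fCyto, decid = fDecid, qpcr = fQpcr)
      }),
      cytometry = timeIt({
        ex <- readCytometry(needInput("cytometry", "cytometry"))
        fits <- runPopulationScreen(ex, transform = config@transform)
        f <- file.path(outDir, "cytometry_screen.csv")
        write.csv(screenReport(fits), f, row.names = FALSE)
        f
      }),
      decid = timeIt({
        d <- readDecid(needInput("decid", "decid"))
        fit <- fitHierarchical(buildHierarchy(d, coding = coding), config,
                               pooledDelta = pooledDelta)
        if (strict && !isConverged(fit))
          .dlStop("hierarchical fit did not converge (strict mode)",
                  "decidlab_convergence_error")
        fSum <- file.path(outDir, "decid_summary.csv")
        write.csv(cellSummary(fit), fSum, row.names = FALSE)
        fDiag <- file.path(outDir, "decid_diagnostics.csv")
        write.csv(mcmcDiagnostics(fit), fDiag, row.names = FALSE)
        arr <- posteriorDraws(fit)
        flat <- do.call(rbind, lapply(seq_len(dim(arr)[2]), function(k) {
          d0 <- as.data.frame(arr[, k, ])
          d0 <- cbind(chain = k, iteration = seq_len(nrow(d0)), d0)
          d0
        }))
        fDraws <- file.path(outDir, "decid_draws.csv")
        write.csv(flat, fDraws, row.names = FALSE)
        c(summary = fSum, diagnostics = fDiag, draws = fDraws)
      }),
      qpcr = timeIt({
        tab <- readQPCR(needInput("qpcr", "qpcr"))
        fc <- deltaDeltaCt(tab)
        fSmp <- file.path(outDir, "qpcr_fold_changes.csv")
        write.csv(samples(fc), fSmp, row.names = FALSE)
        fTst <- file.path(outDir, "qpcr_tests.csv")
        write.csv(foldChangeTests(fc), fTst, row.names = FALSE)
        c(fold_changes = fSmp, tests = fTst)
      }))
    manifest$stages[[stage]] <- list(outputs = as.list(st$result),
                                     wall_seconds = round(st$wall, 3))
    .dlLog("INFO", "stage %s finished in %.2fs", stage, st$wall)
  }
  jsonlite::write_json(manifest, file.path(outDir, "decidlab_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
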