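## CSV readers/writers and run-configuration file support.
## Dialect: comma-separated, UTF-8, one header row, lowercase snake_case
## column names. Unknown enum levels are rejected, never coerced; rows that
## violate a data-model invariant are reported with their row number and
## never reach the analysis modules.

.dlLog <- function(level, fmt, ...) {
  message(sprintf("[decidlab %s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

.readTable <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("format error in %s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown))
    stop(sprintf("format error in %s: unknown column(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  df
}

#' Read a cytometry gate-count table
#'
#' Expects columns \code{subject_id}, \code{group}, \code{cycle_id},
#' \code{collection_day}, \code{collection_time} and any subset of the gate
#' columns in \code{\link{cytometryGates}}; gates not present in the file
#' (or empty cells) are recorded as absent and excluded per-population
#' downstream. Every row is validated against the gate-tree invariants;
#' violations are reported with their row number.
#'
#' @param path CSV file path.
#' @return A \code{\link{CytometryExperiment}}.
#' @export
readCytometry <- function(path) {
  df <- .readTable(path, required = .cytoCovariates,
                   optional = cytometryGates())
  if (!nrow(df)) .dlLog("WARN", "empty cytometry file (header only): %s", path)
  tryCatch(CytometryExperiment(df),
           error = function(e) stop(sprintf("validation error in %s: %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
}

#' Read a decidualization measurement table
#'
#' Columns: \code{subject_id}, \code{group}, \code{treatment},
#' \code{time_h}, \code{igfbp1}. Duplicate (subject, treatment, time) keys
#' and non-positive IGFBP-1 values are rejected.
#'
#' @param path CSV file path.
#' @return A \code{\link{DecidDataset}}.
#' @export
readDecid <- function(path) {
  df <- .readTable(path, required = c("subject_id", "group", "treatment",
                                      "time_h", "igfbp1"))
  if (!nrow(df)) .dlLog("WARN", "empty decidualization file: %s", path)
  tryCatch(DecidDataset(df),
           error = function(e) stop(sprintf("validation error in %s: %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
}

#' Read a qPCR Ct table
#'
#' Columns: \code{sample_id}, \code{subject_id}, \code{group},
#' \code{condition}, \code{replicate}, \code{ct_target},
#' \code{ct_reference}.
#'
#' @param path CSV file path.
#' @return A \code{\link{QPCRTable}}.
#' @export
readQPCR <- function(path) {
  df <- .readTable(path, required = c("sample_id", "subject_id", "group",
                                      "condition", "replicate", "ct_target",
                                      "ct_reference"))
  if (!nrow(df)) .dlLog("WARN", "empty qPCR file: %s", path)
  tryCatch(QPCRTable(df),
           error = function(e) stop(sprintf("validation error in %s: %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
}

#' Write decidlab tables to CSV
#'
#' Writers for the three data containers; \code{write*} output is readable
#' by the corresponding \code{read*} function field-for-field (absent gate
#' counts round-trip as empty cells).
#'
#' @param object the container to write.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeCytometry <- function(object, path) {
  stopifnot(is(object, "CytometryExperiment"))
  write.csv(samples(object), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writers
#' @export
writeDecid <- function(object, path) {
  stopifnot(is(object, "DecidDataset"))
  write.csv(measurements(object), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writers
#' @export
writeQPCR <- function(object, path) {
  stopifnot(is(object, "QPCRTable"))
  write.csv(wells(object), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a run configuration from a YAML key-value file
#'
#' Recognized keys (all optional, defaults from \code{\link{RunConfig}}):
#' \code{seed}, \code{chains}, \code{iterations}, \code{burnin},
#' \code{thin}, \code{prior_fixed_sd}, \code{prior_sd_scale},
#' \code{transform}, \code{out_dir}. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A validated \code{\link{RunConfig}}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(seed = "seed", chains = "chains", iterations = "iterations",
             burnin = "burnin", thin = "thin",
             prior_fixed_sd = "priorFixedSd",
             prior_sd_scale = "priorSdScale", transform = "transform",
             out_dir = "outDir")
  unknown <- setdiff(names(raw), names(known))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- stats::setNames(raw, known[names(raw)])
  do.call(RunConfig, args)
}

#' Serialize a RunConfig to a plain list (for manifests)
#' @param config a \code{RunConfig}.
#' @return Named list of the configuration values.
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "RunConfig"))
  list(seed = config@seed, chains = config@chains,
       iterations = config@iterations, burnin = config@burnin,
       thin = config@thin, prior_fixed_sd = config@priorFixedSd,
       prior_sd_scale = config@priorSdScale, transform = config@transform,
       out_dir = config@outDir)
}
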