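## Parent-gate normalization and the per-population group screen.

#' Normalize gate counts to parent-gate fractions
#'
#' Each population count is divided by its designated parent count
#' (\code{\link{cytometryPopulations}}): CD66b+/- by CD45+; monocytes,
#' T cells, B cells and uNK cells by CD45+CD66b-; epithelial, endothelial,
#' double-negative and SFC by CD45-. Fractions whose denominator is zero
#' or absent are recorded as \code{NA} (absent, not 0) with a logged
#' warning, and are excluded per-population downstream.
#'
#' @param experiment a \code{\link{CytometryExperiment}}.
#' @return data.frame with the carried covariates (\code{subject_id},
#'   \code{group}, \code{cycle_id}, \code{collection_day},
#'   \code{collection_time}) and one \code{fraction_<population>} column
#'   per population.
#' @export
#' @examples
#' ex <- simulateCytometry(cytoSimParams(seed = 2))
#' head(normalizeSubsets(ex))
normalizeSubsets <- function(experiment) {
  stopifnot(is(experiment, "CytometryExperiment"))
  df <- samples(experiment)
  pops <- cytometryPopulations()
  out <- df[, .cytoCovariates, drop = FALSE]
  for (i in seq_len(nrow(pops))) {
    child <- df[[pops$population[i]]]
    parent <- df[[pops$parent[i]]]
    bad <- is.na(parent) | parent <= 0
    if (any(bad & !is.na(child)))
      .dlLog("WARN",
             "fraction_%s: %d sample(s) with zero/absent %s denominator marked absent",
             pops$population[i], sum(bad & !is.na(child)), pops$parent[i])
    frac <- ifelse(bad, NA_real_, child / parent)
    out[[paste0("fraction_", pops$population[i])]] <- frac
  }
  out
}

#' Transform a population fraction
#'
#' \code{"log"} is the natural logarithm (defined for fractions > 0);
#' \code{"arcsine_sqrt"} is arcsin(sqrt(x)), the classical
#' variance-stabilizing transform for proportions; \code{"none"} returns
#' the fraction unchanged.
#'
#' @param x numeric vector of fractions in [0, 1] (NA allowed).
#' @param method one of \code{"none"}, \code{"log"},
#'   \code{"arcsine_sqrt"}.
#' @return Transformed vector of the same length.
#' @export
#' @examples
#' transformFraction(0.25, "arcsine_sqrt")  # pi/6
#' transformFraction(exp(-1), "log")        # -1
transformFraction <- function(x, method = c("none", "log", "arcsine_sqrt")) {
  method <- match.arg(method)
  ok <- is.na(x) | (x >= 0 & x <= 1)
  if (!all(ok)) stop("fractions must lie in [0, 1]")
  switch(method,
         none = x,
         log = {
           if (any(!is.na(x) & x == 0))
             stop(paste("log transform undefined at 0;",
                        "use arcsine_sqrt or add a documented offset"))
           log(x)
         },
         arcsine_sqrt = asin(sqrt(x)))
}

#' Screen every cell population for a group association
#'
#' For each population: normalize to its parent gate, apply the chosen
#' transform, and fit the random-intercept mixed model
#' (\code{\link{fitLMM}}) with group plus the collection covariates
#' (day of cycle the collection started, time of day). Samples whose
#' fraction is absent are excluded from that population only. Analyses are
#' carried out separately per population; no multiple-testing correction
#' is applied to the reported p-values, but \code{\link{screenReport}}
#' adds a Bonferroni column for transparency.
#'
#' @param experiment a \code{\link{CytometryExperiment}}.
#' @param transform fraction transform, as in
#'   \code{\link{transformFraction}}.
#' @param populations populations to screen; default all ten.
#' @param randomEffects passed to \code{\link{fitLMM}}.
#' @param covariates covariate columns to adjust for; default collection
#'   day and time of day.
#' @return Named list of \code{\link{MixedModelFit}} objects, one per
#'   population successfully fitted.
#' @export
#' @examples
#' ex <- simulateCytometry(cytoSimParams(seed = 5))
#' fits <- runPopulationScreen(ex, populations = c("uNK", "Tcell"))
#' screenReport(fits)
runPopulationScreen <- function(experiment,
                                transform = c("none", "log", "arcsine_sqrt"),
                                populations = cytometryPopulations()$population,
                                randomEffects = c("subject", "subject_cycle"),
                                covariates = c("collection_day",
                                               "collection_time")) {
  transform <- match.arg(transform)
  randomEffects <- match.arg(randomEffects)
  bad <- setdiff(populations, cytometryPopulations()$population)
  if (length(bad))
    stop("unknown population(s): ", paste(bad, collapse = ", "))
  fracs <- normalizeSubsets(experiment)
  fits <- list()
  for (pop in populations) {
    d <- fracs
    d$response <- transformFraction(d[[paste0("fraction_", pop)]], transform)
    d <- d[!is.na(d$response), , drop = FALSE]
    fit <- tryCatch(
      fitLMM(d, covariates = covariates, randomEffects = randomEffects,
             population = pop, transform = transform),
      error = function(e) {
        .dlLog("WARN", "population %s not fitted: %s", pop,
               conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) fits[[pop]] <- fit
  }
  fits
}

#' Tabulate a population screen
#'
#' @param fits list of \code{\link{MixedModelFit}} from
#'   \code{\link{runPopulationScreen}}.
#' @return data.frame with one row per population: sample/subject counts,
#'   group-effect estimate, SE, t statistic, df, p-value, a Bonferroni
#'   column (p times number of populations, capped at 1), and the variance
#'   components.
#' @export
screenReport <- function(fits) {
  if (!length(fits))
    return(data.frame(population = character(), transform = character(),
                      n_samples = integer(), n_subjects = integer(),
                      estimate = numeric(), se = numeric(),
                      statistic = numeric(), df = numeric(), p = numeric(),
                      p_bonferroni = numeric(), var_subject = numeric(),
                      var_residual = numeric()))
  rows <- lapply(fits, function(f) {
    gt <- groupTest(f)
    vc <- varComp(f)
    data.frame(population = f@population, transform = f@transform,
               n_samples = f@nSamples, n_subjects = f@nSubjects,
               estimate = gt[["estimate"]], se = gt[["se"]],
               statistic = gt[["statistic"]], df = gt[["df"]],
               p = gt[["p"]], var_subject = vc[["subject"]],
               var_residual = vc[["residual"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out[, c("population", "transform", "n_samples", "n_subjects", "estimate",
          "se", "statistic", "df", "p", "p_bonferroni", "var_subject",
          "var_residual")]
}
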