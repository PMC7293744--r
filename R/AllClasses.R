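#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## SurvivalCohort: expression + aligned right-censored survival data
## ---------------------------------------------------------------------------

#' SurvivalCohort: a cohort of expression profiles with censored survival
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"expr"} holds
#' a genes-by-samples expression matrix, whose \code{colData} carries the
#' follow-up time (\code{time}), the event indicator (\code{event}, 1 = death
#' observed, 0 = right-censored) and optional clinical covariates, and whose
#' \code{rowData} optionally carries planted ground truth (\code{role},
#' \code{beta}) when the cohort was simulated.
#'
#' @export
setClass("SurvivalCohort", contains = "SummarizedExperiment")

.validSurvivalCohort <- function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("time", "event") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'time' and 'event'")
    else {
        if (any(!is.finite(cd$time)) || any(cd$time <= 0))
            msg <- c(msg, "all follow-up times must be finite and > 0")
        if (!all(cd$event %in% c(0, 1)))
            msg <- c(msg, "event must be 0 (censored) or 1 (death)")
    }
    if (!("expr" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'expr' is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("SurvivalCohort", .validSurvivalCohort)

#' Construct a SurvivalCohort
#'
#' @param expression numeric matrix, genes in rows, samples in columns.
#'   Row and column names are used as gene and sample ids; defaults are
#'   generated when absent.
#' @param time positive numeric vector of follow-up times, one per sample.
#' @param event 0/1 vector, 1 = event (death) observed, 0 = right-censored.
#' @param covariates optional data.frame of clinical covariates, one row per
#'   sample (e.g. age, sex, stage, grade, invasiveness).
#' @param geneRoles optional character vector over genes with values in
#'   \code{c("protective", "risky", "null")} (simulation ground truth).
#' @param geneBetas optional numeric vector of true log-hazard coefficients.
#' @return A \linkS4class{SurvivalCohort}.
#' @examples
#' x <- matrix(rnorm(20), nrow = 4)
#' co <- SurvivalCohort(x, time = c(1, 2, 3, 4, 5), event = c(1, 0, 1, 1, 0))
#' survTime(co)
#' @export
SurvivalCohort <- function(expression, time, event, covariates = NULL,
                           geneRoles = NULL, geneBetas = NULL) {
    expression <- as.matrix(expression)
    if (!is.numeric(expression))
        stop("expression must be a numeric matrix")
    if (is.null(rownames(expression)))
        rownames(expression) <- sprintf("g%04d", seq_len(nrow(expression)))
    if (is.null(colnames(expression)))
        colnames(expression) <- sprintf("s%04d", seq_len(ncol(expression)))
    n <- ncol(expression)
    if (length(time) != n || length(event) != n)
        stop("time and event must have one entry per expression column")
    cd <- S4Vectors::DataFrame(time = as.numeric(time),
                               event = as.numeric(event),
                               row.names = colnames(expression))
    if (!is.null(covariates)) {
        if (nrow(covariates) != n)
            stop("covariates must have one row per sample")
        cd <- cbind(cd, S4Vectors::DataFrame(covariates))
    }
    rd <- S4Vectors::DataFrame(row.names = rownames(expression))
    if (!is.null(geneRoles)) rd$role <- geneRoles
    if (!is.null(geneBetas)) rd$beta <- as.numeric(geneBetas)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(expr = expression),
        colData = cd, rowData = rd)
    methods::new("SurvivalCohort", se)
}

## ---------------------------------------------------------------------------
## CoxFit
## ---------------------------------------------------------------------------

#' CoxFit: a fitted Cox proportional-hazards model
#'
#' Holds log-hazard coefficients, Wald standard errors, hazard ratios with
#' 95\% confidence limits, Wald p-values, the maximized partial
#' log-likelihood and convergence diagnostics.
#'
#' @slot beta named numeric, log-hazard coefficients.
#' @slot se numeric, standard errors from the inverse observed information.
#' @slot hr numeric, \code{exp(beta)}.
#' @slot ciLow,ciHigh numeric, 95\% Wald interval on the hazard-ratio scale.
#' @slot pValue numeric in [0,1].
#' @slot loglik numeric(1), partial log-likelihood at the estimate.
#' @slot converged logical(1).
#' @slot nIterations integer(1), Newton-Raphson iterations used.
#' @export
setClass("CoxFit", representation(
    beta = "numeric", se = "numeric", hr = "numeric",
    ciLow = "numeric", ciHigh = "numeric", pValue = "numeric",
    loglik = "numeric", converged = "logical", nIterations = "integer"))

setValidity("CoxFit", function(object) {
    msg <- character()
    k <- length(object@beta)
    if (any(lengths(list(object@se, object@hr, object@ciLow, object@ciHigh,
                         object@pValue)) != k))
        msg <- c(msg, "coefficient vectors must share one length")
    if (any(abs(object@hr - exp(object@beta)) >
            1e-8 * pmax(1, object@hr)))
        msg <- c(msg, "hr must equal exp(beta)")
    ok <- is.finite(object@ciLow) & is.finite(object@ciHigh)
    if (any(object@ciLow[ok] > object@hr[ok] + 1e-12) ||
        any(object@ciHigh[ok] < object@hr[ok] - 1e-12))
        msg <- c(msg, "hazard ratio must lie inside its confidence interval")
    if (any(object@pValue < 0 | object@pValue > 1, na.rm = TRUE))
        msg <- c(msg, "p-values must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RiskProfile / RiskGroups
## ---------------------------------------------------------------------------

#' RiskProfile: per-patient risk scores and risk probabilities
#'
#' The risk score of patient \eqn{i} is \eqn{rs_i = \sum_g x_{ig} \beta_g}
#' over the screened genes; the risk probability \eqn{rp_{ig} = x_{ig}
#' \beta_g / rs_i} is the fractional contribution of gene \eqn{g} to that
#' score. Non-degenerate rows of \code{rp} sum to 1 (components may be
#' negative or exceed 1 under mixed signs). Patients with \eqn{|rs|} below
#' the degeneracy threshold are flagged in \code{degenerate}; their
#' \code{rp} rows are \code{NA}.
#'
#' @slot sampleIds character.
#' @slot rs numeric risk scores.
#' @slot rp numeric matrix, samples by screened genes.
#' @slot geneIds character, the screened genes.
#' @slot degenerate logical, \code{TRUE} where \code{|rs|} is below the
#'   degeneracy threshold.
#' @export
setClass("RiskProfile", representation(
    sampleIds = "character", rs = "numeric", rp = "matrix",
    geneIds = "character", degenerate = "logical"))

setValidity("RiskProfile", function(object) {
    msg <- character()
    n <- length(object@sampleIds)
    if (length(object@rs) != n || nrow(object@rp) != n ||
        length(object@degenerate) != n)
        msg <- c(msg, "per-sample slots must share one length")
    if (ncol(object@rp) != length(object@geneIds))
        msg <- c(msg, "rp must have one column per screened gene")
    ok <- !object@degenerate
    if (any(ok) && ncol(object@rp) > 0) {
        s <- rowSums(object@rp[ok, , drop = FALSE])
        if (any(abs(s - 1) > 1e-10))
            msg <- c(msg, "non-degenerate rp rows must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' RiskGroups: a median or tertile split of risk scores
#'
#' @slot labels factor over samples, levels \code{c("low","high")} or
#'   \code{c("low","median","high")}.
#' @slot cutoff numeric, the median (length 1) or the tertile bounds
#'   (length 2).
#' @export
setClass("RiskGroups",
         representation(labels = "factor", cutoff = "numeric"))

## ---------------------------------------------------------------------------
## WladScadFit
## ---------------------------------------------------------------------------

#' WladScadFit: a penalized weighted-LAD regression fit
#'
#' @slot gamma named numeric, regression coefficients (exact zeros below the
#'   support threshold).
#' @slot support character, names of coefficients with \code{|gamma|} at or
#'   above the zero threshold.
#' @slot weights numeric in (0,1], the leverage-based robustness weights.
#' @slot lambda numeric(1), the SCAD penalty level used.
#' @slot a numeric(1), SCAD shape constant (> 2).
#' @slot objectiveTrace numeric, exact SCAD-penalized objective per outer
#'   LLA iteration (non-increasing).
#' @slot nIterations integer(1), outer LLA iterations.
#' @slot converged logical(1).
#' @slot fitted numeric, fitted response values at the solution.
#' @export
setClass("WladScadFit", representation(
    gamma = "numeric", support = "character", weights = "numeric",
    lambda = "numeric", a = "numeric", objectiveTrace = "numeric",
    nIterations = "integer", converged = "logical", fitted = "numeric"))

setValidity("WladScadFit", function(object) {
    msg <- character()
    if (length(object@weights) &&
        (any(object@weights <= 0) || any(object@weights > 1 + 1e-12)))
        msg <- c(msg, "weights must lie in (0, 1]")
    tr <- object@objectiveTrace
    if (length(tr) > 1 && any(diff(tr) > 1e-8 * pmax(1, abs(tr[-length(tr)]))))
        msg <- c(msg, "objective trace must be non-increasing")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SignatureResult
## ---------------------------------------------------------------------------

#' SignatureResult: the cross-cohort prognostic signature
#'
#' @slot genes character, the final signature (intersection of the two
#'   cohorts' sparse-regression supports).
#' @slot direction named character, \code{"protective"} or \code{"risky"}
#'   per signature gene (from the univariate screens, consistent across
#'   cohorts by construction).
#' @slot perCohortGamma list of two named numeric vectors, the WLAD-SCAD
#'   coefficients of the signature genes in each cohort.
#' @slot multicoxFits list of two \linkS4class{CoxFit}s, the per-cohort
#'   multivariate Cox fits on the signature.
#' @slot riskScores list of two numeric vectors, per-patient prognostic
#'   risk scores.
#' @slot groups list of two \linkS4class{RiskGroups} (median splits).
#' @slot rSquared numeric(2), goodness of fit of the step-3 predicted risk
#'   scores against the actual risk scores, per cohort.
#' @slot stageCounts list, per-stage gene counts (screened, intersected,
#'   support, signature) for run accounting.
#' @export
setClass("SignatureResult", representation(
    genes = "character", direction = "character",
    perCohortGamma = "list", multicoxFits = "list",
    riskScores = "list", groups = "list", rSquared = "numeric",
    stageCounts = "list"))

## ---------------------------------------------------------------------------
## Survival evaluation containers
## ---------------------------------------------------------------------------

#' SurvivalCurve: a Kaplan-Meier product-limit estimate
#'
#' @slot times increasing distinct event times.
#' @slot survival survival probabilities, non-increasing, in [0,1].
#' @slot atRisk integer, number at risk just before each event time.
#' @slot nEvents integer, events at each time.
#' @export
setClass("SurvivalCurve", representation(
    times = "numeric", survival = "numeric",
    atRisk = "integer", nEvents = "integer"))

setValidity("SurvivalCurve", function(object) {
    msg <- character()
    k <- length(object@times)
    if (length(object@survival) != k || length(object@atRisk) != k ||
        length(object@nEvents) != k)
        msg <- c(msg, "all slots must share one length")
    if (k) {
        if (is.unsorted(object@times, strictly = TRUE))
            msg <- c(msg, "event times must be strictly increasing")
        if (any(diff(object@survival) > 1e-12) ||
            any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
            msg <- c(msg, "survival must be non-increasing within [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' LogrankResult: a log-rank test
#'
#' @slot chi2 non-negative chi-square statistic.
#' @slot df positive integer degrees of freedom (groups - 1).
#' @slot pValue in [0,1].
#' @export
setClass("LogrankResult", representation(
    chi2 = "numeric", df = "integer", pValue = "numeric"))

#' TimeROC: a time-dependent ROC analysis at one horizon
#'
#' Cumulative-case / dynamic-control ROC with inverse-probability-of-
#' censoring weights; the AUC is the trapezoidal area under (fpr, tpr).
#'
#' @slot horizon positive time horizon.
#' @slot auc in [0,1].
#' @slot tpr,fpr vectors in [0,1] tracing the ROC curve.
#' @export
setClass("TimeROC", representation(
    horizon = "numeric", auc = "numeric",
    tpr = "numeric", fpr = "numeric"))

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' SimulationConfig: synthetic-cohort generator settings
#'
#' @slot nSamples,nGenes positive integers.
#' @slot nProtective,nRisky non-negative integers; their sum cannot exceed
#'   \code{nGenes}.
#' @slot betaProtective negative log-hazard per unit expression.
#' @slot betaRisky positive log-hazard per unit expression.
#' @slot baselineHazard positive events per time unit (exponential
#'   baseline).
#' @slot censorHorizon upper bound of the Uniform(0, horizon) censoring
#'   time.
#' @slot expressionMean,expressionSd per-gene normal expression model on a
#'   positive log-like scale.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    nSamples = "integer", nGenes = "integer",
    nProtective = "integer", nRisky = "integer",
    betaProtective = "numeric", betaRisky = "numeric",
    baselineHazard = "numeric", censorHorizon = "numeric",
    expressionMean = "numeric", expressionSd = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nSamples < 1L || object@nGenes < 1L)
        msg <- c(msg, "nSamples and nGenes must be positive")
    if (object@nProtective < 0L || object@nRisky < 0L)
        msg <- c(msg, "gene counts must be non-negative")
    if (object@nProtective + object@nRisky > object@nGenes)
        msg <- c(msg, "nProtective + nRisky cannot exceed nGenes")
    if (object@betaProtective > 0)
        msg <- c(msg, "betaProtective must be <= 0")
    if (object@betaRisky < 0)
        msg <- c(msg, "betaRisky must be >= 0")
    if (object@baselineHazard <= 0)
        msg <- c(msg, "baselineHazard must be positive")
    if (object@censorHorizon <= 0)
        msg <- c(msg, "censorHorizon must be positive")
    if (object@expressionSd <= 0)
        msg <- c(msg, "expressionSd must be positive")
    if (length(msg)) msg else TRUE
})

#' RobustWeightConfig: WLAD-SCAD solver settings
#'
#' @slot subsetFraction fraction of samples kept in the clean subset
#'   (default 0.6).
#' @slot zeroThreshold coefficients with \code{|gamma|} below this are set
#'   to exact zero (default 1e-4).
#' @slot lambdaGrid strictly positive penalty grid; when empty a 30-point
#'   log-spaced grid over [0.01 lambda_max, lambda_max] is built from the
#'   data.
#' @slot a SCAD shape constant, must exceed 2 (default 3.7).
#' @slot maxLlaIter maximum outer LLA iterations (default 20).
#' @slot innerTol outer convergence tolerance on max coefficient change
#'   (default 1e-6).
#' @export
setClass("RobustWeightConfig", representation(
    subsetFraction = "numeric", zeroThreshold = "numeric",
    lambdaGrid = "numeric", a = "numeric",
    maxLlaIter = "integer", innerTol = "numeric"))

setValidity("RobustWeightConfig", function(object) {
    msg <- character()
    if (object@subsetFraction <= 0 || object@subsetFraction > 1)
        msg <- c(msg, "subsetFraction must lie in (0, 1]")
    if (length(object@lambdaGrid) && any(object@lambdaGrid <= 0))
        msg <- c(msg, "lambdaGrid must be strictly positive")
    if (object@a <= 2)
        msg <- c(msg, "SCAD shape a must exceed 2")
    if (length(msg)) msg else TRUE
})

#' PipelineConfig: end-to-end RWSR pipeline settings
#'
#' @slot alphaScreen univariate screen significance level (default 0.01).
#' @slot subsetFraction,scadA,zeroThreshold passed to the WLAD-SCAD solver.
#' @slot zeroFractionCutoff samples with a strictly greater fraction of
#'   zero expression values are dropped (default 0.30).
#' @slot aucHorizon time horizon for time-dependent ROC evaluation
#'   (NA = not evaluated).
#' @slot seed integer RNG seed recorded in the run manifest.
#' @export
setClass("PipelineConfig", representation(
    alphaScreen = "numeric", subsetFraction = "numeric",
    scadA = "numeric", zeroThreshold = "numeric",
    zeroFractionCutoff = "numeric", aucHorizon = "numeric",
    seed = "integer"))
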