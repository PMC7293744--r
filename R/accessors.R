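#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn survTime follow-up times
#' @export
setMethod("survTime", "SurvivalCohort", function(x)
    SummarizedExperiment::colData(x)$time)

#' @describeIn survEvent event indicators
#' @export
setMethod("survEvent", "SurvivalCohort", function(x)
    SummarizedExperiment::colData(x)$event)

#' @describeIn exprValues expression assay
#' @export
setMethod("exprValues", "SurvivalCohort", function(x)
    SummarizedExperiment::assay(x, "expr"))

#' @describeIn geneTruth simulation ground truth
#' @export
setMethod("geneTruth", "SurvivalCohort", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!all(c("role", "beta") %in% colnames(rd)))
        return(NULL)
    data.frame(gene_id = rownames(x), role = rd$role, beta = rd$beta,
               stringsAsFactors = FALSE)
})

#' @describeIn sampleInfo clinical covariates
#' @export
setMethod("sampleInfo", "SurvivalCohort", function(x) {
    cd <- SummarizedExperiment::colData(x)
    keep <- setdiff(colnames(cd), c("time", "event"))
    as.data.frame(cd[, keep, drop = FALSE])
})

#' @describeIn supportGenes selected genes of a sparse fit
#' @export
setMethod("supportGenes", "WladScadFit", function(x) x@support)

#' @describeIn supportGenes final signature genes
#' @export
setMethod("supportGenes", "SignatureResult", function(x) x@genes)

#' @describeIn riskScores per-patient risk scores
#' @export
setMethod("riskScores", "RiskProfile", function(x)
    stats::setNames(x@rs, x@sampleIds))

#' @describeIn riskProbabilities fractional contributions
#' @export
setMethod("riskProbabilities", "RiskProfile", function(x) x@rp)

#' @describeIn groupLabels labels of a risk split
#' @export
setMethod("groupLabels", "RiskGroups", function(x) x@labels)

#' @describeIn fitCox coefficients of a Cox fit
#' @param object a fitted model
#' @param ... unused
#' @export
setMethod("coef", "CoxFit", function(object, ...) object@beta)

#' @describeIn solvePenalizedWlad coefficients of a sparse fit
#' @param object a fitted model
#' @param ... unused
#' @export
setMethod("coef", "WladScadFit", function(object, ...) object@gamma)

setMethod("show", "SurvivalCohort", function(object) {
    ev <- survEvent(object)
    cat(sprintf("SurvivalCohort: %d genes x %d samples (%d events, %.1f%%)\n",
                nrow(object), ncol(object), sum(ev),
                100 * mean(ev)))
    tr <- geneTruth(object)
    if (!is.null(tr))
        cat(sprintf("  planted truth: %d protective, %d risky, %d null\n",
                    sum(tr$role == "protective"), sum(tr$role == "risky"),
                    sum(tr$role == "null")))
    methods::callNextMethod()
})

setMethod("show", "CoxFit", function(object) {
    cat(sprintf("CoxFit: %d coefficient(s), loglik %.4f, %s in %d iterations\n",
                length(object@beta), object@loglik,
                if (object@converged) "converged" else "NOT converged",
                object@nIterations))
    df <- data.frame(beta = object@beta, se = object@se, HR = object@hr,
                     ci_low = object@ciLow, ci_high = object@ciHigh,
                     p = object@pValue)
    print(utils::head(df, 10))
    if (length(object@beta) > 10)
        cat(sprintf("  ... and %d more\n", length(object@beta) - 10))
})

setMethod("show", "RiskProfile", function(object) {
    cat(sprintf(
        "RiskProfile: %d patients x %d screened genes (%d degenerate)\n",
        length(object@sampleIds), length(object@geneIds),
        sum(object@degenerate)))
})

setMethod("show", "RiskGroups", function(object) {
    cat("RiskGroups:", paste(sprintf("%s=%d", levels(object@labels),
        tabulate(object@labels, nbins = nlevels(object@labels))),
        collapse = ", "),
        "| cutoff:", paste(signif(object@cutoff, 6), collapse = ", "), "\n")
})

setMethod("show", "WladScadFit", function(object) {
    cat(sprintf(
        "WladScadFit: %d/%d nonzero, lambda %.5g, a %.2f, %d LLA iteration(s)%s\n",
        length(object@support), length(object@gamma), object@lambda,
        object@a, object@nIterations,
        if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SignatureResult", function(object) {
    cat(sprintf("SignatureResult: %d-gene signature (%d protective, %d risky)\n",
                length(object@genes),
                sum(object@direction == "protective"),
                sum(object@direction == "risky")))
    cat("  genes:", paste(utils::head(object@genes, 20), collapse = ", "), "\n")
    cat(sprintf("  R-squared: %s\n",
                paste(signif(object@rSquared, 3), collapse = " / ")))
})

setMethod("show", "SurvivalCurve", function(object) {
    cat(sprintf("SurvivalCurve: %d event time(s); S(last) = %.4f\n",
                length(object@times),
                if (length(object@survival)) object@survival[length(object@survival)] else 1))
})

setMethod("show", "LogrankResult", function(object) {
    cat(sprintf("Log-rank test: chi2 = %.4f on %d df, p = %.4g\n",
                object@chi2, object@df, object@pValue))
})

setMethod("show", "TimeROC", function(object) {
    cat(sprintf("TimeROC at horizon %.4g: AUC = %.4f (%d curve points)\n",
                object@horizon, object@auc, length(object@tpr)))
})
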