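#' @include AllClasses.R
NULL

#' Follow-up times of a cohort
#' @param x a \linkS4class{SurvivalCohort}
#' @return numeric vector of follow-up times
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' Event indicators of a cohort
#' @param x a \linkS4class{SurvivalCohort}
#' @return 0/1 numeric vector (1 = death observed)
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' Expression matrix of a cohort
#' @param x a \linkS4class{SurvivalCohort}
#' @return genes-by-samples numeric matrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Planted ground truth of a simulated cohort
#' @param x a \linkS4class{SurvivalCohort}
#' @return data.frame with columns gene_id, role, beta, or NULL when the
#'   cohort carries no truth annotation
#' @export
setGeneric("geneTruth", function(x) standardGeneric("geneTruth"))

#' Clinical covariates of a cohort
#' @param x a \linkS4class{SurvivalCohort}
#' @return data.frame of covariates (columns other than time/event), one row
#'   per sample; zero columns when none are recorded
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Support of a sparse fit
#' @param x a \linkS4class{WladScadFit} or \linkS4class{SignatureResult}
#' @return character vector of selected gene ids
#' @export
setGeneric("supportGenes", function(x) standardGeneric("supportGenes"))

#' Risk scores
#' @param x a \linkS4class{RiskProfile}
#' @return named numeric vector of per-patient risk scores
#' @export
setGeneric("riskScores", function(x) standardGeneric("riskScores"))

#' Risk-probability matrix
#' @param x a \linkS4class{RiskProfile}
#' @return samples-by-genes matrix of fractional risk contributions
#' @export
setGeneric("riskProbabilities",
           function(x) standardGeneric("riskProbabilities"))

#' Risk-group labels
#' @param x a \linkS4class{RiskGroups}
#' @return factor of group labels
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
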