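#' @include AllClasses.R
NULL

#' Per-patient risk score
#'
#' The risk score is the linear predictor \eqn{rs = \sum_i x_i \beta_i} over
#' the screened genes (those classified protective or risky, all with
#' nonzero coefficient).
#'
#' @param expressionRow expression values of one patient over the screened
#'   genes.
#' @param betas matching univariate Cox coefficients.
#' @return the risk score (a scalar); 0 with a warning when no genes passed
#'   screening.
#' @examples
#' riskScore(c(2, 1), c(0.5, -0.2))  # 0.8
#' @export
riskScore <- function(expressionRow, betas) {
    if (length(expressionRow) != length(betas))
        stop("expressionRow and betas must have the same length")
    if (length(betas) == 0 || all(betas == 0)) {
        warning("no genes passed screening: risk score is 0", call. = FALSE)
        return(0)
    }
    sum(expressionRow * betas)
}

#' Per-patient risk probabilities
#'
#' Component \eqn{i} is the fractional contribution \eqn{x_i \beta_i /
#' \sum_j x_j \beta_j} of gene \eqn{i} to the patient's risk score. The
#' components sum to 1 but may individually be negative or exceed 1 when
#' contributions have mixed signs. A patient whose risk score is within
#' \code{degeneracyEps} of zero has no defined risk probability and raises
#' an error.
#'
#' @param expressionRow,betas as in \code{\link{riskScore}}.
#' @param degeneracyEps degeneracy threshold on \eqn{|rs|} (default 1e-8).
#' @return numeric vector summing to 1.
#' @examples
#' riskProbability(c(2, 1), c(0.5, -0.2))  # c(1.25, -0.25)
#' @export
riskProbability <- function(expressionRow, betas, degeneracyEps = 1e-8) {
    if (length(expressionRow) != length(betas))
        stop("expressionRow and betas must have the same length")
    contrib <- expressionRow * betas
    rs <- sum(contrib)
    if (abs(rs) < degeneracyEps)
        stop("degenerate patient: risk score ~ 0, risk probability undefined")
    contrib / rs
}

#' Risk profile of a cohort over its screened genes
#'
#' Computes the risk score and the risk-probability matrix for every
#' patient from the screened genes' expression and univariate Cox
#' coefficients. Patients with \eqn{|rs|} below \code{degeneracyEps} are
#' flagged as degenerate (their risk-probability rows are \code{NA}) rather
#' than erroring, so downstream stages can exclude them.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param screen a screen data.frame from \code{\link{screenGenes}}, or any
#'   data.frame with columns \code{gene_id}, \code{beta}, \code{role}.
#' @param genes optional character vector restricting the screened genes
#'   used (e.g. the cross-cohort candidate intersection); defaults to all
#'   genes the screen classified protective or risky.
#' @param degeneracyEps degeneracy threshold on \eqn{|rs|}.
#' @return a \linkS4class{RiskProfile}.
#' @export
riskProfile <- function(cohort, screen, genes = NULL, degeneracyEps = 1e-8) {
    stopifnot(methods::is(cohort, "SurvivalCohort"))
    keep <- screen$role %in% c("protective", "risky")
    screened <- screen$gene_id[keep]
    if (!is.null(genes)) screened <- intersect(screened, genes)
    if (length(screened) == 0)
        stop("no screened genes: risk profile undefined")
    beta <- screen$beta[match(screened, screen$gene_id)]
    x <- t(exprValues(cohort)[screened, , drop = FALSE])  # samples x genes
    contrib <- sweep(x, 2, beta, `*`)
    rs <- rowSums(contrib)
    degenerate <- abs(rs) < degeneracyEps
    rp <- contrib / rs
    rp[degenerate, ] <- NA_real_
    methods::new("RiskProfile", sampleIds = rownames(x), rs = rs,
                 rp = rp, geneIds = screened, degenerate = degenerate)
}

#' Split patients into high/low risk groups at the median risk score
#'
#' Scores strictly above the median are labeled \code{"high"}; scores at or
#' below the median (including ties at the median) are labeled
#' \code{"low"}.
#'
#' @param rs numeric risk scores (length >= 2).
#' @return a \linkS4class{RiskGroups} with the cutoff recorded.
#' @examples
#' groupLabels(splitByMedian(c(1, 2, 3, 4)))
#' @export
splitByMedian <- function(rs) {
    if (length(rs) < 2) stop("need at least 2 patients")
    if (diff(range(rs)) == 0)
        stop("no risk separation: all risk scores identical")
    cut <- stats::median(rs)
    labels <- factor(ifelse(rs > cut, "high", "low"),
                     levels = c("low", "high"))
    names(labels) <- names(rs)
    methods::new("RiskGroups", labels = labels, cutoff = cut)
}

#' Split patients into low/median/high risk groups at the tertiles
#'
#' Cuts at the 1/3 and 2/3 empirical quantiles; scores at or below a cut
#' fall in the lower group.
#'
#' @param rs numeric risk scores (length >= 3).
#' @return a \linkS4class{RiskGroups} with both tertile bounds recorded.
#' @export
splitByTertiles <- function(rs) {
    if (length(rs) < 3) stop("need at least 3 patients")
    if (diff(range(rs)) == 0)
        stop("no risk separation: all risk scores identical")
    cuts <- stats::quantile(rs, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    labels <- factor(ifelse(rs > cuts[2], "high",
                            ifelse(rs > cuts[1], "median", "low")),
                     levels = c("low", "median", "high"))
    names(labels) <- names(rs)
    methods::new("RiskGroups", labels = labels, cutoff = cuts)
}
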