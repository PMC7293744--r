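#' @include AllClasses.R cox.R risk.R wlad.R
NULL

#' Intersect candidate gene sets across two cohorts
#'
#' Returns the genes classified protective in both screens
#' (\code{com_prot}) and risky in both screens (\code{com_risk}). A gene
#' with inconsistent direction (protective in one cohort, risky in the
#' other) appears in neither set.
#'
#' @param screenA,screenB screen data.frames from
#'   \code{\link{screenGenes}}.
#' @return a list with character vectors \code{com_prot} and
#'   \code{com_risk}.
#' @export
intersectCandidates <- function(screenA, screenB) {
    pick <- function(s, role) s$gene_id[s$role == role]
    comProt <- intersect(pick(screenA, "protective"),
                         pick(screenB, "protective"))
    comRisk <- intersect(pick(screenA, "risky"), pick(screenB, "risky"))
    if (length(comProt) + length(comRisk) == 0)
        warning("empty candidate intersection between cohorts",
                call. = FALSE)
    list(com_prot = sort(comProt), com_risk = sort(comRisk))
}

#' Prognostic risk score from the multivariate Cox coefficients
#'
#' Per-patient linear predictor \eqn{\sum_i x_i \gamma_i} over the
#' signature genes.
#'
#' @param expression expression matrix over exactly the signature genes
#'   (genes in rows, samples in columns).
#' @param multicoxGamma named coefficient vector from the multivariate Cox
#'   fit on the signature.
#' @return named numeric vector of per-patient risk scores.
#' @export
prognosticRiskScore <- function(expression, multicoxGamma) {
    expression <- as.matrix(expression)
    if (is.null(names(multicoxGamma)) ||
        !setequal(rownames(expression), names(multicoxGamma)))
        stop("gene mismatch between gamma and expression rows")
    g <- multicoxGamma[rownames(expression)]
    stats::setNames(as.vector(crossprod(expression, g)),
                    colnames(expression))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. For least-squares-optimal fits this
#' lies in [0, 1]; for arbitrary predictions it can be negative.
#'
#' @param predicted,actual equal-length numeric vectors; \code{actual} must
#'   not be constant.
#' @return the R-squared value.
#' @examples
#' goodnessOfFit(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
goodnessOfFit <- function(predicted, actual) {
    if (length(predicted) != length(actual))
        stop("predicted and actual must have the same length")
    ssTot <- sum((actual - mean(actual))^2)
    if (ssTot == 0) stop("constant actual values: R-squared undefined")
    1 - sum((actual - predicted)^2) / ssTot
}

#' Derive a cross-cohort prognostic gene signature
#'
#' Runs the full risk-weighted sparse regression workflow on two cohorts
#' sharing the same genes: (1) univariate Cox screening per cohort with
#' protective/risky classification; (2) intersection of the candidate sets
#' across cohorts; (3) per cohort and per direction (the common protective
#' candidates and the common risky candidates are fit separately, so every
#' risk score in a fit carries a single sign and the risk probabilities
#' stay well-defined), a risk profile and the robust SCAD-penalized
#' weighted-LAD fit; the cohort's support is the union over directions and
#' the final signature is the intersection of the two cohorts' supports.
#' The signature is then assessed per cohort with a multivariate Cox fit,
#' prognostic risk scores, a median high/low split and the goodness of fit
#' of the step-3 predicted risk scores against the actual ones (sums of
#' squares pooled over directions, each direction centered on its own
#' mean, so the between-direction gap does not inflate the value).
#'
#' @param cohortA,cohortB \linkS4class{SurvivalCohort}s over the same
#'   genes.
#' @param alpha univariate screen significance level (default 0.01).
#' @param cfg a \linkS4class{RobustWeightConfig} for the sparse fit.
#' @return a \linkS4class{SignatureResult}.
#' @export
deriveSignature <- function(cohortA, cohortB, alpha = 0.01,
                            cfg = robustWeightConfig()) {
    stopifnot(methods::is(cohortA, "SurvivalCohort"),
              methods::is(cohortB, "SurvivalCohort"))
    if (!setequal(rownames(cohortA), rownames(cohortB)))
        stop("cohorts must share the same gene ids")
    screens <- list(A = screenGenes(cohortA, alpha),
                    B = screenGenes(cohortB, alpha))
    com <- suppressWarnings(intersectCandidates(screens$A, screens$B))
    candidates <- sort(c(com$com_prot, com$com_risk))
    if (length(candidates) == 0)
        stop("empty signature: no common candidate genes after ",
             "cross-cohort intersection of the screens")
    cohorts <- list(A = cohortA, B = cohortB)
    dirSets <- Filter(length, com)          # per-direction candidate sets
    supports <- list()
    gammas <- list()
    r2within <- list()
    for (nm in c("A", "B")) {
        supports[[nm]] <- character()
        gammas[[nm]] <- numeric()
        ssRes <- 0
        ssTot <- 0
        for (ds in dirSets) {
            prof <- riskProfile(cohorts[[nm]], screens[[nm]], genes = ds)
            fit <- rwsrStep3(
                exprValues(cohorts[[nm]])[prof@geneIds, , drop = FALSE],
                prof, cfg)
            supports[[nm]] <- c(supports[[nm]], fit@support)
            gammas[[nm]] <- c(gammas[[nm]], fit@gamma)
            rsDir <- prof@rs[!prof@degenerate]
            ssRes <- ssRes + sum((rsDir - fit@fitted)^2)
            ssTot <- ssTot + sum((rsDir - mean(rsDir))^2)
        }
        r2within[[nm]] <- 1 - ssRes / ssTot
    }
    genes <- sort(intersect(supports$A, supports$B))
    if (length(genes) == 0)
        stop("empty signature: sparse-regression supports of the two ",
             "cohorts do not intersect")
    direction <- ifelse(genes %in% com$com_prot, "protective", "risky")
    names(direction) <- genes
    multicox <- list()
    scores <- list()
    groups <- list()
    r2 <- numeric(2)
    names(r2) <- c("A", "B")
    for (nm in c("A", "B")) {
        xs <- t(exprValues(cohorts[[nm]])[genes, , drop = FALSE])
        multicox[[nm]] <- fitCox(xs, survTime(cohorts[[nm]]),
                                 survEvent(cohorts[[nm]]))
        scores[[nm]] <- prognosticRiskScore(
            exprValues(cohorts[[nm]])[genes, , drop = FALSE],
            coef(multicox[[nm]]))
        groups[[nm]] <- splitByMedian(scores[[nm]])
        r2[nm] <- r2within[[nm]]
    }
    counts <- list(
        screened = lapply(screens, function(s) table(s$role)),
        com_prot = length(com$com_prot), com_risk = length(com$com_risk),
        support = vapply(supports, length, integer(1)),
        signature = length(genes))
    methods::new("SignatureResult", genes = genes, direction = direction,
                 perCohortGamma = lapply(gammas, function(g) g[genes]),
                 multicoxFits = multicox, riskScores = scores,
                 groups = groups, rSquared = r2, stageCounts = counts)
}
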