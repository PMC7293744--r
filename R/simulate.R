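#' @include AllClasses.R
NULL

#' Create a simulation configuration
#'
#' The defaults describe the study conditions the package is developed and
#' validated under: two-cohort designs of 300 patients and 500 genes with a
#' sparse planted signal of 5 protective (log-hazard -1 per expression unit)
#' and 5 risky (+1) genes among null genes, positive unit-variance
#' expression on a log2-microarray-like scale (mean 6), an exponential
#' baseline hazard of 0.1 events per time unit and Uniform(0, 10)
#' right-censoring.
#'
#' @param nSamples,nGenes cohort dimensions.
#' @param nProtective,nRisky number of planted protective/risky genes.
#' @param betaProtective,betaRisky true log-hazard per unit expression for
#'   planted genes (negative / positive).
#' @param baselineHazard exponential baseline hazard (events per time unit).
#' @param censorHorizon upper bound of the Uniform(0, horizon) censoring
#'   time.
#' @param expressionMean,expressionSd per-gene normal expression model.
#' @param seed integer RNG seed; the same seed reproduces the cohort
#'   bit-identically.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 300L, nGenes = 500L,
                             nProtective = 5L, nRisky = 5L,
                             betaProtective = -1, betaRisky = 1,
                             baselineHazard = 0.1, censorHorizon = 10,
                             expressionMean = 6, expressionSd = 1,
                             seed = 1L) {
    methods::new("SimulationConfig",
                 nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
                 nProtective = as.integer(nProtective),
                 nRisky = as.integer(nRisky),
                 betaProtective = betaProtective, betaRisky = betaRisky,
                 baselineHazard = baselineHazard,
                 censorHorizon = censorHorizon,
                 expressionMean = expressionMean,
                 expressionSd = expressionSd, seed = as.integer(seed))
}

## Truth labels depend only on the config seed so that paired cohorts share
## them regardless of the per-cohort noise seed.
.planTruth <- function(config) {
    p <- config@nGenes
    geneIds <- sprintf("g%04d", seq_len(p))
    role <- rep("null", p)
    beta <- numeric(p)
    nSig <- config@nProtective + config@nRisky
    if (nSig > 0) {
        set.seed(config@seed)
        idx <- sample.int(p, nSig)
        prot <- idx[seq_len(config@nProtective)]
        risky <- setdiff(idx, prot)
        role[prot] <- "protective"
        beta[prot] <- config@betaProtective
        role[risky] <- "risky"
        beta[risky] <- config@betaRisky
    }
    data.frame(gene_id = geneIds, role = role, beta = beta,
               stringsAsFactors = FALSE)
}

.simulateOne <- function(config, truth, noiseSeed, samplePrefix = "s") {
    set.seed(noiseSeed)
    n <- config@nSamples
    p <- config@nGenes
    x <- matrix(stats::rnorm(p * n, config@expressionMean,
                             config@expressionSd),
                nrow = p, ncol = n,
                dimnames = list(truth$gene_id,
                                sprintf("%s%04d", samplePrefix, seq_len(n))))
    eta <- as.vector(crossprod(x, truth$beta))  # planted linear predictor
    rate <- config@baselineHazard * exp(eta)
    latent <- stats::rexp(n, rate)              # inverse-transform exponential
    censor <- stats::runif(n, 0, config@censorHorizon)
    obsTime <- pmin(latent, censor)
    event <- as.numeric(latent <= censor)
    covariates <- data.frame(
        age = as.integer(round(stats::rnorm(n, 68, 9))),
        sex = sample(c("male", "female"), n, replace = TRUE,
                     prob = c(0.75, 0.25)),
        stage = sample(c("0", "I", "II", "III"), n, replace = TRUE,
                       prob = c(0.15, 0.45, 0.2, 0.2)),
        grade = sample(c("low", "high"), n, replace = TRUE),
        invasiveness = sample(c("yes", "no"), n, replace = TRUE,
                              prob = c(0.3, 0.7)),
        stringsAsFactors = FALSE)
    SurvivalCohort(x, time = obsTime, event = event, covariates = covariates,
                   geneRoles = truth$role, geneBetas = truth$beta)
}

#' Simulate a synthetic cohort with planted prognostic structure
#'
#' Expression is drawn i.i.d. per gene from a normal model on a positive
#' log-like scale. The latent death time is drawn by inverse transform from
#' an exponential hazard \eqn{h_0 \exp(\sum_g \beta_g x_g)} using only the
#' planted signal genes; the censoring time is Uniform(0, horizon); the
#' observed time is the minimum of the two and the event indicator records
#' whether death preceded censoring. Ground-truth gene roles and
#' coefficients are attached as \code{rowData} (see
#' \code{\link{geneTruth}}) so tests never re-infer them. The same
#' configuration (including seed) reproduces the cohort bit-identically.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{SurvivalCohort} with truth annotation.
#' @examples
#' co <- simulateCohort(simulationConfig(nSamples = 50, nGenes = 20, seed = 7))
#' table(geneTruth(co)$role)
#' @export
simulateCohort <- function(config) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    truth <- .planTruth(config)
    .simulateOne(config, truth, noiseSeed = config@seed)
}

#' Simulate a pair of independent cohorts sharing the same ground truth
#'
#' Mirrors a two-cohort discovery/validation design: both cohorts share the
#' planted gene roles and true coefficients but have independent expression
#' noise, survival and censoring draws.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seedOffset nonzero integer added to the seed for the second
#'   cohort's noise stream.
#' @return a list of two \linkS4class{SurvivalCohort}s named \code{A} and
#'   \code{B}.
#' @export
simulatePairedCohorts <- function(config, seedOffset = 1L) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    if (seedOffset == 0L)
        stop("seedOffset must be nonzero: the cohorts would be identical")
    truth <- .planTruth(config)
    list(A = .simulateOne(config, truth, noiseSeed = config@seed,
                          samplePrefix = "a"),
         B = .simulateOne(config, truth,
                          noiseSeed = config@seed + as.integer(seedOffset),
                          samplePrefix = "b"))
}
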