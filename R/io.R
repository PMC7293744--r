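#' @include AllClasses.R pipeline.R surveval.R simulate.R
NULL

## %.17g formatting guarantees that written doubles read back bit-identical.
.fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

.writeTsv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1)) &
        !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], .fmtNum)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Create a pipeline configuration
#'
#' @param alphaScreen univariate screen significance level (default 0.01).
#' @param subsetFraction clean-subset fraction for the robust weights
#'   (default 0.6).
#' @param scadA SCAD shape constant (default 3.7).
#' @param zeroThreshold sparse-support threshold (default 1e-4).
#' @param zeroFractionCutoff samples whose fraction of zero expression
#'   values strictly exceeds this are dropped (default 0.30).
#' @param aucHorizon time horizon for time-dependent ROC evaluation
#'   (NA = skip).
#' @param seed integer seed recorded in the run manifest.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(alphaScreen = 0.01, subsetFraction = 0.6,
                           scadA = 3.7, zeroThreshold = 1e-4,
                           zeroFractionCutoff = 0.30,
                           aucHorizon = NA_real_, seed = 1L) {
    stopifnot(alphaScreen > 0, alphaScreen < 1,
              zeroFractionCutoff >= 0, zeroFractionCutoff <= 1)
    methods::new("PipelineConfig", alphaScreen = alphaScreen,
                 subsetFraction = subsetFraction, scadA = scadA,
                 zeroThreshold = zeroThreshold,
                 zeroFractionCutoff = zeroFractionCutoff,
                 aucHorizon = as.numeric(aucHorizon),
                 seed = as.integer(seed))
}

#' Write a cohort to tab-separated files
#'
#' Writes \code{<prefix>expression.tsv} (first column \code{gene_id}, one
#' column per sample), \code{<prefix>clinical.tsv} (\code{sample_id},
#' \code{time}, \code{event}, covariates) and, when the cohort carries
#' simulation ground truth, \code{<prefix>truth.tsv} (\code{gene_id},
#' \code{role}, \code{beta}). Numeric values are written with full double
#' precision so a write-then-read round trip is exact.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param dir output directory (created if missing).
#' @param prefix optional filename prefix.
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir, prefix = "") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    x <- exprValues(cohort)
    expr <- data.frame(gene_id = rownames(x), as.data.frame(x),
                       check.names = FALSE, stringsAsFactors = FALSE)
    exprPath <- file.path(dir, paste0(prefix, "expression.tsv"))
    .writeTsv(expr, exprPath)
    clin <- data.frame(sample_id = colnames(x), time = survTime(cohort),
                       event = survEvent(cohort), sampleInfo(cohort),
                       check.names = FALSE, stringsAsFactors = FALSE)
    clinPath <- file.path(dir, paste0(prefix, "clinical.tsv"))
    .writeTsv(clin, clinPath)
    paths <- c(expression = exprPath, clinical = clinPath)
    tr <- geneTruth(cohort)
    if (!is.null(tr)) {
        truthPath <- file.path(dir, paste0(prefix, "truth.tsv"))
        .writeTsv(tr, truthPath)
        paths["truth"] <- truthPath
    }
    invisible(paths)
}

#' Read a cohort from expression and clinical TSV files
#'
#' The expression file has a \code{gene_id} first column and one column per
#' sample; the clinical file has \code{sample_id}, \code{time},
#' \code{event} and optional covariate columns. Samples present in only one
#' of the two files are dropped with a message.
#'
#' @param exprPath,clinicalPath file paths.
#' @return a \linkS4class{SurvivalCohort}.
#' @export
readCohort <- function(exprPath, clinicalPath) {
    expr <- utils::read.table(exprPath, header = TRUE, sep = "\t",
                              check.names = FALSE, colClasses = "character")
    if (colnames(expr)[1] != "gene_id")
        stop("expression file must start with a 'gene_id' column")
    if (anyDuplicated(expr$gene_id))
        stop("duplicate gene_ids in expression file")
    x <- as.matrix(expr[, -1, drop = FALSE])
    suppressWarnings(storage.mode(x) <- "double")
    bad <- which(is.na(x) & expr[, -1, drop = FALSE] != "NA", arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                     expr$gene_id[bad[1, 1]], colnames(x)[bad[1, 2]]))
    rownames(x) <- expr$gene_id
    clin <- utils::read.table(clinicalPath, header = TRUE, sep = "\t",
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
    if (!all(c("sample_id", "time", "event") %in% colnames(clin)))
        stop("clinical file must contain sample_id, time and event")
    common <- intersect(colnames(x), clin$sample_id)
    dropped <- (ncol(x) - length(common)) +
        (nrow(clin) - length(common))
    if (dropped > 0)
        message(dropped, " sample(s) present in only one file dropped")
    if (length(common) == 0)
        stop("no samples shared between expression and clinical files")
    x <- x[, common, drop = FALSE]
    clin <- clin[match(common, clin$sample_id), , drop = FALSE]
    covarCols <- setdiff(colnames(clin), c("sample_id", "time", "event"))
    SurvivalCohort(x, time = as.numeric(clin$time),
                   event = as.numeric(clin$event),
                   covariates = if (length(covarCols))
                       clin[, covarCols, drop = FALSE] else NULL)
}

#' Apply cohort input filters
#'
#' Drops samples whose fraction of zero expression values strictly exceeds
#' the cutoff, drops samples with missing survival time or event, and
#' drops clinical covariate columns containing any missing value
#' (\code{NA}, \code{"not available"}, \code{"unknown"}, \code{"NA"} or
#' empty strings). Survival time and event columns are never dropped.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param cfg a \linkS4class{PipelineConfig} supplying
#'   \code{zeroFractionCutoff}.
#' @return the filtered \linkS4class{SurvivalCohort}.
#' @export
applyInputFilters <- function(cohort, cfg = pipelineConfig()) {
    stopifnot(methods::is(cohort, "SurvivalCohort"))
    x <- exprValues(cohort)
    zeroFrac <- colMeans(x == 0)
    keep <- zeroFrac <= cfg@zeroFractionCutoff &
        !is.na(survTime(cohort)) & !is.na(survEvent(cohort))
    if (!any(keep))
        stop("all samples removed by input filters")
    if (any(!keep))
        message(sum(!keep), " sample(s) dropped by input filters")
    out <- cohort[, keep]
    info <- sampleInfo(out)
    if (ncol(info)) {
        missingish <- vapply(info, function(col) {
            v <- trimws(tolower(as.character(col)))
            any(is.na(col) | v %in% c("", "na", "not available", "unknown"))
        }, logical(1))
        if (any(missingish)) {
            message("covariate column(s) dropped for missing values: ",
                    paste(colnames(info)[missingish], collapse = ", "))
            cd <- SummarizedExperiment::colData(out)
            SummarizedExperiment::colData(out) <-
                cd[, !(colnames(cd) %in% colnames(info)[missingish]),
                   drop = FALSE]
        }
    }
    out
}

## Serialize a PipelineConfig to a plain list (manifest form) and back.
.configToList <- function(cfg) {
    list(alphaScreen = cfg@alphaScreen,
         subsetFraction = cfg@subsetFraction, scadA = cfg@scadA,
         zeroThreshold = cfg@zeroThreshold,
         zeroFractionCutoff = cfg@zeroFractionCutoff,
         aucHorizon = cfg@aucHorizon, seed = cfg@seed)
}

.configFromList <- function(x) {
    pipelineConfig(alphaScreen = x$alphaScreen,
                   subsetFraction = x$subsetFraction, scadA = x$scadA,
                   zeroThreshold = x$zeroThreshold,
                   zeroFractionCutoff = x$zeroFractionCutoff,
                   aucHorizon = if (is.null(x$aucHorizon)) NA_real_ else
                       x$aucHorizon,
                   seed = x$seed)
}

#' Run the full two-cohort RWSR pipeline from files
#'
#' Reads both cohorts, applies the input filters, derives the cross-cohort
#' signature, evaluates it (median split, log-rank, optional
#' time-dependent AUC) and writes deterministic outputs to \code{outDir}:
#' \code{signature.tsv}, per-cohort \code{scores_*.tsv},
#' \code{evaluation.tsv} and \code{manifest.json}. Rerunning from the same
#' manifest reproduces the outputs byte-identically.
#'
#' @param exprA,clinA,exprB,clinB input TSV paths for the two cohorts.
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir output directory.
#' @return the \linkS4class{SignatureResult}, invisibly.
#' @export
runPipeline <- function(exprA, clinA, exprB, clinB,
                        config = pipelineConfig(), outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfg <- robustWeightConfig(subsetFraction = config@subsetFraction,
                              zeroThreshold = config@zeroThreshold,
                              a = config@scadA)
    cohorts <- list(
        A = applyInputFilters(readCohort(exprA, clinA), config),
        B = applyInputFilters(readCohort(exprB, clinB), config))
    res <- deriveSignature(cohorts$A, cohorts$B,
                           alpha = config@alphaScreen, cfg = cfg)
    sig <- data.frame(gene_id = res@genes,
                      direction = res@direction[res@genes],
                      gamma_A = res@perCohortGamma$A[res@genes],
                      gamma_B = res@perCohortGamma$B[res@genes],
                      multicox_gamma_A = coef(res@multicoxFits$A)[res@genes],
                      multicox_gamma_B = coef(res@multicoxFits$B)[res@genes],
                      stringsAsFactors = FALSE)
    .writeTsv(sig, file.path(outDir, "signature.tsv"))
    evalRows <- list()
    for (nm in c("A", "B")) {
        co <- cohorts[[nm]]
        sc <- res@riskScores[[nm]]
        .writeTsv(data.frame(sample_id = names(sc), rs = sc,
                             group = as.character(
                                 groupLabels(res@groups[[nm]])),
                             stringsAsFactors = FALSE),
                  file.path(outDir, paste0("scores_", nm, ".tsv")))
        lr <- logrankTest(survTime(co), survEvent(co),
                          groupLabels(res@groups[[nm]]))
        auc <- if (is.finite(config@aucHorizon))
            timeDependentAuc(sc, survTime(co), survEvent(co),
                             config@aucHorizon)@auc else NA_real_
        evalRows[[nm]] <- data.frame(
            cohort = nm, n = ncol(co), r_squared = res@rSquared[[nm]],
            logrank_chi2 = lr@chi2, logrank_p = lr@pValue, auc = auc,
            stringsAsFactors = FALSE)
    }
    .writeTsv(do.call(rbind, evalRows), file.path(outDir, "evaluation.tsv"))
    manifest <- list(config = .configToList(config),
                     inputs = list(exprA = exprA, clinA = clinA,
                                   exprB = exprB, clinB = clinB),
                     counts = list(com_prot = res@stageCounts$com_prot,
                                   com_risk = res@stageCounts$com_risk,
                                   signature = res@stageCounts$signature))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                na = "null", pretty = TRUE),
               file.path(outDir, "manifest.json"))
    invisible(res)
}

#' Rerun a pipeline from its manifest
#'
#' @param manifestPath path to a \code{manifest.json} written by
#'   \code{\link{runPipeline}}.
#' @param outDir output directory for the rerun.
#' @return the \linkS4class{SignatureResult}, invisibly.
#' @export
runFromManifest <- function(manifestPath, outDir) {
    m <- jsonlite::fromJSON(manifestPath)
    runPipeline(m$inputs$exprA, m$inputs$clinA, m$inputs$exprB,
                m$inputs$clinB, .configFromList(m$config), outDir)
}
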