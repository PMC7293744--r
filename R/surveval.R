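#' @include AllClasses.R
NULL

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' over the distinct event times (computed through
#' \code{\link[survival]{survfit}}). With no events the curve is flat at 1.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return a \linkS4class{SurvivalCurve}.
#' @examples
#' kaplanMeier(c(1, 2, 3), c(1, 1, 1))  # S = 2/3, 1/3, 0
#' @export
kaplanMeier <- function(time, event) {
    stopifnot(length(time) == length(event), length(time) >= 1)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            conf.type = "none")
    keep <- sf$n.event > 0
    methods::new("SurvivalCurve",
                 times = sf$time[keep], survival = sf$surv[keep],
                 atRisk = as.integer(sf$n.risk[keep]),
                 nEvents = as.integer(sf$n.event[keep]))
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' (through \code{\link[survival]{survdiff}}), chi-square distributed with
#' (number of groups - 1) degrees of freedom.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group group labels (factor or character); every level must be
#'   nonempty.
#' @return a \linkS4class{LogrankResult}.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    if (nlevels(group) < 2)
        stop("need at least 2 groups")
    counts <- table(group)
    if (any(counts == 0))
        stop("group(s) with zero subjects: ",
             paste(names(counts)[counts == 0], collapse = ", "))
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- nlevels(group) - 1L
    methods::new("LogrankResult", chi2 = as.numeric(sd$chisq),
                 df = df,
                 pValue = stats::pchisq(as.numeric(sd$chisq), df,
                                        lower.tail = FALSE))
}

## Evaluate a KM step function at t; left = TRUE gives the left limit
## S(t-), i.e. the product over event times strictly below t.
.stepEval <- function(times, surv, t, left = FALSE) {
    vapply(t, function(tt) {
        idx <- if (left) sum(times < tt) else sum(times <= tt)
        if (idx == 0) 1 else surv[idx]
    }, numeric(1))
}

#' Time-dependent ROC curve and AUC for a censored outcome
#'
#' Cumulative-case / dynamic-control definition at the given horizon:
#' cases are subjects with an observed event by the horizon, controls are
#' subjects still under observation beyond it. Censoring is adjusted by
#' inverse-probability-of-censoring weights from the Kaplan-Meier estimate
#' of the censoring distribution (case weight \eqn{1/\hat G(T_i^-)},
#' control weight \eqn{1/\hat G(\tau)}). The AUC is the trapezoidal area
#' under the (fpr, tpr) curve; with no censoring before the horizon it
#' reduces exactly to the plain binary AUC of event-by-horizon against the
#' score.
#'
#' @param score numeric risk scores (higher = higher risk).
#' @param time,event follow-up times and 0/1 event indicators.
#' @param horizon positive evaluation time within the follow-up range.
#' @return a \linkS4class{TimeROC}.
#' @export
timeDependentAuc <- function(score, time, event, horizon) {
    stopifnot(length(score) == length(time), length(time) == length(event))
    if (horizon <= 0 || horizon > max(time))
        stop("horizon must lie within the follow-up range")
    isCase <- time <= horizon & event == 1
    isControl <- time > horizon
    if (!any(isCase) || !any(isControl))
        stop("no cases or no controls at the horizon")
    cens <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                              conf.type = "none")
    wCase <- 1 / .stepEval(cens$time[cens$n.event > 0],
                           cens$surv[cens$n.event > 0],
                           time[isCase], left = TRUE)
    wControl <- rep(1 / .stepEval(cens$time[cens$n.event > 0],
                                  cens$surv[cens$n.event > 0], horizon),
                    sum(isControl))
    if (any(!is.finite(wCase)) || any(!is.finite(wControl)))
        stop("censoring survival reaches 0 before the horizon: ",
             "IPCW weights undefined")
    sCase <- score[isCase]
    sControl <- score[isControl]
    thr <- sort(unique(score), decreasing = TRUE)
    tpr <- c(0, vapply(thr, function(cc)
        sum(wCase[sCase >= cc]), numeric(1)) / sum(wCase))
    fpr <- c(0, vapply(thr, function(cc)
        sum(wControl[sControl >= cc]), numeric(1)) / sum(wControl))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    methods::new("TimeROC", horizon = horizon, auc = auc,
                 tpr = tpr, fpr = fpr)
}

#' Split age at a cutoff, boundary value in the lower group
#'
#' @param age numeric ages.
#' @param cutoff boundary (default 70); an age equal to the cutoff is
#'   labeled \code{"<=cutoff"}.
#' @return factor with levels \code{"<=70"}, \code{">70"} (for the default
#'   cutoff).
#' @export
splitAge <- function(age, cutoff = 70) {
    factor(ifelse(age <= cutoff, paste0("<=", cutoff), paste0(">", cutoff)),
           levels = c(paste0("<=", cutoff), paste0(">", cutoff)))
}

#' Stratified Kaplan-Meier comparison of risk groups
#'
#' Within each level of a clinical stratum (e.g. age group, sex, stage,
#' invasiveness), compares the survival of high- vs low-risk patients with
#' Kaplan-Meier curves and a log-rank test. Strata in which only one risk
#' group is represented are skipped with a warning.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param riskGroups a \linkS4class{RiskGroups} or a factor of risk
#'   labels.
#' @param stratum factor of stratum levels, one per patient.
#' @return a named list (one entry per retained stratum level) of lists
#'   with elements \code{curves} (per risk group
#'   \linkS4class{SurvivalCurve}s) and \code{logrank}
#'   (\linkS4class{LogrankResult}).
#' @export
stratifiedKm <- function(time, event, riskGroups, stratum) {
    labels <- if (methods::is(riskGroups, "RiskGroups"))
        groupLabels(riskGroups) else as.factor(riskGroups)
    stratum <- as.factor(stratum)
    stopifnot(length(labels) == length(time),
              length(stratum) == length(time))
    out <- list()
    for (lev in levels(stratum)) {
        sel <- stratum == lev
        present <- unique(droplevels(labels[sel]))
        if (length(present) < 2) {
            warning("stratum '", lev, "' has a single risk group: skipped",
                    call. = FALSE)
            next
        }
        curves <- lapply(stats::setNames(nm = as.character(present)),
                         function(g) kaplanMeier(time[sel & labels == g],
                                                 event[sel & labels == g]))
        out[[lev]] <- list(
            curves = curves,
            logrank = logrankTest(time[sel], event[sel],
                                  droplevels(labels[sel])))
    }
    out
}

#' Eight-group assignment from stage and risk
#'
#' Crosses tumor stage (0, I, II, III) with the high/low risk split into
#' eight groups: Group 1 = stage 0 and low risk, Group 2 = stage 0 and
#' high risk, ..., Group 8 = stage III and high risk.
#'
#' @param stage character or factor with values in
#'   \code{c("0", "I", "II", "III")}.
#' @param risk character, factor or \linkS4class{RiskGroups} with values
#'   \code{"low"}/\code{"high"}.
#' @return integer vector of group indices in 1..8.
#' @examples
#' stageRiskGroups(c("0", "III"), c("low", "high"))  # 1, 8
#' @export
stageRiskGroups <- function(stage, risk) {
    if (methods::is(risk, "RiskGroups")) risk <- groupLabels(risk)
    stage <- as.character(stage)
    risk <- as.character(risk)
    stages <- c("0", "I", "II", "III")
    if (!all(stage %in% stages))
        stop("stage outside {0, I, II, III}: ",
             paste(unique(setdiff(stage, stages)), collapse = ", "))
    if (!all(risk %in% c("low", "high")))
        stop("risk labels must be 'low' or 'high'")
    2L * (match(stage, stages) - 1L) + (risk == "high") + 1L
}
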