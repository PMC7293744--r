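#' @include AllClasses.R
NULL

## Reverse cumulative sum: out[i] = sum(x[i:n]).
.revcumsum <- function(x) rev(cumsum(rev(x)))

## Precompute the sorted-time structure shared by all Cox computations on a
## cohort: ascending time order, tie runs, and per distinct event time the
## first sorted index of its risk set and the number of tied events.
.coxPrep <- function(time, event) {
    stopifnot(length(time) == length(event))
    if (sum(event) == 0)
        stop("no events, partial likelihood undefined")
    ord <- order(time)
    ts <- time[ord]
    ev <- event[ord]
    r <- rle(ts)
    nRuns <- length(r$lengths)
    runFirst <- cumsum(c(1L, r$lengths))[seq_len(nRuns)]
    runId <- rep.int(seq_len(nRuns), r$lengths)
    d <- vapply(split(ev, runId), sum, numeric(1))
    keep <- which(d > 0)
    list(ord = ord, ev = ev, n = length(ts),
         eventIdx = which(ev == 1),
         riskFirst = runFirst[keep],   # risk-set start per distinct event time
         d = d[keep])                  # tied event count per event time
}

## Partial log-likelihood, score and observed information (Breslow ties)
## for sorted linear predictor lp and sorted design X (n x k).
.coxDerivs <- function(lp, X, prep, order = 2L) {
    m <- max(lp)
    w <- exp(lp - m)
    S0 <- .revcumsum(w)[prep$riskFirst]
    ll <- sum(lp[prep$eventIdx]) -
        m * length(prep$eventIdx) - sum(prep$d * log(S0))
    if (order < 1L)
        return(list(loglik = ll))
    k <- ncol(X)
    S1 <- matrix(0, length(S0), k)
    for (j in seq_len(k))
        S1[, j] <- .revcumsum(w * X[, j])[prep$riskFirst]
    Ebar <- S1 / S0
    score <- colSums(X[prep$eventIdx, , drop = FALSE]) -
        colSums(prep$d * Ebar)
    if (order < 2L)
        return(list(loglik = ll, score = score))
    info <- matrix(0, k, k)
    for (j in seq_len(k)) {
        for (l in j:k) {
            S2jl <- .revcumsum(w * X[, j] * X[, l])[prep$riskFirst]
            v <- sum(prep$d * (S2jl / S0 - Ebar[, j] * Ebar[, l]))
            info[j, l] <- v
            info[l, j] <- v
        }
    }
    list(loglik = ll, score = score, info = info)
}

#' Cox partial log-likelihood
#'
#' Evaluates the Cox proportional-hazards partial log-likelihood
#' \deqn{l = \sum_{i: \delta_i = 1} \left( \eta_i - \log \sum_{j \in R(t_i)}
#' e^{\eta_j} \right)}{l = sum_{i: event} (lp_i - log sum_{j in R(t_i)}
#' exp(lp_j))}
#' at a given linear predictor, where \eqn{R(t_i) = \{j : t_j \ge t_i\}} is
#' the risk set. Tied event times are handled with the Breslow convention
#' (tied events share one risk set).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event is required.
#' @param linearPredictor numeric vector, same length.
#' @return the partial log-likelihood (a scalar).
#' @examples
#' coxPartialLoglik(c(1, 2, 3), c(1, 1, 1), c(0, 0, 0))  # -log(6)
#' @export
coxPartialLoglik <- function(time, event, linearPredictor) {
    if (length(linearPredictor) != length(time))
        stop("linearPredictor must match time in length")
    prep <- .coxPrep(time, event)
    .coxDerivs(linearPredictor[prep$ord],
               matrix(0, prep$n, 0), prep, order = 0L)$loglik
}

.waldFromFit <- function(beta, se) {
    z <- ifelse(se > 0 & is.finite(se), beta / se, 0)
    list(hr = exp(beta),
         ciLow = exp(beta - 1.959963984540054 * se),
         ciHigh = exp(beta + 1.959963984540054 * se),
         p = 2 * stats::pnorm(-abs(z)))
}

## Newton-Raphson core on the sorted design. Returns beta, se, loglik,
## convergence flag and iteration count. betaCap guards monotone likelihood.
.coxNewton <- function(Xs, prep, maxIter = 50L, tol = 1e-8, betaCap = 20) {
    k <- ncol(Xs)
    beta <- numeric(k)
    dv <- .coxDerivs(as.vector(Xs %*% beta), Xs, prep)
    iter <- 0L
    while (iter < maxIter) {
        if (max(abs(dv$score)) < tol) break
        iter <- iter + 1L
        step <- tryCatch(solve(dv$info, dv$score),
                         error = function(e) stop(
                             "singular information matrix", call. = FALSE))
        repeat {
            cand <- pmin(pmax(beta + step, -betaCap), betaCap)
            dvNew <- .coxDerivs(as.vector(Xs %*% cand), Xs, prep)
            if (is.finite(dvNew$loglik) && dvNew$loglik >= dv$loglik - 1e-12)
                break
            step <- step / 2
            if (max(abs(step)) < 1e-12) {
                dvNew <- dv
                cand <- beta
                break
            }
        }
        beta <- cand
        dv <- dvNew
        if (all(abs(beta) >= betaCap - 1e-12)) break
    }
    capped <- any(abs(beta) >= betaCap - 1e-12)
    converged <- max(abs(dv$score)) < tol && !capped
    if (capped)
        warning("monotone partial likelihood: coefficient capped at ",
                betaCap, call. = FALSE)
    covBeta <- tryCatch(solve(dv$info), error = function(e) NULL)
    se <- if (is.null(covBeta)) rep(NA_real_, k) else sqrt(pmax(diag(
        as.matrix(covBeta)), 0))
    list(beta = beta, se = se, loglik = dv$loglik,
         converged = converged, iter = iter)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving, starting from zero. Standard errors come from the inverse
#' observed information; hazard ratios, 95\% Wald confidence intervals and
#' Wald p-values are derived from them. Convergence requires the maximum
#' absolute score to fall below \code{tol} within \code{maxIter} iterations.
#' A monotone likelihood (perfect separation) is reported as
#' \code{converged = FALSE} with the coefficient capped; constant covariate
#' columns leave the likelihood flat and return a zero coefficient with a
#' warning.
#'
#' @param X numeric matrix, samples in rows, covariates in columns (a plain
#'   vector is treated as one covariate).
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event is required.
#' @param maxIter,tol Newton-Raphson controls.
#' @return a \linkS4class{CoxFit}.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' tt <- rexp(100, exp(0.5 * x))
#' fitCox(x, tt, rep(1, 100))
#' @export
fitCox <- function(X, time, event, maxIter = 50L, tol = 1e-8) {
    X <- as.matrix(X)
    if (!is.numeric(X)) stop("X must be numeric")
    if (nrow(X) != length(time))
        stop("X must have one row per subject")
    if (is.null(colnames(X)))
        colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
    prep <- .coxPrep(time, event)
    Xs <- X[prep$ord, , drop = FALSE]
    isConst <- apply(Xs, 2, function(v) diff(range(v)) == 0)
    k <- ncol(X)
    beta <- numeric(k)
    se <- rep(Inf, k)
    if (any(isConst))
        warning("constant covariate column(s) ",
                paste(colnames(X)[isConst], collapse = ", "),
                ": flat partial likelihood, coefficient fixed at 0",
                call. = FALSE)
    if (all(isConst)) {
        ll <- .coxDerivs(rep(0, prep$n), Xs, prep, order = 0L)$loglik
        fit <- list(beta = beta, se = se, loglik = ll,
                    converged = TRUE, iter = 0L)
    } else {
        sub <- .coxNewton(Xs[, !isConst, drop = FALSE], prep,
                          maxIter = maxIter, tol = tol)
        beta[!isConst] <- sub$beta
        se[!isConst] <- sub$se
        fit <- list(beta = beta, se = se, loglik = sub$loglik,
                    converged = sub$converged, iter = sub$iter)
    }
    wald <- .waldFromFit(fit$beta, fit$se)
    methods::new("CoxFit",
                 beta = stats::setNames(fit$beta, colnames(X)),
                 se = fit$se, hr = wald$hr,
                 ciLow = wald$ciLow, ciHigh = wald$ciHigh,
                 pValue = wald$p, loglik = fit$loglik,
                 converged = fit$converged, nIterations = as.integer(fit$iter))
}

#' Univariate Cox screen with protective/risky classification
#'
#' Fits a univariate Cox model per gene and classifies each gene as
#' \code{"protective"} (HR < 1 and p < alpha), \code{"risky"} (HR > 1 and
#' p < alpha) or \code{"nonassociated"} otherwise. Zero-variance genes
#' short-circuit to nonassociated with a warning. Rows are ordered by
#' gene id.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param alpha significance threshold for the Wald p-value (default 0.01).
#' @return a data.frame with columns \code{gene_id}, \code{beta}, \code{se},
#'   \code{hr}, \code{ci_low}, \code{ci_high}, \code{p}, \code{role},
#'   mirroring a per-gene screen table.
#' @export
screenGenes <- function(cohort, alpha = 0.01) {
    stopifnot(methods::is(cohort, "SurvivalCohort"))
    x <- exprValues(cohort)
    prep <- .coxPrep(survTime(cohort), survEvent(cohort))
    genes <- sort(rownames(x))
    out <- data.frame(gene_id = genes, beta = NA_real_, se = NA_real_,
                      hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, role = "nonassociated",
                      stringsAsFactors = FALSE)
    flat <- character()
    for (i in seq_along(genes)) {
        v <- x[genes[i], ][prep$ord]
        if (diff(range(v)) == 0) {
            flat <- c(flat, genes[i])
            out$beta[i] <- 0
            out$hr[i] <- 1
            out$p[i] <- 1
            next
        }
        fit <- .coxNewton(matrix(v, ncol = 1), prep)
        wald <- .waldFromFit(fit$beta, fit$se)
        out$beta[i] <- fit$beta
        out$se[i] <- fit$se
        out$hr[i] <- wald$hr
        out$ci_low[i] <- wald$ciLow
        out$ci_high[i] <- wald$ciHigh
        out$p[i] <- wald$p
    }
    if (length(flat))
        warning(length(flat), " zero-variance gene(s) classified ",
                "nonassociated", call. = FALSE)
    sig <- !is.na(out$p) & out$p < alpha
    out$role[sig & out$hr < 1] <- "protective"
    out$role[sig & out$hr > 1] <- "risky"
    out
}
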