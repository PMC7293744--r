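#' @include AllClasses.R
NULL

#' Create a WLAD-SCAD solver configuration
#'
#' @param subsetFraction fraction of samples retained in the clean subset
#'   used for the leverage weights (default 0.6).
#' @param zeroThreshold support threshold on \code{|gamma|} (default 1e-4).
#' @param lambdaGrid optional strictly positive penalty grid; when omitted
#'   a 30-point log-spaced grid over [0.01 lambda_max, lambda_max] is built
#'   from the data at fit time.
#' @param a SCAD shape constant (> 2; default 3.7).
#' @param maxLlaIter maximum outer local-linear-approximation iterations.
#' @param innerTol convergence tolerance on the maximum coefficient change
#'   between outer iterations.
#' @return a \linkS4class{RobustWeightConfig}.
#' @export
robustWeightConfig <- function(subsetFraction = 0.6, zeroThreshold = 1e-4,
                               lambdaGrid = numeric(), a = 3.7,
                               maxLlaIter = 20L, innerTol = 1e-6) {
    methods::new("RobustWeightConfig", subsetFraction = subsetFraction,
                 zeroThreshold = zeroThreshold,
                 lambdaGrid = as.numeric(lambdaGrid), a = a,
                 maxLlaIter = as.integer(maxLlaIter), innerTol = innerTol)
}

#' Min-max normalize a design matrix per feature
#'
#' Maps every feature (column) onto [0, 1] by \eqn{(x - \min)/(\max -
#' \min)} so that between-sample Euclidean distances are scale-free.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @return matrix of the same shape with every column spanning [0, 1].
#' @examples
#' minmaxNormalize(cbind(c(2, 4, 6)))
#' @export
minmaxNormalize <- function(X) {
    X <- as.matrix(X)
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
    flat <- which(hi - lo == 0)
    if (length(flat))
        stop("constant feature(s) cannot be min-max normalized: ",
             paste(if (is.null(colnames(X))) flat else colnames(X)[flat],
                   collapse = ", "))
    sweep(sweep(X, 2, lo), 2, hi - lo, `/`)
}

#' Center distances of samples from the columnwise median
#'
#' @param Xnorm normalized design matrix (samples in rows).
#' @return non-negative vector of Euclidean distances of each row from the
#'   columnwise median vector.
#' @export
centerDistances <- function(Xnorm) {
    Xnorm <- as.matrix(Xnorm)
    if (nrow(Xnorm) == 0 || ncol(Xnorm) == 0)
        stop("empty matrix has no center distances")
    med <- apply(Xnorm, 2, stats::median)
    sqrt(rowSums(sweep(Xnorm, 2, med)^2))
}

#' Select the clean subset of least-outlying samples
#'
#' Keeps the \eqn{l = \lfloor fraction \cdot n \rfloor} rows with the
#' smallest center distance (ties broken by original row index), the subset
#' whose Gram matrix anchors the leverage weights.
#'
#' @param Xnorm normalized design matrix.
#' @param d center distances from \code{\link{centerDistances}}.
#' @param fraction subset fraction in (0, 1] (default 0.6).
#' @return the subset matrix (rows in original order of selection by
#'   distance rank).
#' @export
selectCleanSubset <- function(Xnorm, d, fraction = 0.6) {
    Xnorm <- as.matrix(Xnorm)
    if (fraction <= 0 || fraction > 1)
        stop("fraction must lie in (0, 1]")
    if (length(d) != nrow(Xnorm))
        stop("d must have one distance per row")
    l <- max(1L, floor(fraction * nrow(Xnorm)))
    idx <- order(d, seq_along(d))[seq_len(l)]
    if (l < ncol(Xnorm))
        warning("clean subset smaller than the feature count: ",
                "subset Gram matrix may be singular (pseudo-inverse used)",
                call. = FALSE)
    Xnorm[idx, , drop = FALSE]
}

#' Leverage-based robustness weights
#'
#' Computes the leverage \eqn{h_i = x_i (X_S^T X_S)^{-1} x_i^T} of every
#' sample against the clean-subset Gram matrix (Moore-Penrose
#' pseudo-inverse when singular) and returns \eqn{\omega_i = \min_j h_j /
#' h_i}, so weights lie in (0, 1], the least-leveraged sample gets weight 1
#' and outlying samples are downweighted.
#'
#' @param Xnorm normalized design matrix (all samples).
#' @param XS clean subset from \code{\link{selectCleanSubset}}.
#' @return weight vector in (0, 1].
#' @export
leverageWeights <- function(Xnorm, XS) {
    Xnorm <- as.matrix(Xnorm)
    G <- crossprod(as.matrix(XS))
    Ginv <- tryCatch(solve(G), error = function(e) MASS::ginv(G))
    h <- rowSums((Xnorm %*% Ginv) * Xnorm)
    h[h < 0] <- 0  # guard tiny negative round-off
    zero <- h == 0
    if (any(zero))
        warning(sum(zero), " zero-leverage row(s) (zero row vector) ",
                "assigned weight 1", call. = FALSE)
    if (all(zero)) return(rep(1, length(h)))
    w <- min(h[!zero]) / h
    w[zero] <- 1
    pmin(w, 1)
}

#' SCAD penalty and its derivative
#'
#' The smoothly clipped absolute deviation penalty (shape constant
#' \code{a}, conventionally 3.7) evaluated at \code{|theta|}:
#' linear (\eqn{\lambda|\theta|}) up to \eqn{\lambda}, a quadratic blend on
#' \eqn{(\lambda, a\lambda]}, and constant \eqn{(a+1)\lambda^2/2} beyond
#' \eqn{a\lambda}. The derivative is \eqn{\lambda}, then
#' \eqn{(a\lambda - |\theta|)/(a - 1)}, then 0 on the same pieces.
#'
#' @param theta coefficient value(s); the penalty is symmetric in theta.
#' @param lam penalty level, non-negative.
#' @param a shape constant, must exceed 2.
#' @return penalty (or derivative) values, vectorized over theta.
#' @examples
#' scadPenalty(0, 0.5)                 # 0
#' scadPenalty(10, 0.5)                # (3.7 + 1) * 0.25 / 2
#' @export
scadPenalty <- function(theta, lam, a = 3.7) {
    if (a <= 2) stop("SCAD shape constant a must exceed 2")
    if (lam < 0) stop("lam must be non-negative")
    th <- abs(theta)
    ifelse(th <= lam, lam * th,
           ifelse(th <= a * lam,
                  (2 * a * lam * th - th^2 - lam^2) / (2 * (a - 1)),
                  (a + 1) * lam^2 / 2))
}

#' @rdname scadPenalty
#' @export
scadDerivative <- function(theta, lam, a = 3.7) {
    if (a <= 2) stop("SCAD shape constant a must exceed 2")
    if (lam < 0) stop("lam must be non-negative")
    th <- abs(theta)
    ifelse(th <= lam, lam,
           ifelse(th < a * lam, (a * lam - th) / (a - 1), 0))
}

## Exact (unsmoothed) SCAD-penalized WLAD objective.
.wladObjective <- function(Z, y, gamma, omega, lam, a) {
    r <- y - as.vector(Z %*% gamma)
    sum(omega * abs(r)) +
        if (lam > 0) nrow(Z) * sum(scadPenalty(gamma, lam, a)) else 0
}

## Inner IRLS for min sum omega_i sqrt(r^2 + eps^2) + n sum cj gamma_j^2
## over the active columns. cj may be zero (unpenalized).
.irlsWlad <- function(Z, y, omega, cvec, gamma0, eps = 1e-6,
                      maxIter = 200L, tol = 1e-8) {
    n <- nrow(Z)
    gamma <- gamma0
    for (it in seq_len(maxIter)) {
        r <- y - as.vector(Z %*% gamma)
        u <- omega / (2 * sqrt(r^2 + eps^2))
        M <- crossprod(Z, Z * u)
        diag(M) <- diag(M) + n * cvec
        gammaNew <- tryCatch(solve(M, crossprod(Z, u * y)),
                             error = function(e)
                                 MASS::ginv(M) %*% crossprod(Z, u * y))
        gammaNew <- as.vector(gammaNew)
        if (max(abs(gammaNew - gamma)) < tol) {
            gamma <- gammaNew
            break
        }
        gamma <- gammaNew
    }
    gamma
}

## Exact weighted-LAD finishing step for the unpenalized (lambda = 0)
## problem: a LAD optimum sits at a vertex interpolating p data points, so
## descend from vertex to vertex along the LP edges (directional derivative
## test + breakpoint line search) until no edge improves. The IRLS solution
## supplies the starting basis.
.ladPolish <- function(Z, y, omega, gamma, maxMoves = 500L) {
    n <- nrow(Z)
    p <- ncol(Z)
    r <- y - as.vector(Z %*% gamma)
    basis <- integer()
    for (i in order(abs(r))) {  # smallest residuals, kept full-rank
        cand <- c(basis, i)
        if (qr(Z[cand, , drop = FALSE])$rank > length(basis))
            basis <- cand
        if (length(basis) == p) break
    }
    if (length(basis) < p) return(gamma)
    best <- sum(omega * abs(r))
    for (move in seq_len(maxMoves)) {
        ZB <- Z[basis, , drop = FALSE]
        gv <- tryCatch(solve(ZB, y[basis]), error = function(e) NULL)
        if (is.null(gv)) break
        gv <- as.vector(gv)
        r <- y - as.vector(Z %*% gv)
        r[basis] <- 0
        obj <- sum(omega * abs(r))
        Zinv <- tryCatch(solve(ZB), error = function(e) NULL)
        if (is.null(Zinv)) break
        nb <- setdiff(seq_len(n), basis)
        moved <- FALSE
        for (k in seq_len(p)) {
            d <- Zinv[, k]
            s <- as.vector(Z[nb, , drop = FALSE] %*% d)
            atKink <- abs(r[nb]) < 1e-12
            base <- ifelse(atKink, omega[nb] * abs(s),
                           -omega[nb] * sign(r[nb]) * s)
            dPlus <- omega[basis[k]] + sum(base)
            dMinus <- omega[basis[k]] + sum(ifelse(atKink, base, -base))
            if (dPlus < -1e-12) sgn <- 1
            else if (dMinus < -1e-12) sgn <- -1
            else next
            sDir <- sgn * s
            hit <- which(r[nb] / sDir > 1e-14 & abs(sDir) > 1e-14)
            if (!length(hit)) next  # unbounded edge: skip defensively
            tHit <- r[nb][hit] / sDir[hit]
            j <- hit[which.min(tHit)]
            basis[k] <- nb[j]
            moved <- TRUE
            break
        }
        if (obj < best) {
            best <- obj
            gamma <- gv
        }
        if (!moved) break
    }
    gamma
}

#' Solve the SCAD-penalized weighted-LAD regression
#'
#' Minimizes \deqn{\sum_i \omega_i |y_i - z_i^T\gamma| + n \sum_j
#' p_\lambda(|\gamma_j|)} by local linear approximation (LLA) of the SCAD
#' penalty: each outer iteration re-linearizes the penalty at the current
#' coefficients, yielding a quadratic (ridge-form) penalty
#' \eqn{n \, p'_\lambda(|\gamma_j^{(k)}|)/(2|\gamma_j^{(k)}|)\,\gamma_j^2},
#' and the resulting weighted-LAD subproblem is solved by IRLS on the
#' smoothed absolute value \eqn{\sqrt{r^2 + \epsilon^2}} (\eqn{\epsilon =
#' 10^{-6}}). Coefficients falling below the zero threshold are frozen at
#' exact zero; the exact SCAD objective is tracked and guaranteed
#' non-increasing across outer iterations (an iteration that would increase
#' it is rejected and the solver stops). For \eqn{\lambda = 0} the pure
#' weighted-LAD solution is polished to an exact interpolation vertex.
#'
#' @param Z design matrix, samples in rows.
#' @param y response vector.
#' @param omega observation weights in (0, 1].
#' @param lam penalty level (>= 0).
#' @param cfg a \linkS4class{RobustWeightConfig}.
#' @return a \linkS4class{WladScadFit}.
#' @export
solvePenalizedWlad <- function(Z, y, omega, lam,
                               cfg = robustWeightConfig()) {
    Z <- as.matrix(Z)
    n <- nrow(Z)
    p <- ncol(Z)
    if (n < 2) stop("need at least 2 observations")
    if (length(y) != n || length(omega) != n)
        stop("y and omega must have one entry per row of Z")
    if (any(omega <= 0 | omega > 1 + 1e-12))
        stop("omega must lie in (0, 1]")
    if (is.null(colnames(Z))) colnames(Z) <- sprintf("z%d", seq_len(p))
    ## initial estimate: unpenalized smoothed WLAD (tiny ridge if p >= n)
    ridge0 <- if (p >= n) rep(1e-8, p) else rep(0, p)
    gamma <- .irlsWlad(Z, y, omega, ridge0, numeric(p))
    if (lam == 0)
        gamma <- .ladPolish(Z, y, omega, gamma)
    obj <- .wladObjective(Z, y, gamma, omega, lam, cfg@a)
    if (!is.finite(obj)) stop("non-finite objective")
    trace <- obj
    converged <- lam == 0
    iter <- 0L
    if (lam > 0) {
        active <- abs(gamma) >= cfg@zeroThreshold
        gamma[!active] <- 0
        for (k in seq_len(cfg@maxLlaIter)) {
            iter <- k
            if (!any(active)) { converged <- TRUE; break }
            gOld <- gamma
            cvec <- scadDerivative(abs(gamma[active]), lam, cfg@a) /
                (2 * pmax(abs(gamma[active]), cfg@zeroThreshold))
            gact <- .irlsWlad(Z[, active, drop = FALSE], y, omega, cvec,
                              gamma[active])
            gamma[active] <- gact
            drop <- active & abs(gamma) < cfg@zeroThreshold
            gamma[drop] <- 0
            active <- active & !drop
            objNew <- .wladObjective(Z, y, gamma, omega, lam, cfg@a)
            if (!is.finite(objNew)) stop("non-finite objective")
            if (objNew > obj + 1e-10 * max(1, abs(obj))) {
                gamma <- gOld  # LLA step rejected: keep the better iterate
                converged <- TRUE
                break
            }
            trace <- c(trace, objNew)
            if (max(abs(gamma - gOld)) < cfg@innerTol) {
                obj <- objNew
                converged <- TRUE
                break
            }
            obj <- objNew
        }
    }
    gamma[abs(gamma) < cfg@zeroThreshold] <- 0
    support <- colnames(Z)[abs(gamma) >= cfg@zeroThreshold]
    methods::new("WladScadFit",
                 gamma = stats::setNames(gamma, colnames(Z)),
                 support = support, weights = omega, lambda = lam,
                 a = cfg@a, objectiveTrace = trace,
                 nIterations = as.integer(iter), converged = converged,
                 fitted = as.vector(Z %*% gamma))
}

## Default penalty grid: 30 log-spaced points below lambda_max, the largest
## absolute covariate-response inner product scaled by n.
.lambdaGrid <- function(Z, y, nPoints = 30L, minRatio = 0.01) {
    lamMax <- max(abs(crossprod(Z, y))) / nrow(Z)
    if (lamMax <= 0) lamMax <- 1
    exp(seq(log(minRatio * lamMax), log(lamMax), length.out = nPoints))
}

#' Select the SCAD penalty level by BIC over a grid
#'
#' Fits the solver over the penalty grid and returns the \eqn{\lambda}
#' minimizing \deqn{BIC(\lambda) = n \log(\overline{\omega |r|}) + \log(n)
#' \cdot |support|,} with ties broken toward the larger (sparser)
#' \eqn{\lambda}. The selection is invariant to the ordering of the grid.
#'
#' @inheritParams solvePenalizedWlad
#' @return the selected penalty level, with the BIC values over the sorted
#'   grid attached as attribute \code{"bic"}.
#' @export
selectLambda <- function(Z, y, omega, cfg = robustWeightConfig()) {
    Z <- as.matrix(Z)
    grid <- if (length(cfg@lambdaGrid)) cfg@lambdaGrid else .lambdaGrid(Z, y)
    if (length(grid) == 0) stop("empty lambda grid")
    grid <- sort(unique(grid), decreasing = TRUE)
    n <- nrow(Z)
    bic <- numeric(length(grid))
    supSize <- integer(length(grid))
    for (i in seq_along(grid)) {
        fit <- solvePenalizedWlad(Z, y, omega, grid[i], cfg)
        mar <- mean(omega * abs(y - fit@fitted))
        bic[i] <- n * log(max(mar, 1e-300)) +
            log(n) * length(fit@support)
        supSize[i] <- length(fit@support)
    }
    if (supSize[length(grid)] == 0)
        warning("all-zero solution at the smallest lambda: ",
                "penalty grid may be too coarse/high", call. = FALSE)
    best <- which.min(bic)  # first index = largest lambda on ties
    structure(grid[best], bic = stats::setNames(bic, signif(grid, 6)))
}

#' Step-3 robust sparse fit of risk scores on risk-weighted expression
#'
#' Assembles the design \eqn{z_{ig} = rp_{ig} \cdot x_{ig}} (risk
#' probability times expression) over the screened genes with the risk
#' score as the response, then runs the full robust pipeline:
#' per-feature min-max normalization, center distances, clean-subset
#' selection (fraction 0.6), leverage weights, BIC penalty selection and
#' the SCAD-penalized weighted-LAD solve. Patients flagged degenerate in
#' the risk profile are excluded. The support of the returned fit is this
#' cohort's candidate signature.
#'
#' @param expression expression matrix over the screened genes (genes in
#'   rows, samples in columns), e.g. \code{exprValues(cohort)[genes, ]}.
#' @param profile a \linkS4class{RiskProfile} over the same genes and
#'   samples.
#' @param cfg a \linkS4class{RobustWeightConfig}.
#' @return a \linkS4class{WladScadFit} whose coefficient names are gene
#'   ids.
#' @export
rwsrStep3 <- function(expression, profile, cfg = robustWeightConfig()) {
    stopifnot(methods::is(profile, "RiskProfile"))
    expression <- as.matrix(expression)
    if (!setequal(rownames(expression), profile@geneIds))
        stop("expression rows must be exactly the profile's screened genes")
    expression <- expression[profile@geneIds, profile@sampleIds,
                             drop = FALSE]
    keep <- !profile@degenerate
    if (sum(keep) < 10)
        stop("fewer than 10 usable (non-degenerate) patients")
    x <- t(expression[, keep, drop = FALSE])          # samples x genes
    Z <- profile@rp[keep, , drop = FALSE] * x          # rp-scaled design
    y <- profile@rs[keep]
    Zn <- minmaxNormalize(Z)
    d <- centerDistances(Zn)
    XS <- selectCleanSubset(Zn, d, cfg@subsetFraction)
    omega <- leverageWeights(Zn, XS)
    lam <- selectLambda(Z, y, omega, cfg)
    solvePenalizedWlad(Z, y, omega, as.numeric(lam), cfg)
}
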