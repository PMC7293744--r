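# Independent oracles, deliberately written with naive loops so they share
# no code path with the package internals.

# Brute-force Breslow partial log-likelihood: enumerate risk sets explicitly.
bruteLoglik <- function(time, event, lp) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- which(time >= t)
        evHere <- which(time == t & event == 1)
        ll <- ll + sum(lp[evHere]) -
            length(evHere) * log(sum(exp(lp[atRisk])))
    }
    ll
}

# Dense grid-search maximizer of the brute-force partial likelihood for a
# single covariate, beta in [-5, 5] step 1e-4 (vectorized over the grid).
gridFitCox <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
    grid <- seq(lo, hi, by = step)
    ll <- grid * sum(x[event == 1])
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- which(time >= t)
        d <- sum(time == t & event == 1)
        ll <- ll - d * log(rowSums(exp(outer(grid, x[atRisk]))))
    }
    grid[which.max(ll)]
}

# Exact weighted-LAD optimum by vertex enumeration: some optimum of the LP
# interpolates p data points, so enumerate all full-rank p-subsets.
ladEnumOracle <- function(Z, y, w = rep(1, nrow(Z))) {
    p <- ncol(Z)
    best <- sum(w * abs(y))  # gamma = 0 reference
    for (rows in utils::combn(nrow(Z), p, simplify = FALSE)) {
        Zr <- Z[rows, , drop = FALSE]
        if (abs(det(Zr)) < 1e-12) next
        g <- solve(Zr, y[rows])
        obj <- sum(w * abs(y - as.vector(Z %*% g)))
        if (obj < best) best <- obj
    }
    best
}

# Hand-coded product-limit estimator.
kmRef <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- 1
    surv <- numeric(length(ts))
    for (i in seq_along(ts)) {
        n <- sum(time >= ts[i])
        d <- sum(time == ts[i] & event == 1)
        s <- s * (1 - d / n)
        surv[i] <- s
    }
    list(times = ts, survival = surv)
}

# Hand-enumerated two-group log-rank: per event time, a 2x2 risk table with
# hypergeometric variance.
logrankRef <- function(time, event, group) {
    g1 <- group == unique(group)[1]
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
        n <- sum(time >= t)
        n1 <- sum(time >= t & g1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    chi2 <- (O - E)^2 / V
    list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Second, independently coded implementation of the generative survival
# model (per-subject loops; survival::coxph for the per-gene log-HR).
refSimulate <- function(n, betas, h0, horizon, mu, sd, seed) {
    set.seed(seed)
    p <- length(betas)
    x <- matrix(NA_real_, p, n)
    for (g in seq_len(p)) x[g, ] <- rnorm(n, mu, sd)
    time <- numeric(n); event <- numeric(n)
    for (i in seq_len(n)) {
        eta <- sum(betas * x[, i])
        tDeath <- -log(runif(1)) / (h0 * exp(eta))
        tCens <- runif(1, 0, horizon)
        time[i] <- min(tDeath, tCens)
        event[i] <- as.numeric(tDeath <= tCens)
    }
    list(x = x, time = time, event = event)
}

# Small random censored survival instance for oracle comparisons.
randomSurvInstance <- function(n, seed, tieProb = 0.3) {
    set.seed(seed)
    x <- rnorm(n)
    time <- rexp(n, exp(0.3 * x))
    if (runif(1) < tieProb) time <- ceiling(time * 4) / 4  # induce ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[sample.int(n, 1)] <- 1
    list(x = x, time = time, event = event)
}
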