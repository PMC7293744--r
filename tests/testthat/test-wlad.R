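test_that("min-max normalization maps every feature onto [0,1]", {
    expect_equal(as.vector(minmaxNormalize(cbind(c(2, 4, 6)))),
                 c(0, 0.5, 1))
    x <- cbind(c(0, 0.3, 1))
    expect_equal(minmaxNormalize(x), x)
    set.seed(1)
    m <- minmaxNormalize(matrix(rnorm(50), 10, 5))
    expect_equal(unname(apply(m, 2, min)), rep(0, 5))
    expect_equal(unname(apply(m, 2, max)), rep(1, 5))
    expect_error(minmaxNormalize(cbind(1:3, rep(2, 3))), "constant")
})

test_that("center distances measure departure from the median sample", {
    x <- rbind(c(0, 0), c(1, 1), c(0, 1))
    d <- centerDistances(x)
    expect_equal(d, c(1, 1, 0))  # median vector is (0, 1)
    set.seed(2)
    m <- matrix(runif(60), 12, 5)
    med <- apply(m, 2, median)
    naive <- numeric(12)
    for (i in 1:12) naive[i] <- sqrt(sum((m[i, ] - med)^2))
    expect_equal(centerDistances(m), naive, tolerance = 1e-12)
    expect_error(centerDistances(matrix(0, 0, 3)), "empty")
})

test_that("clean subset keeps the floor(fraction n) closest rows", {
    set.seed(3)
    m <- matrix(runif(50), 10, 5)
    d <- centerDistances(minmaxNormalize(m))
    expect_identical(nrow(selectCleanSubset(m, d, 0.6)), 6L)
    # ties: first rows by index
    same <- selectCleanSubset(m, rep(1, 10), 0.6)
    expect_identical(same, m[1:6, ])
    # hand ordering
    m5 <- matrix(1:25, 5, 5)
    expect_warning(sel <- selectCleanSubset(m5, c(5, 1, 3, 2, 4), 0.6),
                   "singular")
    expect_identical(sel, m5[c(2, 4, 3), ])
})

test_that("leverage weights live in (0,1] and hit 1 at minimum leverage", {
    # identical rows: full symmetry, all weights 1
    xEq <- matrix(1, 8, 3) + 0  # constant design, singular Gram
    w <- leverageWeights(xEq, xEq[1:4, , drop = FALSE])
    expect_equal(w, rep(1, 8))
    set.seed(4)
    for (rep in 1:25) {
        n <- sample(10:30, 1); p <- sample(2:4, 1)
        x <- matrix(rnorm(n * p), n, p)
        d <- centerDistances(x)
        xs <- selectCleanSubset(x, d, 0.6)
        w <- leverageWeights(x, xs)
        expect_true(all(w > 0 & w <= 1 + 1e-12))
        expect_equal(max(w), 1)
        # algebraic equivalence: h via explicit inverse
        G <- solve(crossprod(xs))
        h <- diag(x %*% G %*% t(x))
        expect_equal(w, min(h) / h, tolerance = 1e-10)
    }
    # a gross outlier gets the strict minimum weight
    x <- matrix(rnorm(20 * 3), 20, 3)
    x[7, ] <- x[7, ] * 50
    d <- centerDistances(minmaxNormalize(x))
    xs <- selectCleanSubset(minmaxNormalize(x), d, 0.6)
    w <- leverageWeights(minmaxNormalize(x), xs)
    expect_identical(which.min(w), 7L)
    expect_true(all(w[-7] > w[7]))
})

test_that("weights are invariant to a global scaling of the design", {
    set.seed(5)
    x <- matrix(rnorm(60), 20, 3)
    d <- centerDistances(x)
    xs <- selectCleanSubset(x, d, 0.6)
    w1 <- leverageWeights(x, xs)
    w2 <- leverageWeights(3 * x, 3 * xs)
    expect_equal(w1, w2, tolerance = 1e-8)
})

test_that("SCAD penalty obeys its closed-form regions", {
    a <- 3.7; lam <- 0.5
    expect_identical(scadPenalty(0, lam, a), 0)
    expect_equal(scadPenalty(2 * lam * a, lam, a), (a + 1) * lam^2 / 2)
    expect_identical(scadDerivative(2 * lam * a, lam, a), 0)
    expect_equal(scadDerivative(lam / 2, lam, a), lam)
    expect_equal(scadDerivative(2 * lam, lam, a),
                 (a * lam - 2 * lam) / (a - 1))
    expect_error(scadPenalty(1, lam, a = 2), "exceed 2")
    # symmetric in theta
    th <- seq(-3, 3, by = 0.1)
    expect_equal(scadPenalty(th, lam, a), scadPenalty(-th, lam, a))
    # fundamental theorem: integral of the derivative rebuilds the penalty
    for (theta in c(0.2, 0.5, 1, 2, 3.5)) {
        intg <- stats::integrate(function(t) scadDerivative(t, lam, a),
                                 0, theta, rel.tol = 1e-10)$value
        expect_equal(intg, scadPenalty(theta, lam, a), tolerance = 1e-6)
    }
})

test_that("the inner weighted-LAD solver attains the LP vertex optimum", {
    set.seed(6)
    for (rep in 1:15) {
        n <- sample(10:25, 1); p <- sample(1:3, 1)
        Z <- matrix(rnorm(n * p), n, p)
        y <- as.vector(Z %*% rnorm(p)) + rnorm(n, sd = 0.5)
        w <- runif(n, 0.3, 1); w <- w / max(w)
        fit <- solvePenalizedWlad(Z, y, w, 0)
        obj <- sum(w * abs(y - fit@fitted))
        expect_lt(obj - ladEnumOracle(Z, y, w), 1e-6)
    }
})

test_that("noiseless data are interpolated when the penalty vanishes", {
    set.seed(7)
    Z <- matrix(rnorm(40 * 3), 40, 3)
    gTrue <- c(1.5, -2, 0.7)
    y <- as.vector(Z %*% gTrue)
    fit <- solvePenalizedWlad(Z, y, rep(1, 40), 0)
    expect_equal(unname(coef(fit)), gTrue, tolerance = 1e-4)
})

test_that("a penalty above lambda_max shrinks everything to zero", {
    set.seed(8)
    Z <- matrix(rnorm(30 * 4), 30, 4)
    y <- as.vector(Z %*% c(1, 0, 0.5, 0)) + rnorm(30, sd = 0.1)
    lamMax <- max(abs(crossprod(Z, y))) / 30
    fit <- solvePenalizedWlad(Z, y, rep(1, 30), 10 * lamMax)
    expect_identical(unname(coef(fit)), rep(0, 4))
    expect_identical(fit@support, character(0))
})

test_that("the exact SCAD objective never increases across LLA steps", {
    set.seed(9)
    for (rep in 1:10) {
        n <- 40; p <- 6
        Z <- matrix(rnorm(n * p), n, p)
        y <- as.vector(Z %*% c(2, -1.5, rep(0, p - 2))) + rnorm(n, sd = 0.3)
        w <- runif(n, 0.4, 1); w <- w / max(w)
        for (lam in c(0.02, 0.1, 0.4)) {
            fit <- solvePenalizedWlad(Z, y, w, lam)
            expect_true(all(diff(fit@objectiveTrace) <= 1e-8))
        }
    }
})

test_that("BIC lambda selection recovers a planted sparse support", {
    set.seed(10)
    n <- 200; p <- 50
    Z <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("z%d", 1:p)))
    gTrue <- c(2, -1.5, 1, rep(0, p - 3))
    y <- as.vector(Z %*% gTrue) + rnorm(n, sd = 0.1)
    w <- rep(1, n)
    lam <- selectLambda(Z, y, w)
    fit <- solvePenalizedWlad(Z, y, w, as.numeric(lam))
    expect_identical(fit@support, colnames(Z)[1:3])
    # grid-order invariance
    cfgRev <- robustWeightConfig(lambdaGrid = rev(c(0.01, 0.05, 0.2)))
    cfgFwd <- robustWeightConfig(lambdaGrid = c(0.01, 0.05, 0.2))
    expect_identical(as.numeric(selectLambda(Z, y, w, cfgRev)),
                     as.numeric(selectLambda(Z, y, w, cfgFwd)))
    # single-element grid
    one <- selectLambda(Z, y, w, robustWeightConfig(lambdaGrid = 0.07))
    expect_identical(as.numeric(one), 0.07)
})

test_that("rwsrStep3 reduces to a univariate fit for one screened gene", {
    co <- simulateCohort(simulationConfig(nSamples = 80, nGenes = 20,
                                          nProtective = 0, nRisky = 1,
                                          betaRisky = 1.5, seed = 12))
    scr <- screenGenes(co, alpha = 0.05)
    tr <- geneTruth(co)
    gSig <- tr$gene_id[tr$role == "risky"]
    prof <- riskProfile(co, scr, genes = gSig)
    # rp of a single screened gene is identically 1
    expect_true(all(riskProbabilities(prof)[!prof@degenerate, 1] == 1))
    fit <- suppressWarnings(
        rwsrStep3(exprValues(co)[gSig, , drop = FALSE], prof))
    expect_identical(names(coef(fit)), gSig)
    expect_identical(fit@support, gSig)
})

test_that("rwsrStep3 is invariant to permuting the patients", {
    co <- simulateCohort(simulationConfig(nSamples = 60, nGenes = 30,
                                          nProtective = 0, nRisky = 3,
                                          seed = 14))
    scr <- screenGenes(co, alpha = 0.05)
    risky <- scr$gene_id[scr$role == "risky"]
    prof <- riskProfile(co, scr, genes = risky)
    fit1 <- rwsrStep3(exprValues(co)[risky, , drop = FALSE], prof)
    set.seed(99)
    perm <- sample(ncol(co))
    coP <- co[, perm]
    scrP <- screenGenes(coP, alpha = 0.05)
    profP <- riskProfile(coP, scrP, genes = risky)
    fitP <- rwsrStep3(exprValues(coP)[risky, , drop = FALSE], profP)
    expect_equal(coef(fit1), coef(fitP), tolerance = 1e-8)
})

test_that("rwsrStep3 refuses underpowered designs", {
    co <- simulateCohort(simulationConfig(nSamples = 8, nGenes = 10,
                                          nProtective = 0, nRisky = 1,
                                          seed = 15))
    scr <- screenGenes(co, alpha = 0.5)
    keep <- scr$gene_id[scr$role != "nonassociated"]
    if (length(keep)) {
        prof <- riskProfile(co, scr, genes = keep)
        expect_error(rwsrStep3(exprValues(co)[keep, , drop = FALSE], prof),
                     "fewer than 10")
    } else succeed()
})
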