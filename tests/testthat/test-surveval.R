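test_that("Kaplan-Meier matches hand product-limit computations", {
    km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km@survival, c(2 / 3, 1 / 3, 0))
    # censoring at 1 and 3, event at 2: S(2) = 1 - 1/2
    km2 <- kaplanMeier(c(1, 2, 3), c(0, 1, 0))
    expect_identical(km2@times, 2)
    expect_equal(km2@survival, 0.5)
    # all censored: flat at 1 (no event times)
    km3 <- kaplanMeier(c(1, 2), c(0, 0))
    expect_identical(length(km3@times), 0L)
    # random censored sample vs hand-coded reference estimator
    set.seed(20)
    time <- round(rexp(200, 0.5), 2) + 0.01
    event <- rbinom(200, 1, 0.6)
    km4 <- kaplanMeier(time, event)
    ref <- kmRef(time, event)
    expect_equal(km4@times, ref$times)
    expect_equal(km4@survival, ref$survival, tolerance = 1e-12)
})

test_that("log-rank test matches the hand O/E/V enumeration", {
    # duplicated groups: exactly no separation
    time <- c(1, 2, 3, 4, 5)
    event <- c(1, 0, 1, 1, 0)
    lr0 <- logrankTest(c(time, time), c(event, event),
                       rep(c("a", "b"), each = 5))
    expect_equal(lr0@chi2, 0, tolerance = 1e-12)
    expect_equal(lr0@pValue, 1, tolerance = 1e-12)
    # n = 6 hand-enumerable table
    t6 <- c(1, 2, 3, 4, 5, 6)
    e6 <- c(1, 1, 0, 1, 1, 1)
    g6 <- c("x", "y", "x", "y", "x", "y")
    lr <- logrankTest(t6, e6, g6)
    ref <- logrankRef(t6, e6, g6)
    expect_equal(lr@chi2, ref$chi2, tolerance = 1e-10)
    expect_equal(lr@pValue, ref$p, tolerance = 1e-10)
    expect_identical(lr@df, 1L)
    expect_error(logrankTest(t6, e6, factor(g6, levels = c("x", "y", "z"))),
                 "zero subjects")
})

test_that("log-rank is invariant to relabeling and monotone time maps", {
    set.seed(21)
    time <- rexp(80, 0.3)
    event <- rbinom(80, 1, 0.7)
    grp <- sample(c("p", "q"), 80, replace = TRUE)
    a <- logrankTest(time, event, grp)
    b <- logrankTest(time, event, ifelse(grp == "p", "q", "p"))
    expect_equal(a@chi2, b@chi2, tolerance = 1e-12)
    c2 <- logrankTest(sqrt(time), event, grp)
    expect_equal(a@chi2, c2@chi2, tolerance = 1e-12)
})

test_that("log-rank separates groups with a real hazard difference", {
    set.seed(22)
    hits <- 0
    for (rep in 1:20) {
        n <- 400
        grp <- rep(0:1, each = n / 2)
        tt <- rexp(n, 0.3 * exp(1 * grp))
        cc <- runif(n, 0, 8)
        lr <- logrankTest(pmin(tt, cc), as.numeric(tt <= cc), grp)
        if (lr@pValue < 0.001) hits <- hits + 1
    }
    expect_gte(hits, 19)
})

test_that("time-dependent AUC honors its oracle identities", {
    # perfect ranking, no censoring
    score <- 1:20
    time <- c(rep(1, 10), rep(5, 10))
    event <- rep(1, 20)
    roc <- timeDependentAuc(-score, time, event, horizon = 2)
    expect_equal(roc@auc, 1)
    # flipping the score flips the AUC
    roc2 <- timeDependentAuc(score, time, event, horizon = 2)
    expect_equal(roc2@auc, 0)
    # AUC equals the trapezoid under its own curve by construction;
    # against an independent trapezoid computation
    set.seed(23)
    s <- rnorm(100); t0 <- rexp(100, 0.5); e <- rbinom(100, 1, 0.8)
    e[which.max(t0)] <- 0  # keep controls past any horizon
    roc3 <- timeDependentAuc(s, t0, e, horizon = median(t0))
    expect_equal(roc3@auc,
                 sum(diff(roc3@fpr) *
                     (head(roc3@tpr, -1) + tail(roc3@tpr, -1)) / 2))
    expect_true(all(diff(roc3@tpr) >= 0) && all(diff(roc3@fpr) >= 0))
    # no censoring before the horizon: reduces exactly to the binary AUC
    set.seed(24)
    n <- 300
    s <- rnorm(n)
    tt <- rexp(n, exp(0.8 * s))
    horizon <- quantile(tt, 0.4)
    ev <- rep(1, n)
    roc4 <- timeDependentAuc(s, tt, ev, horizon)
    lab <- tt <= horizon
    mw <- mean(outer(s[lab], s[!lab], `>`) +
               0.5 * outer(s[lab], s[!lab], `==`))
    expect_equal(roc4@auc, mw, tolerance = 1e-12)
})

test_that("an uninformative score scores an AUC near one half", {
    set.seed(25)
    n <- 2000
    s <- rnorm(n)
    tt <- rexp(n, 0.5)
    roc <- timeDependentAuc(s, tt, rep(1, n), horizon = median(tt))
    expect_lt(abs(roc@auc - 0.5), 0.05)
})

test_that("stratified KM compares risk groups within each stratum", {
    co <- simulateCohort(simulationConfig(nSamples = 200, nGenes = 30,
                                          nProtective = 2, nRisky = 2,
                                          seed = 26))
    tr <- geneTruth(co)
    planted <- tr$gene_id[tr$role != "null"]
    rs <- as.vector(crossprod(exprValues(co)[planted, ],
                              tr$beta[tr$role != "null"]))
    groups <- splitByMedian(rs)
    strata <- splitAge(sampleInfo(co)$age)
    out <- suppressWarnings(
        stratifiedKm(survTime(co), survEvent(co), groups, strata))
    expect_true(length(out) >= 1)
    for (lev in names(out)) {
        expect_s4_class(out[[lev]]$logrank, "LogrankResult")
        expect_true(all(c("low", "high") %in% names(out[[lev]]$curves)))
    }
    # a whole-cohort stratum reproduces the unstratified comparison
    whole <- stratifiedKm(survTime(co), survEvent(co), groups,
                          rep("all", ncol(co)))
    direct <- logrankTest(survTime(co), survEvent(co), groupLabels(groups))
    expect_equal(whole$all$logrank@chi2, direct@chi2, tolerance = 1e-12)
    # single-risk-group strata are skipped with a warning each
    oneSided <- factor(ifelse(groupLabels(groups) == "high", "s1", "s2"))
    expect_warning(expect_warning(
        stratifiedKm(survTime(co), survEvent(co), groups, oneSided),
        "single risk group"), "single risk group")
})

test_that("age splits put the boundary in the lower group", {
    s <- splitAge(c(69, 70, 71))
    expect_identical(as.character(s), c("<=70", "<=70", ">70"))
})

test_that("stage-by-risk grouping is the exact eight-cell bijection", {
    expect_identical(stageRiskGroups("0", "low"), 1L)
    expect_identical(stageRiskGroups("0", "high"), 2L)
    expect_identical(stageRiskGroups("III", "low"), 7L)
    expect_identical(stageRiskGroups("III", "high"), 8L)
    full <- expand.grid(stage = c("0", "I", "II", "III"),
                        risk = c("low", "high"),
                        stringsAsFactors = FALSE)
    idx <- stageRiskGroups(full$stage, full$risk)
    expect_identical(sort(idx), 1:8)
    expect_error(stageRiskGroups("IV", "low"), "outside")
    expect_error(stageRiskGroups("I", "medium"), "low")
})
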