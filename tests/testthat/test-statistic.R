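test_that("recurrence scaling solves the closed-form symmetric case", {
    sc <- scaleToRecurrence(c(a = .05, b = .05, c = .05, d = .05), k = 2)
    expect_identical(unname(scaledProb(sc)), rep(0.5, 4))
    expect_equal(sc@s, log(2) / 0.05, tolerance = 1e-12)
    expect_equal(sum(scaledProb(sc)), 2, tolerance = 1e-6)
})

test_that("scaling matches an independent root-finding oracle", {
    lam <- c(a = 0.1, b = 0.2, c = 0)
    sc <- scaleToRecurrence(lam, k = 1)
    p <- scaledProb(sc)
    expect_identical(unname(p["c"]), 0)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(p["b"] > p["a"])
    # independent oracle: uniroot on the defining equation
    f <- function(s) sum(1 - exp(-s * lam)) - 1
    sOracle <- stats::uniroot(f, c(1e-9, 1e3), tol = 1e-12)$root
    expect_equal(unname(p["a"]), 1 - exp(-sOracle * 0.1), tolerance = 1e-6)
    expect_equal(unname(p["b"]), 1 - exp(-sOracle * 0.2), tolerance = 1e-6)
})

test_that("the scaling residual is tiny on random profiles", {
    set.seed(31)
    for (i in 1:25) {
        n <- sample(5:80, 1)
        lam <- stats::rlnorm(n, meanlog = -2, sdlog = 2)
        names(lam) <- paste0("t", seq_len(n))
        k <- sample.int(n - 1L, 1)
        sc <- scaleToRecurrence(lam, k = k)
        expect_lt(abs(sum(scaledProb(sc)) - k), 1e-6)
    }
})

test_that("scaling is exactly invariant to the overall rate scale", {
    set.seed(32)
    lam <- stats::setNames(stats::rlnorm(40, -1, 2), paste0("t", 1:40))
    a <- scaleToRecurrence(lam, k = 7)
    b <- scaleToRecurrence(10 * lam, k = 7)
    expect_identical(scaledProb(a), scaledProb(b))
    expect_identical(a@logP, b@logP)
    expect_identical(a@logQ, b@logQ)
})

test_that("unreachable and degenerate recurrence targets are rejected", {
    lam <- c(a = 1, b = 1, c = 0)
    expect_error(scaleToRecurrence(lam, k = 3), "unreachable")
    expect_error(scaleToRecurrence(lam, k = 0), ">= 1")
    # saturated: k equals the positive count
    sat <- scaleToRecurrence(lam, k = 2)
    expect_identical(unname(scaledProb(sat)), c(1, 1, 0))
})

test_that("the combination log-likelihood matches hand arithmetic", {
    sc <- scaleToRecurrence(c(a = .05, b = .05, c = .05, d = .05), k = 2)
    expect_equal(setLogLik(c("a", "b"), sc), 4 * log(0.5),
        tolerance = 1e-12)
    # bare probability vector: p = (0.9, 0.1), M = {2}
    expect_equal(setLogLik(2L, c(0.9, 0.1)), log(0.1) + log(0.1),
        tolerance = 1e-12)
    # symmetric profiles: likelihood depends only on |M|
    expect_identical(setLogLik(c("a", "b"), sc), setLogLik(c("c", "d"), sc))
    expect_error(setLogLik("nope", sc), "unknown")
    expect_error(setLogLik("c", scaleToRecurrence(c(a = 1, b = 1, c = 0),
        k = 1)), "zero")
})

test_that("moving a mutated tumour down the profile never decreases D", {
    set.seed(33)
    for (i in 1:20) {
        lam <- stats::setNames(stats::rlnorm(15, -1, 1.5), paste0("t", 1:15))
        sc <- scaleToRecurrence(lam, k = 4)
        p <- scaledProb(sc)
        ord <- order(p)
        lowest <- names(p)[ord[1]]
        highest <- names(p)[ord[15]]
        others <- names(p)[ord[7:9]]
        D1 <- -setLogLik(c(others, highest), sc)
        D2 <- -setLogLik(c(others, lowest), sc)
        expect_gte(D2, D1)
    }
})

test_that("both null laws draw uniformly over symmetric profiles", {
    sc <- scaleToRecurrence(c(a = .05, b = .05, c = .05, d = .05), k = 2)
    for (law in c("conditional", "sequential")) {
        ens <- simulateNull(sc, nSim = 60000L, seed = 51, law = law)
        expect_identical(dim(ens@sets), c(2L, 60000L))
        # the sequential law reports sets in draw order; compare as sets
        key <- paste(pmin(ens@sets[1, ], ens@sets[2, ]),
            pmax(ens@sets[1, ], ens@sets[2, ]))
        freq <- table(key) / 60000
        expect_identical(length(freq), 6L)
        se <- sqrt((1 / 6) * (5 / 6) / 60000)
        expect_true(all(abs(freq - 1 / 6) < 3 * se))
        # symmetric profile: D constant across sets
        expect_lt(diff(range(ens@D)), 1e-12)
    }
})

test_that("forced and near-degenerate draws behave as limits", {
    # k equals the number of positive-probability tumours
    sat <- scaleToRecurrence(c(a = 1, b = 1, c = 0), k = 2)
    ens <- simulateNull(sat, nSim = 50L, seed = 52)
    expect_true(all(ens@sets == c(1L, 2L)))
    expect_identical(unique(ens@D), 0)
    # two dominant weights: subset {1,2} almost surely
    sc <- scaleToRecurrence(c(a = 1, b = 1, c = 1e-9, d = 1e-9), k = 2)
    for (law in c("conditional", "sequential")) {
        e2 <- simulateNull(sc, nSim = 2000L, seed = 53, law = law)
        frac12 <- mean(colSums(e2@sets <= 2L) == 2L)
        expect_gt(frac12, 0.99)
    }
})

test_that("null simulation is reproducible and restores the RNG", {
    sc <- scaleToRecurrence(stats::setNames(stats::rgamma(20, 1),
        paste0("t", 1:20)), k = 5)
    set.seed(99)
    before <- stats::runif(1)
    set.seed(99)
    ens1 <- simulateNull(sc, nSim = 100L, seed = 7)
    after <- stats::runif(1)
    expect_identical(before, after)        # caller's stream untouched
    ens2 <- simulateNull(sc, nSim = 100L, seed = 7)
    expect_identical(ens1@sets, ens2@sets)
    expect_identical(ens1@D, ens2@D)
    expect_identical(ens1@law, "conditional")
})

test_that("the conditional sampler realises the conditional-Bernoulli law", {
    set.seed(34)
    lam <- stats::setNames(exp(stats::runif(8, -4, 1)), letters[1:8])
    sc <- scaleToRecurrence(lam, k = 3)
    nSim <- 60000L
    ens <- simulateNull(sc, nSim = nSim, seed = 54, law = "conditional")
    # exact law: P(M) proportional to the product of member odds
    subs <- utils::combn(8, 3)
    lw <- sc@logP - sc@logQ
    lsub <- colSums(matrix(lw[subs], nrow = 3))
    pr <- exp(lsub - max(lsub)); pr <- pr / sum(pr)
    names(pr) <- apply(subs, 2, paste, collapse = ",")
    key <- apply(ens@sets, 2, paste, collapse = ",")
    cnt <- as.numeric(table(factor(key, levels = names(pr))))
    keep <- pr * nSim >= 5
    chi <- sum((cnt[keep] - nSim * pr[keep])^2 / (nSim * pr[keep]))
    # chi-square upper 0.001 quantile as the sanity bound
    expect_lt(chi, stats::qchisq(0.999, df = sum(keep) - 1))
})

test_that("gamma tails degrade gracefully and match known distributions", {
    # degenerate ensemble: fallback to the empirical p
    res <- gammaTailP(rep(3.2, 1000), 3.2)
    expect_identical(res$method, "empirical")
    expect_true("degenerate_null" %in% res$flags)
    expect_identical(res$p, 1)
    # D_obs below the minimum: empirical p is 1, gamma tail larger there
    set.seed(35)
    D <- stats::rgamma(5000, shape = 3, scale = 2)
    low <- gammaTailP(D, min(D) - 1)
    expect_identical(low$pEmpirical, 1)
    expect_true(low$pGamma > stats::pgamma(min(D), 3, scale = 2,
        lower.tail = FALSE) - 0.05)
    # self-consistency at the true 95th percentile
    fit <- gammaTailP(stats::rgamma(10000, shape = 3, scale = 2),
        stats::qgamma(0.95, shape = 3, scale = 2))
    expect_identical(fit$method, "gamma")
    expect_lt(abs(fit$p - 0.05), 0.01)
})

test_that("the empirical p-value follows its defining formula", {
    D <- c(1, 2, 3, 4, 5)
    expect_identical(gammaTailP(D, 3)$pEmpirical, (1 + 3) / 6)
    expect_identical(gammaTailP(D, 10)$pEmpirical, 1 / 6)
    expect_identical(gammaTailP(D, 0)$pEmpirical, 1)
    expect_error(gammaTailP(numeric(0), 1), "empty")
})

test_that("exact enumeration handles the forced and symmetric cases", {
    sym <- scaleToRecurrence(c(a = .05, b = .05, c = .05, d = .05), k = 2)
    Dsym <- -setLogLik(c("a", "b"), sym)
    expect_equal(exactSubsetP(sym, Dsym), 1, tolerance = 1e-9)
    pair <- scaleToRecurrence(c(a = 1, b = 2), k = 2)
    expect_identical(exactSubsetP(pair, 123), 1)
    big <- scaleToRecurrence(stats::setNames(stats::rgamma(40, 1),
        paste0("t", 1:40)), k = 15)
    expect_error(exactSubsetP(big, 1), "too many")
})

test_that("enumeration probabilities sum to one under both laws", {
    set.seed(36)
    lam <- stats::setNames(exp(stats::runif(9, -3, 1)), letters[1:9])
    sc <- scaleToRecurrence(lam, k = 3)
    for (law in c("conditional", "sequential"))
        expect_equal(exactSubsetP(sc, -Inf, law = law), 1,
            tolerance = 1e-9)
})

test_that("Monte-Carlo and enumeration agree for each law", {
    set.seed(37)
    lam <- stats::setNames(exp(stats::runif(9, -3, 1)), letters[1:9])
    sc <- scaleToRecurrence(lam, k = 3)
    Dobs <- -setLogLik(names(sort(scaledProb(sc)))[1:3], sc)
    nSim <- 40000L
    for (law in c("conditional", "sequential")) {
        pExact <- exactSubsetP(sc, Dobs, law = law)
        ens <- simulateNull(sc, nSim = nSim, seed = 55, law = law)
        pEmp <- gammaTailP(ens, Dobs)$pEmpirical
        se <- sqrt(pExact * (1 - pExact) / nSim)
        expect_lt(abs(pEmp - pExact), 3 * se + 1 / (nSim + 1))
    }
})

test_that("the frequency statistic is a Poisson upper tail", {
    prof <- new("RegionProfile", regionId = "r",
        lambda = c(T1 = 1.5, T2 = 1.5), mutatedSamples = c("T1", "T2"),
        nMutations = 3L)
    fs <- frequencyStatistic(prof)
    expect_identical(fs$observed, 3L)
    expect_identical(fs$expected, 3)
    expect_equal(fs$p, 1 - stats::ppois(2, 3), tolerance = 1e-9)
    expect_equal(fs$p, 0.57681, tolerance = 1e-5)
    prof0 <- new("RegionProfile", regionId = "r",
        lambda = c(T1 = 1.5, T2 = 1.5), mutatedSamples = character(0),
        nMutations = 0L)
    expect_identical(frequencyStatistic(prof0)$p, 1)
    # monotone decreasing in the observed count
    ps <- vapply(1:10, function(k) {
        pr <- new("RegionProfile", regionId = "r",
            lambda = c(T1 = 1.5, T2 = 1.5),
            mutatedSamples = "T1", nMutations = as.integer(k))
        frequencyStatistic(pr)$p
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
})
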