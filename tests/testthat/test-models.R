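test_that("WGS models divide per-tumour counts by context territory", {
    m <- mutRecords("T1", 5, "C", "T",
        channel = match("A[C>T]A", mutationChannels()))
    terr <- makeTerritory(c(ACA = 50))
    mod <- buildWgsModels(m, terr, samples = c("T1", "T2"))
    r <- mutationRates(mod)
    expect_identical(unname(r["T1", "A[C>T]A"]), 1 / 50)
    expect_identical(sum(r["T1", ]), 1 / 50)      # all other channels 0
    expect_identical(sum(r["T2", ]), 0)           # no mutations, zero model
    expect_identical(unname(tumourBurdens(mod)), c(1, 0))
    # linearity: doubling counts doubles rates
    mod2 <- buildWgsModels(rbind(m, m), terr, samples = "T1")
    expect_identical(mutationRates(mod2)["T1", ],
        2 * mutationRates(mod)["T1", ])
})

test_that("WGS reconstruction conserves each tumour's burden", {
    set.seed(21)
    spec <- fixtureSpec(nTumours = 20L, burdenRange = c(10, 200),
        nGenes = 5L, geneLength = 60L, intergenic = 300L)
    fx <- generateCohortFixture(spec, seed = 5L)
    terr <- countTerritory(fx$genome)
    mod <- buildWgsModels(fx$mutations, terr)
    recon <- as.vector(mutationRates(mod) %*%
        as.numeric(terr)[channelContext()])
    expect_equal(recon, unname(tumourBurdens(mod)), tolerance = 1e-9)
})

test_that("mutations in a zero-territory context are rejected", {
    m <- mutRecords("T1", 5, "C", "T",
        channel = match("A[C>T]A", mutationChannels()))
    terr <- makeTerritory(c(ACA = 0))
    expect_error(buildWgsModels(m, terr), "zero territory")
    expect_error(buildWgsModels(m, rep(1, 10)), "32-context")
})

test_that("WXS models share a cohort signature scaled by burden", {
    ch <- match(c("A[C>T]A", "C[T>G]G"), mutationChannels())
    m <- rbind(
        mutRecords(rep("T1", 30), 1:30, "C", "T", channel = ch[1]),
        mutRecords(rep("T2", 10), 1:10, "C", "T", channel = ch[2]))
    terr <- makeTerritory(c(ACA = 100, CTG = 100))
    mod <- buildWxsModels(m, terr)
    r <- mutationRates(mod)
    cohortRate <- colSums(r)
    expect_identical(unname(cohortRate[ch[1]]), 30 / 100)
    expect_identical(unname(cohortRate[ch[2]]), 10 / 100)
    # burdens 30 and 10: tumour shares 0.75 and 0.25 of the cohort vector
    expect_equal(r["T1", ch], 0.75 * cohortRate[ch], ignore_attr = TRUE)
    expect_equal(r["T2", ch], 0.25 * cohortRate[ch], ignore_attr = TRUE)
})

test_that("a single-tumour WXS cohort degenerates to the WGS model", {
    set.seed(22)
    spec <- fixtureSpec(nTumours = 1L, burdenRange = c(50, 50), nGenes = 3L,
        geneLength = 60L, intergenic = 200L)
    fx <- generateCohortFixture(spec, seed = 6L)
    terr <- countTerritory(fx$genome)
    expect_equal(mutationRates(buildWxsModels(fx$mutations, terr)),
        mutationRates(buildWgsModels(fx$mutations, terr)))
})

test_that("per-cancer-type scopes isolate each type's signature", {
    chA <- match("A[C>T]A", mutationChannels())
    chB <- match("C[T>G]G", mutationChannels())
    m <- rbind(
        mutRecords(rep("T1", 10), 1:10, "C", "T", channel = chA),
        mutRecords(rep("T2", 10), 1:10, "C", "T", channel = chA),
        mutRecords(rep("T3", 20), 1:20, "C", "T", channel = chB))
    m$cancer_type <- rep(c("mel", "mel", "luad"), c(10, 10, 20))
    terr <- makeTerritory(c(ACA = 100, CTG = 100))
    mod <- buildWxsModels(m, terr)
    r <- mutationRates(mod)
    # a melanoma tumour's rates carry no lung signal and vice versa
    expect_identical(unname(r["T1", chB]), 0)
    expect_identical(unname(r["T3", chA]), 0)
    expect_identical(unname(r["T3", chB]), 20 / 100)
    expect_error(
        buildWxsModels(m, terr, samples = c("T1", "T2", "T3", "T4"),
            cancerType = c(T1 = "mel", T2 = "mel", T3 = "luad")),
        "label")
})

test_that("region profiles apply the model to the qualifying changes", {
    # 10 qualifying changes of one channel with per-site rate 0.02
    ch <- match("A[C>T]A", mutationChannels())
    changes <- data.frame(pos = 1:10, alt = "T", channel = ch,
        effect = "noncoding", stringsAsFactors = FALSE)
    rates <- matrix(0, 2, 96, dimnames = list(c("T1", "T2"),
        mutationChannels()))
    rates["T1", ch] <- 0.02
    mod <- new("TumourModels", rates = rates, burden = c(T1 = 1, T2 = 0),
        mode = "wgs", scope = c(T1 = "T1", T2 = "T2"),
        territory = makeTerritory(c(ACA = 50)))
    rs <- cdsRegion(1, 12, kind = "interval")
    obs <- mutRecords("T1", 3, "C", "T", channel = ch)
    prof <- regionProfile(rs, mod, changes, obs)
    lam <- expectedMutations(prof)
    expect_equal(unname(lam["T1"]), 0.2)
    expect_identical(unname(lam["T2"]), 0)
    p <- mutationProb(prof)
    expect_equal(unname(p["T1"]), 1 - exp(-0.2))
    expect_identical(unname(p["T2"]), 0)
    expect_identical(mutatedSamples(prof), "T1")
    # multiple mutations in one tumour still count once for membership
    obs2 <- rbind(obs, mutRecords("T1", 5, "C", "T", channel = ch))
    prof2 <- regionProfile(rs, mod, changes, obs2)
    expect_identical(mutatedSamples(prof2), "T1")
    expect_identical(prof2@nMutations, 2L)
    # observed mutations not matching a qualifying (pos, alt) are ignored
    obs3 <- mutRecords("T1", 11, "C", "T", channel = ch)
    expect_identical(mutatedSamples(regionProfile(rs, mod, changes, obs3)),
        character(0))
})

test_that("lambda is monotone in the qualifying change set and burden", {
    set.seed(23)
    spec <- fixtureSpec(nTumours = 30L, burdenRange = c(20, 400),
        nGenes = 4L, geneLength = 90L, intergenic = 400L)
    fx <- generateCohortFixture(spec, seed = 7L)
    terr <- countTerritory(fx$genome, fx$regions)
    mod <- buildWxsModels(fx$mutations, terr)
    rs <- fx$regions["gene001"]
    ch <- enumerateQualifyingChanges(rs, fx$genome)
    prof <- regionProfile(rs, mod, ch, fx$mutations)
    profLess <- regionProfile(rs, mod, ch[-1, ], fx$mutations)
    expect_true(all(expectedMutations(profLess) <=
        expectedMutations(prof)))
    # WXS amplitude: lambda ratios equal burden ratios within a scope
    lam <- expectedMutations(prof)
    B <- tumourBurdens(mod)
    nz <- lam > 0 & B > 0
    expect_equal(unname(lam[nz] / lam[nz][1]),
        unname(B[nz] / B[nz][1]), tolerance = 1e-12)
})

test_that("the cohort signature sums tumour rates and normalises", {
    ch <- match("A[C>T]A", mutationChannels())
    m <- mutRecords(rep("T1", 4), 1:4, "C", "T", channel = ch)
    terr <- makeTerritory(c(ACA = 100))
    mod <- buildWxsModels(m, terr)
    sig <- cohortSignature(mod)
    expect_identical(unname(sig[ch]), 1)
    expect_identical(sum(sig), 1)
    expect_identical(unname(cohortSignature(mod, normalize = FALSE)[ch]),
        4 / 100)
})
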