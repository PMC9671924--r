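test_that("synthetic genomes have the requested gene layout", {
    spec <- fixtureSpec(nTumours = 10L, nGenes = 10L, geneLength = 300L,
        intergenic = 500L)
    gg <- generateGenome(spec, seed = 71L)
    expect_identical(length(gg$regions), 10L)
    expect_identical(nchar(gg$genome[[1]]), 10L * 800L + 500L)
    ids <- regionIds(gg$regions)
    expect_identical(ids, sprintf("gene%03d", 1:10))
    widths <- vapply(ids, function(id)
        sum(GenomicRanges::width(regionBlocks(gg$regions)[[id]])),
        integer(1))
    expect_true(all(widths == 300L))
    expect_true(all(widths %% 3L == 0L))
    strands <- vapply(ids, function(id)
        as.character(GenomicRanges::strand(
            regionBlocks(gg$regions)[[id]]))[1], character(1))
    expect_identical(unname(strands), rep(c("+", "-"), 5))
    # determinism
    gg2 <- generateGenome(spec, seed = 71L)
    expect_identical(gg$genome, gg2$genome)
})

test_that("signature presets are normalised and concentrate UV mass", {
    u <- signatureWeights("uniform")
    expect_equal(sum(u), 1, tolerance = 1e-12)
    expect_identical(unname(u), rep(1 / 96, 96))
    uv <- signatureWeights("uv", uvFraction = 0.8)
    expect_equal(sum(uv), 1, tolerance = 1e-12)
    isUv <- grepl("^[CT]\\[C>T\\]", mutationChannels())
    expect_identical(sum(isUv), 8L)
    expect_equal(sum(uv[isUv]), 0.8, tolerance = 1e-12)
})

test_that("neutral cohorts match their burdens and the reference", {
    spec <- fixtureSpec(nTumours = 20L, burdenRange = c(10, 200),
        nGenes = 5L, geneLength = 60L, intergenic = 400L)
    gg <- generateGenome(spec, seed = 72L)
    muts <- generateNeutralCohort(gg$genome, spec, seed = 73L)
    burdens <- attr(muts, "burdens")
    expect_identical(as.vector(table(factor(muts$sample,
        levels = names(burdens)))), as.integer(unname(burdens)))
    # every record validates against the genome without drops
    reval <- suppressMessages(validateMutations(
        muts[c("sample", "contig", "pos", "ref", "alt", "cancer_type")],
        gg$genome))
    expect_identical(nrow(reval), nrow(muts))
    expect_identical(reval$channel, muts$channel)
    # positions unique within each tumour
    expect_false(any(vapply(split(muts$pos, muts$sample),
        function(p) anyDuplicated(p) > 0, logical(1))))
})

test_that("the UV preset produces mostly dipyrimidine C>T mutations", {
    spec <- fixtureSpec(nTumours = 30L, burdenRange = c(100, 400),
        signature = "uv", uvFraction = 0.8, nGenes = 5L, geneLength = 60L,
        intergenic = 600L)
    gg <- generateGenome(spec, seed = 74L)
    muts <- generateNeutralCohort(gg$genome, spec, seed = 75L)
    isUv <- grepl("^[CT]\\[C>T\\]", mutationChannels())
    frac <- mean(isUv[muts$channel])
    # the site-availability correction perturbs the target fraction only
    # mildly on a uniform-composition genome
    expect_gt(frac, 0.7)
})

test_that("neutral per-gene counts track tumour burden", {
    spec <- fixtureSpec(nTumours = 200L, burdenRange = c(20, 2000),
        nGenes = 40L, geneLength = 300L, intergenic = 1000L)
    fx <- generateCohortFixture(spec, seed = 76L)
    genic <- unlist(lapply(regionIds(fx$regions), function(id) {
        b <- regionBlocks(fx$regions)[[id]]
        seq.int(GenomicRanges::start(b), GenomicRanges::end(b))
    }), use.names = FALSE)
    perTumour <- vapply(names(fx$burdens), function(s)
        sum(fx$mutations$sample == s & fx$mutations$pos %in% genic),
        numeric(1))
    ct <- stats::cor.test(perTumour, unname(fx$burdens),
        method = "spearman", exact = FALSE, alternative = "greater")
    expect_lt(ct$p.value, 0.01)
})

test_that("driver injection ignores burden and passes the effect filter", {
    spec <- fixtureSpec(nTumours = 25L, burdenRange = c(10, 100),
        nGenes = 4L, geneLength = 90L, intergenic = 300L)
    gg <- generateGenome(spec, seed = 77L)
    samples <- sprintf("T%03d", 1:25)
    rs <- gg$regions["gene002"]
    add <- injectDriver(gg$genome, rs, samples, kd = 10L, seed = 78L)
    expect_identical(nrow(add), 10L)
    expect_identical(anyDuplicated(add$sample), 0L)
    kept <- filterMutationsByEffect(add, rs, gg$genome)
    expect_identical(nrow(kept), 10L)
    # saturation and empty cases
    expect_identical(nrow(injectDriver(gg$genome, rs, samples,
        kd = 25L, seed = 79L)), 25L)
    expect_identical(nrow(injectDriver(gg$genome, rs, samples, kd = 0L)), 0L)
})

test_that("complete fixtures carry a consistent truth table", {
    spec <- fixtureSpec(nTumours = 30L, burdenRange = c(10, 100),
        nGenes = 8L, geneLength = 90L, intergenic = 300L, nDrivers = 2L,
        driverRecurrence = 6L)
    fx <- generateCohortFixture(spec, seed = 80L)
    expect_identical(sum(fx$truth$driver), 2L)
    expect_identical(unique(fx$truth$kd[fx$truth$driver]), 6L)
    expect_identical(fx$truth$region_id, regionIds(fx$regions))
    fx2 <- generateCohortFixture(spec, seed = 80L)
    expect_identical(fx$mutations, fx2$mutations)
    expect_identical(fx$genome, fx2$genome)
})

test_that("fixtures round-trip through their on-disk formats", {
    spec <- fixtureSpec(nTumours = 8L, burdenRange = c(5, 40), nGenes = 4L,
        geneLength = 60L, intergenic = 200L, nDrivers = 1L,
        driverRecurrence = 3L)
    fx <- generateCohortFixture(spec, seed = 81L)
    dir <- tempfile("fixture")
    paths <- writeFixture(fx, dir)
    g <- readGenome(paths[["genome"]])
    expect_identical(as.character(g[[1]]), unname(fx$genome))
    rs <- readBed12Regions(paths[["regions"]], kind = "cds")
    expect_identical(regionIds(rs), regionIds(fx$regions))
    muts <- suppressMessages(readMutationTable(paths[["mutations"]], g))
    expect_identical(nrow(muts), nrow(fx$mutations))
    truth <- utils::read.delim(paths[["truth"]])
    expect_identical(truth$region_id, fx$truth$region_id)
    unlink(dir, recursive = TRUE)
})
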