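# End-to-end orchestration: cohort QC filters, per-region testing,
# multiple-testing correction, CMT plot series.

#' Remove dominant and hypermutated tumours
#'
#' Applies the cohort-level tumour filters in a single pass against the
#' original totals: a tumour is removed if it contains at least
#' \code{hyperFraction} of all mutations in its scope (default 10\%), or —
#' when \code{hypermutatorAbsolute} is set — if its burden reaches that
#' absolute count (e.g. 2000 exome SNVs). The fraction rule is not
#' iterated after removals.
#'
#' @param mutations typed mutation data.frame.
#' @param hyperFraction fraction-of-cohort threshold (default 0.10).
#' @param hypermutatorAbsolute optional absolute burden threshold.
#' @param scope optional named character vector (by sample) partitioning
#'   the cohort; the fraction rule is then evaluated within each scope
#'   (used for per-cancer-type analyses).
#' @return List with \code{mutations} (retained records) and \code{report}
#'   (data.frame: sample, burden, removed, reason). Removing every tumour
#'   is an error.
#' @examples
#' m <- data.frame(sample = rep(c("a", "b", "c"), c(5, 5, 90)),
#'     contig = "chr1", pos = 1L, ref = "C", alt = "T", channel = 1L)
#' applyCohortFilters(m)$report
#' @export
applyCohortFilters <- function(mutations, hyperFraction = 0.10,
        hypermutatorAbsolute = NULL, scope = NULL) {
    stopifnot(hyperFraction > 0)
    burden <- table(mutations$sample)
    samples <- names(burden)
    burden <- as.integer(burden)
    if (is.null(scope)) {
        sc <- rep("cohort", length(samples))
    } else {
        sc <- as.character(scope[samples])
        sc[is.na(sc)] <- "cohort"
    }
    total <- tapply(burden, sc, sum)[sc]
    removed <- burden >= hyperFraction * total
    reason <- ifelse(removed, "fraction", "")
    if (!is.null(hypermutatorAbsolute)) {
        stopifnot(hypermutatorAbsolute > 0)
        hyper <- burden >= hypermutatorAbsolute
        reason[hyper] <- ifelse(removed[hyper], "fraction+hypermutator",
            "hypermutator")
        removed <- removed | hyper
    }
    if (all(removed)) stop("all tumours removed by cohort filters")
    report <- data.frame(sample = samples, burden = burden,
        removed = removed, reason = reason, stringsAsFactors = FALSE)
    list(mutations = mutations[!mutations$sample %in% samples[removed], ,
            drop = FALSE],
        report = report)
}

#' Select regions with enough qualifying mutations
#'
#' Restricts testing to regions with at least \code{minMutations} observed
#' qualifying (effect-filtered) mutations — by default 3 — and aborts the
#' whole cohort run when fewer than \code{minRegions} regions qualify,
#' mirroring the exclusion of underpowered cohorts.
#'
#' @param regions a \code{\linkS4class{RegionSet}}.
#' @param counts named integer vector of qualifying mutation counts per
#'   region (names matching \code{regionIds(regions)}).
#' @param minMutations minimum qualifying mutations per region (default 3).
#' @param minRegions minimum number of qualifying regions for the cohort
#'   (default 1000).
#' @return The qualifying subset of \code{regions}.
#' @export
selectTestableRegions <- function(regions, counts, minMutations = 3L,
        minRegions = 1000L) {
    stopifnot(minMutations > 0L, minRegions > 0L)
    cnt <- counts[regionIds(regions)]
    cnt[is.na(cnt)] <- 0L
    keep <- cnt >= minMutations
    if (sum(keep) < minRegions)
        stop(sprintf(
            "cohort aborted: only %d region(s) have >= %d qualifying mutations (minimum %d)",
            sum(keep), minMutations, minRegions))
    regions[which(keep)]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment over all tested
#' regions (never a significant subset only).
#'
#' @param p numeric vector of p-values.
#' @return q-values in (0, 1].
#' @export
adjustFdr <- function(p) stats::p.adjust(p, method = "BH")

#' Run the cohort mutational-skew test
#'
#' Full pipeline over a cohort and a set of regions, in fixed order:
#' tumour filters, effect filter, region selection, per-region skew test,
#' BH correction. For each tested region the per-tumour expected counts are
#' computed from the mutation models, scaled to the observed
#' mutated-tumour count, \code{nSim} neutral cohorts are simulated, and a
#' gamma tail fitted to their statistics yields the one-sided p-value.
#'
#' @param mutations typed mutation data.frame from
#'   \code{\link{readMutationTable}} / \code{\link{validateMutations}}.
#' @param regions a \code{\linkS4class{RegionSet}}.
#' @param genome \code{DNAStringSet} or named character vector.
#' @param mode \code{"wxs"} (cohort signature scaled by burden) or
#'   \code{"wgs"} (tumour-specific signatures over whole-genome territory).
#' @param nSim simulated cohorts per region (default 10000).
#' @param seed integer seed for the simulation stream (logged in the
#'   result).
#' @param nullLaw null sampling law passed to \code{\link{simulateNull}}:
#'   \code{"conditional"} (conditional Bernoulli, calibrated default) or
#'   \code{"sequential"} (successive weighted sampling).
#' @param effects effect filter for CDS regions.
#' @param perCancerType estimate WXS signatures (and apply the tumour
#'   fraction filter) per \code{cancer_type} label.
#' @param hyperFraction,hypermutatorAbsolute tumour filters, see
#'   \code{\link{applyCohortFilters}}.
#' @param minMutations,minRegions region selection, see
#'   \code{\link{selectTestableRegions}}.
#' @param reportFrequency also report the optional Poisson frequency
#'   statistic per region (never combined into q).
#' @param keepDetails region ids (or \code{TRUE} for all) whose
#'   \code{RegionProfile}, \code{ScaledProfile} and \code{NullEnsemble}
#'   are retained for CMT plotting.
#' @param verbose print stage-by-stage progress.
#' @return A \code{\linkS4class{SeismicResults}}.
#' @export
seismicTest <- function(mutations, regions, genome,
        mode = c("wxs", "wgs"), nSim = 10000L, seed = 1L,
        nullLaw = c("conditional", "sequential"),
        effects = c("missense", "nonsense"), perCancerType = FALSE,
        hyperFraction = 0.10, hypermutatorAbsolute = NULL,
        minMutations = 3L, minRegions = 1000L, reportFrequency = FALSE,
        keepDetails = character(0), verbose = FALSE) {
    mode <- match.arg(mode)
    nullLaw <- match.arg(nullLaw)
    chars <- .asGenomeChars(genome)
    say <- function(...) if (verbose) message(sprintf(...))

    scope <- NULL
    if (perCancerType) {
        if (is.null(mutations$cancer_type) || anyNA(mutations$cancer_type))
            stop("perCancerType requires a complete cancer_type column")
        scope <- tapply(mutations$cancer_type, mutations$sample,
            function(x) x[1L])
    }
    filt <- applyCohortFilters(mutations, hyperFraction = hyperFraction,
        hypermutatorAbsolute = hypermutatorAbsolute, scope = scope)
    mutations <- filt$mutations
    say("tumour filters: %d of %d tumours retained, %d mutations",
        sum(!filt$report$removed), nrow(filt$report), nrow(mutations))

    territory <- if (mode == "wgs") countTerritory(chars) else
        countTerritory(chars, regions)
    samples <- sort(unique(mutations$sample))
    models <- if (mode == "wgs")
        buildWgsModels(mutations, territory, samples = samples)
    else
        buildWxsModels(mutations, territory, samples = samples,
            cancerType = if (perCancerType) scope else NULL)

    say("enumerating qualifying changes for %d region(s)", length(regions))
    changes <- lapply(seq_len(length(regions)), function(i)
        enumerateQualifyingChanges(regions[i], chars, effects = effects))
    names(changes) <- regionIds(regions)

    # candidate observed mutations per region via one overlap join
    blocksAll <- regionBlocks(regions)
    regOf <- rep(seq_len(length(regions)), elementNROWS(blocksAll))
    mutGr <- GRanges(mutations$contig, IRanges(mutations$pos,
        mutations$pos))
    ov <- findOverlaps(mutGr, unlist(blocksAll, use.names = FALSE),
        ignore.strand = TRUE)
    cand <- split(S4Vectors::queryHits(ov),
        factor(regOf[S4Vectors::subjectHits(ov)],
            levels = seq_len(length(regions))))

    counts <- vapply(seq_len(length(regions)), function(i) {
        ch <- changes[[i]]
        ci <- cand[[i]]
        if (!nrow(ch) || !length(ci)) return(0L)
        obs <- mutations[ci, , drop = FALSE]
        sum(!is.na(match(obs$pos * 4 + match(obs$alt, .BASES),
            ch$pos * 4 + match(ch$alt, .BASES))))
    }, integer(1))
    names(counts) <- regionIds(regions)
    tested <- selectTestableRegions(regions, counts,
        minMutations = minMutations, minRegions = minRegions)
    say("testing %d region(s) with >= %d qualifying mutations",
        length(tested), minMutations)

    if (isTRUE(keepDetails)) keepDetails <- regionIds(tested)
    details <- list()
    set.seed(seed)
    rows <- vector("list", length(tested))
    for (i in seq_len(length(tested))) {
        id <- regionIds(tested)[i]
        ci <- cand[[match(id, regionIds(regions))]]
        prof <- regionProfile(tested[i], models, changes[[id]],
            mutations[ci, , drop = FALSE])
        scaled <- scaleToRecurrence(prof)
        Dobs <- -setLogLik(prof@mutatedSamples, scaled)
        ens <- simulateNull(scaled, nSim = nSim, law = nullLaw)
        tail <- gammaTailP(ens, Dobs)
        row <- data.frame(region_id = id,
            n_mutations = prof@nMutations,
            n_mutated_tumours = length(prof@mutatedSamples),
            expected_mutations = sum(prof@lambda),
            scale_s = scaled@s, D_obs = Dobs,
            p = tail$p, p_empirical = tail$pEmpirical, q = NA_real_,
            flags = paste(tail$flags, collapse = ";"),
            stringsAsFactors = FALSE)
        if (reportFrequency) {
            fr <- frequencyStatistic(prof)
            row$freq_expected <- fr$expected
            row$freq_p <- fr$p
        }
        rows[[i]] <- row
        if (id %in% keepDetails)
            details[[id]] <- list(profile = prof, scaled = scaled,
                ensemble = ens)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab$q <- adjustFdr(tab$p)
    new("SeismicResults", table = tab, filterReport = filt$report,
        config = list(mode = mode, nSim = as.integer(nSim),
            seed = as.integer(seed), nullLaw = nullLaw, effects = effects,
            perCancerType = perCancerType, hyperFraction = hyperFraction,
            hypermutatorAbsolute = hypermutatorAbsolute,
            minMutations = as.integer(minMutations),
            minRegions = as.integer(minRegions)),
        details = details)
}

#' Cumulative mutated-tumours (CMT) series
#'
#' Orders the cohort by the region's scaled mutation probability (ascending,
#' ties broken by sample id) and accumulates the observed mutated-tumour
#' count along that order, together with a per-position simulation envelope:
#' the central 90\% band (5th-95th percentiles) and median of the simulated
#' cumulative counts. Driver-like regions rise above the envelope early
#' (mutations in low-probability tumours); neutral regions track it.
#'
#' @param scaled a \code{\linkS4class{ScaledProfile}}.
#' @param ensemble the matching \code{\linkS4class{NullEnsemble}}.
#' @param observed character vector of observed mutated sample ids (e.g.
#'   \code{mutatedSamples(profile)}).
#' @return data.frame with columns \code{rank}, \code{sample},
#'   \code{ptilde}, \code{observed_cum}, \code{sim_lo}, \code{sim_med},
#'   \code{sim_hi}.
#' @export
cmtSeries <- function(scaled, ensemble, observed) {
    p <- scaled@ptilde
    ord <- order(p, names(p))
    n <- length(p)
    obsCum <- cumsum(names(p)[ord] %in% observed)
    memb <- matrix(0L, n, ncol(ensemble@sets))
    memb[cbind(as.vector(ensemble@sets),
        rep(seq_len(ncol(ensemble@sets)), each = nrow(ensemble@sets)))] <- 1L
    cum <- apply(memb[ord, , drop = FALSE], 2L, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
    qs <- apply(cum, 1L, stats::quantile, probs = c(0.05, 0.5, 0.95),
        names = FALSE)
    data.frame(rank = seq_len(n), sample = names(p)[ord],
        ptilde = unname(p[ord]), observed_cum = obsCum,
        sim_lo = qs[1L, ], sim_med = qs[2L, ], sim_hi = qs[3L, ],
        stringsAsFactors = FALSE)
}

#' Plot a CMT series
#'
#' Minimal base-graphics rendering of \code{\link{cmtSeries}}: simulation
#' envelope as a band, observed cumulative curve on top.
#'
#' @param series data.frame from \code{\link{cmtSeries}}.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return Invisibly, \code{series}.
#' @export
plotCmt <- function(series, main = "Cumulative mutated tumours", ...) {
    graphics::plot(series$rank, series$observed_cum, type = "n",
        xlab = "Tumours ordered by mutation probability",
        ylab = "Cumulative mutated tumours", main = main, ...)
    graphics::polygon(c(series$rank, rev(series$rank)),
        c(series$sim_lo, rev(series$sim_hi)),
        col = "#9ecae1", border = NA)
    graphics::lines(series$rank, series$sim_med, col = "#3182bd", lty = 2)
    graphics::lines(series$rank, series$observed_cum, col = "#de2d26",
        lwd = 2)
    invisible(series)
}
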