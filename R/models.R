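# Per-tumour mutation-rate models and per-region expected-mutation profiles.

# tumours x 96 channel count matrix from a typed mutation table
.channelCounts <- function(mutations, samples) {
    m <- matrix(0, length(samples), 96L,
        dimnames = list(samples, .CHANNELS))
    if (nrow(mutations)) {
        tab <- table(factor(mutations$sample, levels = samples),
            factor(mutations$channel, levels = seq_len(96L)))
        m[] <- as.numeric(tab)
    }
    m
}

.checkTerritory <- function(counts, territory) {
    if (length(territory) != 32L)
        stop("territory must be a 32-context vector")
    used <- which(colSums(counts) > 0)
    zero <- .CTX_OF_CHANNEL[used][territory[.CTX_OF_CHANNEL[used]] <= 0]
    if (length(zero))
        stop("mutations observed in context(s) with zero territory: ",
            paste(.CONTEXTS[unique(zero)], collapse = ", "))
}

#' Build tumour-specific mutation models (WGS)
#'
#' Estimates, for each tumour separately, the per-site rate of each of the
#' 96 mutation types: the tumour's count of that type divided by the
#' trinucleotide territory of the type's context (whole-genome territory for
#' WGS data). Suitable when per-tumour mutation counts are large enough to
#' carry a signature, i.e. whole-genome calls.
#'
#' @param mutations typed mutation data.frame (see
#'   \code{\link{readMutationTable}}).
#' @param territory named 32-vector from \code{\link{countTerritory}} over
#'   the territory covered by the calls.
#' @param samples cohort sample ids; defaults to the samples present in
#'   \code{mutations}. Tumours without mutations get all-zero models.
#' @return A \code{\linkS4class{TumourModels}} object.
#' @export
buildWgsModels <- function(mutations, territory, samples = NULL) {
    if (is.null(samples)) samples <- sort(unique(mutations$sample))
    m <- .channelCounts(mutations, samples)
    .checkTerritory(m, territory)
    rates <- sweep(m, 2L, as.numeric(territory)[.CTX_OF_CHANNEL], "/")
    rates[, territory[.CTX_OF_CHANNEL] == 0] <- 0
    new("TumourModels", rates = rates, burden = rowSums(m), mode = "wgs",
        scope = stats::setNames(samples, samples),
        territory = stats::setNames(as.numeric(territory), .CONTEXTS))
}

#' Build burden-scaled cohort mutation models (WXS)
#'
#' For exome data per-tumour mutation counts are too low to estimate
#' signatures, so the 96-channel rate vector is estimated at the cohort
#' level, \code{r(t) = sum_j m_j(t) / territory(context(t))}, and each
#' tumour receives \code{rates_j = r * B_j / sum(B)} where \code{B_j} is the
#' tumour's total mutational burden: a shared trinucleotide signature whose
#' amplitude varies with burden. When \code{cancerType} labels are supplied
#' (pan-cancer analyses) the procedure is applied within each cancer type,
#' so a tumour's rates depend only on its own type's signature.
#'
#' @inheritParams buildWgsModels
#' @param territory 32-vector of territory counts over the regions covered
#'   by the calls (e.g. CDS territory for exome data).
#' @param cancerType optional per-tumour labels: a named character vector or
#'   \code{NULL} to use the \code{cancer_type} column of \code{mutations}
#'   when fully present, else a single cohort scope. Every tumour must be
#'   labelled when labels are used.
#' @param burdenCounts optional named per-tumour burden override. By
#'   default every typed SNV of the tumour counts toward its burden,
#'   synonymous included — burden measures mutagenesis, not selection; pass
#'   e.g. effect-filtered counts to change that.
#' @return A \code{\linkS4class{TumourModels}} object.
#' @export
buildWxsModels <- function(mutations, territory, samples = NULL,
        cancerType = NULL, burdenCounts = NULL) {
    if (is.null(samples)) samples <- sort(unique(mutations$sample))
    if (is.null(cancerType) && !is.null(mutations$cancer_type) &&
        !anyNA(mutations$cancer_type) && nrow(mutations) > 0L) {
        cancerType <- tapply(mutations$cancer_type, mutations$sample,
            function(x) x[1L])
    }
    if (is.null(cancerType)) {
        scope <- stats::setNames(rep("cohort", length(samples)), samples)
    } else {
        scope <- stats::setNames(as.character(cancerType[samples]), samples)
        if (anyNA(scope))
            stop("every tumour must have a cancer_type label")
    }
    m <- .channelCounts(mutations, samples)
    .checkTerritory(m, territory)
    terr <- as.numeric(territory)[.CTX_OF_CHANNEL]
    B <- rowSums(m)
    if (!is.null(burdenCounts)) {
        if (anyNA(burdenCounts[samples]))
            stop("burdenCounts must cover every tumour")
        B <- as.numeric(burdenCounts[samples])
    }
    rates <- matrix(0, length(samples), 96L,
        dimnames = list(samples, .CHANNELS))
    for (sc in unique(scope)) {
        j <- which(scope == sc)
        r <- colSums(m[j, , drop = FALSE]) / terr
        r[terr == 0] <- 0
        tot <- sum(B[j])
        if (tot == 0) {
            warning(sprintf("signature scope '%s' has zero total burden", sc))
            next
        }
        rates[j, ] <- outer(B[j] / tot, r)
    }
    new("TumourModels", rates = rates, burden = B, mode = "wxs",
        scope = scope,
        territory = stats::setNames(as.numeric(territory), .CONTEXTS))
}

#' Cohort-level 96-channel signature of a model set
#'
#' Sums the per-tumour rate vectors, giving the cohort per-site rate of each
#' mutation type (for WXS models this recovers the scope signature exactly
#' when a single scope is present). Normalised to sum to 1 when
#' \code{normalize = TRUE}.
#'
#' @param models a \code{\linkS4class{TumourModels}}.
#' @param normalize return proportions instead of rates.
#' @return Named numeric vector of length 96.
#' @export
cohortSignature <- function(models, normalize = TRUE) {
    r <- colSums(mutationRates(models))
    if (normalize && sum(r) > 0) r <- r / sum(r)
    r
}

#' Expected-mutation profile of a region across the cohort
#'
#' Applies the mutation models to a region's qualifying changes: each
#' tumour's expected qualifying mutation count is
#' \code{lambda_j = sum over qualifying (site, alt) of rates_j(type)}, and
#' its probability of being mutated (>= 1 qualifying mutation) is
#' \code{1 - exp(-lambda_j)} under a Poisson count model. The observed
#' mutated-tumour set is taken from the observed mutations that match a
#' qualifying change (position and alt), one membership per tumour
#' regardless of multiplicity.
#'
#' @param region a \code{\linkS4class{RegionSet}} of length 1.
#' @param models a \code{\linkS4class{TumourModels}}.
#' @param changes qualifying changes from
#'   \code{\link{enumerateQualifyingChanges}} (computed with the active
#'   effect filter); regions with no qualifying changes are an error, catch
#'   and skip upstream.
#' @param mutations observed typed mutations (any superset; matched to the
#'   region's contig, positions and alts internally).
#' @return A \code{\linkS4class{RegionProfile}}.
#' @export
regionProfile <- function(region, models, changes, mutations) {
    stopifnot(methods::is(region, "RegionSet"), length(region) == 1L)
    if (nrow(changes) == 0L)
        stop(sprintf("region '%s' has no qualifying changes",
            regionIds(region)))
    qtab <- tabulate(changes$channel, 96L)
    lambda <- as.vector(mutationRates(models) %*% qtab)
    names(lambda) <- sampleIds(models)

    ct <- as.character(seqnames(regionBlocks(region)[[1L]]))[1L]
    obs <- mutations[mutations$contig == ct, , drop = FALSE]
    key <- function(p, a) p * 4 + match(a, .BASES)
    hit <- obs[!is.na(match(key(obs$pos, obs$alt),
        key(changes$pos, changes$alt))), , drop = FALSE]
    hit <- hit[hit$sample %in% names(lambda), , drop = FALSE]
    new("RegionProfile", regionId = regionIds(region), lambda = lambda,
        mutatedSamples = sort(unique(hit$sample)),
        nMutations = nrow(hit))
}
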