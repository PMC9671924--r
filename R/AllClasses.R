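#' @import methods
#' @importFrom S4Vectors mcols mcols<- elementNROWS
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end width strand reduce shift findOverlaps
#' @importFrom IRanges IRanges IRangesList ranges ranges<-
NULL

#' Set of genomic regions under test
#'
#' A \code{RegionSet} holds the genomic elements to be tested for cohort
#' mutational skew: either protein-coding sequences (\code{kind = "cds"},
#' possibly multi-exon, where the concatenated blocks form a complete open
#' reading frame on the annotated strand) or plain intervals
#' (\code{kind = "interval"}, e.g. fixed-width promoter windows, always a
#' single block).
#'
#' Blocks of one region must lie on a single contig and strand, be sorted and
#' non-overlapping. CDS regions whose total block length is not divisible by
#' 3 are invalid (they do not consist of full codons); \code{\link{readBed12Regions}}
#' drops such entries with a message rather than failing.
#'
#' @slot blocks \code{GRangesList}, one element per region, named by region id.
#' @slot kind character vector, \code{"cds"} or \code{"interval"} per region.
#'
#' @seealso \code{\link{readBed12Regions}}, \code{\link{promoterRegions}},
#'   \code{\link{enumerateQualifyingChanges}}
#' @export
setClass("RegionSet",
    representation(blocks = "GRangesList", kind = "character"))

setValidity("RegionSet", function(object) {
    blocks <- object@blocks
    kind <- object@kind
    if (length(blocks) != length(kind))
        return("'kind' must have one entry per region")
    ids <- names(blocks)
    if (is.null(ids) || anyDuplicated(ids) || any(ids == ""))
        return("regions must have unique non-empty ids (names of 'blocks')")
    if (!all(kind %in% c("cds", "interval")))
        return("kind must be 'cds' or 'interval'")
    for (i in seq_along(blocks)) {
        b <- blocks[[i]]
        if (length(b) < 1L)
            return(sprintf("region '%s' has no blocks", ids[i]))
        if (length(unique(as.character(seqnames(b)))) != 1L)
            return(sprintf("region '%s' spans multiple contigs", ids[i]))
        st <- unique(as.character(strand(b)))
        if (length(st) != 1L || !st %in% c("+", "-"))
            return(sprintf("region '%s' must have a single strand (+/-)", ids[i]))
        if (is.unsorted(start(b)))
            return(sprintf("region '%s' blocks are not sorted", ids[i]))
        if (length(b) > 1L && any(start(b)[-1L] <= end(b)[-length(b)]))
            return(sprintf("region '%s' blocks overlap", ids[i]))
        if (kind[i] == "cds" && sum(width(b)) %% 3L != 0L)
            return(sprintf("CDS region '%s' length not divisible by 3", ids[i]))
        if (kind[i] == "interval" && length(b) != 1L)
            return(sprintf("interval region '%s' must have exactly one block", ids[i]))
    }
    TRUE
})

#' Construct a RegionSet
#'
#' @param blocks named \code{GRangesList} of region blocks (1-based, inclusive
#'   coordinates as usual for \code{GRanges}).
#' @param kind \code{"cds"} or \code{"interval"}; recycled to the number of
#'   regions.
#' @return A \code{\linkS4class{RegionSet}}.
#' @export
RegionSet <- function(blocks, kind = "cds") {
    kind <- rep_len(kind, length(blocks))
    new("RegionSet", blocks = blocks, kind = kind)
}

#' @describeIn RegionSet-class number of regions
#' @param x,object a \code{RegionSet}
#' @export
setMethod("length", "RegionSet", function(x) length(x@blocks))

#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @describeIn RegionSet-class region identifiers
#' @export
setMethod("regionIds", "RegionSet", function(x) names(x@blocks))

#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))

#' @describeIn RegionSet-class per-region kind ("cds"/"interval")
#' @export
setMethod("regionKind", "RegionSet",
    function(x) stats::setNames(x@kind, names(x@blocks)))

#' @export
setGeneric("regionBlocks", function(x) standardGeneric("regionBlocks"))

#' @describeIn RegionSet-class the underlying \code{GRangesList}
#' @export
setMethod("regionBlocks", "RegionSet", function(x) x@blocks)

#' @describeIn RegionSet-class subset regions by index or id
#' @param i index, logical vector or region ids
#' @param j,drop,... ignored
#' @export
setMethod("[", "RegionSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@blocks))
    initialize(x, blocks = x@blocks[i], kind = x@kind[i])
})

setMethod("show", "RegionSet", function(object) {
    k <- table(factor(object@kind, c("cds", "interval")))
    cat(sprintf("RegionSet with %d regions (%d cds, %d interval)\n",
        length(object), k[["cds"]], k[["interval"]]))
    ids <- names(object@blocks)
    show <- utils::head(ids, 5L)
    cat("  ids:", paste(show, collapse = ", "),
        if (length(ids) > 5L) "..." else "", "\n")
})

#' Per-tumour mutation-rate models
#'
#' One 96-channel rate vector per tumour, on the scale of expected mutations
#' per available trinucleotide site. For WGS data the rates are estimated
#' per tumour (tumour-specific signatures); for WXS data a cohort (or
#' per-cancer-type) signature is estimated and scaled by each tumour's share
#' of the total mutational burden, so that all tumours in a signature scope
#' share the trinucleotide profile and differ only in amplitude.
#'
#' @slot rates numeric matrix, tumours x 96 channels.
#' @slot burden named numeric, total modelled SNV count per tumour.
#' @slot mode \code{"wgs"} or \code{"wxs"}.
#' @slot scope named character, signature scope per tumour (its own id for
#'   WGS; the cohort or cancer-type label for WXS).
#' @slot territory named numeric of length 32, pyrimidine-centred
#'   trinucleotide context counts of the modelled territory.
#' @seealso \code{\link{buildWgsModels}}, \code{\link{buildWxsModels}}
#' @export
setClass("TumourModels",
    representation(rates = "matrix", burden = "numeric", mode = "character",
        scope = "character", territory = "numeric"))

setValidity("TumourModels", function(object) {
    n <- nrow(object@rates)
    if (ncol(object@rates) != 96L)
        return("rates must have 96 columns")
    if (is.null(rownames(object@rates)))
        return("rates must have sample ids as rownames")
    if (length(object@burden) != n || length(object@scope) != n)
        return("burden and scope must have one entry per tumour")
    if (any(object@rates < 0) || any(object@burden < 0))
        return("rates and burdens must be non-negative")
    if (length(object@territory) != 32L || any(object@territory < 0))
        return("territory must be a non-negative 32-vector")
    if (!object@mode %in% c("wgs", "wxs"))
        return("mode must be 'wgs' or 'wxs'")
    zero <- object@burden == 0
    if (any(rowSums(object@rates[zero, , drop = FALSE]) > 0))
        return("tumours with zero burden must have all-zero rates")
    TRUE
})

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn TumourModels-class tumour sample ids
#' @param x,object a \code{TumourModels}
#' @export
setMethod("sampleIds", "TumourModels", function(x) rownames(x@rates))

#' @export
setGeneric("mutationRates", function(x) standardGeneric("mutationRates"))

#' @describeIn TumourModels-class the tumours x 96 rate matrix
#' @export
setMethod("mutationRates", "TumourModels", function(x) x@rates)

#' @export
setGeneric("tumourBurdens", function(x) standardGeneric("tumourBurdens"))

#' @describeIn TumourModels-class named per-tumour burdens
#' @export
setMethod("tumourBurdens", "TumourModels",
    function(x) stats::setNames(x@burden, rownames(x@rates)))

setMethod("show", "TumourModels", function(object) {
    cat(sprintf("TumourModels (%s) for %d tumours\n", object@mode,
        nrow(object@rates)))
    cat(sprintf("  burden range: %g-%g; %d signature scope(s)\n",
        min(object@burden), max(object@burden),
        length(unique(object@scope))))
})

#' Expected-mutation profile of one region across a cohort
#'
#' Per-tumour expected qualifying mutation counts (lambda) for one region
#' under the cohort's mutation models, together with the observed mutated
#' tumour set. The probability of a tumour being mutated (at least one
#' qualifying mutation) is \code{1 - exp(-lambda)} under a Poisson count
#' model; retrieve it with \code{mutationProb}.
#'
#' @slot regionId character scalar.
#' @slot lambda named numeric, expected qualifying mutations per tumour.
#' @slot mutatedSamples character, ids of tumours with >= 1 observed
#'   qualifying mutation (binary status: multiplicity within a tumour is
#'   deliberately ignored).
#' @slot nMutations integer, total observed qualifying mutation count.
#' @seealso \code{\link{regionProfile}}, \code{\link{scaleToRecurrence}}
#' @export
setClass("RegionProfile",
    representation(regionId = "character", lambda = "numeric",
        mutatedSamples = "character", nMutations = "integer"))

setValidity("RegionProfile", function(object) {
    if (is.null(names(object@lambda)))
        return("lambda must be named by sample id")
    if (any(object@lambda < 0)) return("lambda must be non-negative")
    bad <- setdiff(object@mutatedSamples, names(object@lambda))
    if (length(bad))
        return("mutatedSamples contains unknown sample ids")
    if (any(object@lambda[object@mutatedSamples] <= 0))
        return("observed mutated tumours must have lambda > 0")
    if (object@nMutations < length(object@mutatedSamples))
        return("nMutations cannot be below the mutated-tumour count")
    TRUE
})

#' @export
setGeneric("expectedMutations", function(x) standardGeneric("expectedMutations"))

#' @describeIn RegionProfile-class named per-tumour expected counts
#' @param x,object a \code{RegionProfile}
#' @export
setMethod("expectedMutations", "RegionProfile", function(x) x@lambda)

#' @export
setGeneric("mutationProb", function(x) standardGeneric("mutationProb"))

#' @describeIn RegionProfile-class per-tumour probability of >= 1 qualifying
#'   mutation, \code{1 - exp(-lambda)}
#' @export
setMethod("mutationProb", "RegionProfile", function(x) -expm1(-x@lambda))

#' @export
setGeneric("mutatedSamples", function(x) standardGeneric("mutatedSamples"))

#' @describeIn RegionProfile-class ids of observed mutated tumours
#' @export
setMethod("mutatedSamples", "RegionProfile", function(x) x@mutatedSamples)

setMethod("show", "RegionProfile", function(object) {
    cat(sprintf(
        "RegionProfile '%s': %d tumours, k = %d mutated (%d mutations), sum(lambda) = %.4g\n",
        object@regionId, length(object@lambda), length(object@mutatedSamples),
        object@nMutations, sum(object@lambda)))
})

#' Recurrence-matched scaled mutation probabilities
#'
#' The result of \code{\link{scaleToRecurrence}}: per-tumour probabilities
#' \code{ptilde = 1 - exp(-t * w)} where \code{w} is the tumour weight
#' profile (lambda normalised to its maximum and rounded to 9 significant
#' digits, which makes the result exactly invariant to the overall rate
#' scale) and \code{t} solves \code{sum(ptilde) = k}, the observed
#' mutated-tumour count. \code{logP} and \code{logQ} hold
#' \code{log(ptilde)} and \code{log(1 - ptilde)} computed in numerically
#' stable form (\code{log(1 - ptilde) = -t * w} exactly).
#'
#' @slot regionId character scalar.
#' @slot s numeric, scale factor on the original lambda scale (Inf in the
#'   saturated case k = number of tumours with lambda > 0).
#' @slot k integer, target mutated-tumour count.
#' @slot ptilde,logP,logQ named numeric over the full cohort.
#' @export
setClass("ScaledProfile",
    representation(regionId = "character", s = "numeric", k = "integer",
        ptilde = "numeric", logP = "numeric", logQ = "numeric"))

setValidity("ScaledProfile", function(object) {
    p <- object@ptilde
    if (is.null(names(p))) return("ptilde must be named by sample id")
    if (any(p < 0 | p > 1)) return("ptilde must lie in [0, 1]")
    if (abs(sum(p) - object@k) > 1e-6)
        return("sum(ptilde) must equal k within 1e-6")
    if (length(object@logP) != length(p) || length(object@logQ) != length(p))
        return("logP/logQ must match ptilde in length")
    TRUE
})

#' @describeIn ScaledProfile-class tumour sample ids
#' @export
setMethod("sampleIds", "ScaledProfile", function(x) names(x@ptilde))

#' @export
setGeneric("scaledProb", function(x) standardGeneric("scaledProb"))

#' @describeIn ScaledProfile-class the scaled probabilities ptilde
#' @param x,object a \code{ScaledProfile}
#' @export
setMethod("scaledProb", "ScaledProfile", function(x) x@ptilde)

setMethod("show", "ScaledProfile", function(object) {
    cat(sprintf(
        "ScaledProfile '%s': k = %d over %d tumours (%d with ptilde > 0), s = %.4g\n",
        object@regionId, object@k, length(object@ptilde),
        sum(object@ptilde > 0), object@s))
})

#' Simulated null ensemble for one region
#'
#' \code{nSim} cohorts of exactly \code{k} mutated tumours drawn from the
#' chosen null law over mutated-tumour sets (conditional Bernoulli by
#' default, or successive weighted sampling without replacement), with the
#' negative log-likelihood statistic \code{D} of each simulated combination.
#'
#' @slot regionId character scalar.
#' @slot sets integer matrix, k x nSim; column j holds the cohort indices
#'   (into \code{samples}) of the j-th simulated mutated-tumour set.
#' @slot D numeric of length nSim, statistic per simulated cohort.
#' @slot samples character, cohort sample ids the indices refer to.
#' @slot seed integer seed used (NA if drawn from the caller's RNG stream).
#' @slot law character scalar, the sampling law used
#'   (\code{"conditional"} or \code{"sequential"}).
#' @seealso \code{\link{simulateNull}}, \code{\link{gammaTailP}}
#' @export
setClass("NullEnsemble",
    representation(regionId = "character", sets = "matrix", D = "numeric",
        samples = "character", seed = "integer", law = "character"))

setValidity("NullEnsemble", function(object) {
    if (length(object@D) != ncol(object@sets))
        return("one D value per simulated cohort required")
    if (nrow(object@sets) > 0L && anyNA(object@sets))
        return("sets must not contain NA")
    if (nrow(object@sets) > 0L &&
        (min(object@sets) < 1L || max(object@sets) > length(object@samples)))
        return("set indices out of range")
    TRUE
})

setMethod("show", "NullEnsemble", function(object) {
    cat(sprintf(
        "NullEnsemble '%s' (%s law): %d simulations of k = %d; D in [%.4g, %.4g]\n",
        object@regionId, object@law, ncol(object@sets), nrow(object@sets),
        min(object@D), max(object@D)))
})

#' Results of a cohort mutational-skew test
#'
#' Container returned by \code{\link{seismicTest}}: one row per tested
#' region with the skew statistic, gamma-tail and empirical p-values and
#' BH-adjusted q-values, plus the tumour filter report and the run
#' configuration. Per-region \code{ScaledProfile}/\code{NullEnsemble}
#' details are retained for regions requested via \code{keepDetails}.
#'
#' @slot table data.frame of per-region results.
#' @slot filterReport data.frame describing removed tumours.
#' @slot config list of run parameters (including the seed).
#' @slot details named list of per-region detail lists.
#' @export
setClass("SeismicResults",
    representation(table = "data.frame", filterReport = "data.frame",
        config = "list", details = "list"))

#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @describeIn SeismicResults-class the per-region result data.frame
#' @param x,object a \code{SeismicResults}
#' @export
setMethod("resultsTable", "SeismicResults", function(x) x@table)

#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @describeIn SeismicResults-class the tumour filter report
#' @export
setMethod("filterReport", "SeismicResults", function(x) x@filterReport)

setMethod("show", "SeismicResults", function(object) {
    tab <- object@table
    cat(sprintf("SeismicResults: %d regions tested (%s mode, nSim = %d, seed = %s)\n",
        nrow(tab), object@config$mode, object@config$nSim,
        as.character(object@config$seed)))
    if (nrow(tab)) {
        sig <- sum(tab$q < 0.05)
        cat(sprintf("  %d region(s) at q < 0.05; smallest q = %.3g (%s)\n",
            sig, min(tab$q), tab$region_id[which.min(tab$q)]))
    }
})
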