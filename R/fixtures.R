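# Self-contained synthetic genomes and cohorts with the statistical
# structure the skew test assumes: neutral genes mutated in proportion to
# burden x signature, plus injected driver genes whose mutated tumours are
# chosen independently of burden.

#' Specification of a synthetic cohort fixture
#'
#' Bundles and validates the generator parameters. Defaults emulate a
#' heavy-tailed exome-like cohort: per-tumour burdens log-uniform over
#' [5, 5000] (an orders-of-magnitude spread as seen in UV-exposed
#' melanoma), 300 single-exon genes of 300 bp separated by 6 kb of
#' intergenic sequence, and a choice of a uniform or UV-like trinucleotide
#' signature.
#'
#' @param nTumours cohort size.
#' @param burdenRange log-uniform burden range (min, max), in SNVs per
#'   tumour.
#' @param signature \code{"uniform"} (all 96 channels equal) or \code{"uv"}
#'   (fraction \code{uvFraction} of mass on C>T channels with a pyrimidine
#'   5' flank, the dipyrimidine-context UV signature).
#' @param uvFraction mass on UV channels for the \code{"uv"} preset.
#' @param nGenes,geneLength,intergenic genome layout in bp;
#'   \code{geneLength} must be divisible by 3.
#' @param nDrivers number of driver genes to inject.
#' @param driverRecurrence tumours mutated per driver (chosen uniformly,
#'   ignoring burden).
#' @param contig contig name of the synthetic genome.
#' @return A validated list of class \code{FixtureSpec}.
#' @export
fixtureSpec <- function(nTumours = 200L, burdenRange = c(5, 5000),
        signature = c("uniform", "uv"), uvFraction = 0.8, nGenes = 300L,
        geneLength = 300L, intergenic = 6000L, nDrivers = 0L,
        driverRecurrence = 10L, contig = "chr1") {
    signature <- match.arg(signature)
    stopifnot(nTumours >= 1L, length(burdenRange) == 2L,
        burdenRange[1] >= 0, burdenRange[2] >= burdenRange[1],
        geneLength %% 3L == 0L, nGenes >= 1L, intergenic >= 2L,
        nDrivers >= 0L, nDrivers <= nGenes,
        nDrivers == 0L || driverRecurrence <= nTumours,
        uvFraction > 0, uvFraction < 1)
    structure(list(nTumours = as.integer(nTumours),
        burdenRange = as.numeric(burdenRange), signature = signature,
        uvFraction = uvFraction, nGenes = as.integer(nGenes),
        geneLength = as.integer(geneLength),
        intergenic = as.integer(intergenic),
        nDrivers = as.integer(nDrivers),
        driverRecurrence = as.integer(driverRecurrence),
        contig = contig), class = "FixtureSpec")
}

#' 96-channel signature weights for the fixture presets
#'
#' @param signature \code{"uniform"} or \code{"uv"}.
#' @param uvFraction mass on the UV channels (C>T with pyrimidine 5'
#'   flank) for the \code{"uv"} preset.
#' @return Named numeric vector of length 96 summing to 1.
#' @export
signatureWeights <- function(signature = c("uniform", "uv"),
        uvFraction = 0.8) {
    signature <- match.arg(signature)
    w <- stats::setNames(rep(1 / 96, 96L), .CHANNELS)
    if (signature == "uv") {
        uv <- grepl("^[CT]\\[C>T\\]", .CHANNELS)
        w[uv] <- uvFraction / sum(uv)
        w[!uv] <- (1 - uvFraction) / sum(!uv)
    }
    w
}

#' Generate a synthetic genome with gene models
#'
#' Builds a random uniform-composition genome laid out as alternating
#' intergenic gaps and single-exon CDS genes on alternating strands
#' (genes 1, 3, 5, ... on plus). Deterministic under \code{seed}.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param seed optional integer seed (caller's RNG restored).
#' @return List with \code{genome} (named character vector, one contig) and
#'   \code{regions} (a \code{\linkS4class{RegionSet}} of \code{nGenes} CDS
#'   regions named \code{gene001}, ...).
#' @export
generateGenome <- function(spec, seed = NULL) {
    gen <- function() {
        L <- spec$nGenes * (spec$geneLength + spec$intergenic) +
            spec$intergenic
        seqc <- paste(sample(.BASES, L, replace = TRUE), collapse = "")
        starts <- spec$intergenic + 1L +
            (seq_len(spec$nGenes) - 1L) * (spec$geneLength + spec$intergenic)
        ids <- sprintf("gene%03d", seq_len(spec$nGenes))
        grl <- GRangesList(lapply(seq_len(spec$nGenes), function(i)
            GRanges(spec$contig,
                IRanges(starts[i], width = spec$geneLength),
                strand = if (i %% 2L == 1L) "+" else "-")))
        names(grl) <- ids
        list(genome = stats::setNames(seqc, spec$contig),
            regions = RegionSet(grl, kind = "cds"))
    }
    if (is.null(seed)) gen() else .withSeed(seed, gen())
}

# per-context site index of a genome: list of 32 integer vectors of
# positions (full non-N triplet), plus the context index per listed site
.contextSites <- function(chars) {
    stopifnot(length(chars) == 1L)
    b <- .encodeBases(chars[[1L]])
    L <- length(b)
    pos <- seq.int(2L, L - 1L)
    ctx <- 16L * b[pos - 1L] + 4L * b[pos] + b[pos + 1L]
    ctx32 <- .COLLAPSE$ctx32[ctx + 1L]
    ok <- !is.na(ctx32)
    split(pos[ok], factor(ctx32[ok], levels = seq_len(32L)))
}

#' Generate a neutral synthetic cohort
#'
#' Draws each tumour's burden from the log-uniform range in \code{spec},
#' then places that many SNVs across the genome with probability
#' proportional to the signature weight of the resulting mutation type:
#' context counts are multinomial over the 32 contexts (weight x available
#' sites), positions within a context are drawn uniformly without
#' replacement (so positions are unique within a tumour), and the
#' alternate allele follows the channel weights within the context. Genes
#' containing only these passenger mutations are therefore mutated in
#' proportion to burden x signature, the neutral premise of the skew test.
#'
#' @param genome named character vector (one contig), from
#'   \code{\link{generateGenome}}.
#' @param spec a \code{\link{fixtureSpec}}.
#' @param seed optional integer seed.
#' @return Typed mutation data.frame (columns as
#'   \code{\link{readMutationTable}}); per-tumour burdens attached as
#'   \code{attr(x, "burdens")}.
#' @export
generateNeutralCohort <- function(genome, spec, seed = NULL) {
    chars <- .asGenomeChars(genome)
    run <- function() {
        sites <- .contextSites(chars)
        nSites <- lengths(sites)
        w <- signatureWeights(spec$signature, spec$uvFraction)
        wCtx <- vapply(seq_len(32L), function(c)
            sum(w[.CTX_OF_CHANNEL == c]), numeric(1))
        siteWeight <- wCtx * nSites
        samples <- sprintf("T%03d", seq_len(spec$nTumours))
        burdens <- round(exp(stats::runif(spec$nTumours,
            log(max(spec$burdenRange[1], 1)), log(spec$burdenRange[2]))))
        if (any(burdens > sum(nSites)))
            stop("burden exceeds available sites")
        out <- vector("list", spec$nTumours)
        for (j in seq_len(spec$nTumours)) {
            B <- burdens[j]
            if (B == 0) next
            repeat {
                cnt <- as.vector(stats::rmultinom(1L, B, siteWeight))
                if (all(cnt <= nSites)) break
            }
            posL <- altL <- chanL <- vector("list", 32L)
            for (c in which(cnt > 0L)) {
                p <- sites[[c]][sample.int(nSites[c], cnt[c])]
                chIdx <- which(.CTX_OF_CHANNEL == c)  # 3 channels
                ch <- chIdx[sample.int(3L, cnt[c], replace = TRUE,
                    prob = w[chIdx])]
                posL[[c]] <- p
                chanL[[c]] <- ch
                altL[[c]] <- substr(.CHANNELS[ch], 5L, 5L)
            }
            pos <- unlist(posL); chan <- unlist(chanL); alt <- unlist(altL)
            ref <- substring(chars[[1L]], pos, pos)
            # channels were assigned in pyrimidine-collapsed space; recover
            # the genomic-strand alt where the reference base is a purine
            pur <- ref %in% c("A", "G")
            alt[pur] <- unname(.COMP[alt[pur]])
            out[[j]] <- data.frame(sample = samples[j],
                contig = names(chars), pos = pos, ref = ref, alt = alt,
                cancer_type = NA_character_, channel = chan,
                stringsAsFactors = FALSE)
        }
        res <- do.call(rbind, out)
        rownames(res) <- NULL
        attr(res, "burdens") <- stats::setNames(burdens, samples)
        res
    }
    if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Inject a burden-independent driver signal
#'
#' Picks \code{kd} tumours uniformly at random — ignoring burden, as a
#' selective force would — and gives each one qualifying (by default
#' non-synonymous) SNV at a random qualifying site of the region. The
#' returned records are only the additions; append them to a neutral
#' background so driver genes also carry passenger mutations.
#'
#' @param genome named character vector or \code{DNAStringSet}.
#' @param region a \code{\linkS4class{RegionSet}} of length 1.
#' @param samples cohort sample ids to draw from.
#' @param kd number of tumours to mutate.
#' @param effects qualifying effects.
#' @param seed optional integer seed.
#' @return Typed mutation data.frame of \code{kd} records.
#' @export
injectDriver <- function(genome, region, samples, kd,
        effects = c("missense", "nonsense"), seed = NULL) {
    stopifnot(kd >= 0L, kd <= length(samples))
    chars <- .asGenomeChars(genome)
    changes <- enumerateQualifyingChanges(region, chars, effects = effects)
    if (!nrow(changes)) stop("region has no qualifying site")
    run <- function() {
        chosen <- sample(samples, kd)
        idx <- sample.int(nrow(changes), kd, replace = TRUE)
        pos <- changes$pos[idx]
        data.frame(sample = chosen, contig = names(chars)[1L], pos = pos,
            ref = substring(chars[[1L]], pos, pos), alt = changes$alt[idx],
            cancer_type = NA_character_, channel = changes$channel[idx],
            stringsAsFactors = FALSE)
    }
    if (kd == 0L)
        return(data.frame(sample = character(0), contig = character(0),
            pos = integer(0), ref = character(0), alt = character(0),
            cancer_type = character(0), channel = integer(0),
            stringsAsFactors = FALSE))
    if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Generate a complete cohort fixture
#'
#' Convenience wrapper: genome + neutral cohort + injected drivers (chosen
#' at random among the genes) + truth table.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param seed integer seed controlling the whole fixture.
#' @return List with \code{genome}, \code{regions}, \code{mutations},
#'   \code{burdens} and \code{truth} (data.frame region_id / driver / kd).
#' @export
generateCohortFixture <- function(spec, seed = 1L) {
    .withSeed(seed, {
        gg <- generateGenome(spec)
        muts <- generateNeutralCohort(gg$genome, spec)
        samples <- names(attr(muts, "burdens"))
        ids <- regionIds(gg$regions)
        driverIds <- if (spec$nDrivers > 0L)
            sort(sample(ids, spec$nDrivers)) else character(0)
        add <- lapply(driverIds, function(id)
            injectDriver(gg$genome, gg$regions[id], samples,
                spec$driverRecurrence))
        mutations <- do.call(rbind, c(list(muts), add))
        rownames(mutations) <- NULL
        list(genome = gg$genome, regions = gg$regions,
            mutations = mutations, burdens = attr(muts, "burdens"),
            truth = data.frame(region_id = ids,
                driver = ids %in% driverIds,
                kd = ifelse(ids %in% driverIds, spec$driverRecurrence, 0L),
                stringsAsFactors = FALSE))
    })
}

#' Write a fixture to disk
#'
#' Writes the genome as FASTA, the gene models as BED12, the mutation
#' table as TSV and the truth table as TSV.
#'
#' @param fixture list from \code{\link{generateCohortFixture}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeFixture <- function(fixture, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
        regions = file.path(dir, "regions.bed"),
        mutations = file.path(dir, "mutations.tsv"),
        truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(fixture$genome), paths[["genome"]])
    writeBed12Regions(fixture$regions, paths[["regions"]])
    writeMutationTable(fixture$mutations, paths[["mutations"]])
    utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(paths)
}
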