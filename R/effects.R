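# Coding-effect annotation of single-base substitutions under the standard
# genetic code, and enumeration of a region's qualifying changes.

.GC <- Biostrings::GENETIC_CODE

# Coding map of a single region: the spliced coding-strand sequence and, in
# coding order, the genomic position of each coding base. Minus-strand
# regions are reverse complemented.
.codingMap <- function(blocks, kind, chrStr) {
    st <- as.character(strand(blocks))[1L]
    gpos <- unlist(lapply(seq_along(blocks), function(i)
        seq.int(start(blocks)[i], end(blocks)[i])), use.names = FALSE)
    bases <- strsplit(substringJoin(chrStr, blocks), "")[[1L]]
    if (st == "-") {
        gpos <- rev(gpos)
        bases <- rev(unname(.COMP[bases]))
        bases[is.na(bases)] <- "N"
    }
    list(strand = st, gpos = gpos, bases = bases)
}

# Concatenated substring over the blocks of one region.
substringJoin <- function(chrStr, blocks) {
    paste(substring(chrStr, start(blocks), end(blocks)), collapse = "")
}

#' Annotate the coding effect of substitutions
#'
#' Classifies single-base substitutions within one region as
#' \code{synonymous}, \code{missense} or \code{nonsense} under the standard
#' genetic code, resolving minus-strand regions on the coding strand.
#' Changes that turn a stop codon into a non-stop codon (stop-loss), or
#' disrupt the start codon, are folded into \code{missense}. Positions in
#' \code{kind = "interval"} regions are \code{noncoding}.
#'
#' @param region a \code{\linkS4class{RegionSet}} of length 1 (subset a
#'   larger set first, e.g. \code{regions["TP53"]}).
#' @param position 1-based genomic positions; must lie within the region's
#'   blocks (anything else is an error).
#' @param alt alternate alleles on the genomic plus strand.
#' @param genome \code{DNAStringSet} or named character vector.
#' @return Character vector of effects.
#' @examples
#' # single-codon gene TGG (Trp); G>A at the third base gives TGA (stop)
#' g <- c(chr1 = "ATGGA")
#' rs <- RegionSet(GenomicRanges::GRangesList(
#'     w = GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 4), strand = "+")))
#' annotateEffect(rs, 4, "A", g)
#' @export
annotateEffect <- function(region, position, alt, genome) {
    stopifnot(methods::is(region, "RegionSet"), length(region) == 1L)
    chars <- .asGenomeChars(genome)
    blocks <- regionBlocks(region)[[1L]]
    ct <- as.character(seqnames(blocks))[1L]
    .contigOrStop(chars, ct)
    n <- max(length(position), length(alt))
    position <- rep_len(as.integer(position), n)
    alt <- rep_len(toupper(as.character(alt)), n)

    map <- .codingMap(blocks, regionKind(region)[[1L]], chars[[ct]])
    idx <- match(position, map$gpos)
    if (anyNA(idx))
        stop(sprintf("position(s) outside region '%s' blocks: %s",
            regionIds(region),
            paste(utils::head(position[is.na(idx)], 3L), collapse = ", ")))
    if (regionKind(region)[[1L]] == "interval")
        return(rep("noncoding", n))

    altCoding <- if (map$strand == "-") unname(.COMP[alt]) else alt
    .codonEffects(map$bases, idx, altCoding)
}

# Effects for coding-strand substitutions: bases = coding sequence chars,
# idx = coding positions (1-based), altCoding = coding-strand alternate.
.codonEffects <- function(bases, idx, altCoding) {
    codonIdx <- (idx - 1L) %/% 3L
    within <- (idx - 1L) %% 3L
    c1 <- bases[codonIdx * 3L + 1L]
    c2 <- bases[codonIdx * 3L + 2L]
    c3 <- bases[codonIdx * 3L + 3L]
    refCodon <- paste0(c1, c2, c3)
    mutCodon <- refCodon
    mutCodon[within == 0L] <- paste0(altCoding, c2, c3)[within == 0L]
    mutCodon[within == 1L] <- paste0(c1, altCoding, c3)[within == 1L]
    mutCodon[within == 2L] <- paste0(c1, c2, altCoding)[within == 2L]
    aaRef <- unname(.GC[refCodon])
    aaAlt <- unname(.GC[mutCodon])
    eff <- rep(NA_character_, length(idx))
    ok <- !is.na(aaRef) & !is.na(aaAlt)
    eff[ok & aaRef == aaAlt] <- "synonymous"
    eff[ok & aaRef != aaAlt & aaAlt == "*"] <- "nonsense"
    eff[ok & aaRef != aaAlt & aaAlt != "*"] <- "missense"
    eff
}

#' Enumerate the qualifying single-base changes of a region
#'
#' Lists every possible single-base substitution in the region that passes
#' the effect filter, with its 96-channel mutation type. For CDS regions the
#' default filter keeps missense and nonsense changes (synonymous changes
#' are excluded, as selection is not expected to act on them); for interval
#' regions every change qualifies with effect \code{noncoding}. Positions
#' whose trinucleotide context contains a non-ACGT base or whose codon
#' cannot be translated are skipped.
#'
#' @param region a \code{\linkS4class{RegionSet}} of length 1.
#' @param genome \code{DNAStringSet} or named character vector.
#' @param effects effects retained for CDS regions.
#' @return data.frame with columns \code{pos}, \code{alt} (plus-strand),
#'   \code{channel}, \code{effect}, ordered by position then alt.
#' @export
enumerateQualifyingChanges <- function(region, genome,
        effects = c("missense", "nonsense")) {
    stopifnot(methods::is(region, "RegionSet"), length(region) == 1L)
    chars <- .asGenomeChars(genome)
    blocks <- regionBlocks(region)[[1L]]
    ct <- as.character(seqnames(blocks))[1L]
    .contigOrStop(chars, ct)
    kind <- regionKind(region)[[1L]]

    map <- .codingMap(blocks, kind, chars[[ct]])
    nPos <- length(map$gpos)
    # three coding-strand alts per position, in coding order; positions with
    # a non-ACGT reference base yield NA alts and are dropped
    altMat <- do.call(rbind, .ALTS)                       # 4 x 3, rows ACGT
    baseIdx <- match(map$bases, .BASES)
    altCoding <- as.vector(t(altMat[ifelse(is.na(baseIdx), 1L, baseIdx), ,
        drop = FALSE]))
    altCoding[rep(is.na(baseIdx), each = 3L)] <- NA_character_
    idx <- rep(seq_len(nPos), each = 3L)
    keep <- !is.na(altCoding)
    idx <- idx[keep]
    altCoding <- altCoding[keep]

    if (kind == "cds") {
        eff <- .codonEffects(map$bases, idx, altCoding)
        sel <- !is.na(eff) & eff %in% effects
    } else {
        eff <- rep("noncoding", length(idx))
        sel <- rep(TRUE, length(idx))
    }
    idx <- idx[sel]; altCoding <- altCoding[sel]; eff <- eff[sel]

    gpos <- map$gpos[idx]
    altGenomic <- if (map$strand == "-") unname(.COMP[altCoding]) else altCoding
    channel <- classifyMutationType(chars, ct, gpos, altGenomic)
    ok <- !is.na(channel)
    out <- data.frame(pos = gpos[ok], alt = altGenomic[ok],
        channel = channel[ok], effect = eff[ok], stringsAsFactors = FALSE)
    out <- out[order(out$pos, out$alt), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Filter observed mutations by coding effect
#'
#' Restricts a mutation table to records falling inside a region's blocks
#' whose annotated effect passes the filter. For \code{kind = "interval"}
#' regions all in-region records are retained as \code{noncoding}.
#'
#' @param mutations mutation data.frame (see
#'   \code{\link{readMutationTable}}).
#' @param region a \code{\linkS4class{RegionSet}} of length 1.
#' @param genome \code{DNAStringSet} or named character vector.
#' @param effects non-empty subset of
#'   \code{c("synonymous", "missense", "nonsense")} for CDS regions.
#' @return The retained records with an \code{effect} column appended.
#' @export
filterMutationsByEffect <- function(mutations, region, genome,
        effects = c("missense", "nonsense")) {
    stopifnot(length(effects) > 0L)
    blocks <- regionBlocks(region)[[1L]]
    ct <- as.character(seqnames(blocks))[1L]
    inRegion <- mutations$contig == ct &
        .posInBlocks(mutations$pos, blocks)
    sub <- mutations[inRegion, , drop = FALSE]
    if (!nrow(sub)) {
        sub$effect <- character(0)
        return(sub)
    }
    sub$effect <- annotateEffect(region, sub$pos, sub$alt, genome)
    if (regionKind(region)[[1L]] == "cds")
        sub <- sub[!is.na(sub$effect) & sub$effect %in% effects, ,
            drop = FALSE]
    rownames(sub) <- NULL
    sub
}

.posInBlocks <- function(pos, blocks) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_along(blocks))
        hit <- hit | (pos >= start(blocks)[i] & pos <= end(blocks)[i])
    hit
}
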