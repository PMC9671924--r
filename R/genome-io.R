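# Readers and writers for the standard interchange formats: MAF-like
# mutation TSVs, BED12 region models and promoter derivation.

#' Read a table of somatic SNV calls
#'
#' Reads a tab-separated mutation table with header columns \code{sample},
#' \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt} and optionally
#' \code{cancer_type}. Records are validated against the reference genome:
#' non-SNV rows (multi-base or non-ACGT alleles, or ref equal to alt),
#' rows whose reference base does not match the genome, and rows whose
#' trinucleotide context cannot be typed (N in the triplet, contig edge)
#' are dropped, with per-reason counts reported via \code{message} and
#' attached as \code{attr(x, "dropped")}.
#'
#' @param path TSV file path.
#' @param genome \code{DNAStringSet} or named character vector of contigs.
#' @return data.frame with columns \code{sample}, \code{contig}, \code{pos},
#'   \code{ref}, \code{alt}, \code{cancer_type} (\code{NA} if absent) and
#'   \code{channel} (integer 1..96, see \code{\link{mutationChannels}}).
#' @export
readMutationTable <- function(path, genome) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE, check.names = FALSE)
    required <- c("sample", "chrom", "pos", "ref", "alt")
    for (col in required)
        if (!col %in% names(tab))
            stop(sprintf("mutation table is missing required column '%s'", col))
    df <- data.frame(
        sample = as.character(tab$sample),
        contig = as.character(tab$chrom),
        pos = as.integer(tab$pos),
        ref = toupper(as.character(tab$ref)),
        alt = toupper(as.character(tab$alt)),
        cancer_type = if ("cancer_type" %in% names(tab))
            as.character(tab$cancer_type) else NA_character_,
        stringsAsFactors = FALSE)
    validateMutations(df, genome)
}

#' @rdname readMutationTable
#' @param mutations data.frame with columns \code{sample}, \code{contig},
#'   \code{pos}, \code{ref}, \code{alt} (and optionally \code{cancer_type})
#'   to validate and type in place of reading a file.
#' @export
validateMutations <- function(mutations, genome) {
    chars <- .asGenomeChars(genome)
    df <- mutations
    if (is.null(df$cancer_type)) df$cancer_type <- NA_character_
    .contigOrStop(chars, df$contig)

    isSnv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
        df$ref %in% .BASES & df$alt %in% .BASES & df$ref != df$alt
    dropped <- c(non_snv = sum(!isSnv))
    df <- df[isSnv, , drop = FALSE]

    refOk <- logical(nrow(df))
    for (ct in unique(df$contig)) {
        sel <- which(df$contig == ct)
        L <- nchar(chars[[ct]])
        pos <- df$pos[sel]
        inb <- pos >= 1L & pos <= L
        gref <- rep(NA_character_, length(pos))
        gref[inb] <- substring(chars[[ct]], pos[inb], pos[inb])
        refOk[sel] <- inb & gref == df$ref[sel]
    }
    dropped <- c(dropped, ref_mismatch = sum(!refOk))
    df <- df[refOk, , drop = FALSE]

    df$channel <- classifyMutationType(chars, df$contig, df$pos, df$alt)
    dropped <- c(dropped, untyped = sum(is.na(df$channel)))
    df <- df[!is.na(df$channel), , drop = FALSE]
    rownames(df) <- NULL

    if (any(dropped > 0))
        message(sprintf(
            "dropped %d record(s): %d non-SNV, %d reference mismatch, %d untyped",
            sum(dropped), dropped[["non_snv"]], dropped[["ref_mismatch"]],
            dropped[["untyped"]]))
    attr(df, "dropped") <- dropped
    df
}

#' Write a mutation table
#'
#' @param mutations mutation data.frame as returned by
#'   \code{\link{readMutationTable}}.
#' @param path output TSV path.
#' @export
writeMutationTable <- function(mutations, path) {
    out <- data.frame(sample = mutations$sample, chrom = mutations$contig,
        pos = mutations$pos, ref = mutations$ref, alt = mutations$alt,
        cancer_type = mutations$cancer_type, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
}

#' Read gene models from a BED12 file
#'
#' Imports a BED12 file (via \pkg{rtracklayer}) and converts each entry's
#' blocks into a \code{\linkS4class{RegionSet}} region. For
#' \code{kind = "cds"} the blocks are taken to be the CDS exons in genomic
#' order, spanning a complete reading frame on the annotated strand; entries
#' whose total block length is not divisible by 3 are dropped with a message
#' (they do not consist of full codons). Entries without a strand are
#' dropped likewise.
#'
#' @param path BED12 file path.
#' @param kind \code{"cds"} (default) or \code{"interval"}.
#' @return A \code{\linkS4class{RegionSet}} named by the BED \code{name}
#'   column.
#' @export
readBed12Regions <- function(path, kind = c("cds", "interval")) {
    kind <- match.arg(kind)
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || anyNA(gr$name))
        stop("BED12 entries must carry a name")
    keep <- as.character(strand(gr)) %in% c("+", "-")
    if (!all(keep)) {
        message(sprintf("dropping %d region(s) without strand", sum(!keep)))
        gr <- gr[keep]
    }
    blocks <- gr$blocks
    if (is.null(blocks))  # plain BED: single block spanning the entry
        blocks <- IRangesList(lapply(width(gr), function(w) IRanges(1L, w)))
    absBlocks <- shift(blocks, start(gr) - 1L)
    if (kind == "cds") {
        ok <- sum(width(absBlocks)) %% 3L == 0L
        if (!all(ok)) {
            message(sprintf(
                "dropping %d CDS region(s) whose length is not divisible by 3",
                sum(!ok)))
            gr <- gr[ok]
            absBlocks <- absBlocks[ok]
        }
    }
    grl <- GRangesList(lapply(seq_along(gr), function(i)
        GRanges(seqnames(gr)[i], absBlocks[[i]],
            strand = strand(gr)[i])))
    names(grl) <- gr$name
    RegionSet(grl, kind = kind)
}

# One span per region (min start to max end, keeping contig and strand).
.regionSpans <- function(grl) {
    st <- min(start(grl))
    en <- max(end(grl))
    u <- unlist(grl, use.names = FALSE)
    firstIdx <- cumsum(c(1L, utils::head(S4Vectors::elementNROWS(grl), -1L)))
    GRanges(seqnames(u)[firstIdx], IRanges(st, en),
        strand = strand(u)[firstIdx])
}

#' Write regions as BED12
#'
#' @param regions a \code{\linkS4class{RegionSet}}.
#' @param path output BED file path.
#' @export
writeBed12Regions <- function(regions, path) {
    grl <- regionBlocks(regions)
    gr <- .regionSpans(grl)
    gr$name <- names(grl)
    gr$blocks <- IRangesList(lapply(seq_along(grl), function(i)
        shift(IRanges(start(grl[[i]]), end(grl[[i]])),
            1L - start(gr)[i])))
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Derive promoter intervals from gene models
#'
#' Builds fixed-width promoter regions immediately upstream of each gene's
#' transcription start (the 5' end of the region on its annotated strand):
#' for a plus-strand gene the \code{width} bases before its first position,
#' for a minus-strand gene the \code{width} bases after its last. Promoters
#' truncated by a contig start are clipped; genes whose promoter would be
#' empty are dropped with a message.
#'
#' @param regions \code{\linkS4class{RegionSet}} or stranded \code{GRanges}
#'   of gene spans.
#' @param width promoter width in bp upstream of the start (default 500).
#' @param genome optional genome (\code{DNAStringSet} or named character)
#'   used to clip promoters at contig ends.
#' @return A \code{\linkS4class{RegionSet}} of \code{kind = "interval"}
#'   regions named \code{<gene>_promoter}.
#' @export
promoterRegions <- function(regions, width = 500L, genome = NULL) {
    if (methods::is(regions, "RegionSet")) {
        gr <- .regionSpans(regionBlocks(regions))
        names(gr) <- regionIds(regions)
    } else {
        gr <- regions
        if (is.null(names(gr))) stop("gene spans must be named")
    }
    prom <- GenomicRanges::promoters(gr, upstream = width, downstream = 0L)
    # clip at contig bounds
    newStart <- pmax(start(prom), 1L)
    if (!is.null(genome)) {
        chars <- .asGenomeChars(genome)
        .contigOrStop(chars, as.character(seqnames(prom)))
        lims <- nchar(chars)[as.character(seqnames(prom))]
        newEnd <- pmin(end(prom), lims)
    } else newEnd <- end(prom)
    keep <- newStart <= newEnd
    if (!all(keep))
        message(sprintf("dropping %d empty promoter(s) at contig edges",
            sum(!keep)))
    prom <- prom[keep]
    ranges(prom) <- IRanges(newStart[keep], newEnd[keep])
    grl <- GRangesList(lapply(seq_along(prom), function(i) prom[i]))
    names(grl) <- paste0(names(gr)[keep], "_promoter")
    RegionSet(grl, kind = "interval")
}
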