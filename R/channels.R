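# 96-channel substitution typing in pyrimidine-centred trinucleotide context.
#
# Encoding contract (stable, documented): channels are ordered
# lexicographically over (5' flank, central C/T, 3' flank, alternate base);
# the 32 contexts over (5' flank, central C/T, 3' flank). Purine-centred
# substitutions are mapped to the reverse complement so every substitution
# has exactly one channel.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.ALTS <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))

.buildChannels <- function() {
    out <- character(0)
    for (f in .BASES) for (ctr in c("C", "T")) for (t in .BASES)
        for (a in setdiff(.BASES, ctr))
            out <- c(out, sprintf("%s[%s>%s]%s", f, ctr, a, t))
    out
}

.buildContexts <- function() {
    out <- character(0)
    for (f in .BASES) for (ctr in c("C", "T")) for (t in .BASES)
        out <- c(out, paste0(f, ctr, t))
    out
}

.CHANNELS <- .buildChannels()   # length 96
.CONTEXTS <- .buildContexts()   # length 32

# context index (1..32) of each channel
.CTX_OF_CHANNEL <- match(
    paste0(substr(.CHANNELS, 1L, 1L), substr(.CHANNELS, 3L, 3L),
           substr(.CHANNELS, 7L, 7L)),
    .CONTEXTS)

# byte-code lookup: A,C,G,T -> 0..3, everything else NA
.BASECODE <- local({
    v <- rep(NA_integer_, 256L)
    v[utf8ToInt("A") + 1L] <- 0L
    v[utf8ToInt("C") + 1L] <- 1L
    v[utf8ToInt("G") + 1L] <- 2L
    v[utf8ToInt("T") + 1L] <- 3L
    v
})

# For a raw 64-context code (16*five + 4*central + three, codes 0..3 in
# A,C,G,T order): the pyrimidine-collapsed context index (1..32), and the
# channel index (1..96) for each alt code, NA where alt equals the reference.
.buildCollapseTables <- function() {
    ctx32 <- integer(64L)
    chan <- matrix(NA_integer_, 64L, 4L)
    comp <- c(3L, 2L, 1L, 0L)  # complement of codes 0..3
    for (code in 0:63) {
        f <- code %/% 16L; ctr <- (code %/% 4L) %% 4L; t <- code %% 4L
        if (ctr %in% c(1L, 3L)) {       # central C or T: keep
            key <- c(f, ctr, t)
        } else {                        # purine: reverse complement
            key <- c(comp[t + 1L], comp[ctr + 1L], comp[f + 1L])
        }
        ctxName <- paste0(.BASES[key[1L] + 1L], .BASES[key[2L] + 1L],
            .BASES[key[3L] + 1L])
        ctx32[code + 1L] <- match(ctxName, .CONTEXTS)
        for (a in 0:3) {
            if (a == ctr) next
            aKey <- if (ctr %in% c(1L, 3L)) a else comp[a + 1L]
            chName <- sprintf("%s[%s>%s]%s", .BASES[key[1L] + 1L],
                .BASES[key[2L] + 1L], .BASES[aKey + 1L],
                .BASES[key[3L] + 1L])
            chan[code + 1L, a + 1L] <- match(chName, .CHANNELS)
        }
    }
    list(ctx32 = ctx32, chan = chan)
}

.COLLAPSE <- .buildCollapseTables()

#' Mutation channel and context encodings
#'
#' The 96 substitution channels (e.g. \code{"A[C>T]G"}) and 32
#' pyrimidine-centred trinucleotide contexts (e.g. \code{"ACG"}) used
#' throughout the package, in their stable order: lexicographic over
#' (5' flank, central C/T, 3' flank, alternate base).
#'
#' @return Character vector of length 96 (channels) or 32 (contexts).
#' @examples
#' mutationChannels()[1:6]
#' trinucContexts()[1:4]
#' @export
mutationChannels <- function() .CHANNELS

#' @rdname mutationChannels
#' @export
trinucContexts <- function() .CONTEXTS

#' Context index of each mutation channel
#'
#' Maps channel indices (1..96) to their pyrimidine-centred context index
#' (1..32), e.g. for normalising channel counts by context territory.
#'
#' @param channel integer channel indices in 1..96.
#' @return Integer context indices in 1..32.
#' @export
channelContext <- function(channel = seq_len(96L)) .CTX_OF_CHANNEL[channel]

# genome helpers ------------------------------------------------------------

# Accept a Biostrings::DNAStringSet or a named character vector of uppercase
# contig sequences; return the latter.
.asGenomeChars <- function(genome) {
    if (is.character(genome)) {
        if (is.null(names(genome))) stop("genome contigs must be named")
        return(genome)
    }
    if (methods::is(genome, "DNAStringSet")) {
        if (is.null(names(genome))) stop("genome contigs must be named")
        return(stats::setNames(toupper(as.character(genome)), names(genome)))
    }
    stop("genome must be a DNAStringSet or a named character vector")
}

# Integer base codes (0..3, NA for N etc.) of one contig string.
.encodeBases <- function(chrStr) {
    .BASECODE[utf8ToInt(chrStr) + 1L]
}

.contigOrStop <- function(chars, contig) {
    bad <- setdiff(unique(contig), names(chars))
    if (length(bad))
        stop("unknown contig(s): ", paste(bad, collapse = ", "))
}

#' Read a reference genome from FASTA
#'
#' Thin wrapper around \code{\link[Biostrings]{readDNAStringSet}} that
#' uppercases the sequence and strips description text from contig names.
#'
#' @param path FASTA file path.
#' @return A \code{DNAStringSet} named by contig.
#' @export
readGenome <- function(path) {
    g <- Biostrings::readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    Biostrings::DNAStringSet(toupper(g))
}

#' Classify substitutions into 96 pyrimidine-centred channels
#'
#' Determines the trinucleotide context of each position from the genome and
#' returns the channel index of the substitution, collapsing purine-centred
#' changes onto the reverse-complement strand. Positions whose triplet
#' contains a non-ACGT base or lies at a contig edge are untyped (\code{NA}).
#'
#' @param genome \code{DNAStringSet} or named character vector of contigs.
#' @param contig,position,alt vectors (recycled to common length) giving the
#'   contig, 1-based position and alternate allele of each substitution.
#' @return Integer vector of channel indices (1..96, see
#'   \code{\link{mutationChannels}}), \code{NA} for untyped positions.
#' @examples
#' g <- c(chr1 = "AAAACAAA")
#' mutationChannels()[classifyMutationType(g, "chr1", 5, "T")]
#' @export
classifyMutationType <- function(genome, contig, position, alt) {
    chars <- .asGenomeChars(genome)
    n <- max(length(contig), length(position), length(alt))
    contig <- rep_len(as.character(contig), n)
    position <- rep_len(as.integer(position), n)
    alt <- rep_len(toupper(as.character(alt)), n)
    .contigOrStop(chars, contig)
    out <- rep(NA_integer_, n)
    altCode <- rep(NA_integer_, n)
    single <- !is.na(alt) & nchar(alt) == 1L
    if (any(single))
        altCode[single] <- .BASECODE[
            utf8ToInt(paste(alt[single], collapse = "")) + 1L]
    # per-contig vectorised lookup
    for (ct in unique(contig)) {
        sel <- which(contig == ct)
        b <- .encodeBases(chars[[ct]])
        L <- length(b)
        pos <- position[sel]
        ok <- pos >= 2L & pos <= L - 1L
        ctx <- rep(NA_integer_, length(pos))
        ctx[ok] <- 16L * b[pos[ok] - 1L] + 4L * b[pos[ok]] + b[pos[ok] + 1L]
        a <- altCode[sel]
        good <- !is.na(ctx) & !is.na(a)
        out[sel][good] <- .COLLAPSE$chan[cbind(ctx[good] + 1L, a[good] + 1L)]
    }
    out
}

#' Count trinucleotide territory
#'
#' Tallies, over a set of genomic intervals (or the whole genome), how many
#' positions fall in each of the 32 pyrimidine-centred trinucleotide
#' contexts. Each position is counted once on the reference strand with
#' purine-centred contexts collapsed to their reverse complement. Positions
#' whose triplet contains a non-ACGT base, or that lack a flanking base at a
#' contig edge, are excluded — consistently with
#' \code{\link{classifyMutationType}}, so that rate numerators and
#' denominators cover the same sites.
#'
#' @param genome \code{DNAStringSet} or named character vector.
#' @param regions optional \code{\linkS4class{RegionSet}} or \code{GRanges};
#'   overlapping intervals are merged so no position is counted twice.
#'   \code{NULL} counts the whole genome.
#' @return Named numeric vector of length 32 (see
#'   \code{\link{trinucContexts}}).
#' @examples
#' countTerritory(c(chr1 = "ACAC"))
#' @export
countTerritory <- function(genome, regions = NULL) {
    chars <- .asGenomeChars(genome)
    if (is.null(regions)) {
        gr <- GRanges(names(chars), IRanges(1L, nchar(chars)))
    } else {
        if (methods::is(regions, "RegionSet"))
            regions <- unlist(regionBlocks(regions), use.names = FALSE)
        if (length(regions) == 0L) stop("empty region set")
        gr <- reduce(granges(regions), ignore.strand = TRUE)
    }
    .contigOrStop(chars, as.character(seqnames(gr)))
    counts <- stats::setNames(numeric(32L), .CONTEXTS)
    for (ct in unique(as.character(seqnames(gr)))) {
        b <- .encodeBases(chars[[ct]])
        L <- length(b)
        sub <- gr[as.character(seqnames(gr)) == ct]
        if (any(start(sub) < 1L) || any(end(sub) > L))
            stop(sprintf("region outside bounds of contig '%s'", ct))
        pos <- unlist(lapply(seq_along(sub), function(i)
            seq.int(start(sub)[i], end(sub)[i])), use.names = FALSE)
        pos <- pos[pos >= 2L & pos <= L - 1L]
        if (!length(pos)) next
        ctx <- 16L * b[pos - 1L] + 4L * b[pos] + b[pos + 1L]
        ctx32 <- .COLLAPSE$ctx32[ctx + 1L]          # NA propagates (N bases)
        tab <- tabulate(ctx32[!is.na(ctx32)], 32L)
        counts <- counts + tab
    }
    counts
}
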