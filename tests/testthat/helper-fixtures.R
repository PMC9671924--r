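# Shared helpers for the test suite.

# A 32-context territory vector with the named contexts set and the rest 1
# (so no context present in test data ever has zero territory by accident).
makeTerritory <- function(..., default = 1) {
    set <- c(...)
    terr <- stats::setNames(rep(default, 32L), trinucContexts())
    terr[names(set)] <- set
    terr
}

# Single-region RegionSet on contig "chr1" from block coordinates.
cdsRegion <- function(starts, ends, strand = "+", id = "g1",
                      kind = "cds", contig = "chr1") {
    grl <- GenomicRanges::GRangesList(GenomicRanges::GRanges(contig,
        IRanges::IRanges(starts, ends), strand = strand))
    names(grl) <- id
    RegionSet(grl, kind = kind)
}

# Minimal typed mutation data.frame.
mutRecords <- function(sample, pos, ref, alt, contig = "chr1",
                       channel = NA_integer_) {
    data.frame(sample = sample, contig = contig, pos = as.integer(pos),
        ref = ref, alt = alt, cancer_type = NA_character_,
        channel = channel, stringsAsFactors = FALSE)
}

# Reference Benjamini-Hochberg step-up implementation, written directly
# from the definition: q_(i) = min_{j >= i} min(1, m * p_(j) / j).
refStepUp <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- pmin(1, m * p[ord] / seq_len(m))
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[ord] <- q
    out
}

# Brute-force sliding-window territory tally over one contig string,
# independent of the package's lookup tables.
bruteTerritory <- function(seqStr) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    counts <- stats::setNames(numeric(32L), trinucContexts())
    n <- nchar(seqStr)
    for (i in seq_len(max(n - 2L, 0L))) {
        tri <- substr(seqStr, i, i + 2L)
        b <- strsplit(tri, "")[[1L]]
        if (any(!b %in% names(comp))) next
        if (!b[2L] %in% c("C", "T"))
            tri <- paste(rev(unname(comp[b])), collapse = "")
        counts[tri] <- counts[tri] + 1
    }
    counts
}

# Random uppercase DNA string.
randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
    replace = TRUE), collapse = "")
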