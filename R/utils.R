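# Internal helpers shared across modules.

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Deterministic, locale-independent ordering of character vectors.
orderChr <- function(x) order(x, method = "radix")

# Validate a GRangesList of transcript models: per transcript the exons are
# non-empty, on one chromosome and strand, sorted, and pairwise disjoint.
validateTranscriptModels <- function(grl) {
    if (is.null(names(grl)) || anyDuplicated(names(grl)))
        stop("transcript models must carry unique names (transcript ids)")
    n <- S4Vectors::elementNROWS(grl)
    if (any(n == 0L))
        stop("transcript '", names(grl)[which(n == 0L)[1L]], "' has no exons")
    ugr <- unlist(grl, use.names = FALSE)
    txIdx <- rep.int(seq_along(grl), n)
    firstOf <- cumsum(c(1L, n[-length(n)]))
    chr <- as.integer(GenomicRanges::seqnames(ugr))
    if (any(chr != chr[firstOf][txIdx]))
        stop("each transcript must lie on a single chromosome")
    std <- as.integer(BiocGenerics::strand(ugr))
    if (any(std == 3L))  # '*'
        stop("transcript strand must be '+' or '-'")
    if (any(std != std[firstOf][txIdx]))
        stop("each transcript must lie on a single strand")
    ## sorted + disjoint: every exon must start strictly after the
    ## previous exon of its transcript ends
    if (any(n > 1L)) {
        us <- BiocGenerics::start(ugr)
        ue <- BiocGenerics::end(ugr)
        isLast <- logical(length(us))
        isLast[cumsum(n)] <- TRUE
        nxtStart <- c(us[-1L], NA_integer_)
        viol <- !isLast & nxtStart <= ue
        if (any(viol))
            stop("transcript '", names(grl)[txIdx[which(viol)[1L]]],
                 "' has unsorted or overlapping exons")
    }
    invisible(grl)
}

# Genomic span (one range per transcript) of a transcript GRangesList.
txSpan <- function(grl) {
    chr <- as.character(unlist(S4Vectors::runValue(
        GenomicRanges::seqnames(grl)), use.names = FALSE))
    std <- as.character(unlist(S4Vectors::runValue(
        BiocGenerics::strand(grl)), use.names = FALSE))
    sp <- GenomicRanges::GRanges(
        chr,
        IRanges::IRanges(min(BiocGenerics::start(grl)),
                         max(BiocGenerics::end(grl))),
        strand = std)
    names(sp) <- names(grl)
    sp
}

# Transcription start site of gene spans (start on '+', end on '-').
geneTss <- function(genes) {
    ifelse(as.character(BiocGenerics::strand(genes)) == "+",
           BiocGenerics::start(genes), BiocGenerics::end(genes))
}

# findOverlaps requires a shared seqlevel set; inputs from independent
# sources (e.g. a known catalog missing some chromosomes) are harmonized
# to the union so disjoint chromosomes simply never overlap.
harmonize <- function(query, subject) {
    ql <- GenomeInfoDb::seqlevels(query)
    sl <- GenomeInfoDb::seqlevels(subject)
    if (!setequal(ql, sl)) {
        lv <- union(ql, sl)
        GenomeInfoDb::seqlevels(query) <- lv
        GenomeInfoDb::seqlevels(subject) <- lv
    }
    list(query, subject)
}

anyOverlap <- function(query, subject, ignoreStrand) {
    h <- harmonize(query, subject)
    suppressWarnings(
        IRanges::overlapsAny(h[[1L]], h[[2L]], ignore.strand = ignoreStrand))
}

countOv <- function(query, subject, ignoreStrand) {
    h <- harmonize(query, subject)
    suppressWarnings(GenomicRanges::countOverlaps(
        h[[1L]], h[[2L]], ignore.strand = ignoreStrand))
}

hitSources <- c("cpc", "phylocsf", "pfam", "blastx")
evalueSources <- c("pfam", "blastx")
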