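#' Build promoter regions upstream of protein-coding TSSs
#'
#' The promoter of a gene is the window of \code{windowNt} nucleotides
#' immediately upstream of its transcription start site: for a plus-strand
#' gene with span \code{[s, e]} this is \code{[s - windowNt, s - 1]}
#' (clamped at the chromosome start), for a minus-strand gene
#' \code{[e + 1, e + windowNt]}. Windows that collapse to zero length are
#' omitted.
#'
#' @param genes a \code{GRanges} of gene spans with strand and a
#'   \code{gene_id} column (see [readGeneModels()]).
#' @param windowNt window size in nt, default 5000.
#' @return A \code{GRanges} of promoter windows carrying \code{gene_id}.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 12000), "+",
#'                             gene_id = "g1")
#' buildPromoterRegions(g)  # chr1:5001-10000
#' @export
buildPromoterRegions <- function(genes, windowNt = 5000L) {
    windowNt <- as.integer(windowNt)
    if (length(windowNt) != 1L || is.na(windowNt) || windowNt <= 0L)
        stop("'windowNt' must be a single positive integer")
    if (is.null(genes$gene_id)) stop("'genes' must carry a gene_id column")
    plus <- as.character(BiocGenerics::strand(genes)) == "+"
    st <- ifelse(plus,
                 pmax(1L, BiocGenerics::start(genes) - windowNt),
                 BiocGenerics::end(genes) + 1L)
    en <- ifelse(plus,
                 BiocGenerics::start(genes) - 1L,
                 BiocGenerics::end(genes) + windowNt)
    keep <- en >= st
    out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(genes)[keep],
        IRanges::IRanges(st[keep], en[keep]),
        strand = BiocGenerics::strand(genes)[keep],
        gene_id = genes$gene_id[keep])
    names(out) <- out$gene_id
    out
}

#' Classify candidate lncRNAs by genomic context
#'
#' A candidate is \code{promoter_associated} iff its genomic span overlaps
#' at least one promoter window by at least one nucleotide, tested
#' strand-agnostically (divergent transcription from a shared promoter is
#' thereby captured); all remaining candidates are long intergenic lncRNAs
#' (\code{lincRNA}). An informational \code{antisense} flag marks
#' candidates whose exons overlap a protein-coding gene span on the
#' opposite strand; it is a flag, not a third class.
#'
#' @param candidates a named \code{GRangesList} of candidate transcripts.
#' @param promoters promoter windows from [buildPromoterRegions()], built
#'   from the same gene set as \code{genes}.
#' @param genes the protein-coding gene spans.
#' @return A \code{DataFrame} with columns \code{transcript_id},
#'   \code{context} (\code{promoter_associated} or \code{lincRNA}) and
#'   \code{antisense}.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 12000), "+",
#'                             gene_id = "g1")
#' cand <- GenomicRanges::GRangesList(
#'     c1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(6001, 6500), "+"))
#' classifyContext(cand, buildPromoterRegions(g), g)
#' @export
classifyContext <- function(candidates, promoters, genes) {
    validateTranscriptModels(candidates)
    spans <- txSpan(candidates)
    inProm <- anyOverlap(spans, promoters, ignoreStrand = TRUE)
    ## antisense: exonic overlap with a gene span on the opposite strand
    flipped <- BiocGenerics::invertStrand(genes)
    anti <- anyOverlap(candidates, flipped, ignoreStrand = FALSE)
    S4Vectors::DataFrame(
        transcript_id = names(candidates),
        context = ifelse(inProm, "promoter_associated", "lincRNA"),
        antisense = anti)
}

#' Nearest protein-coding gene of each candidate
#'
#' For each candidate, the gene on the same chromosome minimising the
#' span-to-span gap; overlapping or abutting features have distance 0.
#' Ties are broken deterministically by smaller gene start, then
#' lexicographic gene id. The distance is signed: negative when the
#' candidate lies on the gene's TSS side (upstream of the gene), positive
#' when it lies on the 3' side, 0 on overlap. Candidates on a chromosome
#' without genes receive gene id \code{"none"} and distance \code{NA}.
#'
#' @param candidates a named \code{GRangesList} of candidate transcripts.
#' @param genes a \code{GRanges} of gene spans with \code{gene_id}.
#' @return A \code{DataFrame} with columns \code{transcript_id},
#'   \code{nearest_gene} and \code{distance}.
#' @examples
#' g <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(301, 451), c(400, 500)), "+",
#'     gene_id = c("g1", "g2"))
#' cand <- GenomicRanges::GRangesList(
#'     c1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' nearestGene(cand, g)  # g1 at distance -100 (candidate upstream)
#' @export
nearestGene <- function(candidates, genes) {
    validateTranscriptModels(candidates)
    if (is.null(genes$gene_id)) stop("'genes' must carry a gene_id column")
    spans <- txSpan(candidates)
    n <- length(spans)
    outGene <- rep("none", n)
    outDist <- rep(NA_integer_, n)
    gChr <- as.character(GenomicRanges::seqnames(genes))
    gStart <- BiocGenerics::start(genes)
    gEnd <- BiocGenerics::end(genes)
    gStrand <- as.character(BiocGenerics::strand(genes))
    gId <- genes$gene_id
    cChr <- as.character(GenomicRanges::seqnames(spans))
    cStart <- BiocGenerics::start(spans)
    cEnd <- BiocGenerics::end(spans)
    byChr <- split(seq_along(genes), gChr)
    for (i in seq_len(n)) {
        j <- byChr[[cChr[i]]]
        if (is.null(j) || !length(j)) next
        gap <- pmax(0L, pmax(gStart[j] - cEnd[i], cStart[i] - gEnd[j]) - 1L)
        o <- order(gap, gStart[j], gId[j], method = "radix")
        best <- j[o[1L]]
        d <- gap[o[1L]]
        if (d > 0L) {
            candLeft <- cEnd[i] < gStart[best]
            upstream <- (candLeft & gStrand[best] == "+") |
                        (!candLeft & gStrand[best] == "-")
            if (upstream) d <- -d
        }
        outGene[i] <- gId[best]
        outDist[i] <- d
    }
    S4Vectors::DataFrame(transcript_id = names(candidates),
                         nearest_gene = outGene,
                         distance = outDist)
}

#' Annotate candidates with context and nearest gene
#'
#' Convenience wrapper combining [buildPromoterRegions()],
#' [classifyContext()] and [nearestGene()].
#'
#' @inheritParams classifyContext
#' @param windowNt promoter window size in nt.
#' @return A \code{DataFrame} with columns \code{transcript_id},
#'   \code{context}, \code{antisense}, \code{nearest_gene},
#'   \code{distance}.
#' @export
annotateContext <- function(candidates, genes, windowNt = 5000L) {
    promoters <- buildPromoterRegions(genes, windowNt)
    ctx <- classifyContext(candidates, promoters, genes)
    ng <- nearestGene(candidates, genes)
    ctx$nearest_gene <- ng$nearest_gene
    ctx$distance <- ng$distance
    ctx
}
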