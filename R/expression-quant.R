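#' Count reads overlapping spliced features
#'
#' A read increments a transcript's count iff at least one nucleotide of
#' any read block overlaps any exon of the transcript (same strand required
#' only when \code{stranded}). A read may count toward several transcripts;
#' no disambiguation is attempted, matching a plain overlap count.
#'
#' @param reads a \code{GRanges} (single-block reads, e.g. from
#'   [readReadsBed()]) or \code{GRangesList} (blocked reads from the BAM
#'   adapter).
#' @param transcripts a named \code{GRangesList} of exons per transcript.
#' @param stranded require read and transcript strand to match
#'   (default \code{FALSE}).
#' @return Named integer vector of per-transcript read counts.
#' @examples
#' tx <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' rd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 180), "+")
#' countReads(rd, tx)
#' @export
countReads <- function(reads, transcripts, stranded = FALSE) {
    validateTranscriptModels(transcripts)
    cnt <- countOv(transcripts, reads, ignoreStrand = !stranded)
    stats::setNames(as.integer(cnt), names(transcripts))
}

#' Fragments per kilobase per million assigned reads
#'
#' \code{fpkm = count * 1e9 / (totalAssignedReads * splicedLengthNt)}.
#'
#' @param count read count(s), non-negative.
#' @param totalAssignedReads library normalisation denominator, >= 1.
#' @param splicedLengthNt spliced feature length(s) in nt, >= 1.
#' @return Numeric FPKM value(s).
#' @examples
#' fpkm(10, 1e6, 1000)  # 10
#' @export
fpkm <- function(count, totalAssignedReads, splicedLengthNt) {
    if (any(totalAssignedReads < 1))
        stop("'totalAssignedReads' must be >= 1")
    if (any(splicedLengthNt < 1))
        stop("'splicedLengthNt' must be >= 1")
    if (any(count < 0)) stop("counts must be >= 0")
    count * 1e9 / (as.numeric(totalAssignedReads) *
                   as.numeric(splicedLengthNt))
}

#' Enrichment fold change and tier
#'
#' The fold change is \code{(fpkmEC + c) / (fpkmNEC + c)} with pseudocount
#' \code{c}; the pseudocount keeps features unexpressed in one condition
#' finite. Tiers use inclusive bounds: \code{ge10} iff fold >= the upper
#' threshold, else \code{ge2} iff fold >= the lower threshold, else
#' \code{below2}; the upper tier is nested inside the lower by
#' construction.
#'
#' @param fpkmEC,fpkmNEC FPKM in the endothelial and non-endothelial
#'   condition.
#' @param pseudocount pseudocount \code{c}, default 0.01.
#' @return \code{foldChange}: numeric fold change(s).
#' @examples
#' foldChange(10, 1, pseudocount = 0)   # 10
#' enrichmentTier(c(12, 3, 1))          # ge10, ge2, below2
#' @export
foldChange <- function(fpkmEC, fpkmNEC, pseudocount = 0.01) {
    if (pseudocount < 0) stop("'pseudocount' must be >= 0")
    if (pseudocount == 0 && any(fpkmNEC == 0))
        stop("zero denominator: use a positive pseudocount or nonzero fpkmNEC")
    (fpkmEC + pseudocount) / (fpkmNEC + pseudocount)
}

#' @param fold fold change(s) from [foldChange()].
#' @param thresholds inclusive tier bounds, upper first (default
#'   \code{c(10, 2)}).
#' @return \code{enrichmentTier}: character vector of \code{ge10},
#'   \code{ge2}, \code{below2}.
#' @rdname foldChange
#' @export
enrichmentTier <- function(fold, thresholds = c(10, 2)) {
    if (length(thresholds) != 2L || diff(thresholds) >= 0)
        stop("'thresholds' must be two decreasing values")
    ifelse(fold >= thresholds[1L], "ge10",
           ifelse(fold >= thresholds[2L], "ge2", "below2"))
}

#' Quantify EC/NEC expression of transcript models
#'
#' Counts reads per condition, computes FPKM against each library's total
#' assigned reads, and assigns the enrichment fold change and tier.
#'
#' @param readsEC,readsNEC aligned reads of the endothelial and
#'   non-endothelial libraries (\code{GRanges} or \code{GRangesList}).
#' @param transcripts a named \code{GRangesList} of exons per transcript.
#' @param stranded strand-aware counting, default \code{FALSE}.
#' @param pseudocount FPKM pseudocount for the fold change.
#' @param thresholds inclusive tier bounds, upper first.
#' @param totalEC,totalNEC library sizes used as FPKM denominators;
#'   default the number of reads in each input.
#' @return A \code{DataFrame} with columns \code{transcript_id},
#'   \code{count_EC}, \code{count_NEC}, \code{fpkm_EC}, \code{fpkm_NEC},
#'   \code{fold_change} and \code{tier}.
#' @examples
#' tx <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' ec <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(110, 150), width = 20))
#' nec <- GenomicRanges::GRanges("chr1", IRanges::IRanges(120, width = 20))
#' quantifyExpression(ec, nec, tx)
#' @export
quantifyExpression <- function(readsEC, readsNEC, transcripts,
                               stranded = FALSE, pseudocount = 0.01,
                               thresholds = c(10, 2),
                               totalEC = length(readsEC),
                               totalNEC = length(readsNEC)) {
    cEC <- countReads(readsEC, transcripts, stranded)
    cNEC <- countReads(readsNEC, transcripts, stranded)
    len <- splicedLength(transcripts)
    fEC <- fpkm(cEC, totalEC, len)
    fNEC <- fpkm(cNEC, totalNEC, len)
    fold <- foldChange(fEC, fNEC, pseudocount)
    S4Vectors::DataFrame(
        transcript_id = names(transcripts),
        count_EC = cEC, count_NEC = cNEC,
        fpkm_EC = fEC, fpkm_NEC = fNEC,
        fold_change = fold,
        tier = enrichmentTier(fold, thresholds))
}
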