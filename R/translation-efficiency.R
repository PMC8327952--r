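#' Filter ribosome-profiling reads by footprint length
#'
#' Keeps reads whose total aligned length lies inside the inclusive window
#' \code{[minNt, maxNt]}; 27-32 nt is the canonical ribosome-footprint
#' range.
#'
#' @param reads a \code{GRanges} or \code{GRangesList} of aligned reads.
#' @param minNt,maxNt inclusive length bounds, nt.
#' @return The filtered reads, same container type as the input.
#' @examples
#' rd <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(1, width = c(26, 27, 30, 32, 33)))
#' filterRiboReads(rd)  # keeps widths 27, 30, 32
#' @export
filterRiboReads <- function(reads, minNt = 27L, maxNt = 32L) {
    if (minNt > maxNt)
        stop("'minNt' must not exceed 'maxNt'")
    len <- readLengths(reads)
    reads[len >= minNt & len <= maxNt]
}

#' Translation Efficiency Score
#'
#' The TES of a feature is the ratio of its ribosome-footprint read count
#' to its RNA-seq read count. When the RNA count is zero the score is
#' undefined (\code{NA}) and the negligible-translation call is
#' undetermined (\code{NA}) - an unexpressed feature is never classified.
#' Otherwise the feature shows negligible evidence of translation iff its
#' TES is strictly below \code{threshold}.
#'
#' @param riboCount,rnaCount non-negative integer count vectors (recycled).
#' @param threshold strict upper bound for the negligible-translation
#'   call, default 0.001.
#' @return A \code{DataFrame} with columns \code{ribo_count},
#'   \code{rna_count}, \code{tes} and \code{negligible_translation}
#'   (logical; \code{NA} = undetermined).
#' @examples
#' computeTes(c(0, 5, 1, 3), c(100, 1000, 1000, 0))
#' @export
computeTes <- function(riboCount, rnaCount, threshold = 0.001) {
    if (any(riboCount < 0) || any(rnaCount < 0))
        stop("counts must be >= 0")
    n <- max(length(riboCount), length(rnaCount))
    riboCount <- rep_len(riboCount, n)
    rnaCount <- rep_len(rnaCount, n)
    tes <- ifelse(rnaCount >= 1, riboCount / rnaCount, NA_real_)
    S4Vectors::DataFrame(
        ribo_count = as.integer(riboCount),
        rna_count = as.integer(rnaCount),
        tes = tes,
        negligible_translation = tes < threshold)
}

#' Per-transcript translation table
#'
#' Applies the footprint length filter, counts filtered ribosome reads and
#' RNA-seq reads over each transcript's exons with the same overlap rule
#' (see [countReads()]), and computes the TES. When several RNA libraries
#' are supplied their counts are pooled for the denominator.
#'
#' @param riboReads ribosome-profiling reads (\code{GRanges} or
#'   \code{GRangesList}).
#' @param rnaReads RNA-seq reads, or a list of such read sets to pool.
#' @param transcripts a named \code{GRangesList} of exons per transcript.
#' @param stranded strand-aware counting, default \code{FALSE}.
#' @param lengthBounds inclusive footprint-length window, nt.
#' @param threshold negligible-translation TES threshold.
#' @return A \code{DataFrame} with columns \code{transcript_id},
#'   \code{ribo_count}, \code{rna_count}, \code{tes},
#'   \code{negligible_translation}.
#' @examples
#' tx <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' ribo <- GenomicRanges::GRanges("chr1", IRanges::IRanges(110, width = 28))
#' rna <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(110, 150), width = 75))
#' tesTable(ribo, rna, tx)
#' @export
tesTable <- function(riboReads, rnaReads, transcripts, stranded = FALSE,
                     lengthBounds = c(27L, 32L), threshold = 0.001) {
    ribo <- filterRiboReads(riboReads, lengthBounds[1L], lengthBounds[2L])
    riboCount <- countReads(ribo, transcripts, stranded)
    if (!is.list(rnaReads)) rnaReads <- list(rnaReads)
    rnaCount <- Reduce(`+`, lapply(rnaReads, countReads,
                                   transcripts = transcripts,
                                   stranded = stranded))
    out <- computeTes(riboCount, rnaCount, threshold)
    out <- cbind(S4Vectors::DataFrame(transcript_id = names(transcripts)),
                 out)
    out
}

#' Category-wise TES summary
#'
#' Median, quartiles and negligible-translation fraction of the TES per
#' feature category (e.g. novel lncRNA, known noncoding, protein-coding),
#' the summary used to contrast translation evidence across classes.
#'
#' @param tes a table from [tesTable()] (or any data frame with
#'   \code{tes} and \code{negligible_translation} columns).
#' @param category character vector of category labels, one per row.
#' @return A \code{data.frame} with one row per category: \code{n},
#'   \code{n_determined}, \code{median_tes}, \code{q25}, \code{q75},
#'   \code{frac_negligible}.
#' @export
tesSummary <- function(tes, category) {
    stopifnot(length(category) == nrow(tes))
    cats <- unique(category)
    rows <- lapply(cats, function(cc) {
        t0 <- tes$tes[category == cc]
        neg <- tes$negligible_translation[category == cc]
        det <- !is.na(t0)
        data.frame(
            category = cc,
            n = sum(category == cc),
            n_determined = sum(det),
            median_tes = if (any(det)) stats::median(t0[det]) else NA_real_,
            q25 = if (any(det)) unname(stats::quantile(t0[det], 0.25)) else NA_real_,
            q75 = if (any(det)) unname(stats::quantile(t0[det], 0.75)) else NA_real_,
            frac_negligible = if (any(det)) mean(neg[det]) else NA_real_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
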