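#' Six-frame open reading frame detection
#'
#' Scans a nucleotide sequence for ATG-initiated open reading frames in all
#' six frames. Within a frame, a maximal ORF starts at the first ATG after
#' the previous stop codon and extends to the next in-frame stop (TAA, TAG
#' or TGA). Codons containing N never match ATG or a stop. ORFs that reach
#' the sequence end without a stop are reported only when
#' \code{allowOpenEnd} is \code{TRUE}.
#'
#' Positions are reported on the forward (input) sequence in 1-based
#' inclusive coordinates; for minus-strand frames the span is the
#' forward-strand footprint of the ORF found on the reverse complement.
#' The span of a complete ORF includes its stop codon, so
#' \code{aa_length = (end - start + 1)/3 - 1} when complete and
#' \code{(end - start + 1)/3} otherwise. \code{aa_length} counts the
#' initiator methionine and excludes the stop.
#'
#' @param sequence a single nucleotide string (or \code{DNAString}) over
#'   A, C, G, T, N; case-insensitive; length at least 3.
#' @param mode ORF convention; only \code{"atg_to_stop"} is implemented.
#' @param allowOpenEnd report ORFs lacking an in-frame stop before the
#'   sequence end (default \code{TRUE}).
#' @return A \code{data.frame} with columns \code{frame} (+1, +2, +3, -1,
#'   -2, -3), \code{start}, \code{end}, \code{aa_length} and
#'   \code{complete}, ordered by frame then start; zero rows when no ORF.
#' @examples
#' findOrfs("ATGAAATAA")          # one complete ORF, MK
#' findOrfs("TTACAT")             # ORF on the minus strand
#' findOrfs("ATGAAAAAA", allowOpenEnd = FALSE)  # open ORF suppressed
#' @seealso [longestOrfAa()], [scanOrfs()]
#' @export
findOrfs <- function(sequence, mode = "atg_to_stop", allowOpenEnd = TRUE) {
    mode <- match.arg(mode, "atg_to_stop")
    s <- toupper(as.character(sequence))
    if (length(s) != 1L || is.na(s) || !nzchar(s))
        stop("'sequence' must be a single non-empty nucleotide string")
    if (grepl("[^ACGTN]", s))
        stop("'sequence' contains characters outside A, C, G, T, N")
    n <- nchar(s)
    if (n < 3L)
        stop("'sequence' must be at least 3 nt long")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    res <- vector("list", 6L)
    k <- 0L
    for (strandChar in c("+", "-")) {
        subject <- if (strandChar == "+") s else rc
        for (off in 0:2) {
            k <- k + 1L
            res[[k]] <- scanFrame(subject, off, n, strandChar, allowOpenEnd)
        }
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

# One frame of one strand; returns ORFs mapped to forward coordinates.
scanFrame <- function(subject, off, n, strandChar, allowOpenEnd) {
    empty <- data.frame(frame = integer(), start = integer(),
                        end = integer(), aa_length = integer(),
                        complete = logical())
    nCodon <- (n - off) %/% 3L
    if (nCodon < 1L) return(empty)
    starts <- off + 3L * (seq_len(nCodon) - 1L) + 1L
    codons <- substring(subject, starts, starts + 2L)
    isAtg <- codons == "ATG"
    if (!any(isAtg)) return(empty)
    isStop <- codons %in% c("TAA", "TAG", "TGA")
    atgIdx <- which(isAtg)
    stopIdx <- which(isStop)
    ## segment of each ATG = number of stops strictly before it; keep the
    ## first ATG per segment (maximal ORFs)
    seg <- findInterval(atgIdx, stopIdx)
    first <- atgIdx[!duplicated(seg)]
    segOf <- seg[!duplicated(seg)]
    nxt <- segOf + 1L
    hasStop <- nxt <= length(stopIdx)
    stopAt <- ifelse(hasStop, stopIdx[pmin(nxt, length(stopIdx))], NA_integer_)
    if (!allowOpenEnd) {
        first <- first[hasStop]
        stopAt <- stopAt[hasStop]
        hasStop <- hasStop[hasStop]
    }
    if (!length(first)) return(empty)
    lastCodon <- ifelse(hasStop, stopAt, nCodon)
    aa <- ifelse(hasStop, lastCodon - first, lastCodon - first + 1L)
    ## positions on the scanned strand, 1-based inclusive
    sStart <- off + 3L * (first - 1L) + 1L
    sEnd <- off + 3L * lastCodon
    if (strandChar == "+") {
        fStart <- sStart
        fEnd <- sEnd
        frame <- off + 1L
    } else {
        fStart <- n - sEnd + 1L
        fEnd <- n - sStart + 1L
        frame <- -(off + 1L)
    }
    o <- order(fStart)
    data.frame(frame = rep.int(frame, length(first)),
               start = fStart, end = fEnd,
               aa_length = as.integer(aa),
               complete = hasStop)[o, , drop = FALSE]
}

#' Longest open reading frame, in amino acids
#'
#' The maximum \code{aa_length} over all six-frame ORFs found by
#' [findOrfs()]; 0 when the sequence contains no ATG-initiated ORF.
#'
#' @inheritParams findOrfs
#' @return A single integer number of amino acids.
#' @examples
#' longestOrfAa("ATGAAATAA")   # 2
#' longestOrfAa("CCCCCCCCC")   # 0
#' @export
longestOrfAa <- function(sequence, allowOpenEnd = TRUE) {
    orfs <- findOrfs(sequence, allowOpenEnd = allowOpenEnd)
    if (!nrow(orfs)) 0L else max(orfs$aa_length)
}

#' Scan transcript models for ORFs
#'
#' Extracts the spliced sequence of each transcript and reports its longest
#' ORF and ORF count, the per-transcript quantities consumed by the filter
#' cascade.
#'
#' @param genome a \code{DNAStringSet} named by chromosome.
#' @param transcripts a named \code{GRangesList} of exons per transcript.
#' @param allowOpenEnd passed to [findOrfs()].
#' @return A \code{data.frame} with columns \code{transcript_id},
#'   \code{longest_orf_aa} and \code{n_orfs}.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "AAATGAAATAACC"))
#' tx <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 13), "+"))
#' scanOrfs(genome, tx)
#' @export
scanOrfs <- function(genome, transcripts, allowOpenEnd = TRUE) {
    seqs <- extractSplicedSequence(genome, transcripts)
    res <- lapply(as.character(seqs), findOrfs, allowOpenEnd = allowOpenEnd)
    data.frame(
        transcript_id = names(transcripts),
        longest_orf_aa = vapply(res, function(d)
            if (nrow(d)) max(d$aa_length) else 0L, integer(1)),
        n_orfs = vapply(res, nrow, integer(1)),
        row.names = NULL)
}
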