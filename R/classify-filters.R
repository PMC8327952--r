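cascadeStages <- c("length", "orf", "cpc", "phylocsf", "pfam", "blastx")

#' Apply the candidate-lncRNA threshold cascade
#'
#' Evaluates each transcript against the filter stages in the fixed order
#' length, ORF, CPC, PhyloCSF, Pfam, BLASTx. The first failing stage halts
#' evaluation; later stages are marked \code{not_evaluated}. A transcript
#' passes the length stage iff its spliced length is strictly greater than
#' \code{minLengthNt}, the ORF stage iff its longest ORF is at most
#' \code{maxOrfAa} amino acids, the score stages iff its score is strictly
#' below the configured maximum, and the E-value stages iff its best
#' E-value is \emph{not} strictly below the cut. A transcript with no hit
#' record for a source passes that stage (hit tables are sparse).
#'
#' @param transcripts a named \code{GRangesList} of exons per transcript.
#' @param orfLengths named integer vector of longest-ORF lengths (aa), as
#'   from [scanOrfs()]; an entry is required for every transcript.
#' @param hits a hit table (see [readHitTable()]); may have zero rows.
#' @param thresholds a [FilterThresholds-class] object.
#' @return A \code{DataFrame} with \code{transcript_id}, one
#'   \code{stage_*} column per stage (levels \code{pass}, \code{fail},
#'   \code{not_evaluated}) and \code{final} (\code{candidate_lncRNA} or
#'   \code{rejected}), in input order.
#' @examples
#' tx <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 300), "+"))
#' applyThresholdFilters(tx, c(t1 = 40L),
#'     data.frame(transcript_id = character(), source = character(),
#'                value = numeric()),
#'     filterThresholds())
#' @export
applyThresholdFilters <- function(transcripts, orfLengths, hits,
                                  thresholds = filterThresholds()) {
    stopifnot(is(thresholds, "FilterThresholds"))
    validateTranscriptModels(transcripts)
    ids <- names(transcripts)
    miss <- setdiff(ids, names(orfLengths))
    if (length(miss))
        stop("no ORF length for transcript(s): ",
             paste(utils::head(miss, 5L), collapse = ", "),
             " - run the ORF scan first")
    hits <- hitTable(hits)
    lens <- splicedLength(transcripts)
    aa <- orfLengths[ids]

    hitVal <- function(source) {
        h <- hits[hits$source == source, , drop = FALSE]
        stats::setNames(h$value, h$transcript_id)[ids]
    }
    cpc <- hitVal("cpc"); phy <- hitVal("phylocsf")
    pfam <- hitVal("pfam"); blx <- hitVal("blastx")

    ## per-stage keep decisions; NA hit means no record, which passes
    keep <- cbind(
        length   = lens > thresholds@minLengthNt,
        orf      = aa <= thresholds@maxOrfAa,
        cpc      = is.na(cpc) | cpc < thresholds@cpcMaxScore,
        phylocsf = is.na(phy) | phy < thresholds@phylocsfMaxScore,
        pfam     = is.na(pfam) | !(pfam < thresholds@pfamEvalueCut),
        blastx   = is.na(blx) | !(blx < thresholds@blastxEvalueCut))

    flags <- matrix("not_evaluated", nrow = length(ids),
                    ncol = length(cascadeStages),
                    dimnames = list(NULL, cascadeStages))
    alive <- rep(TRUE, length(ids))
    for (stg in cascadeStages) {
        flags[alive, stg] <- ifelse(keep[alive, stg], "pass", "fail")
        alive <- alive & keep[, stg]
    }
    out <- S4Vectors::DataFrame(transcript_id = ids)
    for (stg in cascadeStages)
        out[[paste0("stage_", stg)]] <- flags[, stg]
    out$final <- unname(ifelse(alive, "candidate_lncRNA", "rejected"))
    out
}

#' Remove candidates with same-strand exonic protein-coding overlap
#'
#' A candidate is removed iff at least one nucleotide of its exons overlaps
#' an exon of a protein-coding transcript on the same strand. Antisense
#' overlaps survive: an lncRNA antisense to a coding 3' UTR is a
#' legitimate lncRNA, so the exclusion is strand-aware. Intron-only
#' overlaps also survive.
#'
#' @param candidates a named \code{GRangesList} of candidate transcripts.
#' @param coding a \code{GRangesList} of protein-coding transcript models.
#' @return A list with elements \code{kept} and \code{removed}, both
#'   \code{GRangesList} subsets of \code{candidates}.
#' @examples
#' cand <- GenomicRanges::GRangesList(
#'     c1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "-"))
#' cds <- GenomicRanges::GRangesList(
#'     p1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160), "+"))
#' excludeProteinCodingOverlap(cand, cds)$kept  # antisense survives
#' @export
excludeProteinCodingOverlap <- function(candidates, coding) {
    validateTranscriptModels(candidates)
    if (length(coding)) validateTranscriptModels(coding)
    hit <- anyOverlap(candidates, coding, ignoreStrand = FALSE)
    list(kept = candidates[!hit], removed = candidates[hit])
}

#' Split candidates into novel and known lncRNAs
#'
#' A candidate is labelled known iff at least one nucleotide of its exons
#' overlaps an entry of the known-lncRNA catalog on the same strand;
#' otherwise it is novel. Candidates on chromosomes absent from the known
#' catalog are novel.
#'
#' @param candidates a named \code{GRangesList} of candidate lncRNAs.
#' @param known a \code{GRangesList} of known lncRNA models.
#' @return A list with elements \code{novel} and \code{known}, both
#'   \code{GRangesList} subsets of \code{candidates}; their lengths sum to
#'   \code{length(candidates)}.
#' @examples
#' cand <- GenomicRanges::GRangesList(
#'     c1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"),
#'     c2 = GenomicRanges::GRanges("chr2", IRanges::IRanges(101, 200), "+"))
#' kn <- GenomicRanges::GRangesList(
#'     k1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' splitNovelVsKnown(cand, kn)
#' @export
splitNovelVsKnown <- function(candidates, known) {
    validateTranscriptModels(candidates)
    if (length(known)) validateTranscriptModels(known)
    hit <- anyOverlap(candidates, known, ignoreStrand = FALSE)
    list(novel = candidates[!hit], known = candidates[hit])
}
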