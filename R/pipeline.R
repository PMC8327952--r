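#' Run the full lncRNA discovery and annotation workflow
#'
#' Executes every stage in the fixed order ORF scan, threshold cascade,
#' protein-coding-overlap exclusion, novelty split, genomic-context
#' annotation, EC/NEC expression quantification and translation-efficiency
#' scoring, and joins the results into one catalog row per input
#' transcript, sorted lexicographically by transcript id. Context,
#' expression and translation columns are populated for all transcripts
#' (not only candidates) so the catalog has no missing values apart from
#' an undetermined TES.
#'
#' @param transcripts a named \code{GRangesList} of assembled transcript
#'   models (exons per transcript).
#' @param genome a \code{DNAStringSet} named by chromosome.
#' @param genes a \code{GRanges} of protein-coding gene spans with
#'   \code{gene_id}.
#' @param coding a \code{GRangesList} of protein-coding transcript models
#'   used by the overlap-exclusion stage.
#' @param known a \code{GRangesList} of known lncRNA models.
#' @param hits hit table of externally computed coding-potential and
#'   homology evidence (see [readHitTable()]).
#' @param readsEC,readsNEC,readsRibo aligned reads of the endothelial
#'   RNA-seq, non-endothelial RNA-seq and ribosome-profiling libraries.
#' @param param a [PipelineParam-class] bundling all thresholds.
#' @return An [LncCatalog-class].
#' @examples
#' par <- simulationParam(seed = 7, nCodingGenes = 3, nLincRNA = 3,
#'     nPromoterAssociated = 1, nKnownOverlap = 1, nAntisense = 1,
#'     genomeLengthNt = 3e5, nChromosomes = 1,
#'     rnaDepth = 2e4, riboDepth = 2e3)
#' ref <- generateReference(par)
#' reads <- simulateReads(par, ref)
#' cat <- runPipeline(ref$transcripts, ref$genome, ref$genes, ref$coding,
#'     ref$known, ref$hits, reads$ec, reads$nec, reads$ribo)
#' cat
#' @export
runPipeline <- function(transcripts, genome, genes, coding, known, hits,
                        readsEC, readsNEC, readsRibo,
                        param = pipelineParam()) {
    stopifnot(is(param, "PipelineParam"))
    validObject(param)
    validateTranscriptModels(transcripts)
    ids <- names(transcripts)

    ## 1. ORF scan
    orfs <- scanOrfs(genome, transcripts)
    orfAa <- stats::setNames(orfs$longest_orf_aa, orfs$transcript_id)

    ## 2. threshold cascade
    cascade <- applyThresholdFilters(transcripts, orfAa, hits,
                                     param@filters)
    survivors <- cascade$transcript_id[cascade$final == "candidate_lncRNA"]

    ## 3. same-strand protein-coding overlap exclusion
    excl <- excludeProteinCodingOverlap(transcripts[survivors], coding)
    overlapFlag <- rep("not_evaluated", length(ids))
    names(overlapFlag) <- ids
    overlapFlag[names(excl$kept)] <- "pass"
    overlapFlag[names(excl$removed)] <- "fail"
    candidates <- names(excl$kept)

    ## 4. novelty split (computed for every transcript; the candidate
    ## subset is what the counts report)
    novelAll <- names(splitNovelVsKnown(transcripts, known)$novel)
    novel <- stats::setNames(ids %in% novelAll, ids)

    ## 5. genomic context + nearest gene
    ctx <- annotateContext(transcripts, genes, param@promoterWindowNt)

    ## 6. expression quantification
    expr <- quantifyExpression(readsEC, readsNEC, transcripts,
                               stranded = param@stranded,
                               pseudocount = param@pseudocount,
                               thresholds = param@enrichmentThresholds)

    ## 7. translation efficiency (RNA denominator pools both conditions)
    tes <- tesTable(readsRibo, list(readsEC, readsNEC), transcripts,
                    stranded = param@stranded,
                    lengthBounds = param@riboLengthBounds,
                    threshold = param@tesThreshold)

    ## 8. join
    tab <- S4Vectors::DataFrame(
        transcript_id = ids,
        spliced_length = unname(splicedLength(transcripts)),
        longest_orf_aa = unname(orfAa[ids]))
    for (cc in setdiff(colnames(cascade), "transcript_id"))
        tab[[cc]] <- cascade[[cc]]
    tab$stage_coding_overlap <- unname(overlapFlag)
    tab$final <- ifelse(ids %in% candidates, "candidate_lncRNA", "rejected")
    tab$novel <- unname(novel)
    for (cc in c("context", "antisense", "nearest_gene", "distance"))
        tab[[cc]] <- ctx[[cc]]
    for (cc in setdiff(colnames(expr), "transcript_id"))
        tab[[cc]] <- expr[[cc]]
    for (cc in setdiff(colnames(tes), "transcript_id"))
        tab[[cc]] <- tes[[cc]]
    tab <- tab[orderChr(tab$transcript_id), ]
    rownames(tab) <- NULL

    stages <- c(
        input = length(ids),
        length = sum(cascade$stage_length == "pass"),
        orf = sum(cascade$stage_orf == "pass"),
        cpc = sum(cascade$stage_cpc == "pass"),
        phylocsf = sum(cascade$stage_phylocsf == "pass"),
        pfam = sum(cascade$stage_pfam == "pass"),
        blastx = sum(cascade$stage_blastx == "pass"),
        coding_overlap = length(candidates),
        candidates = length(candidates),
        novel = sum(novel[candidates]),
        known = sum(!novel[candidates]))

    new("LncCatalog", table = tab, stageCounts = stages, param = param)
}

#' Write a catalog to a TSV file
#'
#' Plain tab-separated output with a fixed, documented column order (the
#' order constructed by [runPipeline()]) and one row per transcript;
#' undetermined TES values are written as \code{NA}. Byte-identical across
#' runs for identical inputs.
#'
#' @param catalog an [LncCatalog-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
    stopifnot(is(catalog, "LncCatalog"))
    df <- as.data.frame(catalogTable(catalog))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read back a catalog table written by [writeCatalog()]
#'
#' @param path path to the TSV file.
#' @return A \code{data.frame}.
#' @export
readCatalog <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
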