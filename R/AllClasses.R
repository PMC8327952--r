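#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Filter thresholds for the lncRNA identification cascade
#'
#' Container for the numeric cut-offs applied by the candidate-lncRNA filter
#' cascade. A transcript is retained when its spliced length is strictly
#' greater than \code{minLengthNt}, its longest open reading frame is at most
#' \code{maxOrfAa} amino acids, its coding-potential scores (CPC, PhyloCSF)
#' are strictly below their respective maxima, and its best Pfam / BLASTx
#' E-values are not strictly below the corresponding cut (a hit with
#' E-value below the cut removes the transcript; absence of a hit passes).
#'
#' @slot minLengthNt integer, minimum spliced length in nucleotides
#'   (exclusive bound; default 200).
#' @slot maxOrfAa integer, maximum longest-ORF length in amino acids
#'   (inclusive bound; default 100).
#' @slot cpcMaxScore numeric, keep iff CPC score strictly below this
#'   (default 0).
#' @slot phylocsfMaxScore numeric, keep iff PhyloCSF score strictly below
#'   this (default 0).
#' @slot pfamEvalueCut numeric, drop iff best Pfam E-value strictly below
#'   this (default 1e-3).
#' @slot blastxEvalueCut numeric, drop iff best BLASTx E-value strictly
#'   below this (default 1e-4).
#'
#' @seealso [filterThresholds()], [applyThresholdFilters()]
#' @exportClass FilterThresholds
setClass("FilterThresholds",
    representation(
        minLengthNt = "integer",
        maxOrfAa = "integer",
        cpcMaxScore = "numeric",
        phylocsfMaxScore = "numeric",
        pfamEvalueCut = "numeric",
        blastxEvalueCut = "numeric"
    )
)

setValidity("FilterThresholds", function(object) {
    msg <- character()
    for (s in c("minLengthNt", "maxOrfAa", "cpcMaxScore", "phylocsfMaxScore",
                "pfamEvalueCut", "blastxEvalueCut")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v))
            msg <- c(msg, paste0("'", s, "' must be a single non-NA value"))
    }
    if (!length(msg)) {
        if (object@minLengthNt < 0L)
            msg <- c(msg, "'minLengthNt' must be >= 0")
        if (object@maxOrfAa < 0L)
            msg <- c(msg, "'maxOrfAa' must be >= 0")
        if (object@pfamEvalueCut <= 0)
            msg <- c(msg, "'pfamEvalueCut' must be positive")
        if (object@blastxEvalueCut <= 0)
            msg <- c(msg, "'blastxEvalueCut' must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct filter thresholds
#'
#' @param minLengthNt minimum spliced length in nt, strict lower bound.
#' @param maxOrfAa maximum longest-ORF length in amino acids, inclusive.
#' @param cpcMaxScore keep iff CPC score strictly below this value.
#' @param phylocsfMaxScore keep iff PhyloCSF score strictly below this value.
#' @param pfamEvalueCut drop iff best Pfam E-value strictly below this value.
#' @param blastxEvalueCut drop iff best BLASTx E-value strictly below this
#'   value.
#'
#' @return A [FilterThresholds-class] object.
#' @examples
#' filterThresholds()
#' filterThresholds(minLengthNt = 300)
#' @export
filterThresholds <- function(minLengthNt = 200L, maxOrfAa = 100L,
                             cpcMaxScore = 0, phylocsfMaxScore = 0,
                             pfamEvalueCut = 1e-3, blastxEvalueCut = 1e-4) {
    new("FilterThresholds",
        minLengthNt = as.integer(minLengthNt),
        maxOrfAa = as.integer(maxOrfAa),
        cpcMaxScore = as.numeric(cpcMaxScore),
        phylocsfMaxScore = as.numeric(phylocsfMaxScore),
        pfamEvalueCut = as.numeric(pfamEvalueCut),
        blastxEvalueCut = as.numeric(blastxEvalueCut))
}

#' Parameters controlling a full pipeline run
#'
#' Bundles every tunable constant of the workflow: cascade thresholds,
#' promoter window size, enrichment fold-change tier bounds, the FPKM
#' pseudocount, the ribosome-footprint length window, the negligible-
#' translation TES threshold, and the strandedness of read counting.
#'
#' @slot filters a [FilterThresholds-class] object.
#' @slot promoterWindowNt integer, promoter window upstream of a
#'   protein-coding TSS in nt (default 5000).
#' @slot enrichmentThresholds numeric(2), inclusive fold-change bounds of
#'   the upper and lower enrichment tiers (default \code{c(10, 2)}).
#' @slot pseudocount numeric, added to both FPKM values before forming the
#'   fold change (default 0.01).
#' @slot riboLengthBounds integer(2), inclusive ribosome-footprint length
#'   window in nt (default \code{c(27, 32)}).
#' @slot tesThreshold numeric, TES strictly below this is called
#'   negligible translation (default 0.001).
#' @slot stranded logical, whether read counting requires matching strand
#'   (default \code{FALSE}).
#'
#' @seealso [pipelineParam()], [runPipeline()]
#' @exportClass PipelineParam
setClass("PipelineParam",
    representation(
        filters = "FilterThresholds",
        promoterWindowNt = "integer",
        enrichmentThresholds = "numeric",
        pseudocount = "numeric",
        riboLengthBounds = "integer",
        tesThreshold = "numeric",
        stranded = "logical"
    )
)

setValidity("PipelineParam", function(object) {
    msg <- character()
    if (length(object@promoterWindowNt) != 1L || object@promoterWindowNt <= 0L)
        msg <- c(msg, "'promoterWindowNt' must be a single positive integer")
    if (length(object@enrichmentThresholds) != 2L ||
        any(object@enrichmentThresholds <= 0) ||
        diff(object@enrichmentThresholds) >= 0)
        msg <- c(msg, "'enrichmentThresholds' must be two decreasing positive values")
    if (length(object@pseudocount) != 1L || object@pseudocount < 0)
        msg <- c(msg, "'pseudocount' must be a single value >= 0")
    if (length(object@riboLengthBounds) != 2L ||
        object@riboLengthBounds[1L] > object@riboLengthBounds[2L] ||
        any(object@riboLengthBounds < 1L))
        msg <- c(msg, "'riboLengthBounds' must be an increasing pair of positive integers")
    if (length(object@tesThreshold) != 1L || object@tesThreshold <= 0)
        msg <- c(msg, "'tesThreshold' must be a single positive value")
    if (length(object@stranded) != 1L || is.na(object@stranded))
        msg <- c(msg, "'stranded' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct pipeline parameters
#'
#' @param filters a [FilterThresholds-class] object.
#' @param promoterWindowNt promoter window upstream of a protein-coding
#'   TSS, in nt.
#' @param enrichmentThresholds inclusive fold-change bounds of the two
#'   enrichment tiers, upper first.
#' @param pseudocount added to both FPKM values before the fold change.
#' @param riboLengthBounds inclusive ribosome-footprint length window, nt.
#' @param tesThreshold TES strictly below this is negligible translation.
#' @param stranded whether read counting is strand-aware.
#'
#' @return A [PipelineParam-class] object.
#' @examples
#' pipelineParam()
#' pipelineParam(stranded = TRUE, pseudocount = 0)
#' @export
pipelineParam <- function(filters = filterThresholds(),
                          promoterWindowNt = 5000L,
                          enrichmentThresholds = c(10, 2),
                          pseudocount = 0.01,
                          riboLengthBounds = c(27L, 32L),
                          tesThreshold = 0.001,
                          stranded = FALSE) {
    new("PipelineParam",
        filters = filters,
        promoterWindowNt = as.integer(promoterWindowNt),
        enrichmentThresholds = as.numeric(enrichmentThresholds),
        pseudocount = as.numeric(pseudocount),
        riboLengthBounds = as.integer(riboLengthBounds),
        tesThreshold = as.numeric(tesThreshold),
        stranded = as.logical(stranded))
}

#' Parameters of the synthetic-data generator
#'
#' Describes the study conditions the generator emulates: a toy genome,
#' planted protein-coding genes carrying >100-aa ORFs, planted lncRNAs of
#' each genomic-context class, RNA-seq libraries for sorted endothelial
#' (EC) and non-endothelial (NEC) cells with known FPKM fold changes, and a
#' ribosome-profiling library whose occupancy separates translated from
#' untranslated transcripts.
#'
#' @slot seed integer, seed for all randomness in the generator.
#' @slot genomeLengthNt integer, length of each toy chromosome in nt.
#' @slot nChromosomes integer, number of chromosomes.
#' @slot nCodingGenes integer, planted protein-coding genes (each with an
#'   embedded ORF of more than 100 amino acids).
#' @slot nLincRNA integer, planted long intergenic lncRNAs.
#' @slot nPromoterAssociated integer, planted lncRNAs overlapping the
#'   promoter window of a coding gene.
#' @slot nKnownOverlap integer, planted lincRNAs duplicated into the
#'   known-lncRNA catalog.
#' @slot nAntisense integer, planted lncRNAs antisense to the 3' region of
#'   a coding gene.
#' @slot ecFoldChanges numeric, FPKM fold changes (EC over NEC) cycled over
#'   the planted noncoding transcripts.
#' @slot rnaDepth integer, RNA-seq reads per condition library.
#' @slot riboDepth integer, nominal total ribosome-footprint reads.
#' @slot translatedTesTarget numeric, expected post-filter TES of
#'   translated transcripts.
#' @slot gcContent numeric in (0, 1), background GC content.
#' @slot rnaReadLengthNt integer, RNA-seq read length.
#' @slot riboLengthRange integer(2), footprint lengths drawn uniformly over
#'   this inclusive range (straddles the 27-32 nt filter on purpose).
#'
#' @seealso [simulationParam()], [generateReference()], [simulateReads()]
#' @exportClass SimulationParam
setClass("SimulationParam",
    representation(
        seed = "integer",
        genomeLengthNt = "integer",
        nChromosomes = "integer",
        nCodingGenes = "integer",
        nLincRNA = "integer",
        nPromoterAssociated = "integer",
        nKnownOverlap = "integer",
        nAntisense = "integer",
        ecFoldChanges = "numeric",
        rnaDepth = "integer",
        riboDepth = "integer",
        translatedTesTarget = "numeric",
        gcContent = "numeric",
        rnaReadLengthNt = "integer",
        riboLengthRange = "integer"
    )
)

setValidity("SimulationParam", function(object) {
    msg <- character()
    cnt <- c("nCodingGenes", "nLincRNA", "nPromoterAssociated",
             "nKnownOverlap", "nAntisense")
    for (s in cnt)
        if (slot(object, s) < 0L)
            msg <- c(msg, paste0("'", s, "' must be >= 0"))
    if (object@nChromosomes < 1L)
        msg <- c(msg, "'nChromosomes' must be >= 1")
    if (object@rnaDepth < 1L || object@riboDepth < 1L)
        msg <- c(msg, "read depths must be >= 1")
    if (any(object@ecFoldChanges <= 0))
        msg <- c(msg, "'ecFoldChanges' must all be positive")
    if (object@gcContent <= 0 || object@gcContent >= 1)
        msg <- c(msg, "'gcContent' must lie in (0, 1)")
    if (object@translatedTesTarget <= 0)
        msg <- c(msg, "'translatedTesTarget' must be positive")
    if (length(object@riboLengthRange) != 2L ||
        object@riboLengthRange[1L] > object@riboLengthRange[2L])
        msg <- c(msg, "'riboLengthRange' must be an increasing pair")
    if (object@rnaReadLengthNt < 1L)
        msg <- c(msg, "'rnaReadLengthNt' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct synthetic-data generator parameters
#'
#' The defaults define the standard simulated study: 50 coding genes, 50
#' lincRNAs, 10 promoter-associated lncRNAs, 10 lincRNAs shared with the
#' known catalog, 5 antisense lncRNAs, 1e6 RNA-seq reads per condition and
#' a nominal 1e5 ribosome footprints, with noncoding EC/NEC fold changes
#' cycling through 0.2, 1, 4 and 20.
#'
#' @param seed integer seed driving all randomness.
#' @param genomeLengthNt length of each toy chromosome, nt.
#' @param nChromosomes number of chromosomes.
#' @param nCodingGenes,nLincRNA,nPromoterAssociated,nKnownOverlap,nAntisense
#'   planted feature counts per class.
#' @param ecFoldChanges FPKM fold changes (EC over NEC) cycled over the
#'   planted noncoding transcripts.
#' @param rnaDepth RNA-seq reads per condition library.
#' @param riboDepth nominal total ribosome-footprint reads.
#' @param translatedTesTarget expected post-filter TES of translated
#'   transcripts.
#' @param gcContent background GC content in (0, 1).
#' @param rnaReadLengthNt RNA-seq read length, nt.
#' @param riboLengthRange inclusive footprint-length range, nt.
#'
#' @return A [SimulationParam-class] object.
#' @examples
#' simulationParam(seed = 1)
#' simulationParam(seed = 7, nCodingGenes = 5, nLincRNA = 5,
#'     nPromoterAssociated = 2, nKnownOverlap = 2, nAntisense = 1,
#'     genomeLengthNt = 4e5, rnaDepth = 1e5, riboDepth = 1e4)
#' @export
simulationParam <- function(seed = 1L,
                            genomeLengthNt = 1500000L,
                            nChromosomes = 2L,
                            nCodingGenes = 50L,
                            nLincRNA = 50L,
                            nPromoterAssociated = 10L,
                            nKnownOverlap = 10L,
                            nAntisense = 5L,
                            ecFoldChanges = c(0.2, 1, 4, 20),
                            rnaDepth = 1000000L,
                            riboDepth = 100000L,
                            translatedTesTarget = 0.1,
                            gcContent = 0.42,
                            rnaReadLengthNt = 75L,
                            riboLengthRange = c(26L, 34L)) {
    new("SimulationParam",
        seed = as.integer(seed),
        genomeLengthNt = as.integer(genomeLengthNt),
        nChromosomes = as.integer(nChromosomes),
        nCodingGenes = as.integer(nCodingGenes),
        nLincRNA = as.integer(nLincRNA),
        nPromoterAssociated = as.integer(nPromoterAssociated),
        nKnownOverlap = as.integer(nKnownOverlap),
        nAntisense = as.integer(nAntisense),
        ecFoldChanges = as.numeric(ecFoldChanges),
        rnaDepth = as.integer(rnaDepth),
        riboDepth = as.integer(riboDepth),
        translatedTesTarget = as.numeric(translatedTesTarget),
        gcContent = as.numeric(gcContent),
        rnaReadLengthNt = as.integer(rnaReadLengthNt),
        riboLengthRange = as.integer(riboLengthRange))
}

#' Result of a full pipeline run
#'
#' One row per input transcript, joining the filter-cascade flags, novelty,
#' genomic context, nearest protein-coding gene, expression (counts, FPKM,
#' fold change, enrichment tier) and translation (ribosome-footprint count,
#' TES, negligible-translation call). Per-stage survivor counts and the
#' parameters of the run are carried alongside.
#'
#' @slot table a \code{DataFrame} with one row per transcript.
#' @slot stageCounts named integer vector of per-stage survivor counts.
#' @slot param the [PipelineParam-class] the catalog was built with.
#'
#' @seealso [runPipeline()], [catalogTable()], [stageCounts()]
#' @exportClass LncCatalog
setClass("LncCatalog",
    representation(
        table = "DataFrame",
        stageCounts = "integer",
        param = "PipelineParam"
    )
)

setValidity("LncCatalog", function(object) {
    msg <- character()
    if (!"transcript_id" %in% colnames(object@table))
        msg <- c(msg, "catalog table must contain a 'transcript_id' column")
    else if (anyDuplicated(object@table$transcript_id))
        msg <- c(msg, "catalog must have one row per transcript")
    if (is.null(names(object@stageCounts)))
        msg <- c(msg, "'stageCounts' must be named")
    if (length(msg)) msg else TRUE
})

#' @describeIn LncCatalog-class number of transcripts in the catalog.
#' @param x,object an \code{LncCatalog}.
#' @export
setMethod("length", "LncCatalog", function(x) nrow(x@table))

#' Accessors for LncCatalog
#'
#' \code{catalogTable} returns the per-transcript table; \code{stageCounts}
#' returns the named vector of per-stage survivor counts;
#' \code{catalogParam} returns the parameters of the run.
#'
#' @param x an [LncCatalog-class].
#' @return a \code{DataFrame}, a named integer vector, or a
#'   [PipelineParam-class], respectively.
#' @name catalog-accessors
#' @examples
#' ## see ?runPipeline for construction of a catalog
NULL

#' @rdname catalog-accessors
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' @rdname catalog-accessors
#' @export
setMethod("catalogTable", "LncCatalog", function(x) x@table)

#' @rdname catalog-accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname catalog-accessors
#' @export
setMethod("stageCounts", "LncCatalog", function(x) x@stageCounts)

#' @rdname catalog-accessors
#' @export
setGeneric("catalogParam", function(x) standardGeneric("catalogParam"))

#' @rdname catalog-accessors
#' @export
setMethod("catalogParam", "LncCatalog", function(x) x@param)

setMethod("show", "FilterThresholds", function(object) {
    cat("FilterThresholds\n")
    cat("  spliced length     : > ", object@minLengthNt, " nt\n", sep = "")
    cat("  longest ORF        : <= ", object@maxOrfAa, " aa\n", sep = "")
    cat("  CPC score          : < ", object@cpcMaxScore, "\n", sep = "")
    cat("  PhyloCSF score     : < ", object@phylocsfMaxScore, "\n", sep = "")
    cat("  Pfam E-value drop  : < ", object@pfamEvalueCut, "\n", sep = "")
    cat("  BLASTx E-value drop: < ", object@blastxEvalueCut, "\n", sep = "")
})

setMethod("show", "PipelineParam", function(object) {
    cat("PipelineParam\n")
    show(object@filters)
    cat("  promoter window    : ", object@promoterWindowNt, " nt upstream of TSS\n",
        sep = "")
    cat("  enrichment tiers   : fold >= ",
        paste(object@enrichmentThresholds, collapse = ", fold >= "),
        "\n", sep = "")
    cat("  FPKM pseudocount   : ", object@pseudocount, "\n", sep = "")
    cat("  footprint lengths  : ", object@riboLengthBounds[1L], "-",
        object@riboLengthBounds[2L], " nt\n", sep = "")
    cat("  negligible TES     : < ", object@tesThreshold, "\n", sep = "")
    cat("  stranded counting  : ", object@stranded, "\n", sep = "")
})

setMethod("show", "SimulationParam", function(object) {
    cat("SimulationParam (seed ", object@seed, ")\n", sep = "")
    cat("  genome             : ", object@nChromosomes, " x ",
        object@genomeLengthNt, " nt, GC ", object@gcContent, "\n", sep = "")
    cat("  planted features   : ", object@nCodingGenes, " coding, ",
        object@nLincRNA, " lincRNA, ", object@nPromoterAssociated,
        " promoter-associated, ", object@nKnownOverlap, " known-overlap, ",
        object@nAntisense, " antisense\n", sep = "")
    cat("  EC/NEC fold changes: ",
        paste(object@ecFoldChanges, collapse = ", "), "\n", sep = "")
    cat("  depths             : RNA ", object@rnaDepth,
        " per condition, ribo ~", object@riboDepth, "\n", sep = "")
    cat("  translated TES     : ", object@translatedTesTarget, "\n", sep = "")
})

setMethod("show", "LncCatalog", function(object) {
    tab <- object@table
    cat("LncCatalog with ", nrow(tab), " transcripts\n", sep = "")
    cat("  candidate lncRNAs  : ",
        sum(tab$final == "candidate_lncRNA"), "\n", sep = "")
    if ("novel" %in% colnames(tab)) {
        cand <- tab$final == "candidate_lncRNA"
        cat("  novel / known      : ", sum(tab$novel[cand]), " / ",
            sum(!tab$novel[cand]), "\n", sep = "")
    }
    cat("  stage survivors    : ",
        paste(names(object@stageCounts), object@stageCounts,
              sep = "=", collapse = ", "), "\n", sep = "")
})
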