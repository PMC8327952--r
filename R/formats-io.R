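#' Read a genome FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that truncates
#' sequence names at the first whitespace, so chromosome names match those
#' used in GTF/BED annotation.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 toy", "ACGTACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    genome <- Biostrings::readDNAStringSet(path)
    names(genome) <- sub("\\s.*", "", names(genome))
    genome
}

#' Read transcript models from GTF or BED12
#'
#' Transcript models are represented as a named [GenomicRanges::GRangesList]
#' with one element per transcript holding its exons, sorted by genomic
#' start. GTF input uses the \code{exon} rows grouped by
#' \code{transcript_id}; BED12 input expands the block structure. Both
#' formats are converted to the 1-based closed coordinates used throughout
#' the Bioconductor stack (the BED 0-based half-open convention is handled
#' at this boundary by \pkg{rtracklayer}). Exons of one transcript must be
#' disjoint; violations raise an error naming the transcript.
#'
#' @param path path to the annotation file.
#' @param format \code{"gtf"} or \code{"bed12"}; never sniffed from the
#'   file name.
#' @return A named \code{GRangesList} of exons per transcript. Elements
#'   carry the transcript's strand; a \code{biotype} column is attached to
#'   the list metadata when the source provides one.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\ttx1\t0\t+", bed)
#' readTranscriptModels(bed, format = "bed12")
#' @export
readTranscriptModels <- function(path, format = c("gtf", "bed12")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "gtf") {
        gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                       error = function(e)
                           stop("parse error in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
        gr <- gr[!is.na(gr$type) & gr$type == "exon"]
        if (!length(gr)) stop("no exon records in ", path)
        if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
            stop("GTF exon rows must carry a transcript_id attribute")
        grl <- GenomicRanges::split(gr, gr$transcript_id)
    } else {
        gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                       error = function(e)
                           stop("parse error in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
        if (is.null(gr$name) || anyDuplicated(gr$name))
            stop("BED12 transcript names must be present and unique")
        if ("blocks" %in% colnames(S4Vectors::mcols(gr))) {
            grl <- rtracklayer::blocks(gr)
        } else {
            grl <- GenomicRanges::split(granges(gr), gr$name)[gr$name]
        }
        names(grl) <- gr$name
    }
    grl <- endoapply(grl, function(g) {
        g <- BiocGenerics::sort(g, ignore.strand = TRUE)
        S4Vectors::mcols(g) <- NULL
        g
    })
    validateTranscriptModels(grl)
}

#' Write transcript models to BED12
#'
#' Inverse of [readTranscriptModels()] for the BED12 format; exon structure,
#' strand and transcript ids round-trip.
#'
#' @param grl a named \code{GRangesList} of exons per transcript.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\ttx1\t0\t+", bed)
#' tx <- readTranscriptModels(bed, format = "bed12")
#' writeTranscriptModels(tx, tempfile(fileext = ".bed"))
#' @export
writeTranscriptModels <- function(grl, path) {
    validateTranscriptModels(grl)
    bed <- rtracklayer::asBED(grl)
    rtracklayer::export(bed, path, format = "bed")
    invisible(path)
}

#' Read protein-coding gene models
#'
#' Gene models are single-span features (a [GenomicRanges::GRanges] with
#' one range per gene) carrying \code{gene_id} and \code{biotype} metadata
#' columns. GTF input uses \code{gene} rows when present, otherwise the
#' per-gene range of its exon rows; BED input uses the \code{name} column
#' as the gene id.
#'
#' @param path path to the annotation file.
#' @param format \code{"gtf"} or \code{"bed"}.
#' @param biotype biotype assigned when the source does not state one
#'   (default \code{"protein_coding"}).
#' @return A \code{GRanges} named by gene id with \code{gene_id} and
#'   \code{biotype} columns.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t1000\t3000\tgeneA\t0\t+", bed)
#' readGeneModels(bed, format = "bed")
#' @export
readGeneModels <- function(path, format = c("gtf", "bed"),
                           biotype = "protein_coding") {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "gtf") {
        gr <- rtracklayer::import(path, format = "gtf")
        genes <- gr[!is.na(gr$type) & gr$type == "gene"]
        if (!length(genes)) {
            if (is.null(gr$gene_id)) stop("GTF lacks gene rows and gene_id")
            sp <- unlist(BiocGenerics::range(
                GenomicRanges::split(gr, gr$gene_id)))
            genes <- sp
            genes$gene_id <- names(sp)
        }
        bt <- genes$gene_biotype
        if (is.null(bt)) bt <- genes$gene_type
        if (is.null(bt)) bt <- rep(biotype, length(genes))
        out <- GenomicRanges::granges(genes)
        out$gene_id <- genes$gene_id
        out$biotype <- bt
    } else {
        gr <- rtracklayer::import(path, format = "bed")
        if (is.null(gr$name)) stop("BED gene records must carry names")
        out <- GenomicRanges::granges(gr)
        out$gene_id <- gr$name
        out$biotype <- rep(biotype, length(gr))
    }
    if (anyDuplicated(out$gene_id)) stop("duplicated gene ids in ", path)
    names(out) <- out$gene_id
    out
}

#' Read aligned reads from BED6
#'
#' Each BED6 line becomes one single-block aligned read; the read length is
#' the interval width. Spliced alignments enter through the BAM adapter
#' ([readReadsBam()]) instead.
#'
#' @param path path to a BED6 file.
#' @return A \code{GRanges}, one range per read.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t150\t225\tr1\t0\t+", bed)
#' readReadsBed(bed)
#' @export
readReadsBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "bed")
    S4Vectors::mcols(gr) <- NULL
    gr
}

#' Read aligned reads from BAM (adapter)
#'
#' Optional adapter converting BAM alignments to the block representation
#' used by the counting functions: each alignment becomes its set of
#' aligned blocks (CIGAR N gaps split blocks). Requires \pkg{Rsamtools}
#' and \pkg{GenomicAlignments}.
#'
#' @param path path to a BAM file.
#' @return A \code{GRangesList} with one element (the aligned blocks) per
#'   read.
#' @export
readReadsBam <- function(path) {
    if (!requireNamespace("Rsamtools", quietly = TRUE) ||
        !requireNamespace("GenomicAlignments", quietly = TRUE))
        stop("the BAM adapter requires Rsamtools and GenomicAlignments")
    if (!file.exists(path)) stop("no such file: ", path)
    aln <- GenomicAlignments::readGAlignments(path)
    GenomicAlignments::grglist(aln)
}

#' Total aligned length of each read
#'
#' @param reads a \code{GRanges} (single-block reads) or \code{GRangesList}
#'   (blocked reads).
#' @return Integer vector of read lengths in nt (sum of block widths).
#' @examples
#' readLengths(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 75)))
#' @export
readLengths <- function(reads) {
    if (is(reads, "GRangesList"))
        as.integer(sum(BiocGenerics::width(reads)))
    else
        BiocGenerics::width(reads)
}

#' Read a coding-potential / homology hit table
#'
#' The integration point for externally computed evidence: a TSV with
#' columns \code{transcript_id}, \code{source} and \code{value}, where
#' \code{source} is one of \code{cpc}, \code{phylocsf} (scores; larger
#' means more coding-like) or \code{pfam}, \code{blastx} (E-values; smaller
#' means more significant). One best record is kept per (transcript,
#' source): the maximum for scores, the minimum for E-values.
#'
#' @param path path to the TSV file.
#' @return A \code{data.frame} with one row per (transcript, source).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\tsource\tvalue",
#'              "tx1\tpfam\t0.01", "tx1\tpfam\t1e-4"), tsv)
#' readHitTable(tsv)
#' @export
readHitTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "source", "value")
    if (!all(need %in% colnames(df)))
        stop("hit table must have columns: ", paste(need, collapse = ", "))
    hitTable(df[need])
}

#' Validate and deduplicate a hit table
#'
#' @param df a \code{data.frame} with columns \code{transcript_id},
#'   \code{source}, \code{value}.
#' @return The validated table, one best row per (transcript, source).
#' @rdname readHitTable
#' @export
hitTable <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    bad <- setdiff(unique(df$source), hitSources)
    if (length(bad))
        stop("unknown hit source(s): ", paste(bad, collapse = ", "),
             " (expected ", paste(hitSources, collapse = ", "), ")")
    if (!is.numeric(df$value)) stop("hit values must be numeric")
    isE <- df$source %in% evalueSources
    if (any(df$value[isE] < 0))
        stop("E-values must be >= 0")
    if (!nrow(df)) return(df)
    ## best per (transcript, source): min for E-values, max for scores
    key <- paste(df$transcript_id, df$source, sep = "\r")
    rank <- ifelse(isE, df$value, -df$value)
    o <- order(key, rank, method = "radix")
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(key[o]), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Spliced length of transcript models
#'
#' @param grl a \code{GRangesList} of exons per transcript.
#' @return Named integer vector of summed exon widths.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\ttx1\t0\t+", bed)
#' splicedLength(readTranscriptModels(bed, format = "bed12"))
#' @export
splicedLength <- function(grl) {
    len <- as.integer(sum(BiocGenerics::width(grl)))
    names(len) <- names(grl)
    len
}

#' Extract the spliced sequence of transcript models
#'
#' Concatenates the exon substrings of the genome in genomic order and
#' reverse-complements the concatenation as one unit for minus-strand
#' transcripts, yielding the 5'-to-3' transcript sequence.
#'
#' @param genome a \code{DNAStringSet} named by chromosome.
#' @param grl a named \code{GRangesList} of exons per transcript.
#' @return A \code{DNAStringSet}, one sequence per transcript, with
#'   lengths equal to [splicedLength()].
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "AAACGTTTGG"))
#' tx <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 5), "+"))
#' extractSplicedSequence(genome, tx)
#' @export
extractSplicedSequence <- function(genome, grl) {
    validateTranscriptModels(grl)
    chr <- as.character(unlist(S4Vectors::runValue(
        GenomicRanges::seqnames(grl)), use.names = FALSE))
    miss <- setdiff(unique(chr), names(genome))
    if (length(miss))
        stop("chromosome(s) absent from genome: ",
             paste(miss, collapse = ", "))
    chromLen <- stats::setNames(BiocGenerics::width(genome), names(genome))
    maxEnd <- max(BiocGenerics::end(grl))
    minStart <- min(BiocGenerics::start(grl))
    if (any(minStart < 1L) || any(maxEnd > chromLen[chr]))
        stop("exon out of chromosome bounds for transcript '",
             names(grl)[which(minStart < 1L | maxEnd > chromLen[chr])[1L]],
             "'")
    strandOf <- as.character(unlist(S4Vectors::runValue(
        BiocGenerics::strand(grl)), use.names = FALSE))
    seqs <- vapply(seq_along(grl), function(i) {
        ex <- grl[[i]]
        pieces <- Biostrings::extractAt(
            genome[[chr[i]]],
            IRanges::IRanges(BiocGenerics::start(ex), BiocGenerics::end(ex)))
        paste(as.character(pieces), collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    neg <- strandOf == "-"
    if (any(neg))
        out[neg] <- Biostrings::reverseComplement(out[neg])
    names(out) <- names(grl)
    out
}
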