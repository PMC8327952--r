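# Synthetic reference and read simulator with a known truth manifest.
#
# Sequence construction uses a "stop cassette", a 15-mer containing a stop
# codon in every reading frame of both strands; interleaving it with short
# random chunks bounds the longest possible ORF well below the 50-aa margin
# required of planted noncoding transcripts, which is then verified against
# the package's own ORF scanner.
stopCassette <- "TAATTAATTAATTAA"

# Random DNA as a character vector of single letters.
randomBases <- function(n, gc) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# ORF-poor sequence on both strands: cassette + 85-nt random chunks,
# beginning with a cassette so concatenations stay bounded.
noncodingSeq <- function(len, gc) {
    out <- character(0)
    while (sum(nchar(out)) < len) {
        out <- c(out, stopCassette,
                 paste(randomBases(85L, gc), collapse = ""))
    }
    substr(paste(out, collapse = ""), 1L, len)
}

# Spliced sequence of a planted coding transcript: short 5' UTR, an
# ATG-initiated ORF of `orfAa` amino acids, and an ORF-poor tail (the tail
# must stay ORF-poor on both strands because antisense lncRNAs overlap it).
codingSplicedSeq <- function(len, gc, orfAa = 111L, utrNt = 45L) {
    senseCodons <- setdiff(
        apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          c("A", "C", "G", "T")), 1L, paste, collapse = ""),
        c("TAA", "TAG", "TGA"))
    orf <- paste0("ATG",
                  paste(sample(senseCodons, orfAa - 1L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    stopifnot(nchar(orf) == 3L * (orfAa + 1L))
    tailLen <- len - utrNt - nchar(orf)
    stopifnot(tailLen > 0L)
    paste0(paste(randomBases(utrNt, gc), collapse = ""), orf,
           noncodingSeq(tailLen, gc))
}

# Write a spliced sequence into the chromosome letter vectors. For a minus
# strand transcript the reverse complement of the spliced sequence is laid
# across the exons in genomic order.
plantSequence <- function(chromLetters, chrom, exons, strandChar, spliced) {
    genomic <- if (strandChar == "-")
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(spliced)))
    else spliced
    stopifnot(nchar(genomic) == sum(exons$width))
    pos <- 1L
    for (i in seq_len(nrow(exons))) {
        w <- exons$width[i]
        piece <- strsplit(substr(genomic, pos, pos + w - 1L), "")[[1L]]
        chromLetters[[chrom]][exons$start[i]:(exons$start[i] + w - 1L)] <-
            piece
        pos <- pos + w
    }
    chromLetters
}

#' Generate a synthetic reference with known ground truth
#'
#' Builds a toy genome and plants, with generous spacing, protein-coding
#' genes (two-exon transcripts carrying an embedded ORF of more than 100
#' amino acids), long intergenic lncRNAs, promoter-associated lncRNAs
#' (overlapping the 5-kb window upstream of a coding TSS),
#' known-catalog-overlap lincRNAs (duplicated into the known-lncRNA set)
#' and antisense lncRNAs (overlapping a coding 3' region on the opposite
#' strand). Planted noncoding sequences are constructed to contain no
#' ATG-initiated ORF longer than 50 amino acids in any of the six frames
#' and verified against [longestOrfAa()]. The hit table gives every coding
#' transcript a Pfam E-value of 1e-6 and a CPC score of +1; noncoding
#' transcripts get no hits. All randomness derives from the seed; the same
#' parameters always yield identical output.
#'
#' @param param a [SimulationParam-class] object.
#' @return A list with elements \code{genome} (\code{DNAStringSet}),
#'   \code{transcripts} (\code{GRangesList}, all planted transcripts),
#'   \code{coding} (\code{GRangesList} of the protein-coding subset),
#'   \code{genes} (\code{GRanges} of coding gene spans), \code{known}
#'   (\code{GRangesList}, the known-lncRNA catalog), \code{hits}
#'   (hit-table \code{data.frame}) and \code{truth} (the truth manifest,
#'   one row per planted transcript).
#' @examples
#' ref <- generateReference(simulationParam(seed = 7, nCodingGenes = 3,
#'     nLincRNA = 3, nPromoterAssociated = 1, nKnownOverlap = 1,
#'     nAntisense = 1, genomeLengthNt = 3e5, nChromosomes = 1))
#' ref$truth[, c("transcript_id", "class")]
#' @export
generateReference <- function(param) {
    stopifnot(is(param, "SimulationParam"))
    validObject(param)
    if (param@nPromoterAssociated + param@nAntisense > param@nCodingGenes)
        stop("need at least nPromoterAssociated + nAntisense coding genes ",
             "to host promoter-associated and antisense lncRNAs")
    withSeed(param@seed, buildReference(param))
}

buildReference <- function(param) {
    gc <- param@gcContent
    chroms <- sprintf("chr%d", seq_len(param@nChromosomes))
    L <- param@genomeLengthNt
    chromLetters <- stats::setNames(
        lapply(chroms, function(x) randomBases(L, gc)), chroms)

    fmtId <- function(prefix, i) sprintf("%s_%03d", prefix, i)
    ## planted feature bookkeeping
    exonList <- list(); txStrand <- character(); txChrom <- character()
    txClass <- character(); txId <- character()
    geneRows <- list()
    knownExon <- list(); knownOf <- character()

    ## unit plan: coding genes first (hosting promoter/antisense lncRNAs),
    ## then plain lincRNAs and known-overlap lincRNAs
    nCod <- param@nCodingGenes
    units <- c(rep("coding", nCod), rep("linc", param@nLincRNA),
               rep("klinc", param@nKnownOverlap))
    hostProm <- seq_len(param@nPromoterAssociated)
    hostAnti <- param@nPromoterAssociated + seq_len(param@nAntisense)
    cursors <- stats::setNames(rep(1000L, length(chroms)), chroms)
    margin <- 2000L
    interUnit <- 12000L
    iCod <- 0L; iLinc <- 0L; iKlinc <- 0L; iProm <- 0L; iAnti <- 0L

    codingSeqs <- list()
    orfRegion <- list()
    addTx <- function(id, chrom, exons, strandChar, class) {
        exonList[[id]] <<- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(exons$start,
                                    exons$start + exons$width - 1L),
            strand = strandChar)
        txStrand[id] <<- strandChar; txChrom[id] <<- chrom
        txClass[id] <<- class; txId[id] <<- id
    }

    for (u in seq_along(units)) {
        chrom <- chroms[((u - 1L) %% length(chroms)) + 1L]
        cur <- cursors[[chrom]]
        kind <- units[u]
        if (kind == "coding") {
            iCod <- iCod + 1L
            id <- fmtId("tx_coding", iCod)
            gid <- fmtId("gene", iCod)
            strandChar <- if (stats::runif(1) < 0.5) "+" else "-"
            splicedLen <- 1200L
            if (strandChar == "+") {
                geneStart <- cur + 7000L
                exons <- data.frame(start = c(geneStart, geneStart + 700L),
                                    width = c(400L, 800L))
            } else {
                geneStart <- cur + 1000L
                exons <- data.frame(start = c(geneStart, geneStart + 1100L),
                                    width = c(800L, 400L))
            }
            geneEnd <- exons$start[2L] + exons$width[2L] - 1L
            unitEnd <- if (strandChar == "+") geneEnd + 1000L
                       else geneEnd + 7000L
            if (unitEnd + margin > L)
                stop("genome too small: increase genomeLengthNt to at least ",
                     ceiling(1.3 * (unitEnd + margin)), " nt")
            spliced <- codingSplicedSeq(splicedLen, gc)
            stopifnot(longestOrfAa(spliced) >= 101L)
            chromLetters <- plantSequence(chromLetters, chrom, exons,
                                          strandChar, spliced)
            codingSeqs[[id]] <- spliced
            addTx(id, chrom, exons, strandChar, "coding")
            ## genomic interval of the embedded ORF (spliced 46..381 falls
            ## inside the 400-nt 5' exon); ribosome footprints are placed
            ## here, mirroring CDS-restricted ribosome occupancy
            orfRegion[[id]] <- if (strandChar == "+")
                c(exons$start[1L] + 45L, exons$start[1L] + 380L)
            else
                c(exons$start[2L] + 19L, exons$start[2L] + 354L)
            geneRows[[gid]] <- data.frame(
                gene_id = gid, chrom = chrom, start = exons$start[1L],
                end = geneEnd, strand = strandChar)

            if (iCod %in% hostProm) {
                iProm <- iProm + 1L
                pid <- fmtId("tx_prom", iProm)
                pStrand <- if (stats::runif(1) < 0.5) "+" else "-"
                pLen <- 600L
                pStart <- if (strandChar == "+") exons$start[1L] - 3500L
                          else geneEnd + 2901L
                pEx <- data.frame(start = pStart, width = pLen)
                pSeq <- plantNoncoding(pLen, gc)
                chromLetters <- plantSequence(chromLetters, chrom, pEx,
                                              pStrand, pSeq)
                addTx(pid, chrom, pEx, pStrand, "promoter_associated")
            }
            if (iCod %in% hostAnti) {
                iAnti <- iAnti + 1L
                aid <- fmtId("tx_anti", iAnti)
                aStrand <- if (strandChar == "+") "-" else "+"
                if (strandChar == "+") {
                    ## 3' end is the genomic right; extend 400 nt beyond
                    extStart <- geneEnd + 1L
                    aEx <- data.frame(start = geneEnd - 199L, width = 600L)
                } else {
                    extStart <- exons$start[1L] - 400L
                    aEx <- data.frame(start = extStart, width = 600L)
                }
                ## the 200 nt inside the gene are already ORF-poor (coding
                ## tail); plant an ORF-poor extension outside the gene
                extEx <- data.frame(start = extStart, width = 400L)
                for (try in 1:50) {
                    ext <- noncodingSeq(400L, gc)
                    chromLetters <- plantSequence(chromLetters, chrom,
                                                  extEx, "+", ext)
                    aSeq <- spliceFromLetters(chromLetters, chrom, aEx,
                                              aStrand)
                    if (longestOrfAa(aSeq) <= 50L) break
                    if (try == 50L)
                        stop("failed to construct an ORF-poor antisense lncRNA")
                }
                addTx(aid, chrom, aEx, aStrand, "antisense")
            }
        } else {
            oneExon <- stats::runif(1) < 0.5
            len <- 800L
            if (oneExon) {
                exons <- data.frame(start = cur, width = 800L)
            } else {
                exons <- data.frame(start = c(cur, cur + 600L),
                                    width = c(400L, 400L))
            }
            txEnd <- exons$start[nrow(exons)] + exons$width[nrow(exons)] - 1L
            unitEnd <- txEnd
            if (unitEnd + margin > L)
                stop("genome too small: increase genomeLengthNt to at least ",
                     ceiling(1.3 * (unitEnd + margin)), " nt")
            strandChar <- if (stats::runif(1) < 0.5) "+" else "-"
            if (kind == "linc") {
                iLinc <- iLinc + 1L
                id <- fmtId("tx_linc", iLinc)
                class <- "lincRNA"
            } else {
                iKlinc <- iKlinc + 1L
                id <- fmtId("tx_klinc", iKlinc)
                class <- "known_overlap"
            }
            seqs <- plantNoncoding(len, gc)
            chromLetters <- plantSequence(chromLetters, chrom, exons,
                                          strandChar, seqs)
            addTx(id, chrom, exons, strandChar, class)
            if (kind == "klinc") {
                kid <- fmtId("known", iKlinc)
                knownExon[[kid]] <- GenomicRanges::GRanges(
                    chrom, IRanges::IRanges(exons$start,
                                            exons$start + exons$width - 1L),
                    strand = strandChar)
                knownOf[kid] <- id
            }
        }
        cursors[[chrom]] <- unitEnd + interUnit
    }

    genome <- Biostrings::DNAStringSet(
        vapply(chromLetters, paste, character(1), collapse = ""))
    names(genome) <- chroms

    transcripts <- GenomicRanges::GRangesList(exonList)
    validateTranscriptModels(transcripts)
    gdf <- do.call(rbind, geneRows)
    genes <- GenomicRanges::GRanges(
        gdf$chrom, IRanges::IRanges(gdf$start, gdf$end),
        strand = gdf$strand, gene_id = gdf$gene_id)
    names(genes) <- genes$gene_id
    known <- GenomicRanges::GRangesList(knownExon)

    ## verify the planted ORF margins against the package's own scanner
    seqs <- extractSplicedSequence(genome, transcripts)
    aa <- vapply(as.character(seqs), longestOrfAa, integer(1))
    isCoding <- txClass[names(transcripts)] == "coding"
    stopifnot(all(aa[isCoding] >= 101L), all(aa[!isCoding] <= 50L))

    hits <- data.frame(
        transcript_id = rep(names(transcripts)[isCoding], each = 2L),
        source = rep(c("pfam", "cpc"), sum(isCoding)),
        value = rep(c(1e-6, 1), sum(isCoding)),
        stringsAsFactors = FALSE)

    truth <- buildTruth(param, transcripts, txClass, txStrand, txChrom)
    orfRegions <- if (length(orfRegion)) GenomicRanges::GRanges(
        txChrom[names(orfRegion)],
        IRanges::IRanges(vapply(orfRegion, `[`, integer(1), 1L),
                         vapply(orfRegion, `[`, integer(1), 2L)),
        strand = txStrand[names(orfRegion)])
    else GenomicRanges::GRanges()
    names(orfRegions) <- names(orfRegion)
    list(genome = genome, transcripts = transcripts,
         coding = transcripts[isCoding], genes = genes, known = known,
         hits = hits, truth = truth, orfRegions = orfRegions)
}

# Noncoding spliced sequence with verified ORF margin.
plantNoncoding <- function(len, gc) {
    for (try in 1:50) {
        s <- noncodingSeq(len, gc)
        if (longestOrfAa(s) <= 50L) return(s)
    }
    stop("failed to construct an ORF-poor noncoding sequence")
}

# Spliced sequence from the letter-vector genome (used before the
# DNAStringSet is assembled).
spliceFromLetters <- function(chromLetters, chrom, exons, strandChar) {
    pieces <- vapply(seq_len(nrow(exons)), function(i)
        paste(chromLetters[[chrom]][exons$start[i]:
                                    (exons$start[i] + exons$width[i] - 1L)],
              collapse = ""), character(1))
    s <- paste(pieces, collapse = "")
    if (strandChar == "-")
        s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
    s
}

# Truth manifest: class labels, expression design (NEC/EC read-sampling
# weights and the implied FPKM-scale fold change), translation status and
# expected pipeline calls. EC weights of noncoding transcripts are the NEC
# weights times the planted fold. Because the two libraries are sampled to
# the same depth, the noncoding baseline weights are chosen to balance the
# compositions (sum of EC weights = sum of NEC weights); any residual is
# absorbed by a common coding-gene fold, recorded in the manifest. When the
# planted fold list straddles 1 the balance is exact and the coding fold
# is exactly 1.
buildTruth <- function(param, transcripts, txClass, txStrand, txChrom) {
    ids <- names(transcripts)
    cls <- txClass[ids]
    isCoding <- cls == "coding"
    nNc <- sum(!isCoding)
    folds <- rep(NA_real_, length(ids))
    ## antisense lncRNAs share exonic sequence with their host mRNA, so
    ## unstranded counting cannot attribute those reads uniquely; they are
    ## planted at neutral enrichment and low expression, and the fold list
    ## is cycled over the remaining noncoding transcripts
    isAnti <- cls == "antisense"
    cyc <- !isCoding & !isAnti
    if (any(cyc))
        folds[cyc] <- param@ecFoldChanges[((seq_len(sum(cyc)) - 1L) %%
                                           length(param@ecFoldChanges)) + 1L]
    folds[isAnti] <- 1
    jit <- stats::runif(length(ids), 0.7, 1.3)
    jit[isAnti] <- 0.1 * jit[isAnti]
    wNEC <- numeric(length(ids))
    codShare <- if (nNc && any(isCoding)) 1 / 3 else as.numeric(any(isCoding))
    if (any(isCoding)) {
        w <- jit[isCoding]
        wNEC[isCoding] <- codShare * w / sum(w)
    }
    if (nNc) {
        f <- folds[!isCoding]
        j <- jit[!isCoding]
        ## baseline ~ j * (num + den / f) zeroes sum(w * (f - 1)) when both
        ## coefficients are positive, i.e. when folds straddle 1
        num <- sum(j / f) - sum(j)
        den <- sum(j * f) - sum(j)
        w <- if (num > 0 && den > 0) j * (num + den / f)
             else if (den <= 0) j       # all folds <= 1: flat baseline
             else j / f                 # all folds >= 1: EC-flat baseline
        wNEC[!isCoding] <- (1 - codShare) * w / sum(w)
    }
    wEC <- numeric(length(ids))
    wEC[!isCoding] <- wNEC[!isCoding] * folds[!isCoding]
    if (any(isCoding)) {
        tc <- (1 - sum(wEC[!isCoding])) / sum(wNEC[isCoding])
        if (tc <= 0)
            stop("infeasible fold composition: EC proportions of the ",
                 "noncoding transcripts exceed 1; lower 'ecFoldChanges' ",
                 "or their expression share")
        wEC[isCoding] <- wNEC[isCoding] * tc
        folds[isCoding] <- tc
    }
    data.frame(
        transcript_id = ids,
        class = cls,
        chrom = txChrom[ids],
        strand = txStrand[ids],
        spliced_length = unname(splicedLength(transcripts)),
        true_fold = folds,
        true_tier = enrichmentTier(folds),
        translated = isCoding,
        expected_context = ifelse(cls == "promoter_associated",
                                  "promoter_associated", "lincRNA"),
        expected_novel = cls != "known_overlap",
        expected_candidate = !isCoding,
        nec_weight = wNEC,
        ec_weight = wEC,
        stringsAsFactors = FALSE)
}

#' Simulate RNA-seq and ribosome-profiling reads
#'
#' Per-transcript RNA-seq read counts are drawn multinomially per condition
#' from the truth manifest's sampling weights, so the expected EC:NEC FPKM
#' ratio of each transcript equals its planted fold change. Read start
#' positions are uniform over exon positions where the read fits (reads
#' are single-block and never span junctions); RNA-seq reads have fixed
#' length, ribosome footprints draw lengths uniformly from
#' \code{riboLengthRange} so the 27-32 nt filter removes a known fraction.
#' Footprints are placed only on transcripts flagged translated and only
#' within their planted ORF interval (ribosome occupancy is
#' CDS-restricted), in numbers such that the expected \emph{post-filter}
#' footprint/RNA count ratio of every translated transcript equals
#' \code{translatedTesTarget}; untranslated transcripts receive none. A
#' warning is issued when the implied footprint total differs from the
#' nominal \code{riboDepth} by more than 1.5-fold, or when some transcript
#' expects fewer than one read.
#'
#' @param param the [SimulationParam-class] used for the reference.
#' @param ref the output of [generateReference()].
#' @return A list with elements \code{ec}, \code{nec} and \code{ribo},
#'   each a \code{GRanges} of single-block reads.
#' @examples
#' par <- simulationParam(seed = 7, nCodingGenes = 3, nLincRNA = 3,
#'     nPromoterAssociated = 1, nKnownOverlap = 1, nAntisense = 1,
#'     genomeLengthNt = 3e5, nChromosomes = 1,
#'     rnaDepth = 2e4, riboDepth = 2e3)
#' reads <- simulateReads(par, generateReference(par))
#' lengths(reads)
#' @export
simulateReads <- function(param, ref) {
    stopifnot(is(param, "SimulationParam"))
    truth <- ref$truth
    withSeed(param@seed + 1L, {
        tx <- ref$transcripts[truth$transcript_id]
        if (min(c(truth$nec_weight, truth$ec_weight)) * param@rnaDepth < 1)
            warning("RNA depth too low to expect at least one read per ",
                    "expressed transcript")
        cNEC <- as.integer(stats::rmultinom(1L, param@rnaDepth,
                                            truth$nec_weight))
        cEC <- as.integer(stats::rmultinom(1L, param@rnaDepth,
                                           truth$ec_weight))
        ec <- placeReads(tx, cEC, rep(param@rnaReadLengthNt,
                                      length(tx)), fixedLen = TRUE)
        nec <- placeReads(tx, cNEC, rep(param@rnaReadLengthNt,
                                        length(tx)), fixedLen = TRUE)
        ## footprints: post-filter ratio target; compensate for the length
        ## fraction that the canonical 27-32 nt window will remove
        lens <- param@riboLengthRange[1L]:param@riboLengthRange[2L]
        keptFrac <- mean(lens >= 27L & lens <= 32L)
        if (keptFrac == 0)
            stop("no footprint length in 'riboLengthRange' survives the ",
                 "27-32 nt filter")
        tr <- truth$translated
        pooled <- cEC + cNEC
        nPlace <- as.integer(round(param@translatedTesTarget / keptFrac *
                                   sum(pooled[tr])))
        if (nPlace > 0 && (nPlace > 1.5 * param@riboDepth ||
                           nPlace < param@riboDepth / 1.5))
            warning("implied footprint total (", nPlace, ") differs from ",
                    "nominal riboDepth (", param@riboDepth, ") by more ",
                    "than 1.5-fold; the TES target takes precedence")
        riboCounts <- integer(length(tx))
        if (nPlace > 0 && any(tr))
            riboCounts[tr] <- as.integer(stats::rmultinom(
                1L, nPlace, pooled[tr] / sum(pooled[tr])))
        ## footprints are confined to the planted ORF interval of each
        ## translated transcript (CDS-restricted ribosome occupancy)
        ribo <- placeFootprints(ref$orfRegions[truth$transcript_id[tr]],
                                riboCounts[tr], lens)
        list(ec = ec, nec = nec, ribo = ribo)
    })
}

# Place k[i] footprints uniformly inside the i-th ORF window, with lengths
# drawn uniformly from `lens`.
placeFootprints <- function(windows, k, lens) {
    n <- sum(k)
    if (n == 0L)
        return(GenomicRanges::GRanges())
    rl <- sample(lens, n, replace = TRUE)
    wIdx <- rep.int(seq_along(windows), k)
    wStart <- BiocGenerics::start(windows)[wIdx]
    wWidth <- BiocGenerics::width(windows)[wIdx]
    if (any(rl > wWidth))
        stop("footprint longer than its ORF window")
    off <- as.integer(floor(stats::runif(n) * (wWidth - rl + 1L)))
    GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(windows))[wIdx],
        IRanges::IRanges(wStart + off, width = rl),
        strand = as.character(BiocGenerics::strand(windows))[wIdx])
}

# Place k[i] single-block reads on transcript i, uniformly over exon
# positions where the read fits entirely inside one exon.
placeReads <- function(tx, k, lens, fixedLen) {
    chrom <- as.character(unlist(S4Vectors::runValue(
        GenomicRanges::seqnames(tx)), use.names = FALSE))
    strandOf <- as.character(unlist(S4Vectors::runValue(
        BiocGenerics::strand(tx)), use.names = FALSE))
    starts <- BiocGenerics::start(tx)
    widths <- BiocGenerics::width(tx)
    outChrom <- character(0); outStart <- integer(0)
    outWidth <- integer(0); outStrand <- character(0)
    li <- 0L
    for (i in seq_along(tx)) {
        ki <- k[i]
        if (ki == 0L) next
        rl <- if (fixedLen) rep.int(lens[i], ki) else lens[li + seq_len(ki)]
        li <- li + if (fixedLen) 0L else ki
        w <- widths[[i]]; s <- starts[[i]]
        if (length(w) == 1L) {
            eIdx <- rep.int(1L, ki)
        } else {
            rStart <- integer(ki)
            eIdx <- integer(ki)
            for (r in unique(rl)) {
                sel <- rl == r
                elig <- pmax(w - r + 1L, 0L)
                if (sum(elig) == 0L)
                    stop("read length ", r, " exceeds every exon of ",
                         "transcript ", names(tx)[i])
                eIdx[sel] <- sample.int(length(w), sum(sel), replace = TRUE,
                                        prob = elig)
            }
        }
        maxOff <- w[eIdx] - rl
        if (any(maxOff < 0L))
            stop("read longer than its exon on transcript ", names(tx)[i])
        off <- as.integer(floor(stats::runif(ki) * (maxOff + 1L)))
        outChrom <- c(outChrom, rep.int(chrom[i], ki))
        outStart <- c(outStart, s[eIdx] + off)
        outWidth <- c(outWidth, rl)
        outStrand <- c(outStrand, rep.int(strandOf[i], ki))
    }
    GenomicRanges::GRanges(outChrom,
                           IRanges::IRanges(outStart, width = outWidth),
                           strand = outStrand)
}

#' Write a simulated data set to disk
#'
#' Emits the plain-text file set the pipeline consumes: \code{genome.fa},
#' \code{transcripts.bed} (BED12), \code{genes.bed}, \code{known.bed},
#' \code{hits.tsv}, \code{truth.tsv} and per-library read BED files.
#' Output is byte-identical across runs for the same parameters.
#'
#' @param ref output of [generateReference()].
#' @param reads output of [simulateReads()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
writeSimulation <- function(ref, reads, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
    writeTranscriptModels(ref$transcripts, file.path(dir, "transcripts.bed"))
    g <- ref$genes
    g$name <- g$gene_id
    rtracklayer::export(g, file.path(dir, "genes.bed"), format = "bed")
    writeTranscriptModels(ref$known, file.path(dir, "known.bed"))
    utils::write.table(ref$hits, file.path(dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ref$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in names(reads))
        rtracklayer::export(reads[[nm]],
                            file.path(dir, paste0("reads_", nm, ".bed")),
                            format = "bed")
    invisible(dir)
}
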