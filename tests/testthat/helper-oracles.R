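# Independent brute-force oracles used by the property tests. They share
# no code with the implementation: the ORF oracle goes through
# Biostrings translation plus regular expressions, the interval oracles
# are plain nested loops over integer coordinates.

# Longest ATG-initiated ORF (aa) via six-frame translation (seqinr's
# translator, an implementation independent of the codon-index scan under
# test): every maximal ORF is an M-run up to the next stop in the
# translated frame; an ORF with no stop before the sequence end only
# counts when open ends are allowed. Codons containing N translate to X,
# which is neither M nor *.
oracleLongestOrf <- function(seq, allowOpenEnd = TRUE) {
    best <- 0L
    fwd <- strsplit(seq, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rev <- unname(comp[rev(fwd)])
    for (sv in list(fwd, rev)) {
        for (off in 0:2) {
            nCodon <- (length(sv) - off) %/% 3
            if (nCodon < 1) next
            aa <- seqinr::translate(sv, frame = off, ambiguous = FALSE)
            prot <- paste(aa, collapse = "")
            m <- gregexpr("M[^*]*", prot)[[1]]
            if (m[1] == -1) next
            lens <- attr(m, "match.length")
            ends <- as.integer(m) + lens - 1L
            open <- ends == nchar(prot) &
                substr(prot, nchar(prot), nchar(prot)) != "*"
            use <- allowOpenEnd | !open
            if (any(use)) best <- max(best, lens[use])
        }
    }
    best
}

# Enumeration oracle for the full ORF list: walk codons of each frame.
oracleOrfList <- function(seq, allowOpenEnd = TRUE) {
    stops <- c("TAA", "TAG", "TGA")
    out <- list()
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    n <- nchar(seq)
    for (strandChar in c("+", "-")) {
        s <- if (strandChar == "+") seq else rc
        for (off in 0:2) {
            nCodon <- (n - off) %/% 3
            if (nCodon < 1) next
            i <- 1
            while (i <= nCodon) {
                codon <- substr(s, off + 3 * (i - 1) + 1, off + 3 * i)
                if (codon == "ATG") {
                    j <- i
                    stopAt <- NA
                    while (j <= nCodon) {
                        cj <- substr(s, off + 3 * (j - 1) + 1, off + 3 * j)
                        if (cj %in% stops) { stopAt <- j; break }
                        j <- j + 1
                    }
                    if (!is.na(stopAt)) {
                        aa <- stopAt - i
                        sS <- off + 3 * (i - 1) + 1; sE <- off + 3 * stopAt
                        complete <- TRUE
                        i <- stopAt + 1
                    } else if (allowOpenEnd) {
                        aa <- nCodon - i + 1
                        sS <- off + 3 * (i - 1) + 1; sE <- off + 3 * nCodon
                        complete <- FALSE
                        i <- nCodon + 1
                    } else {
                        i <- nCodon + 1
                        next
                    }
                    fr <- if (strandChar == "+") off + 1 else -(off + 1)
                    fS <- if (strandChar == "+") sS else n - sE + 1
                    fE <- if (strandChar == "+") sE else n - sS + 1
                    out[[length(out) + 1]] <- data.frame(
                        frame = fr, start = fS, end = fE,
                        aa_length = aa, complete = complete)
                } else {
                    i <- i + 1
                }
            }
        }
    }
    if (!length(out))
        return(data.frame(frame = integer(), start = integer(),
                          end = integer(), aa_length = integer(),
                          complete = logical()))
    do.call(rbind, out)
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All-pairs overlap counter on 1-based closed blocks/exons, strand-aware
# on demand. `reads` and `txs` are lists of data.frames with columns
# chrom, start, end, strand (one row per block/exon).
oracleCountReads <- function(reads, txs, stranded = FALSE) {
    vapply(txs, function(tx) {
        sum(vapply(reads, function(rd) {
            if (rd$chrom[1] != tx$chrom[1]) return(FALSE)
            if (stranded && rd$strand[1] != tx$strand[1]) return(FALSE)
            for (i in seq_len(nrow(rd)))
                for (j in seq_len(nrow(tx)))
                    if (rd$start[i] <= tx$end[j] && tx$start[j] <= rd$end[i])
                        return(TRUE)
            FALSE
        }, logical(1)))
    }, numeric(1))
}

# All-pairs nearest gene with the documented tie-break (gap, gene start,
# gene id); returns list(gene, dist) with the signed convention.
oracleNearestGene <- function(candSpan, genes) {
    onChrom <- genes[genes$chrom == candSpan$chrom, , drop = FALSE]
    if (!nrow(onChrom)) return(list(gene = "none", dist = NA_integer_))
    gap <- pmax(0L, pmax(onChrom$start - candSpan$end,
                         candSpan$start - onChrom$end) - 1L)
    o <- order(gap, onChrom$start, onChrom$gene_id)
    b <- o[1]
    d <- gap[b]
    if (d > 0) {
        candLeft <- candSpan$end < onChrom$start[b]
        ups <- (candLeft && onChrom$strand[b] == "+") ||
               (!candLeft && onChrom$strand[b] == "-")
        if (ups) d <- -d
    }
    list(gene = onChrom$gene_id[b], dist = d)
}

# Helpers building GenomicRanges containers from the plain representations.
asTxGRL <- function(txs) {
    df <- do.call(rbind, txs)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    f <- factor(rep(names(txs), vapply(txs, nrow, integer(1))),
                levels = names(txs))
    GenomicRanges::split(gr, f)
}

asReadGR <- function(reads) {
    df <- do.call(rbind, reads)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand)
}

# Random single-block reads and multi-exon transcripts on a small genome.
randomReadSet <- function(n, chroms = c("chr1", "chr2"), span = 5000) {
    lapply(seq_len(n), function(i) {
        st <- sample.int(span, 1)
        data.frame(chrom = sample(chroms, 1), start = st,
                   end = st + sample.int(80, 1),
                   strand = sample(c("+", "-"), 1),
                   stringsAsFactors = FALSE)
    })
}

randomTxSet <- function(n, chroms = c("chr1", "chr2"), span = 5000) {
    txs <- lapply(seq_len(n), function(i) {
        chrom <- sample(chroms, 1)
        strand <- sample(c("+", "-"), 1)
        nEx <- sample(1:3, 1)
        pos <- sample.int(span, 1)
        st <- integer(nEx); en <- integer(nEx)
        for (k in seq_len(nEx)) {
            w <- sample(30:150, 1)
            st[k] <- pos; en[k] <- pos + w - 1L
            pos <- en[k] + sample.int(200, 1) + 1L
        }
        data.frame(chrom = chrom, start = st, end = en, strand = strand,
                   stringsAsFactors = FALSE)
    })
    names(txs) <- sprintf("tx%03d", seq_len(n))
    txs
}

# Random-configuration sweep comparing the four interval operations with
# their all-pairs brute-force counterparts; returns mismatch counts.
# Configurations are mutually isolated by giving each its own chromosome
# namespace, so the package operations run batched over all of them at
# once while the brute-force oracles stay per-configuration loops.
intervalOracleSweep <- function(nConfig = 1000L) {
    cfg <- lapply(seq_len(nConfig), function(i) {
        pre <- sprintf("c%04d_", i)
        txs <- randomTxSet(4, chroms = paste0(pre, c("chr1", "chr2")),
                           span = 7000)
        names(txs) <- paste0(pre, names(txs))
        reads <- randomReadSet(20, chroms = paste0(pre, c("chr1", "chr2")),
                               span = 7000)
        nG <- sample(2:6, 1)
        gdf <- data.frame(
            chrom = sample(paste0(pre, c("chr1", "chr2")), nG,
                           replace = TRUE),
            start = sample.int(6000, nG),
            strand = sample(c("+", "-"), nG, replace = TRUE),
            gene_id = paste0(pre, sprintf("g%02d", seq_len(nG))))
        gdf$end <- gdf$start + sample.int(900, nG)
        cods <- randomTxSet(3, chroms = paste0(pre, c("chr1", "chr2")),
                            span = 7000)
        names(cods) <- paste0(pre, "cod", seq_along(cods))
        list(pre = pre, txs = txs, reads = reads, genes = gdf,
             cods = cods, win = sample(200:2000, 1))
    })

    allTxs <- do.call(c, lapply(cfg, `[[`, "txs"))
    allCand <- asTxGRL(allTxs)
    allReads <- asReadGR(do.call(c, lapply(cfg, `[[`, "reads")))
    allCoding <- asTxGRL(do.call(c, lapply(cfg, `[[`, "cods")))
    gdfAll <- do.call(rbind, lapply(cfg, `[[`, "genes"))
    allGenes <- GenomicRanges::GRanges(
        gdfAll$chrom, IRanges::IRanges(gdfAll$start, gdfAll$end),
        strand = gdfAll$strand, gene_id = gdfAll$gene_id)
    names(allGenes) <- allGenes$gene_id
    allProm <- do.call(c, lapply(cfg, function(cc) {
        g <- allGenes[cc$genes$gene_id]
        buildPromoterRegions(g, cc$win)
    }))

    gotUn <- countReads(allReads, allCand, stranded = FALSE)
    gotSt <- countReads(allReads, allCand, stranded = TRUE)
    ctx <- classifyContext(allCand, allProm, allGenes)
    ng <- nearestGene(allCand, allGenes)
    excl <- excludeProteinCodingOverlap(allCand, allCoding)
    ctxOf <- stats::setNames(ctx$context, ctx$transcript_id)
    ngGene <- stats::setNames(ng$nearest_gene, ng$transcript_id)
    ngDist <- stats::setNames(ng$distance, ng$transcript_id)

    countingMismatch <- promoterMismatch <- 0L
    nearestMismatch <- exclusionMismatch <- 0L
    for (cc in cfg) {
        ids <- names(cc$txs)
        wantUn <- oracleCountReads(cc$reads, cc$txs, stranded = FALSE)
        wantSt <- oracleCountReads(cc$reads, cc$txs, stranded = TRUE)
        if (!identical(unname(gotUn[ids]), as.integer(unname(wantUn))) ||
            !identical(unname(gotSt[ids]), as.integer(unname(wantSt))))
            countingMismatch <- countingMismatch + 1L

        gdf <- cc$genes
        isPlus <- gdf$strand == "+"
        pS <- ifelse(isPlus, pmax(1, gdf$start - cc$win), gdf$end + 1)
        pE <- ifelse(isPlus, gdf$start - 1, gdf$end + cc$win)
        keep <- pE >= pS
        for (k in ids) {
            tx <- cc$txs[[k]]
            span <- list(chrom = tx$chrom[1], start = min(tx$start),
                         end = max(tx$end))
            hit <- any(keep & gdf$chrom == span$chrom & pS <= span$end &
                       span$start <= pE)
            if (!identical(unname(ctxOf[k]),
                           if (hit) "promoter_associated" else "lincRNA"))
                promoterMismatch <- promoterMismatch + 1L
            want <- oracleNearestGene(span, gdf)
            if (!identical(unname(ngGene[k]), want$gene) ||
                !identical(unname(ngDist[k]), as.integer(want$dist)))
                nearestMismatch <- nearestMismatch + 1L

            ov <- FALSE
            for (cd in cc$cods) {
                if (cd$chrom[1] != tx$chrom[1] ||
                    cd$strand[1] != tx$strand[1]) next
                for (a in seq_len(nrow(cd)))
                    if (any(cd$start[a] <= tx$end & tx$start <= cd$end[a]))
                        ov <- TRUE
            }
            if (!identical(k %in% names(excl$removed), ov))
                exclusionMismatch <- exclusionMismatch + 1L
        }
    }
    list(counting_mismatch = countingMismatch,
         promoter_mismatch = promoterMismatch,
         nearest_mismatch = nearestMismatch,
         exclusion_mismatch = exclusionMismatch,
         n = nConfig)
}

smallSimParam <- function(seed = 101) {
    simulationParam(seed = seed, nCodingGenes = 5, nLincRNA = 6,
                    nPromoterAssociated = 2, nKnownOverlap = 2,
                    nAntisense = 1, genomeLengthNt = 4e5,
                    nChromosomes = 2, rnaDepth = 1e5, riboDepth = 1e4)
}
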