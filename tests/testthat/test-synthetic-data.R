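# The small parameterisation used here keeps the suite fast; the
# default-scale study is exercised in test-acceptance.R.

test_that("generator plants the requested classes with verified ORF margins", {
    p <- smallSimParam()
    ref <- generateReference(p)
    tr <- ref$truth
    expect_identical(sum(tr$class == "coding"), 5L)
    expect_identical(sum(tr$class == "lincRNA"), 6L)
    expect_identical(sum(tr$class == "promoter_associated"), 2L)
    expect_identical(sum(tr$class == "known_overlap"), 2L)
    expect_identical(sum(tr$class == "antisense"), 1L)
    expect_identical(length(ref$known), 2L)
    ## ORF margins, measured with the scanner on the emitted genome
    orfs <- scanOrfs(ref$genome, ref$transcripts)
    aa <- stats::setNames(orfs$longest_orf_aa, orfs$transcript_id)
    expect_true(all(aa[tr$transcript_id[tr$class == "coding"]] >= 101L))
    expect_true(all(aa[tr$transcript_id[tr$class != "coding"]] <= 50L))
    ## every planted transcript is longer than the 200-nt filter
    expect_true(all(tr$spliced_length > 200L))
    ## hit table: coding get pfam 1e-6 and cpc +1, noncoding nothing
    expect_setequal(unique(ref$hits$transcript_id),
                    tr$transcript_id[tr$class == "coding"])
    expect_equal(ref$hits$value[ref$hits$source == "pfam"],
                 rep(1e-6, 5))
    expect_equal(ref$hits$value[ref$hits$source == "cpc"], rep(1, 5))
})

test_that("planted geometry matches each class definition", {
    p <- smallSimParam(seed = 202)
    ref <- generateReference(p)
    tr <- ref$truth
    spans <- unlist(GenomicRanges::reduce(ref$transcripts, min.gapwidth = 1e9))
    prom <- buildPromoterRegions(ref$genes, 5000)
    ## promoter-associated lncRNAs overlap a promoter window; lincRNAs do not
    pa <- tr$transcript_id[tr$class == "promoter_associated"]
    li <- tr$transcript_id[tr$class %in% c("lincRNA", "known_overlap")]
    expect_true(all(IRanges::overlapsAny(spans[pa], prom,
                                         ignore.strand = TRUE)))
    expect_false(any(IRanges::overlapsAny(spans[li], prom,
                                          ignore.strand = TRUE)))
    ## antisense lncRNAs overlap a coding transcript on the opposite strand
    an <- tr$transcript_id[tr$class == "antisense"]
    expect_true(all(IRanges::overlapsAny(
        ref$transcripts[an], ref$coding, ignore.strand = TRUE)))
    expect_false(any(IRanges::overlapsAny(
        ref$transcripts[an], ref$coding, ignore.strand = FALSE)))
    ## known-overlap transcripts coincide with known catalog entries
    expect_true(all(IRanges::overlapsAny(
        ref$transcripts[tr$transcript_id[tr$class == "known_overlap"]],
        ref$known)))
})

test_that("identical seed gives byte-identical files; different seeds differ", {
    p <- smallSimParam(seed = 303)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    r1 <- generateReference(p); w1 <- simulateReads(p, r1)
    r2 <- generateReference(p); w2 <- simulateReads(p, r2)
    writeSimulation(r1, w1, d1)
    writeSimulation(r2, w2, d2)
    for (f in list.files(d1))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
    p3 <- smallSimParam(seed = 304)
    r3 <- generateReference(p3)
    expect_false(identical(as.character(r3$genome),
                           as.character(r1$genome)))
})

test_that("the generator does not disturb the caller's RNG stream", {
    set.seed(99)
    a <- stats::runif(3)
    set.seed(99)
    invisible(generateReference(smallSimParam()))
    b <- stats::runif(3)
    expect_identical(a, b)
})

test_that("simulated read counts converge to the planted design", {
    p <- smallSimParam(seed = 404)
    ref <- generateReference(p)
    reads <- simulateReads(p, ref)
    tr <- ref$truth
    expect_identical(length(reads$ec), 100000L)
    expect_identical(length(reads$nec), 100000L)
    cEC <- countReads(reads$ec, ref$transcripts[tr$transcript_id])
    cNEC <- countReads(reads$nec, ref$transcripts[tr$transcript_id])
    ## non-overlapping features: observed counts within 4 sd of expected
    solo <- tr$class %in% c("lincRNA", "known_overlap",
                            "promoter_associated")
    expEC <- tr$ec_weight * p@rnaDepth
    expNEC <- tr$nec_weight * p@rnaDepth
    expect_true(all(abs(cEC[solo] - expEC[solo]) <=
                    4 * sqrt(expEC[solo]) + 1))
    expect_true(all(abs(cNEC[solo] - expNEC[solo]) <=
                    4 * sqrt(expNEC[solo]) + 1))
    ## footprints only on translated transcripts, lengths span 26-34
    ribo <- reads$ribo
    expect_true(all(width(ribo) >= 26L & width(ribo) <= 34L))
    rc <- countReads(ribo, ref$transcripts[tr$transcript_id])
    expect_true(all(rc[!tr$translated & solo] == 0L))
    expect_true(all(rc[tr$translated] > 0L))
})

test_that("RNA reads are single-block, exonic and of the configured length", {
    p <- smallSimParam(seed = 505)
    ref <- generateReference(p)
    reads <- simulateReads(p, ref)
    expect_true(all(width(reads$ec) == p@rnaReadLengthNt))
    ## every read lies entirely inside one exon
    exons <- unlist(ref$transcripts)
    hits <- GenomicRanges::findOverlaps(reads$ec, exons, type = "within",
                                        ignore.strand = TRUE)
    expect_identical(length(unique(S4Vectors::queryHits(hits))),
                     length(reads$ec))
})

test_that("infeasible placements raise informative errors", {
    tiny <- simulationParam(seed = 1, nCodingGenes = 30, nLincRNA = 30,
                            nPromoterAssociated = 2, nKnownOverlap = 2,
                            nAntisense = 2, genomeLengthNt = 50000,
                            nChromosomes = 1)
    expect_error(generateReference(tiny), "genome too small")
    bad <- simulationParam(seed = 1, nCodingGenes = 2,
                           nPromoterAssociated = 2, nKnownOverlap = 0,
                           nAntisense = 1, nLincRNA = 2)
    expect_error(generateReference(bad), "coding genes")
})
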