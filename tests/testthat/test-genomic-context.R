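mkGene <- function(chrom, start, end, strand, id) {
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand,
                                gene_id = id)
    names(g) <- id
    g
}
mkCand <- function(chrom, start, end, strand = "+", id = "c1") {
    grl <- GenomicRanges::GRangesList(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand))
    names(grl) <- id
    grl
}

test_that("promoter windows are strand-aware 5-kb upstream boxes, clamped at 1", {
    ## plus gene at 0-based 10000-12000 is 1-based 10001-12000
    plus <- mkGene("chr1", 10001, 12000, "+", "gp")
    pw <- buildPromoterRegions(plus, 5000)
    expect_identical(start(pw), 5001L)
    expect_identical(end(pw), 10000L)

    minus <- mkGene("chr1", 10001, 12000, "-", "gm")
    pm <- buildPromoterRegions(minus, 5000)
    expect_identical(start(pm), 12001L)
    expect_identical(end(pm), 17000L)

    near <- mkGene("chr1", 3001, 4000, "+", "gn")
    pn <- buildPromoterRegions(near, 5000)
    expect_identical(start(pn), 1L)      # clamped at chromosome start
    expect_identical(end(pn), 3000L)

    atEdge <- mkGene("chr1", 1, 100, "+", "ge")
    expect_identical(length(buildPromoterRegions(atEdge, 5000)), 0L)
})

test_that("context classification is span-level, strand-agnostic, >= 1 nt", {
    gene <- mkGene("chr1", 10001, 12000, "+", "g1")
    prom <- buildPromoterRegions(gene, 5000)
    within <- classifyContext(mkCand("chr1", 6001, 6500, "-"), prom, gene)
    expect_identical(within$context, "promoter_associated")
    away <- classifyContext(mkCand("chr1", 40001, 41000), prom, gene)
    expect_identical(away$context, "lincRNA")
    ## 5-nt overlap at the window edge still counts
    edge <- classifyContext(mkCand("chr1", 4991, 5005), prom, gene)
    expect_identical(edge$context, "promoter_associated")
    ## abutting the window (0-nt overlap) does not count
    abut <- classifyContext(mkCand("chr1", 4001, 5000), prom, gene)
    expect_identical(abut$context, "lincRNA")
    expect_identical(
        classifyContext(mkCand("chr1", 17001, 18000),
                        buildPromoterRegions(
                            mkGene("chr1", 10001, 12000, "-", "g3"), 5000),
                        mkGene("chr1", 10001, 12000, "-", "g3"))$context,
        "lincRNA")
})

test_that("antisense flag marks opposite-strand exonic gene overlap only", {
    gene <- mkGene("chr1", 1001, 2000, "+", "g1")
    prom <- buildPromoterRegions(gene, 500)
    anti <- classifyContext(mkCand("chr1", 1901, 2400, "-"), prom, gene)
    expect_true(anti$antisense)
    sense <- classifyContext(mkCand("chr1", 1901, 2400, "+"), prom, gene)
    expect_false(sense$antisense)
})

test_that("nearest gene follows gap arithmetic, tie-breaks and sign convention", {
    genes <- c(mkGene("chr1", 301, 400, "+", "g1"),
               mkGene("chr1", 451, 500, "+", "g2"))
    res <- nearestGene(mkCand("chr1", 101, 200), genes)
    expect_identical(res$nearest_gene, "g1")
    ## gap of 100 nt; candidate sits upstream of the plus-strand gene
    expect_identical(res$distance, -100L)

    ## overlap gives distance 0
    ov <- nearestGene(mkCand("chr1", 350, 470), genes)
    expect_identical(ov$distance, 0L)

    ## downstream of a plus-strand gene is positive
    dn <- nearestGene(mkCand("chr1", 601, 700), genes["g2"])
    expect_identical(dn$distance, 100L)
    ## same position relative to a minus-strand gene is upstream
    gm <- mkGene("chr1", 451, 500, "-", "gm")
    expect_identical(nearestGene(mkCand("chr1", 601, 700), gm)$distance,
                     -100L)

    ## equidistant genes: smaller start wins, then lexicographic id
    tie <- c(mkGene("chr1", 1, 100, "+", "zz"),
             mkGene("chr1", 251, 300, "+", "aa"))
    expect_identical(nearestGene(mkCand("chr1", 151, 200), tie)$nearest_gene,
                     "zz")
    tie2 <- c(mkGene("chr1", 251, 300, "+", "b"),
              mkGene("chr1", 251, 300, "+", "a"))
    expect_identical(nearestGene(mkCand("chr1", 151, 200), tie2)$nearest_gene,
                     "a")

    ## no gene on the chromosome
    none <- nearestGene(mkCand("chr2", 101, 200), genes)
    expect_identical(none$nearest_gene, "none")
    expect_true(is.na(none$distance))
})

test_that("context and nearest gene agree with all-pairs brute force", {
    withr::local_seed(31)
    for (rep in 1:60) {
        nG <- sample(3:8, 1)
        genes <- suppressWarnings(do.call(c, lapply(seq_len(nG), function(i) {
            st <- sample.int(8000, 1)
            mkGene(sample(c("chr1", "chr2"), 1), st,
                   st + sample.int(800, 1),
                   sample(c("+", "-"), 1), sprintf("g%02d", i))
        })))
        prom <- buildPromoterRegions(genes, 1000)
        txs <- randomTxSet(6, span = 9000)
        cand <- asTxGRL(txs)
        ctx <- classifyContext(cand, prom, genes)
        ng <- nearestGene(cand, genes)
        gdf <- data.frame(chrom = as.character(seqnames(genes)),
                          start = start(genes), end = end(genes),
                          strand = as.character(strand(genes)),
                          gene_id = genes$gene_id)
        for (i in seq_along(cand)) {
            span <- list(chrom = txs[[i]]$chrom[1],
                         start = min(txs[[i]]$start),
                         end = max(txs[[i]]$end))
            ## brute-force promoter overlap on the candidate span
            pdf <- data.frame(chrom = as.character(seqnames(prom)),
                              start = start(prom), end = end(prom))
            hit <- any(pdf$chrom == span$chrom & pdf$start <= span$end &
                       span$start <= pdf$end)
            expect_identical(ctx$context[i],
                             if (hit) "promoter_associated" else "lincRNA")
            want <- oracleNearestGene(span, gdf)
            expect_identical(ng$nearest_gene[i], want$gene)
            expect_identical(ng$distance[i], as.integer(want$dist))
        }
        ## partition property: exactly one of the two classes each
        expect_true(all(ctx$context %in% c("promoter_associated", "lincRNA")))
    }
})

test_that("shrinking the promoter window never converts lincRNA to promoter-associated", {
    withr::local_seed(32)
    for (rep in 1:20) {
        genes <- do.call(c, lapply(1:4, function(i) {
            st <- sample.int(6000, 1)
            mkGene("chr1", st, st + 500, sample(c("+", "-"), 1),
                   sprintf("g%d", i))
        }))
        cand <- asTxGRL(randomTxSet(5, chroms = "chr1", span = 7000))
        big <- classifyContext(cand, buildPromoterRegions(genes, 2000), genes)
        small <- classifyContext(cand, buildPromoterRegions(genes, 400), genes)
        promBig <- big$context == "promoter_associated"
        promSmall <- small$context == "promoter_associated"
        expect_true(all(promBig | !promSmall))
    }
})
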