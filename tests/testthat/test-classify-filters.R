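mkTx <- function(len, strand = "+", chrom = "chr1", start = 1000L) {
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(start, start + len - 1L),
                           strand)
}
noHits <- data.frame(transcript_id = character(), source = character(),
                     value = numeric())

test_that("cascade applies the quoted inequalities at their boundaries", {
    tx <- GenomicRanges::GRangesList(
        t200 = mkTx(200L), t201 = mkTx(201L), veal = mkTx(1127L),
        pfamFail = mkTx(500L), pfamEdge = mkTx(500L), blastx = mkTx(500L))
    aa <- c(t200 = 10L, t201 = 10L, veal = 57L,
            pfamFail = 40L, pfamEdge = 40L, blastx = 40L)
    hits <- data.frame(
        transcript_id = c("pfamFail", "pfamEdge", "blastx"),
        source = c("pfam", "pfam", "blastx"),
        value = c(0.0009, 0.001, 0.00009))
    res <- as.data.frame(applyThresholdFilters(tx, aa, hits))
    rownames(res) <- res$transcript_id

    ## length strictly greater than 200 nt
    expect_identical(res["t200", "stage_length"], "fail")
    expect_identical(res["t201", "stage_length"], "pass")
    expect_identical(res["t201", "final"], "candidate_lncRNA")
    ## a 1,127-nt transcript with a 57-aa longest ORF and no hits passes
    expect_identical(res["veal", "final"], "candidate_lncRNA")
    ## Pfam drops strictly below the cut; the boundary value passes
    expect_identical(res["pfamFail", "stage_pfam"], "fail")
    expect_identical(res["pfamEdge", "stage_pfam"], "pass")
    expect_identical(res["pfamEdge", "final"], "candidate_lncRNA")
    ## BLASTx boundary is 1e-4
    expect_identical(res["blastx", "stage_blastx"], "fail")
    expect_identical(res["blastx", "final"], "rejected")
})

test_that("first failing stage halts evaluation and later stages are not evaluated", {
    tx <- GenomicRanges::GRangesList(short = mkTx(150L), longOrf = mkTx(500L))
    aa <- c(short = 10L, longOrf = 150L)
    hits <- data.frame(transcript_id = "short", source = "pfam", value = 1e-9)
    res <- as.data.frame(applyThresholdFilters(tx, aa, hits))
    rownames(res) <- res$transcript_id
    ## short fails length; its (would-fail) pfam stage is never reached
    expect_identical(res["short", "stage_length"], "fail")
    expect_identical(unlist(res["short", c("stage_orf", "stage_cpc",
        "stage_phylocsf", "stage_pfam", "stage_blastx")], use.names = FALSE),
        rep("not_evaluated", 5))
    ## ORF kept iff <= 100 aa
    expect_identical(res["longOrf", "stage_length"], "pass")
    expect_identical(res["longOrf", "stage_orf"], "fail")
    expect_identical(res["longOrf", "final"], "rejected")
})

test_that("ORF stage boundary keeps 100 aa and drops 101 aa", {
    tx <- GenomicRanges::GRangesList(a = mkTx(500L), b = mkTx(500L))
    res <- applyThresholdFilters(tx, c(a = 100L, b = 101L), noHits)
    expect_identical(res$final, c("candidate_lncRNA", "rejected"))
})

test_that("CPC and PhyloCSF stages keep strictly negative scores only", {
    tx <- GenomicRanges::GRangesList(neg = mkTx(500L), zero = mkTx(500L),
                                     pos = mkTx(500L))
    hits <- data.frame(transcript_id = c("neg", "zero", "pos"),
                       source = "cpc", value = c(-0.5, 0, 1.2))
    res <- applyThresholdFilters(tx, c(neg = 10L, zero = 10L, pos = 10L),
                                 hits)
    expect_identical(res$stage_cpc, c("pass", "fail", "fail"))
})

test_that("a transcript without an ORF length entry is an error", {
    tx <- GenomicRanges::GRangesList(a = mkTx(500L))
    expect_error(applyThresholdFilters(tx, c(b = 10L), noHits),
                 "ORF")
})

test_that("hit-table row order never changes the cascade outcome", {
    withr::local_seed(21)
    tx <- asTxGRL(randomTxSet(15))
    aa <- stats::setNames(sample(10:120, 15, replace = TRUE), names(tx))
    hits <- data.frame(
        transcript_id = sample(names(tx), 30, replace = TRUE),
        source = sample(c("cpc", "phylocsf", "pfam", "blastx"), 30, TRUE),
        value = stats::runif(30, -2, 2))
    hits$value[hits$source %in% c("pfam", "blastx")] <-
        abs(hits$value[hits$source %in% c("pfam", "blastx")]) * 1e-3
    r1 <- applyThresholdFilters(tx, aa, hits)
    r2 <- applyThresholdFilters(tx, aa, hits[sample(nrow(hits)), ])
    expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("cascade survivors shrink monotonically through the stages", {
    withr::local_seed(22)
    tx <- asTxGRL(randomTxSet(40))
    aa <- stats::setNames(sample(5:200, 40, replace = TRUE), names(tx))
    hits <- data.frame(
        transcript_id = sample(names(tx), 25, replace = TRUE),
        source = sample(c("cpc", "pfam"), 25, TRUE),
        value = stats::runif(25, -1, 1))
    hits$value[hits$source == "pfam"] <- abs(hits$value[hits$source == "pfam"])
    res <- applyThresholdFilters(tx, aa, hits)
    stages <- paste0("stage_", c("length", "orf", "cpc", "phylocsf",
                                 "pfam", "blastx"))
    surv <- vapply(stages, function(s) sum(res[[s]] == "pass"), integer(1))
    expect_true(all(diff(surv) <= 0L))
    ## every transcript that reached stage k passed all earlier stages
    for (k in 2:length(stages)) {
        reached <- res[[stages[k]]] != "not_evaluated"
        expect_true(all(res[[stages[k - 1]]][reached] == "pass"))
    }
})

test_that("protein-coding exclusion is same-strand and exonic", {
    coding <- GenomicRanges::GRangesList(
        cod = GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160), "+"))
    cand <- GenomicRanges::GRangesList(
        same = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"),
        anti = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "-"),
        intronic = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(101, 301), c(200, 400)), "+"))
    coding2 <- GenomicRanges::GRangesList(
        cod = GenomicRanges::GRanges("chr1", IRanges::IRanges(211, 290), "+"))
    res <- excludeProteinCodingOverlap(cand[c("same", "anti")], coding)
    expect_identical(names(res$removed), "same")
    expect_identical(names(res$kept), "anti")
    ## overlap confined to the candidate's intron does not remove it
    res2 <- excludeProteinCodingOverlap(cand["intronic"], coding2)
    expect_identical(names(res2$kept), "intronic")
})

test_that("novelty split is strand-aware, exact and exhaustive", {
    withr::local_seed(23)
    txs <- randomTxSet(10)
    cand <- asTxGRL(txs)
    ## plant 3 known overlaps (identical models)
    known <- cand[c(2, 5, 9)]
    names(known) <- paste0("known", 1:3)
    res <- splitNovelVsKnown(cand, known)
    expect_identical(sort(names(res$known)), sort(names(cand)[c(2, 5, 9)]))
    expect_identical(length(res$novel) + length(res$known), length(cand))
    ## a candidate on a chromosome with no known entries is novel
    far <- GenomicRanges::GRangesList(
        faroff = GenomicRanges::GRanges("chrUn", IRanges::IRanges(1, 300), "+"))
    expect_identical(names(splitNovelVsKnown(far, known)$novel), "faroff")
})
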