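# Default-scale simulated study (50 coding, 50 lincRNA, 10
# promoter-associated, 10 known-overlap, 5 antisense; RNA depth 1e6 per
# condition, nominal ribo depth 1e5), generated once and reused across
# acceptance blocks.
defaultSimOnce <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            p <- simulationParam(seed = 1)
            ref <- generateReference(p)
            reads <- simulateReads(p, ref)
            cat <- runPipeline(ref$transcripts, ref$genome, ref$genes,
                               ref$coding, ref$known, ref$hits,
                               reads$ec, reads$nec, reads$ribo)
            cache <<- list(p = p, ref = ref, reads = reads, cat = cat,
                           df = as.data.frame(catalogTable(cat)),
                           truth = ref$truth[order(ref$truth$transcript_id), ])
        }
        cache
    }
})
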