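test_that("configuration invariants are enforced", {
    expect_error(simConfig(seed = 1, fracMethylated = 1.5), "proportion")
    expect_error(simConfig(seed = 1, dispersion = 0), "dispersion")
    expect_error(simConfig(seed = 1, exprFc = 0.5), "exprFc")
    expect_error(simConfig(nTranscripts = 10), "seed")
    # quadrant weights normalise to 1
    cfg <- simConfig(seed = 1, quadrantMix = c(7, 1, 1, 1))
    expect_equal(sum(cfg@quadrantMix), 1)
})

test_that("ground truth honours planted fractions and degenerate configs", {
    # zero transcripts: empty outputs, not an error
    gt0 <- generateTruth(simConfig(nTranscripts = 0, seed = 1))
    expect_equal(nrow(gt0$transcripts), 0)

    # no methylation: no peak intervals anywhere
    gtNone <- generateTruth(simConfig(nTranscripts = 200, fracMethylated = 0,
                                      seed = 2))
    expect_true(all(is.na(gtNone$truth$peak_start)))
    expect_true(all(gtNone$truth$meth_direction == "none"))

    # binomial fraction within 3 SDs at n = 2000, by direct count
    gt <- generateTruth(simConfig(nTranscripts = 2000, fracMethylated = 0.5,
                                  seed = 3))
    frac <- sum(gt$truth$is_methylated) / 2000
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))

    # segment arithmetic and peak containment
    tr <- gt$transcripts
    expect_equal(tr$total_len, tr$utr5_len + tr$cds_len + tr$utr3_len)
    meth <- gt$truth[gt$truth$is_methylated, ]
    expect_true(all(meth$peak_start >= 0))
    expect_true(all(meth$peak_end <= tr$total_len[match(meth$transcript_id,
                                                        tr$transcript_id)]))
    expect_true(all(meth$peak_end > meth$peak_start))
})

test_that("quadrant labels converge to the configured mixture", {
    mix <- c(0.7, 0.1, 0.1, 0.1)
    gt <- generateTruth(simConfig(nTranscripts = 5000, fracMethylated = 1,
                                  fracDiffMethylated = 1, quadrantMix = mix,
                                  seed = 4))
    tab <- table(factor(gt$truth$true_quadrant,
                        levels = c("hyper-up", "hyper-down", "hypo-up", "hypo-down")))
    freq <- as.numeric(tab) / 5000
    for (i in 1:4)
        expect_lt(abs(freq[i] - mix[i]), 3 * sqrt(mix[i] * (1 - mix[i]) / 5000))
})

test_that("windows tile transcripts end-to-end, half-open, without overlap", {
    cfg <- simConfig(nTranscripts = 40, nPatients = 2, seed = 5)
    gt <- generateTruth(cfg)
    se <- simulateMeripWindows(gt$truth, gt$transcripts, cfg)
    rr <- SummarizedExperiment::rowRanges(se)
    df <- data.frame(tx = as.character(GenomicRanges::seqnames(rr)),
                     start = GenomicRanges::start(rr) - 1L,
                     end = GenomicRanges::end(rr))
    for (t in unique(df$tx)) {
        w <- df[df$tx == t, ]
        w <- w[order(w$start), ]
        expect_equal(w$start[1], 0)
        expect_equal(w$end[nrow(w)],
                     gt$transcripts$total_len[gt$transcripts$transcript_id == t])
        if (nrow(w) > 1)
            expect_equal(w$start[-1], w$end[-nrow(w)])  # tiling, no gaps/overlap
        expect_true(all(w$end > w$start))
    }
    # counts are nonnegative integers
    expect_true(all(SummarizedExperiment::assay(se, "ip") >= 0))
    expect_true(all(SummarizedExperiment::assay(se, "input") >= 0))

    # a transcript shorter than one window gets a single covering window
    shortTr <- data.frame(transcript_id = "s1", gene_id = "gs1", utr5_len = 5L,
                          cds_len = 15L, utr3_len = 5L, total_len = 25L)
    shortTruth <- data.frame(transcript_id = "s1", gene_id = "gs1",
                             is_methylated = FALSE, peak_start = NA_integer_,
                             peak_end = NA_integer_, meth_direction = "none",
                             expr_direction = "none", true_quadrant = NA_character_)
    se1 <- simulateMeripWindows(shortTruth, shortTr, cfg)
    rr1 <- SummarizedExperiment::rowRanges(se1)
    expect_equal(length(rr1), 1)
    expect_equal(GenomicRanges::start(rr1) - 1L, 0L)
    expect_equal(GenomicRanges::end(rr1), 25L)
})

test_that("fixed seeds make every generator bit-identical across runs", {
    cfg <- simConfig(nTranscripts = 30, nPatients = 2, seed = 6)
    gt1 <- generateTruth(cfg); gt2 <- generateTruth(cfg)
    expect_identical(gt1, gt2)
    se1 <- simulateMeripWindows(gt1$truth, gt1$transcripts, cfg)
    se2 <- simulateMeripWindows(gt2$truth, gt2$transcripts, cfg)
    expect_identical(SummarizedExperiment::assay(se1, "ip"),
                     SummarizedExperiment::assay(se2, "ip"))
    ex1 <- simulateExpression(gt1$truth, cfg)
    ex2 <- simulateExpression(gt2$truth, cfg)
    expect_identical(SummarizedExperiment::assay(ex1, "counts"),
                     SummarizedExperiment::assay(ex2, "counts"))
})

test_that("null configuration gives unit IP/input ratio; peaks multiply it", {
    # no peaks, enrichment 1: mean IP/input ratio ~ 1 over >= 1e4 windows
    cfg <- simConfig(nTranscripts = 300, nPatients = 2, fracMethylated = 0,
                     peakEnrichment = 1, seed = 7)
    gt <- generateTruth(cfg)
    se <- simulateMeripWindows(gt$truth, gt$transcripts, cfg)
    ip <- rowSums(SummarizedExperiment::assay(se, "ip"))
    input <- rowSums(SummarizedExperiment::assay(se, "input"))
    expect_gte(length(ip), 1e4)
    expect_lt(abs(sum(ip) / sum(input) - 1), 0.02)

    # planted enrichment 4: in-peak IP/input about 4x the out-of-peak ratio
    cfg4 <- simConfig(nTranscripts = 400, nPatients = 2, fracMethylated = 0.5,
                      fracDiffMethylated = 0, peakEnrichment = 4, seed = 8)
    gt4 <- generateTruth(cfg4)
    se4 <- simulateMeripWindows(gt4$truth, gt4$transcripts, cfg4)
    rr <- SummarizedExperiment::rowRanges(se4)
    tx <- as.character(GenomicRanges::seqnames(rr))
    tr <- gt4$truth[match(tx, gt4$truth$transcript_id), ]
    inPeak <- !is.na(tr$peak_start) &
        (GenomicRanges::start(rr) - 1L) < tr$peak_end &
        tr$peak_start < GenomicRanges::end(rr)
    ip <- rowSums(SummarizedExperiment::assay(se4, "ip"))
    input <- rowSums(SummarizedExperiment::assay(se4, "input"))
    ratioIn <- sum(ip[inPeak]) / sum(input[inPeak])
    ratioOut <- sum(ip[!inPeak]) / sum(input[!inPeak])
    expect_lt(abs(ratioIn / ratioOut - 4), 0.25)
})

test_that("peak midpoints follow the segment placement bias", {
    cfg <- simConfig(nTranscripts = 1500, fracMethylated = 1,
                     peakSegmentBias = c(0.1, 0.35, 0.55), seed = 9)
    gt <- generateTruth(cfg)
    tr <- gt$transcripts; th <- gt$truth
    mid <- floor((th$peak_start + th$peak_end) / 2)
    seg <- ifelse(mid < tr$utr5_len, "utr5",
           ifelse(mid < tr$utr5_len + tr$cds_len, "cds", "utr3"))
    expect_gt(sum(seg == "utr3"), sum(seg == "utr5"))
})

test_that("planted expression effects show through at depth 500", {
    cfg <- simConfig(nTranscripts = 400, nPatients = 4, exprFc = 2,
                     fracMethylated = 0.6, fracDiffMethylated = 0.8, seed = 10)
    gt <- generateTruth(cfg)
    ex <- simulateExpression(gt$truth, cfg)
    ec <- expressionChanges(ex)
    up <- gt$truth$gene_id[gt$truth$expr_direction == "up"]
    expect_gte(length(up), 100)
    lfcUp <- ec$log2_fc[ec$gene_id %in% up]
    expect_gte(mean(lfcUp > 0), 0.95)

    # no planted effect: mean fold change of the same genes about zero
    cfg1 <- simConfig(nTranscripts = 400, nPatients = 4, exprFc = 1,
                      fracMethylated = 0.6, fracDiffMethylated = 0.8, seed = 10)
    ec1 <- expressionChanges(simulateExpression(gt$truth, cfg1))
    expect_lt(abs(mean(ec1$log2_fc)), 0.05)
})

test_that("decay series are exact without noise and reject bad input", {
    s <- simulateDecaySeries(log(2), c(0, 1, 2), cv = 0, seed = 1)
    expect_equal(s$rel_abundance, c(1, 0.5, 0.25))
    expect_equal(s$rel_abundance[s$time_h == 0], 1)  # normalisation identity
    expect_error(simulateDecaySeries(-1, c(0, 1), seed = 1), "k must be > 0")
    expect_error(simulateDecaySeries(1, numeric(0), seed = 1), "non-empty")
    expect_error(simulateDecaySeries(1, c(1, 2), seed = 1), "include 0")
})

test_that("calibration runs are linear and labelled by mass transition", {
    run <- simulateCalibrationRun(0.005, c(1, 2, 5, 10), noise = 0, seed = 1)
    expect_setequal(unique(run$standards$transition), c("282>150", "268>136"))
    m6a <- run$standards[run$standards$channel == "m6A", ]
    # noiseless responses sit exactly on the slope-2 line
    expect_equal(m6a$response, 2 * m6a$concentration)
    expect_error(simulateCalibrationRun(0.005, 3, seed = 1), "at least 2")
    expect_error(simulateCalibrationRun(1.5, c(1, 2), seed = 1), "trueRatio")
})
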