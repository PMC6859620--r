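test_that("expression changes use CPM with a 0.5 pseudocount", {
    # gene1 at exactly 100 CPM in A and 25 CPM in B
    counts <- matrix(c(100, 999900, 25, 999975), 2, 2,
                     dimnames = list(c("g1", "g2"), c("s1", "s2")))
    ec <- expressionChanges(counts, conditions = c("B", "A"))
    # B column is s1 here: gene1 100 CPM in B, 25 in A
    expect_equal(ec$log2_fc[1], log2(100.5 / 25.5), tolerance = 1e-12)
    expect_equal(ec$direction[1], "up")

    # identical vectors: zero change, direction none
    same <- matrix(c(10, 90, 10, 90), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
    ec0 <- expressionChanges(same, conditions = c("A", "B"))
    expect_equal(ec0$log2_fc, c(0, 0))
    expect_true(all(ec0$direction == "none"))

    # a 2-fold threshold needs |log2 fc| > 1
    ec2 <- expressionChanges(counts, conditions = c("B", "A"), minAbsLog2fc = 2.5)
    expect_equal(ec2$direction[1], "none")
})

test_that("quadrant vocabulary combines the two directions", {
    tr <- data.frame(transcript_id = c("t1", "t2", "t3"),
                     gene_id = c("g1", "g2", "g3"))
    mkPeak <- function(tx, dir, q, lfc, start = 1) {
        gr <- GenomicRanges::GRanges(tx, IRanges::IRanges(start, start + 99))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            log2_meth_fc = lfc, p_value_diff = q / 2, q_value = q, direction = dir)
        gr
    }
    dp <- suppressWarnings(
        c(mkPeak("t1", "hyper", 0.01, 2), mkPeak("t2", "hyper", 0.01, 1.5),
          mkPeak("t3", "hypo", 0.02, -1)))
    ec <- data.frame(gene_id = c("g1", "g2", "g3"),
                     log2_fc = c(1, -1, 0.5),
                     direction = c("up", "down", "up"))
    calls <- classifyQuadrants(dp, ec, tr)
    expect_equal(calls$quadrant[match(c("g1", "g2", "g3"), calls$gene_id)],
                 c("hyper-up", "hyper-down", "hypo-up"))

    # direction none on the expression axis excludes the gene
    ec$direction[1] <- "none"
    calls2 <- classifyQuadrants(dp, ec, tr)
    expect_false("g1" %in% calls2$gene_id)

    # multi-peak gene: the smallest q wins (hyper at 0.01 beats hypo at 0.04)
    dp2 <- c(mkPeak("t1", "hyper", 0.01, 1),
             mkPeak("t1", "hypo", 0.04, -3, start = 200))
    calls3 <- classifyQuadrants(dp2, data.frame(gene_id = "g1", log2_fc = 1,
                                                direction = "up"), tr)
    expect_equal(calls3$quadrant, "hyper-up")
})

test_that("quadrant percentages sum to 100 and average unweighted", {
    one <- data.frame(patient = "P1", quadrant = rep("hyper-up", 5))
    s1 <- quadrantPercentages(one)
    expect_equal(unname(s1$cohort_mean), c(100, 0, 0, 0))

    counts <- data.frame(
        patient = "P1",
        quadrant = rep(c("hyper-up", "hyper-down", "hypo-up", "hypo-down"),
                       c(7, 1, 1, 1)))
    s2 <- quadrantPercentages(counts)
    expect_equal(unname(s2$cohort_mean), c(70, 10, 10, 10))

    two <- rbind(
        data.frame(patient = "P1",
                   quadrant = rep(c("hyper-up", "hyper-down", "hypo-up", "hypo-down"),
                                  c(16, 2, 1, 1))),   # 80/10/5/5
        data.frame(patient = "P2",
                   quadrant = rep(c("hyper-up", "hyper-down", "hypo-up", "hypo-down"),
                                  c(6, 2, 1, 1))))    # 60/20/10/10
    s3 <- quadrantPercentages(two)
    expect_equal(unname(s3$cohort_mean), c(70, 15, 7.5, 7.5))
    sums <- rowSums(s3$per_patient[, c("hyper-up", "hyper-down", "hypo-up", "hypo-down")])
    expect_equal(unname(sums), c(100, 100), tolerance = 1e-9)
})

test_that("high-frequency rule counts patients sharing a gene", {
    sets <- list(c("a", "b"), "a", c("a", "c"))
    hf <- highFrequencyHyperUp(sets, minShare = 2)
    expect_equal(hf$gene_id, "a")
    expect_equal(hf$n_patients, 3L)

    eight <- c(list(c("x", "y"), c("x", "z"), "x"), replicate(5, "w", simplify = FALSE))
    hf8 <- highFrequencyHyperUp(eight, minShare = 3)
    expect_true("x" %in% hf8$gene_id)   # shared by exactly 3 of 8
    expect_false("y" %in% hf8$gene_id)  # shared by 1
    expect_false("z" %in% hf8$gene_id)
    expect_error(highFrequencyHyperUp(sets, minShare = 0), "minShare")
})

test_that("the candidate screen intersects the two over-threshold lists", {
    a <- data.frame(gene_id = c("IL11", "SERPINE2", "X"), fold_change = c(3, 4, 5))
    b <- data.frame(gene_id = c("IL11", "SERPINE2", "Y"), fold_change = c(3, 3, 3),
                    hyper = TRUE)
    sc <- screenCandidates(a, b)
    expect_equal(sc$candidates, c("IL11", "SERPINE2"))
    expect_equal(unname(sc$sizes), c(3L, 3L, 2L))
    expect_true(all(sc$candidates %in% sc$list_a))
    expect_true(all(sc$candidates %in% sc$list_b))

    # hyper flag gates list B; threshold gates both
    b2 <- b; b2$hyper <- c(FALSE, TRUE, TRUE)
    expect_equal(screenCandidates(a, b2)$candidates, "SERPINE2")
    expect_equal(screenCandidates(a, b, fcThreshold = 10)$candidates, character(0))

    # disjoint lists give an empty intersection
    d <- data.frame(gene_id = "Q", fold_change = 9, hyper = TRUE)
    expect_equal(screenCandidates(a, d)$candidates, character(0))
    expect_error(screenCandidates(a, b, fcThreshold = 0), "fcThreshold")
})

test_that("noiseless planted effects are screened back exactly", {
    # fold changes taken directly from a truth table, no sampling noise
    set.seed(31)
    genes <- sprintf("g%03d", 1:60)
    upA <- sample(genes, 20)                     # over-threshold in axis A
    hyper <- sample(genes, 25)                   # hypermethylated flags
    upB <- sample(genes, 30)                     # over-threshold in axis B
    a <- data.frame(gene_id = genes,
                    fold_change = ifelse(genes %in% upA, 2.5, 1))
    b <- data.frame(gene_id = genes,
                    fold_change = ifelse(genes %in% upB, 2.5, 1),
                    hyper = genes %in% hyper)
    sc <- screenCandidates(a, b)
    expect_setequal(sc$candidates, intersect(upA, intersect(upB, hyper)))
})

test_that("per-patient analysis stacks calls with patient labels", {
    cfg <- simConfig(nTranscripts = 200, nPatients = 3, seed = 32)
    gt <- generateTruth(cfg)
    se <- simulateMeripWindows(gt$truth, gt$transcripts, cfg)
    ex <- simulateExpression(gt$truth, cfg)
    calls <- quadrantsByPatient(callPeaks(se), se, ex, gt$transcripts)
    expect_true(all(calls$patient %in% c("P01", "P02", "P03")))
    expect_true(all(calls$quadrant %in%
                    c("hyper-up", "hyper-down", "hypo-up", "hypo-down")))
    expect_equal(calls$quadrant,
                 paste0(calls$meth_direction, "-", calls$expr_direction))
})
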