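# Independent brute-force oracles, deliberately written from first
# principles (factorial pmf, literal loops) so they share no code with the
# package implementations they check.

# hypergeometric pmf of the first cell of [a, b; c, d] from choose()
.tablePmf <- function(x, rowA, rowB, colA) {
    choose(rowA, x) * choose(rowB, colA - x) / choose(rowA + rowB, colA)
}

# one-sided (upper tail) exact p by exhaustive enumeration
oracleOneSidedP <- function(a, b, c, d) {
    rowA <- a + b; rowB <- c + d; colA <- a + c
    xs <- max(0, colA - rowB):min(colA, rowA)
    sum(vapply(xs[xs >= a], .tablePmf, numeric(1), rowA = rowA, rowB = rowB,
               colA = colA))
}

# two-sided exact p: all tables at most as probable as the observed one
oracleTwoSidedP <- function(a, b, c, d) {
    rowA <- a + b; rowB <- c + d; colA <- a + c
    xs <- max(0, colA - rowB):min(colA, rowA)
    probs <- vapply(xs, .tablePmf, numeric(1), rowA = rowA, rowB = rowB,
                    colA = colA)
    pObs <- .tablePmf(a, rowA, rowB, colA)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# direct step-up Benjamini-Hochberg
oracleBH <- function(p) {
    n <- length(p)
    ord <- order(p)
    q <- numeric(n)
    prev <- 1
    for (i in n:1) {
        val <- min(prev, p[ord[i]] * n / i)
        q[ord[i]] <- val
        prev <- val
    }
    q
}

# literal re-walk of the weighted running sum (p = 1)
oracleES <- function(genes, scores, geneSet) {
    ord <- order(-scores)
    genes <- genes[ord]; scores <- scores[ord]
    hit <- genes %in% geneSet
    denom <- sum(abs(scores[hit]))
    N <- length(genes); nh <- sum(hit)
    running <- 0; best <- 0
    for (i in seq_len(N)) {
        if (hit[i]) running <- running + abs(scores[i]) / denom
        else running <- running - 1 / (N - nh)
        if (abs(running) > abs(best)) best <- running
    }
    best
}

# a small hand-built windows SummarizedExperiment: one sample per condition,
# counts supplied as windows x samples matrices, windows tiled on the given
# transcripts
makeWindowSE <- function(ip, input, transcriptId = "tx1", windowSize = 50,
                         conditions = NULL) {
    nW <- nrow(ip)
    if (length(transcriptId) == 1L) transcriptId <- rep(transcriptId, nW)
    if (is.null(conditions))
        conditions <- rep(c("A", "B"), length.out = ncol(ip))
    starts <- (ave(seq_len(nW), transcriptId, FUN = seq_along) - 1L) * windowSize
    sampleId <- paste0("S", seq_len(ncol(ip)), "_", conditions)
    colnames(ip) <- colnames(input) <- sampleId
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ip = ip, input = input),
        rowRanges = GenomicRanges::GRanges(
            seqnames = transcriptId,
            ranges = IRanges::IRanges(start = starts + 1L,
                                      end = starts + windowSize)),
        colData = S4Vectors::DataFrame(
            sample_id = sampleId,
            patient = paste0("P", seq_len(ncol(ip))),
            condition = conditions,
            row.names = sampleId))
    se
}
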