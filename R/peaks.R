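## Peak calling, differential methylation and metagene segment summaries.
## Windows arrive as a RangedSummarizedExperiment (assays ip/input); peaks
## and differential peaks are GRanges on transcript seqnames. Internally
## GRanges are 1-based closed (Bioconductor convention); the TSV/BED
## writers convert to 0-based half-open.

.poolCounts <- function(se, samples = NULL) {
    ip <- SummarizedExperiment::assay(se, "ip")
    input <- SummarizedExperiment::assay(se, "input")
    if (!is.null(samples)) {
        ip <- ip[, samples, drop = FALSE]
        input <- input[, samples, drop = FALSE]
    }
    list(ip = rowSums(ip), input = rowSums(input))
}

#' Call m6A peaks from pooled IP/input window counts
#'
#' Sums counts over the selected samples (by default all samples, pooling
#' conditions and replicates), tests each window for IP enrichment against
#' its transcript's totals with the one-sided exact test, and merges
#' significant windows into peaks: per transcript, windows with p < alpha
#' form maximal runs allowing up to `maxGap` intervening non-significant
#' windows; runs with fewer than `minRun` significant windows are dropped.
#' The peak p-value is the minimum window p; the peak enrichment is the
#' pseudocounted odds ratio of the pooled run counts against the
#' transcript totals.
#'
#' @param se windows as returned by [simulateMeripWindows()] (assays `ip`
#'   and `input`, transcript seqnames).
#' @param alpha per-window p-value cutoff (default 0.05).
#' @param minRun minimum significant windows per peak (default 2).
#' @param maxGap maximum non-significant windows bridged inside a peak
#'   (default 1).
#' @param pseudocount odds-ratio pseudocount (default 1).
#' @param samples optional character vector of sample ids to pool.
#' @return A [GenomicRanges::GRanges] of peaks with metadata columns
#'   `enrichment`, `p_value`, `n_windows`.
#' @export
callPeaks <- function(se, alpha = 0.05, minRun = 2L, maxGap = 1L,
                      pseudocount = 1, samples = NULL) {
    stopifnot(alpha > 0, alpha < 1, minRun >= 1L, maxGap >= 0L)
    pooled <- .poolCounts(se, samples)
    tx <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(se)))
    starts <- GenomicRanges::start(SummarizedExperiment::rowRanges(se)) - 1L
    ends <- GenomicRanges::end(SummarizedExperiment::rowRanges(se))

    totIp <- tapply(pooled$ip, tx, sum)[tx]
    totInput <- tapply(pooled$input, tx, sum)[tx]
    ok <- totIp > 0 & totInput > 0
    p <- rep(1, length(tx))
    p[ok] <- windowEnrichmentTest(pooled$ip[ok], pooled$input[ok],
                                  totIp[ok], totInput[ok], pseudocount)$p_value

    out <- list()
    idxByTx <- split(seq_along(tx), tx)[unique(tx)]
    for (t in names(idxByTx)) {
        idx <- idxByTx[[t]]
        idx <- idx[order(starts[idx])]
        sig <- which(p[idx] < alpha)
        if (length(sig) == 0L) next
        ## split significant window positions into runs with gaps <= maxGap
        runBreak <- c(TRUE, diff(sig) > maxGap + 1L)
        runId <- cumsum(runBreak)
        for (r in unique(runId)) {
            s <- sig[runId == r]
            if (length(s) < minRun) next
            span <- idx[min(s)]:idx[max(s)]
            ipSum <- sum(pooled$ip[span]); inputSum <- sum(pooled$input[span])
            a <- pseudocount
            enr <- ((ipSum + a) / (totIp[idx[1]] - ipSum + a)) /
                ((inputSum + a) / (totInput[idx[1]] - inputSum + a))
            out[[length(out) + 1L]] <- data.frame(
                transcript_id = t,
                start = starts[idx[min(s)]], end = ends[idx[max(s)]],
                enrichment = unname(enr), p_value = min(p[idx][s]),
                n_windows = length(s))
        }
    }
    if (length(out) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            enrichment = numeric(), p_value = numeric(), n_windows = integer())
        return(gr)
    }
    df <- do.call(rbind, out)
    GenomicRanges::GRanges(
        seqnames = df$transcript_id,
        ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
        enrichment = df$enrichment, p_value = df$p_value,
        n_windows = df$n_windows)
}

#' Test peaks for differential methylation between conditions
#'
#' For each peak, IP and input counts of the overlapping windows are summed
#' per condition (replicates within a condition pooled), the two-sided
#' exact test is applied to the table `[IP_B, input_B; IP_A, input_A]`, and
#' the methylation change is `log2(((IP_B+a)/(input_B+a)) /
#' ((IP_A+a)/(input_A+a)))` with pseudocount a. Benjamini-Hochberg q-values
#' are computed across all peaks; a peak is called `hyper` (`hypo`) when
#' its change is positive (negative), p < alpha and q < fdr.
#'
#' @param peaks GRanges from [callPeaks()].
#' @param se the windows SummarizedExperiment (colData column `condition`
#'   with levels "A" and "B").
#' @param fdr BH q-value threshold (default 0.05).
#' @param alpha raw p-value threshold (default 0.05).
#' @param pseudocount fold-change pseudocount (default 1).
#' @param samples optional sample ids to restrict to (e.g. one patient's
#'   pair).
#' @return `peaks` with added metadata columns `ip_a`, `input_a`, `ip_b`,
#'   `input_b`, `log2_meth_fc`, `p_value_diff`, `q_value`, `direction`
#'   (hyper/hypo/none).
#' @export
differentialMethylation <- function(peaks, se, fdr = 0.05, alpha = 0.05,
                                    pseudocount = 1, samples = NULL) {
    cd <- SummarizedExperiment::colData(se)
    keep <- if (is.null(samples)) rownames(cd) else samples
    sampA <- keep[cd[keep, "condition"] == "A"]
    sampB <- keep[cd[keep, "condition"] == "B"]
    if (length(sampA) == 0L || length(sampB) == 0L)
        stop("both conditions must be represented among the selected samples")
    if (length(peaks) == 0L) {
        S4Vectors::mcols(peaks) <- cbind(
            S4Vectors::mcols(peaks),
            S4Vectors::DataFrame(ip_a = numeric(), input_a = numeric(),
                                 ip_b = numeric(), input_b = numeric(),
                                 log2_meth_fc = numeric(),
                                 p_value_diff = numeric(), q_value = numeric(),
                                 direction = character()))
        return(peaks)
    }
    pooledA <- .poolCounts(se, sampA)
    pooledB <- .poolCounts(se, sampB)
    hits <- GenomicRanges::findOverlaps(SummarizedExperiment::rowRanges(se), peaks)
    sumOver <- function(v) {
        out <- numeric(length(peaks))
        s <- tapply(v[S4Vectors::queryHits(hits)], S4Vectors::subjectHits(hits), sum)
        out[as.integer(names(s))] <- s
        out
    }
    ipA <- sumOver(pooledA$ip); inputA <- sumOver(pooledA$input)
    ipB <- sumOver(pooledB$ip); inputB <- sumOver(pooledB$input)

    a <- pseudocount
    lfc <- log2(((ipB + a) / (inputB + a)) / ((ipA + a) / (inputA + a)))
    p <- rep(1, length(peaks))
    nz <- (ipA + inputA + ipB + inputB) > 0
    p[nz] <- .twoSidedExactPVec(ipB[nz], inputB[nz], ipA[nz], inputA[nz])
    q <- bhAdjust(p)
    dir <- ifelse(p < alpha & q < fdr & lfc > 0, "hyper",
           ifelse(p < alpha & q < fdr & lfc < 0, "hypo", "none"))
    dir[!nz] <- "none"

    mc <- S4Vectors::mcols(peaks)
    mc$ip_a <- ipA; mc$input_a <- inputA
    mc$ip_b <- ipB; mc$input_b <- inputB
    mc$log2_meth_fc <- lfc
    mc$p_value_diff <- p
    mc$q_value <- q
    mc$direction <- dir
    S4Vectors::mcols(peaks) <- mc
    peaks
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values in the input order, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Fraction of peaks per transcript segment
#'
#' Assigns each peak to exactly one of 5'UTR, CDS or 3'UTR by its integer
#' midpoint `floor((start + end) / 2)` in 0-based coordinates, using
#' half-open segment intervals (a midpoint on the CDS/3'UTR boundary
#' belongs to the 3'UTR).
#'
#' @param peaks GRanges of peaks.
#' @param transcripts transcript table from [generateTruth()] (or any
#'   data.frame with transcript_id, utr5_len, cds_len, total_len).
#' @return list with `frac_utr5`, `frac_cds`, `frac_utr3`, `n_peaks`.
#' @export
segmentFractions <- function(peaks, transcripts) {
    n <- length(peaks)
    if (n == 0L)
        return(list(frac_utr5 = NaN, frac_cds = NaN, frac_utr3 = NaN, n_peaks = 0L))
    tid <- as.character(GenomicRanges::seqnames(peaks))
    i <- match(tid, transcripts$transcript_id)
    if (anyNA(i))
        stop("peak references unknown transcript: ", tid[which(is.na(i))[1]])
    start0 <- GenomicRanges::start(peaks) - 1L
    end0 <- GenomicRanges::end(peaks)
    mid <- floor((start0 + end0) / 2)
    u5 <- transcripts$utr5_len[i]
    cdsEnd <- u5 + transcripts$cds_len[i]
    seg <- ifelse(mid < u5, "utr5", ifelse(mid < cdsEnd, "cds", "utr3"))
    list(frac_utr5 = sum(seg == "utr5") / n,
         frac_cds = sum(seg == "cds") / n,
         frac_utr3 = sum(seg == "utr3") / n,
         n_peaks = n)
}
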