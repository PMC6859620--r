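## Synthetic MeRIP-seq / RNA-seq data with planted ground truth.
##
## All coordinates are transcript-space, 0-based, half-open. Counts are
## negative binomial (mean mu, size 1/dispersion). Seeding: each generator
## derives its stream from config@seed plus a fixed stage offset, so stages
## are reproducible in isolation.

.QUADRANTS <- c("hyper-up", "hyper-down", "hypo-up", "hypo-down")

.stageSeed <- function(seed, offset) as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)

#' Generate transcript models and planted ground truth
#'
#' Draws a cohort of transcripts with 5'UTR/CDS/3'UTR architecture, marks a
#' seeded binomial fraction of them as m6A-methylated, plants one contiguous
#' peak per methylated transcript (midpoint drawn by segment weights,
#' uniform within the segment), and assigns a joint methylation/expression
#' quadrant to the differential subset according to `quadrantMix`.
#'
#' @param config a [SimConfig-class] object.
#' @return A list with elements `transcripts` (data.frame: transcript_id,
#'   gene_id, utr5_len, cds_len, utr3_len, total_len) and `truth`
#'   (data.frame: transcript_id, gene_id, is_methylated, peak_start,
#'   peak_end, meth_direction in gain/loss/none, expr_direction in
#'   up/down/none, true_quadrant). Peak coordinates are 0-based half-open;
#'   NA when the transcript is unmethylated.
#' @examples
#' gt <- generateTruth(simConfig(nTranscripts = 50, nPatients = 2, seed = 7))
#' table(gt$truth$true_quadrant, useNA = "ifany")
#' @export
generateTruth <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nTranscripts
    if (n == 0L) {
        empty <- data.frame(transcript_id = character(), gene_id = character())
        return(list(
            transcripts = cbind(empty, utr5_len = integer(), cds_len = integer(),
                                utr3_len = integer(), total_len = integer()),
            truth = cbind(empty, is_methylated = logical(),
                          peak_start = integer(), peak_end = integer(),
                          meth_direction = character(), expr_direction = character(),
                          true_quadrant = character())))
    }
    set.seed(.stageSeed(config@seed, 0))
    m <- config@segmentLengthMeans
    ## gamma-distributed segment lengths (shape 4 gives realistic spread);
    ## CDS kept strictly positive, UTRs may be short but not negative
    utr5 <- pmax(10L, as.integer(round(rgamma(n, shape = 4, rate = 4 / m[1]))))
    cds  <- pmax(90L, as.integer(round(rgamma(n, shape = 4, rate = 4 / m[2]))))
    utr3 <- pmax(10L, as.integer(round(rgamma(n, shape = 4, rate = 4 / m[3]))))
    total <- utr5 + cds + utr3
    tid <- sprintf("tx%04d", seq_len(n))
    gid <- sprintf("gene%04d", seq_len(n))
    transcripts <- data.frame(
        transcript_id = tid, gene_id = gid,
        utr5_len = utr5, cds_len = cds, utr3_len = utr3, total_len = total,
        stringsAsFactors = FALSE)

    isMeth <- runif(n) < config@fracMethylated
    isDiff <- isMeth & (runif(n) < config@fracDiffMethylated)
    quadrant <- rep(NA_character_, n)
    nd <- sum(isDiff)
    if (nd > 0L)
        quadrant[isDiff] <- sample(.QUADRANTS, nd, replace = TRUE,
                                   prob = config@quadrantMix)
    methDir <- ifelse(is.na(quadrant), ifelse(isMeth, "none", "none"),
                      ifelse(startsWith(quadrant, "hyper"), "gain", "loss"))
    exprDir <- ifelse(is.na(quadrant), "none",
                      ifelse(endsWith(quadrant, "-up"), "up", "down"))

    ## peak placement: segment by weights (segments of zero length excluded
    ## per transcript), midpoint uniform within the segment
    peakStart <- rep(NA_integer_, n)
    peakEnd <- rep(NA_integer_, n)
    halfw <- as.integer(round(config@peakWidthWindows * config@windowSize / 2))
    segProb <- config@peakSegmentBias
    for (i in which(isMeth)) {
        lens <- c(utr5[i], cds[i], utr3[i])
        w <- segProb * (lens > 0)
        seg <- sample.int(3L, 1L, prob = w)
        off <- c(0L, utr5[i], utr5[i] + cds[i])[seg]
        mid <- off + sample.int(lens[seg], 1L) - 1L
        peakStart[i] <- max(0L, mid - halfw)
        peakEnd[i] <- min(total[i], mid + halfw)
        if (peakEnd[i] <= peakStart[i]) peakEnd[i] <- peakStart[i] + 1L
    }
    truth <- data.frame(
        transcript_id = tid, gene_id = gid,
        is_methylated = isMeth,
        peak_start = peakStart, peak_end = peakEnd,
        meth_direction = methDir, expr_direction = exprDir,
        true_quadrant = quadrant,
        stringsAsFactors = FALSE)
    list(transcripts = transcripts, truth = truth)
}

## tile one transcript end-to-end with half-open windows (0-based)
.tileWindows <- function(totalLen, windowSize) {
    nWin <- max(1L, as.integer(ceiling(totalLen / windowSize)))
    start <- (seq_len(nWin) - 1L) * windowSize
    end <- pmin(start + windowSize, totalLen)
    data.frame(start = start, end = end)
}

## per-sample metadata shared by the window and expression simulators
.sampleLayout <- function(config) {
    patients <- sprintf("P%02d", seq_len(config@nPatients))
    data.frame(
        sample_id = paste0(rep(patients, each = 2L), "_", c("A", "B")),
        patient = rep(patients, each = 2L),
        condition = rep(c("A", "B"), config@nPatients),
        stringsAsFactors = FALSE)
}

## patient size factors and per-transcript relative expression, drawn from
## their own sub-stream so windows and expression share none of each other's
## randomness but see the same planted effects
.latentLevels <- function(config, n) {
    set.seed(.stageSeed(config@seed, 10))
    list(sizeFactor = exp(rnorm(config@nPatients, 0, 0.15)),
         relExpr = rgamma(n, shape = 2, rate = 2))
}

#' Simulate IP/input window counts for a paired MeRIP-seq cohort
#'
#' Tiles every transcript end-to-end with half-open windows and draws
#' negative-binomial IP and input counts for each window in each sample.
#' Input rates track expression only; IP rates are additionally multiplied
#' by `peakEnrichment` inside the planted peak, and by `diffShift` in
#' condition B for methylation gains (condition A for losses).
#'
#' @param truth,transcripts outputs of [generateTruth()].
#' @param config the same [SimConfig-class] used to generate them.
#' @return A [SummarizedExperiment::RangedSummarizedExperiment] with assays
#'   `ip` and `input` (windows x samples), row ranges on transcript
#'   seqnames, and colData columns `sample_id`, `patient`, `condition`.
#' @export
simulateMeripWindows <- function(truth, transcripts, config) {
    stopifnot(is(config, "SimConfig"), nrow(truth) == nrow(transcripts))
    layout <- .sampleLayout(config)
    lat <- .latentLevels(config, nrow(transcripts))
    ws <- config@windowSize
    nWin <- pmax(1L, as.integer(ceiling(transcripts$total_len / ws)))
    txIdx <- rep(seq_len(nrow(transcripts)), nWin)
    winStart <- (sequence(nWin) - 1L) * ws
    win <- data.frame(tx = txIdx, start = winStart,
                      end = pmin(winStart + ws, transcripts$total_len[txIdx]))
    nW <- nrow(win); nS <- nrow(layout)

    txTotal <- transcripts$total_len[win$tx]
    winLen <- win$end - win$start
    inPeak <- !is.na(truth$peak_start[win$tx]) &
        win$start < truth$peak_end[win$tx] & truth$peak_start[win$tx] < win$end
    methDir <- truth$meth_direction[win$tx]
    exprDir <- truth$expr_direction[win$tx]

    baseRate <- config@seqDepth * lat$relExpr[win$tx] * winLen / txTotal
    size <- 1 / config@dispersion

    set.seed(.stageSeed(config@seed, 1))
    ip <- matrix(0L, nW, nS)
    input <- matrix(0L, nW, nS)
    for (j in seq_len(nS)) {
        condB <- layout$condition[j] == "B"
        sf <- lat$sizeFactor[match(layout$patient[j], unique(layout$patient))]
        exprMult <- ifelse(exprDir == "up", if (condB) config@exprFc else 1,
                    ifelse(exprDir == "down", if (condB) 1 / config@exprFc else 1, 1))
        mu <- baseRate * sf * exprMult
        enrich <- ifelse(inPeak, config@peakEnrichment, 1)
        shifted <- inPeak & ((condB & methDir == "gain") | (!condB & methDir == "loss"))
        enrich[shifted] <- enrich[shifted] * config@diffShift
        input[, j] <- rnbinom(nW, mu = mu, size = size)
        ip[, j] <- rnbinom(nW, mu = mu * enrich, size = size)
    }
    colnames(ip) <- colnames(input) <- layout$sample_id

    rr <- GenomicRanges::GRanges(
        seqnames = transcripts$transcript_id[win$tx],
        ranges = IRanges::IRanges(start = win$start + 1L, end = win$end))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ip = ip, input = input),
        rowRanges = rr,
        colData = S4Vectors::DataFrame(layout, row.names = layout$sample_id))
    SummarizedExperiment::rowData(se)$transcript_id <- transcripts$transcript_id[win$tx]
    se
}

#' Simulate gene-level expression counts
#'
#' Negative-binomial gene counts for the same paired cohort; genes planted
#' "up" have their mean multiplied by `exprFc` in condition B, "down" genes
#' divided by it. Library size factors are patient-level and recorded in
#' the colData.
#'
#' @param truth output of [generateTruth()].
#' @param config the matching [SimConfig-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (gene x sample), rowData `gene_id`, colData `sample_id`,
#'   `patient`, `condition`, `size_factor`.
#' @export
simulateExpression <- function(truth, config) {
    stopifnot(is(config, "SimConfig"))
    layout <- .sampleLayout(config)
    lat <- .latentLevels(config, nrow(truth))
    nG <- nrow(truth); nS <- nrow(layout)
    size <- 1 / config@dispersion
    set.seed(.stageSeed(config@seed, 2))
    counts <- matrix(0L, nG, nS, dimnames = list(truth$gene_id, layout$sample_id))
    for (j in seq_len(nS)) {
        condB <- layout$condition[j] == "B"
        sf <- lat$sizeFactor[match(layout$patient[j], unique(layout$patient))]
        exprMult <- ifelse(truth$expr_direction == "up", if (condB) config@exprFc else 1,
                    ifelse(truth$expr_direction == "down", if (condB) 1 / config@exprFc else 1, 1))
        counts[, j] <- rnbinom(nG, mu = config@seqDepth * lat$relExpr * sf * exprMult,
                               size = size)
    }
    layout$size_factor <- lat$sizeFactor[match(layout$patient, unique(layout$patient))]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = truth$gene_id),
        colData = S4Vectors::DataFrame(layout, row.names = layout$sample_id))
}

#' Simulate an exponential RNA decay time course
#'
#' Abundances follow N_t = exp(-k t) * (1 + eps_t) with mean-zero Gaussian
#' noise of coefficient of variation `cv`; the series is re-normalised to
#' its t = 0 value so the first abundance is exactly 1.
#'
#' @param k degradation rate per hour (> 0).
#' @param timepoints hours, must include 0.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `time_h` and `rel_abundance`.
#' @examples
#' simulateDecaySeries(log(2), c(0, 1, 2), cv = 0, seed = 1)
#' @export
simulateDecaySeries <- function(k, timepoints, cv = 0, seed) {
    if (length(timepoints) == 0L) stop("timepoints must be non-empty")
    if (!any(timepoints == 0)) stop("timepoints must include 0")
    if (k <= 0) stop("decay rate k must be > 0")
    if (cv < 0) stop("cv must be >= 0")
    if (!missing(seed)) set.seed(as.integer(seed))
    tp <- sort(unique(as.numeric(timepoints)))
    ab <- exp(-k * tp) * pmax(1 + rnorm(length(tp), 0, cv), 1e-6)
    ab <- ab / ab[tp == 0]
    data.frame(time_h = tp, rel_abundance = ab)
}

.TRANSITIONS <- c(m6A = "282>150", A = "268>136")

#' Simulate an LC-MS/MS calibration run
#'
#' Generates, for the m6A (mass transition 282->150) and A (268->136)
#' channels, instrument responses linear in concentration over a shared set
#' of standards, plus one sample whose underlying concentrations are
#' consistent with the requested true m6A/A ratio.
#'
#' @param trueRatio planted m6A/A concentration ratio in (0, 1).
#' @param standards strictly positive, distinct standard concentrations
#'   (>= 2 values).
#' @param noise standard deviation of additive response noise.
#' @param seed integer seed.
#' @param slope,intercept named per-channel line parameters.
#' @param concA adenosine concentration of the simulated sample (defaults
#'   to the mean standard concentration).
#' @return list with `standards` (data.frame: channel, transition,
#'   concentration, response) and `sample` (data.frame: channel, response).
#' @export
simulateCalibrationRun <- function(trueRatio, standards, noise = 0, seed,
                                   slope = c(m6A = 2, A = 2),
                                   intercept = c(m6A = 0, A = 0),
                                   concA = NULL) {
    if (length(standards) < 2L) stop("need at least 2 calibration standards")
    if (any(standards <= 0) || anyDuplicated(standards))
        stop("standards must be strictly positive and distinct")
    if (trueRatio <= 0 || trueRatio >= 1) stop("trueRatio must lie in (0, 1)")
    if (!missing(seed)) set.seed(as.integer(seed))
    if (is.null(concA)) concA <- mean(standards)
    conc <- c(m6A = trueRatio * concA, A = concA)
    std <- do.call(rbind, lapply(names(.TRANSITIONS), function(ch) {
        data.frame(channel = ch, transition = .TRANSITIONS[[ch]],
                   concentration = standards,
                   response = slope[[ch]] * standards + intercept[[ch]] +
                       rnorm(length(standards), 0, noise),
                   stringsAsFactors = FALSE)
    }))
    smp <- data.frame(channel = names(.TRANSITIONS),
                      response = slope[names(.TRANSITIONS)] * conc +
                          intercept[names(.TRANSITIONS)] +
                          rnorm(2L, 0, noise),
                      stringsAsFactors = FALSE)
    rownames(std) <- rownames(smp) <- NULL
    list(standards = std, sample = smp)
}
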