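#' @import methods
#' @importFrom stats dhyper phyper rnbinom rnorm rgamma runif lm coef
#'   p.adjust ks.test setNames
NULL

#' Simulation configuration for synthetic MeRIP-seq experiments
#'
#' Parameterises the data-generating process used by [generateTruth()],
#' [simulateMeripWindows()] and [simulateExpression()]: a cohort of paired
#' tumour-like ("B") and normal-like ("A") samples, transcripts with
#' 5'UTR/CDS/3'UTR architecture, negative-binomial IP/input window counts,
#' planted m6A peaks with a segment placement bias, and planted joint
#' methylation/expression ("quadrant") effects.
#'
#' @slot nTranscripts number of transcripts (one gene per transcript).
#' @slot nPatients number of patients; each contributes one sample per
#'   condition sharing a patient-level size factor.
#' @slot windowSize window width in nucleotides used to tile transcripts.
#' @slot segmentLengthMeans mean lengths (nt) of 5'UTR, CDS and 3'UTR.
#' @slot fracMethylated proportion of transcripts carrying a true m6A peak.
#' @slot fracDiffMethylated proportion of methylated transcripts whose
#'   methylation changes between conditions.
#' @slot quadrantMix weights over the four joint labels
#'   (hyper-up, hyper-down, hypo-up, hypo-down); normalised to sum to 1.
#' @slot peakEnrichment IP-over-input rate multiplier inside peaks (>= 1).
#' @slot diffShift extra multiplicative IP shift, applied in condition B for
#'   methylation gains and in condition A for losses.
#' @slot exprFc multiplicative expression change for planted up/down genes
#'   (>= 1; the direction is encoded separately in the truth table).
#' @slot seqDepth mean reads per transcript per sample.
#' @slot dispersion negative-binomial overdispersion (> 0); the Poisson
#'   limit corresponds to dispersion -> 0 but 0 itself is rejected.
#' @slot peakSegmentBias placement weights of peak midpoints over
#'   5'UTR/CDS/3'UTR.
#' @slot peakWidthWindows planted peak width in windows.
#' @slot seed integer seed; every simulation derives its stream from it.
#'
#' @seealso [simConfig()] for construction with defaults.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nTranscripts      = "integer",
    nPatients         = "integer",
    windowSize        = "integer",
    segmentLengthMeans = "numeric",
    fracMethylated    = "numeric",
    fracDiffMethylated = "numeric",
    quadrantMix       = "numeric",
    peakEnrichment    = "numeric",
    diffShift         = "numeric",
    exprFc            = "numeric",
    seqDepth          = "numeric",
    dispersion        = "numeric",
    peakSegmentBias   = "numeric",
    peakWidthWindows  = "integer",
    seed              = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nTranscripts < 0L) msg <- c(msg, "nTranscripts must be >= 0")
    if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
    if (object@windowSize < 1L) msg <- c(msg, "windowSize must be >= 1")
    if (length(object@segmentLengthMeans) != 3L ||
        any(object@segmentLengthMeans <= 0))
        msg <- c(msg, "segmentLengthMeans must be 3 positive values")
    for (p in c("fracMethylated", "fracDiffMethylated")) {
        v <- slot(object, p)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, paste(p, "must be a proportion in [0, 1]"))
    }
    if (length(object@quadrantMix) != 4L || any(object@quadrantMix < 0) ||
        sum(object@quadrantMix) <= 0)
        msg <- c(msg, "quadrantMix must be 4 nonnegative weights with positive sum")
    if (object@peakEnrichment < 1) msg <- c(msg, "peakEnrichment must be >= 1")
    if (object@diffShift <= 0) msg <- c(msg, "diffShift must be > 0")
    if (object@exprFc < 1) msg <- c(msg, "exprFc must be >= 1 (direction is encoded separately)")
    if (object@seqDepth <= 0) msg <- c(msg, "seqDepth must be > 0")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (length(object@peakSegmentBias) != 3L || any(object@peakSegmentBias < 0) ||
        sum(object@peakSegmentBias) <= 0)
        msg <- c(msg, "peakSegmentBias must be 3 nonnegative weights with positive sum")
    if (object@peakWidthWindows < 1L) msg <- c(msg, "peakWidthWindows must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults mirror the study design the generator emulates: 8 paired
#' tumour/paratumour patients, a quadrant mixture dominated by hyper-up
#' (70/10/10/10), a 2-fold expression change for planted genes, a 2.5-fold
#' differential methylation shift, and peak placement biased towards the
#' 3'UTR and CDS.
#'
#' @param nTranscripts,nPatients cohort dimensions.
#' @param windowSize tiling window width (nt).
#' @param segmentLengthMeans mean 5'UTR/CDS/3'UTR lengths (nt).
#' @param fracMethylated,fracDiffMethylated planted methylation proportions.
#' @param quadrantMix weights over hyper-up, hyper-down, hypo-up, hypo-down.
#' @param peakEnrichment,diffShift,exprFc effect sizes (multiplicative).
#' @param seqDepth mean reads per transcript per sample.
#' @param dispersion negative-binomial overdispersion (> 0).
#' @param peakSegmentBias peak midpoint weights over the three segments.
#' @param peakWidthWindows planted peak width in windows.
#' @param seed integer seed (mandatory).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nTranscripts = 100, nPatients = 2, seed = 1)
#' cfg
#' @export
simConfig <- function(nTranscripts = 1000L,
                      nPatients = 8L,
                      windowSize = 50L,
                      segmentLengthMeans = c(200, 1200, 800),
                      fracMethylated = 0.5,
                      fracDiffMethylated = 0.5,
                      quadrantMix = c(0.7, 0.1, 0.1, 0.1),
                      peakEnrichment = 4,
                      diffShift = 2.5,
                      exprFc = 2,
                      seqDepth = 500,
                      dispersion = 0.01,
                      peakSegmentBias = c(0.1, 0.35, 0.55),
                      peakWidthWindows = 2L,
                      seed) {
    if (missing(seed)) stop("'seed' is mandatory in a simulation configuration")
    new("SimConfig",
        nTranscripts = as.integer(nTranscripts),
        nPatients = as.integer(nPatients),
        windowSize = as.integer(windowSize),
        segmentLengthMeans = as.numeric(segmentLengthMeans),
        fracMethylated = as.numeric(fracMethylated),
        fracDiffMethylated = as.numeric(fracDiffMethylated),
        quadrantMix = as.numeric(quadrantMix) / sum(as.numeric(quadrantMix)),
        peakEnrichment = as.numeric(peakEnrichment),
        diffShift = as.numeric(diffShift),
        exprFc = as.numeric(exprFc),
        seqDepth = as.numeric(seqDepth),
        dispersion = as.numeric(dispersion),
        peakSegmentBias = as.numeric(peakSegmentBias),
        peakWidthWindows = as.integer(peakWidthWindows),
        seed = as.integer(seed))
}

#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nTranscripts, "transcripts,",
        object@nPatients, "paired patients\n")
    cat("  window", object@windowSize, "nt; depth", object@seqDepth,
        "reads/transcript; NB dispersion", object@dispersion, "\n")
    cat("  methylated:", object@fracMethylated,
        "| differential:", object@fracDiffMethylated,
        "| quadrant mix:", paste(signif(object@quadrantMix, 3), collapse = "/"), "\n")
    cat("  peak enrichment", object@peakEnrichment, "x; diff shift",
        object@diffShift, "x; expression fc", object@exprFc, "x\n")
    cat("  seed:", object@seed, "\n")
})

#' First-order RNA decay fit
#'
#' Result of [fitDecay()]: the degradation rate `k` (per hour) of the model
#' N_t/N_0 = exp(-k t), the half-life t1/2 = ln(2)/k, and the goodness of
#' fit on the log scale. A non-decaying (growing) series is returned with
#' `flagged = TRUE` and an infinite half-life rather than an error.
#'
#' @slot k degradation rate, per hour.
#' @slot tHalf half-life in hours (`Inf` when k <= 0).
#' @slot rSquared coefficient of determination of the zero-intercept
#'   log-linear fit (<= 1).
#' @slot nPoints number of timepoints used.
#' @slot flagged TRUE when the fitted k is non-positive.
#' @exportClass DecayFit
setClass("DecayFit", representation(
    k = "numeric", tHalf = "numeric", rSquared = "numeric",
    nPoints = "integer", flagged = "logical"))

setValidity("DecayFit", function(object) {
    if (object@nPoints < 3L) return("decay fits require >= 3 timepoints")
    if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-12)
        return("rSquared must be <= 1")
    if (object@k > 0 && abs(object@tHalf - log(2) / object@k) > 1e-9)
        return("tHalf must equal ln(2)/k")
    TRUE
})

#' @export
setMethod("show", "DecayFit", function(object) {
    cat(sprintf("DecayFit: k = %.4g /h, t1/2 = %.4g h, R^2(log) = %.4f (n = %d)%s\n",
                object@k, object@tHalf, object@rSquared, object@nPoints,
                if (object@flagged) " [flagged: non-decaying]" else ""))
})

#' LC-MS/MS nucleoside calibration curve
#'
#' Ordinary least-squares line (response = slope * concentration +
#' intercept) fitted to pure nucleoside standards for one multiple-reaction
#' monitoring channel. The two supported channels carry their
#' nucleoside-to-base ion mass transitions: m6A 282->150 and A 268->136.
#'
#' @slot channel "m6A" or "A".
#' @slot transition mass transition string for the channel.
#' @slot slope,intercept fitted line coefficients.
#' @slot rSquared coefficient of determination.
#' @slot nStandards number of calibration standards.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve", representation(
    channel = "character", transition = "character",
    slope = "numeric", intercept = "numeric",
    rSquared = "numeric", nStandards = "integer"))

setValidity("CalibrationCurve", function(object) {
    if (!object@channel %in% c("m6A", "A"))
        return("channel must be 'm6A' or 'A'")
    if (object@nStandards < 2L) return("calibration needs >= 2 standards")
    TRUE
})

#' @export
setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf("CalibrationCurve [%s, %s]: response = %.6g * conc %+.6g (R^2 = %.4f, n = %d)\n",
                object@channel, object@transition, object@slope,
                object@intercept, object@rSquared, object@nStandards))
})

#' Gene-set enrichment result
#'
#' Output of [nesAndPvalue()]: the weighted running-sum enrichment score,
#' its permutation-normalised version and a one-sided permutation p-value
#' with the +1 correction (never exactly zero).
#'
#' @slot es enrichment score in `[-1, 1]`.
#' @slot nes normalised enrichment score (es scaled by the mean same-sign
#'   permutation ES magnitude; 0 when es is 0, NA when no same-sign null
#'   ES was observed).
#' @slot pValue permutation p-value in (0, 1].
#' @slot nPermutations number of gene-label permutations used.
#' @slot nHits number of gene-set members found in the ranked list.
#' @slot seed seed used for the permutation stream.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
    es = "numeric", nes = "numeric", pValue = "numeric",
    nPermutations = "integer", nHits = "integer", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
    if (abs(object@es) > 1 + 1e-9) return("|es| must be <= 1")
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    TRUE
})

#' @export
setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult: ES = %.4f, NES = %.4f, p = %.4g (%d hits, %d permutations, seed %d)\n",
                object@es, object@nes, object@pValue, object@nHits,
                object@nPermutations, object@seed))
})
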