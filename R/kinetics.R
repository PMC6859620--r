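## First-order RNA decay fitting, LC-MS/MS standard-curve calibration and
## percent-input qPCR enrichment.

#' Fit first-order exponential decay
#'
#' Least-squares fit of `ln(N_t) = -k t` with the intercept fixed at zero
#' (the series is normalised so N_0 = 1), matching the model
#' N_t/N_0 = exp(-k t). The half-life is t1/2 = ln(2)/k. R-squared is
#' computed on the log scale against the mean-log baseline. A fitted
#' k <= 0 (growing series) is returned flagged with an infinite
#' half-life instead of raising an error.
#'
#' @param time timepoints in hours (>= 3, must include 0).
#' @param abundance relative abundances (> 0), N_0 normalised to 1.
#' @return A [DecayFit-class] object.
#' @examples
#' fitDecay(c(0, 1, 2), c(1, 0.5, 0.25))  # k = ln 2, t1/2 = 1 h
#' @export
fitDecay <- function(time, abundance) {
    if (is.data.frame(time)) {
        abundance <- time$rel_abundance; time <- time$time_h
    }
    if (length(time) != length(abundance)) stop("time and abundance differ in length")
    if (length(time) < 3L) stop("decay fitting needs >= 3 timepoints")
    if (!any(time == 0)) stop("timepoints must include 0")
    bad <- which(abundance <= 0)
    if (length(bad))
        stop("non-positive abundance at timepoint t = ", time[bad[1]], " h")
    y <- log(abundance)
    k <- -sum(time * y) / sum(time^2)
    resid <- y - (-k * time)
    ssTot <- sum((y - mean(y))^2)
    r2 <- if (ssTot == 0) 1 else 1 - sum(resid^2) / ssTot
    flagged <- k <= 0
    new("DecayFit", k = k,
        tHalf = if (flagged) Inf else log(2) / k,
        rSquared = min(1, r2), nPoints = length(time), flagged = flagged)
}

#' Half-life from a first-order decay rate
#'
#' @param k degradation rate per hour (> 0).
#' @return half-life t1/2 = ln(2)/k, in hours.
#' @examples
#' halfLife(log(2))  # 1 hour
#' @export
halfLife <- function(k) {
    if (any(k <= 0)) stop("half-life is defined for k > 0 only")
    log(2) / k
}

#' Fit an LC-MS/MS calibration standard curve
#'
#' Ordinary least squares of instrument response on standard concentration
#' (free intercept: instrument baselines are not assumed to be zero).
#'
#' @param concentration standard concentrations (>= 2 distinct values).
#' @param response instrument responses.
#' @param channel "m6A" (transition 282->150) or "A" (268->136).
#' @return A [CalibrationCurve-class] object.
#' @examples
#' fitCalibration(c(1, 3), c(3, 7), "A")  # slope 2, intercept 1
#' @export
fitCalibration <- function(concentration, response, channel = c("m6A", "A")) {
    channel <- match.arg(channel)
    if (length(concentration) < 2L) stop("need >= 2 calibration standards")
    if (length(unique(concentration)) < 2L)
        stop("singular fit: calibration concentrations are identical")
    fit <- lm(response ~ concentration)
    ssTot <- sum((response - mean(response))^2)
    r2 <- if (ssTot == 0) 1 else 1 - sum(fit$residuals^2) / ssTot
    new("CalibrationCurve", channel = channel,
        transition = .TRANSITIONS[[channel]],
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        rSquared = r2, nStandards = length(concentration))
}

#' m6A/A ratio from calibrated channel responses
#'
#' Inverts each channel's standard curve (`conc = (response - intercept) /
#' slope`) and returns the ratio of the calibrated m6A concentration to
#' the calibrated A concentration.
#'
#' @param responses named numeric with elements `m6A` and `A`.
#' @param curves list with [CalibrationCurve-class] elements `m6A` and `A`.
#' @return the m6A/A concentration ratio.
#' @export
quantifyM6aToARatio <- function(responses, curves) {
    stopifnot(all(c("m6A", "A") %in% names(responses)),
              all(c("m6A", "A") %in% names(curves)))
    conc <- vapply(c("m6A", "A"), function(ch) {
        cv <- curves[[ch]]
        if (cv@slope <= 0) stop("invalid calibration slope on channel ", ch)
        val <- (responses[[ch]] - cv@intercept) / cv@slope
        if (val <= 0)
            stop("calibrated concentration is non-positive on channel ", ch)
        val
    }, numeric(1))
    unname(conc["m6A"] / conc["A"])
}

#' Percent-input qPCR enrichment
#'
#' `percent_input = 100 * 2^((ct_input - log2(dilution)) - ct_ip)`: the IP
#' signal as a percentage of the dilution-corrected input signal under the
#' 2^dCt assumption.
#'
#' @param ctIp,ctInput cycle thresholds (finite, positive).
#' @param inputDilutionFactor input dilution factor (>= 1; default 1).
#' @return percent of input (vectorised).
#' @examples
#' qpcrPercentInput(25, 25)  # 100
#' @export
qpcrPercentInput <- function(ctIp, ctInput, inputDilutionFactor = 1) {
    if (any(inputDilutionFactor < 1)) stop("inputDilutionFactor must be >= 1")
    if (any(!is.finite(ctIp)) || any(!is.finite(ctInput)) ||
        any(ctIp <= 0) || any(ctInput <= 0))
        stop("ct values must be finite and positive")
    100 * 2^((ctInput - log2(inputDilutionFactor)) - ctIp)
}

#' Fold enrichment of one target over a reference
#'
#' Ratio of two percent-input values (e.g. an m6A-marked region over a
#' non-methylated control region).
#'
#' @param percentTarget,percentReference percent-input values (> 0).
#' @return `percentTarget / percentReference`.
#' @export
foldEnrichment <- function(percentTarget, percentReference) {
    if (any(percentReference <= 0)) stop("reference percent input must be > 0")
    percentTarget / percentReference
}
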