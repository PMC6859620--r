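## Exact hypergeometric tests on 2x2 IP/input tables.
##
## Conditioning on all margins of [a, b; c, d], the first cell follows a
## hypergeometric distribution; the one-sided (enrichment) p-value is the
## upper tail P(X >= a), and the two-sided p-value sums the probabilities
## of all tables at most as probable as the observed one (the standard
## Fisher two-sided definition, with the usual 1 + 1e-7 relative tolerance
## guarding against floating-point ties).

#' One-sided exact enrichment test for an IP/input window
#'
#' Tests whether a window's share of a transcript's IP reads exceeds its
#' share of the input reads, conditioning on the 2x2 table
#' `[ip, totalIp - ip; input, totalInput - input]`. Returns the upper-tail
#' hypergeometric p-value and the pseudocounted odds ratio. All arguments
#' are vectorised.
#'
#' @param ip,input window counts in the IP and input fractions.
#' @param totalIp,totalInput transcript-wide totals for the same fractions
#'   (must be >= the window counts and > 0).
#' @param pseudocount added to all four cells of the odds ratio (default 1).
#' @return data.frame with columns `p_value` and `odds_ratio`.
#' @examples
#' windowEnrichmentTest(1, 1, 2, 2)  # p = 5/6
#' @export
windowEnrichmentTest <- function(ip, input, totalIp, totalInput,
                                 pseudocount = 1) {
    if (any(totalIp <= 0) || any(totalInput <= 0))
        stop("undefined test: transcript IP and input totals must be > 0")
    if (any(ip > totalIp) || any(input > totalInput))
        stop("window counts exceed transcript totals")
    if (any(ip < 0) || any(input < 0)) stop("counts must be nonnegative")
    ## X ~ Hypergeometric(m = totalIp, n = totalInput, k = ip + input)
    p <- phyper(ip - 1, totalIp, totalInput, ip + input, lower.tail = FALSE)
    a <- pseudocount
    or <- ((ip + a) / (totalIp - ip + a)) / ((input + a) / (totalInput - input + a))
    data.frame(p_value = p, odds_ratio = or)
}

## two-sided exact p for one table [a, b; c, d]
.twoSidedExactP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    x <- lo:hi
    px <- dhyper(x, m, n, k)
    pa <- dhyper(a, m, n, k)
    min(1, sum(px[px <= pa * (1 + 1e-7)]))
}

## vectorised over tables (used for differential peaks)
.twoSidedExactPVec <- function(a, b, c, d) {
    vapply(seq_along(a), function(i) .twoSidedExactP(a[i], b[i], c[i], d[i]),
           numeric(1))
}
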