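## Gene-set enrichment analysis: weighted Kolmogorov-Smirnov running-sum
## enrichment score, gene-label permutation NES and p-value, and the
## built-in 14-gene hypoxia metagene signature.

#' The 14-gene hypoxia metagene signature
#'
#' The hypoxia metagene expression signature used for tumour-vs-paratumour
#' gene-set enrichment: ALDOA, MIF, TUBB6, P4HA1, SLC2A1, PGAM1, ENO1,
#' LDHA, CDKN3, TPI1, NDRG1, VEGFA, ACOT7 and ADM.
#'
#' @return character vector of the 14 gene symbols.
#' @examples
#' length(hypoxiaSignature())
#' @export
hypoxiaSignature <- function() {
    c("ALDOA", "MIF", "TUBB6", "P4HA1", "SLC2A1", "PGAM1", "ENO1",
      "LDHA", "CDKN3", "TPI1", "NDRG1", "VEGFA", "ACOT7", "ADM")
}

.checkRanked <- function(genes, scores) {
    if (length(genes) != length(scores)) stop("genes and scores differ in length")
    if (anyDuplicated(genes)) stop("ranked gene ids must be unique")
    ord <- order(-scores)          # stable: ties keep input order
    list(genes = genes[ord], scores = scores[ord])
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list (sorted by score, descending; ties keep
#' input order). Gene-set hits increment the running sum by
#' `|score|^p / sum_hits |score|^p`, misses decrement it by
#' `1 / (N - N_hits)`. The enrichment score is the signed maximum
#' deviation of the running sum from zero.
#'
#' @param genes character vector of gene ids.
#' @param scores ranking scores (same length).
#' @param geneSet character vector of gene-set members.
#' @param p hit weight exponent (default 1, the classic weighted ES).
#' @return list with `es`, `running_sum` (over the sorted list),
#'   `hit_indices` (positions of hits in the sorted list) and the sorted
#'   `genes`.
#' @export
enrichmentScore <- function(genes, scores, geneSet, p = 1) {
    r <- .checkRanked(genes, scores)
    hits <- r$genes %in% geneSet
    nHits <- sum(hits)
    if (nHits == 0L) stop("no gene-set member present in the ranked list")
    N <- length(r$genes)
    w <- abs(r$scores)^p
    denom <- sum(w[hits])
    if (denom == 0 && p > 0)
        stop("all hit scores are zero; the weighted ES is undefined")
    incr <- numeric(N)
    incr[hits] <- if (p == 0) 1 / nHits else w[hits] / denom
    if (nHits < N) incr[!hits] <- -1 / (N - nHits)
    rs <- cumsum(incr)
    es <- rs[which.max(abs(rs))]
    list(es = es, running_sum = rs, hit_indices = which(hits), genes = r$genes)
}

## ES from sorted hit positions only (O(n_hits)); extrema of the running
## sum occur immediately after a hit or immediately before one
.esFromPositions <- function(w, N, idx) {
    nh <- length(idx)
    if (nh == N) return(1)
    wi <- w[idx]
    denom <- sum(wi)
    hitCum <- cumsum(wi) / denom
    missStep <- 1 / (N - nh)
    missBefore <- (idx - seq_len(nh)) * missStep
    atHit <- hitCum - missBefore                 # just after each hit
    beforeHit <- c(0, hitCum[-nh]) - missBefore  # just before each hit
    vals <- c(atHit, beforeHit)
    vals[which.max(abs(vals))]
}

#' Permutation NES and p-value for an enrichment score
#'
#' Null enrichment scores come from seeded gene-label permutations:
#' size-matched random gene sets drawn from the ranked list. The NES is
#' the ES divided by the mean magnitude of same-sign null scores (0 when
#' ES is 0); the p-value is `(1 + #same-sign nulls at least as extreme) /
#' (1 + #same-sign nulls)`, so it is never exactly zero.
#'
#' @param genes,scores,geneSet,p as in [enrichmentScore()].
#' @param nPermutations number of permutations (>= 10; default 1000).
#' @param seed integer seed (mandatory).
#' @return An [EnrichmentResult-class] object.
#' @export
nesAndPvalue <- function(genes, scores, geneSet, nPermutations = 1000L,
                         seed, p = 1) {
    if (missing(seed)) stop("'seed' is mandatory for the permutation null")
    if (nPermutations < 10L) stop("nPermutations must be >= 10")
    obs <- enrichmentScore(genes, scores, geneSet, p = p)
    r <- .checkRanked(genes, scores)
    N <- length(r$genes)
    nHits <- length(obs$hit_indices)
    w <- abs(r$scores)^p
    set.seed(as.integer(seed))
    nullEs <- vapply(seq_len(nPermutations), function(b)
        .esFromPositions(w, N, sort(sample.int(N, nHits))), numeric(1))
    es <- obs$es
    if (es == 0) {
        nes <- 0; pv <- 1
    } else {
        sameSign <- nullEs[sign(nullEs) == sign(es)]
        if (length(sameSign) == 0L) {
            warning("no same-sign null enrichment score; p floored at 1/(1+n)")
            nes <- NA_real_
            pv <- 1 / (1 + nPermutations)
        } else {
            nes <- es / abs(mean(sameSign))
            pv <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))
        }
    }
    new("EnrichmentResult", es = es, nes = nes, pValue = pv,
        nPermutations = as.integer(nPermutations), nHits = as.integer(nHits),
        seed = as.integer(seed))
}

#' Rank genes by expression fold change
#'
#' Builds the ranked list for GSEA from an expression table: per-gene
#' log2 fold change of condition B over A (CPM, 0.5 pseudocount), sorted
#' descending.
#'
#' @param se expression SummarizedExperiment (or matrix plus `conditions`).
#' @param conditions optional per-column condition labels.
#' @return data.frame with `gene_id` and `score`, sorted by descending
#'   score.
#' @export
rankGenesByFoldChange <- function(se, conditions = NULL) {
    ec <- expressionChanges(se, conditions = conditions)
    out <- data.frame(gene_id = ec$gene_id, score = ec$log2_fc,
                      stringsAsFactors = FALSE)
    out[order(-out$score), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param geneSets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled; default "na").
#' @return invisibly, the path.
#' @export
writeGmt <- function(geneSets, path, description = "na") {
    stopifnot(length(names(geneSets)) == length(geneSets))
    lines <- vapply(seq_along(geneSets), function(i)
        paste(c(names(geneSets)[i], description, geneSets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}
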