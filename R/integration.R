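## Joint methylation x expression integration: quadrant calls, per-patient
## percentage summaries, the high-frequency gene rule and the two-list
## fold-change candidate screen.

#' Per-gene expression changes between conditions
#'
#' Counts are normalised to counts-per-million per sample; the per-gene
#' change is `log2((meanCPM_B + pc) / (meanCPM_A + pc))` with a 0.5-CPM
#' pseudocount. Direction is `up`/`down` when |log2 fc| exceeds
#' `minAbsLog2fc`, else `none`. With the default threshold of 0 the
#' direction is the pure sign, matching a classification of all altered
#' transcripts; the candidate screen uses threshold 1 (2-fold).
#'
#' @param se expression SummarizedExperiment (assay `counts`, colData
#'   `condition` in A/B), or a plain count matrix if `conditions` is given.
#' @param conditions optional character vector of "A"/"B" per column when
#'   `se` is a matrix.
#' @param minAbsLog2fc minimum |log2 fc| for a directional call (default 0).
#' @param pseudocountCPM CPM pseudocount (default 0.5).
#' @param samples optional subset of sample ids/columns.
#' @return data.frame with `gene_id`, `log2_fc`, `direction`.
#' @export
expressionChanges <- function(se, conditions = NULL, minAbsLog2fc = 0,
                              pseudocountCPM = 0.5, samples = NULL) {
    if (is(se, "SummarizedExperiment")) {
        counts <- SummarizedExperiment::assay(se, "counts")
        conditions <- as.character(SummarizedExperiment::colData(se)$condition)
        genes <- SummarizedExperiment::rowData(se)$gene_id
        if (is.null(genes)) genes <- rownames(counts)
    } else {
        counts <- as.matrix(se)
        if (is.null(conditions) || length(conditions) != ncol(counts))
            stop("'conditions' must label every column when 'se' is a matrix")
        genes <- rownames(counts)
    }
    if (!is.null(samples)) {
        keep <- match(samples, colnames(counts))
        counts <- counts[, keep, drop = FALSE]
        conditions <- conditions[keep]
    }
    libSize <- colSums(counts)
    if (any(libSize <= 0)) stop("library sizes must be > 0")
    cpm <- sweep(counts, 2, libSize, "/") * 1e6
    mA <- rowMeans(cpm[, conditions == "A", drop = FALSE])
    mB <- rowMeans(cpm[, conditions == "B", drop = FALSE])
    lfc <- log2((mB + pseudocountCPM) / (mA + pseudocountCPM))
    dir <- ifelse(lfc > minAbsLog2fc, "up",
           ifelse(lfc < -minAbsLog2fc, "down", "none"))
    data.frame(gene_id = as.character(genes), log2_fc = unname(lfc),
               direction = unname(dir), stringsAsFactors = FALSE)
}

#' Classify genes into methylation/expression quadrants
#'
#' One call per gene that has both a directional differential peak and a
#' directional expression change; genes with `none` on either axis are
#' excluded. A gene with several differential peaks takes the peak with
#' the smallest q-value (ties: largest |log2 methylation fc|, then
#' leftmost start).
#'
#' @param diffPeaks GRanges from [differentialMethylation()].
#' @param exprChanges data.frame from [expressionChanges()].
#' @param transcripts transcript table mapping transcript_id to gene_id.
#' @return data.frame with `gene_id`, `meth_direction`, `expr_direction`,
#'   `quadrant` (e.g. "hyper-up").
#' @export
classifyQuadrants <- function(diffPeaks, exprChanges, transcripts) {
    if (length(diffPeaks) == 0L)
        return(data.frame(gene_id = character(), meth_direction = character(),
                          expr_direction = character(), quadrant = character(),
                          stringsAsFactors = FALSE))
    tid <- as.character(GenomicRanges::seqnames(diffPeaks))
    gene <- transcripts$gene_id[match(tid, transcripts$transcript_id)]
    mc <- S4Vectors::mcols(diffPeaks)
    keep <- mc$direction != "none" & !is.na(gene)
    if (!any(keep))
        return(data.frame(gene_id = character(), meth_direction = character(),
                          expr_direction = character(), quadrant = character(),
                          stringsAsFactors = FALSE))
    df <- data.frame(gene_id = gene[keep],
                     meth_direction = mc$direction[keep],
                     q = mc$q_value[keep],
                     alfc = abs(mc$log2_meth_fc[keep]),
                     start = GenomicRanges::start(diffPeaks)[keep],
                     stringsAsFactors = FALSE)
    ## best peak per gene: smallest q, then largest |lfc|, then leftmost
    df <- df[order(df$gene_id, df$q, -df$alfc, df$start), ]
    df <- df[!duplicated(df$gene_id), ]
    ex <- exprChanges[exprChanges$direction != "none", ]
    m <- merge(df[, c("gene_id", "meth_direction")],
               ex[, c("gene_id", "direction")], by = "gene_id")
    if (nrow(m) == 0L)
        return(data.frame(gene_id = character(), meth_direction = character(),
                          expr_direction = character(), quadrant = character(),
                          stringsAsFactors = FALSE))
    data.frame(gene_id = m$gene_id,
               meth_direction = m$meth_direction,
               expr_direction = m$direction,
               quadrant = paste0(m$meth_direction, "-", m$direction),
               stringsAsFactors = FALSE)
}

.QUADRANT_LEVELS <- c("hyper-up", "hyper-down", "hypo-up", "hypo-down")

#' Per-patient and cohort quadrant percentages
#'
#' Percentages over the four quadrants within each patient (summing to
#' 100), and the cohort mean as the unweighted mean of per-patient
#' percentages. Patients without any call are dropped from the cohort
#' mean with a message.
#'
#' @param calls data.frame with columns `patient` and `quadrant` (e.g.
#'   rbind of per-patient [classifyQuadrants()] outputs).
#' @return list with `per_patient` (data.frame: patient, n_calls, one
#'   percentage column per quadrant) and `cohort_mean` (named numeric).
#' @export
quadrantPercentages <- function(calls) {
    stopifnot(all(c("patient", "quadrant") %in% names(calls)))
    patients <- unique(calls$patient)
    rows <- lapply(patients, function(p) {
        q <- calls$quadrant[calls$patient == p]
        if (length(q) == 0L) return(NULL)
        tab <- table(factor(q, levels = .QUADRANT_LEVELS))
        pct <- 100 * as.numeric(tab) / length(q)
        data.frame(patient = p, n_calls = length(q),
                   t(setNames(pct, .QUADRANT_LEVELS)), check.names = FALSE,
                   stringsAsFactors = FALSE)
    })
    empty <- patients[vapply(rows, is.null, logical(1))]
    if (length(empty))
        message("patients with zero quadrant calls excluded from cohort mean: ",
                paste(empty, collapse = ", "))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) stop("no quadrant calls in any patient")
    perPatient <- do.call(rbind, rows)
    cohort <- colMeans(perPatient[, .QUADRANT_LEVELS, drop = FALSE])
    list(per_patient = perPatient, cohort_mean = cohort)
}

#' High-frequency hyper-up genes shared across patients
#'
#' Genes appearing in at least `minShare` patients' hyper-up sets, sorted
#' by descending share then lexicographically.
#'
#' @param hyperUpSets list of character vectors, one per patient.
#' @param minShare minimum number of patients sharing the gene (default 3).
#' @return data.frame with `gene_id` and `n_patients`.
#' @export
highFrequencyHyperUp <- function(hyperUpSets, minShare = 3L) {
    if (minShare < 1L) stop("minShare must be >= 1")
    if (length(hyperUpSets) < minShare)
        stop("need at least 'minShare' patient sets")
    counts <- table(unlist(lapply(hyperUpSets, unique)))
    keep <- counts[counts >= minShare]
    ord <- order(-as.numeric(keep), names(keep))
    data.frame(gene_id = names(keep)[ord],
               n_patients = as.integer(keep)[ord],
               stringsAsFactors = FALSE)
}

#' Two-list fold-change candidate screen
#'
#' Mirrors a combined screen of two regulatory axes: list A collects genes
#' whose fold change exceeds `fcThreshold` (e.g. upregulated after reader
#' knockdown), list B collects hypermethylation-flagged genes whose fold
#' change exceeds the same threshold (e.g. hyper-up under hypoxia);
#' candidates are their sorted intersection.
#'
#' @param listAChanges data.frame with `gene_id` and `fold_change`.
#' @param listBChanges data.frame with `gene_id`, `fold_change` and a
#'   logical `hyper` column.
#' @param fcThreshold linear fold-change threshold (> 0; default 2, i.e.
#'   "over 2-fold").
#' @return list with `list_a`, `list_b`, `candidates` (sorted character
#'   vectors) and `sizes` (named integer vector).
#' @export
screenCandidates <- function(listAChanges, listBChanges, fcThreshold = 2) {
    if (fcThreshold <= 0) stop("fcThreshold must be > 0")
    stopifnot(all(c("gene_id", "fold_change") %in% names(listAChanges)),
              all(c("gene_id", "fold_change", "hyper") %in% names(listBChanges)))
    listA <- sort(unique(listAChanges$gene_id[listAChanges$fold_change > fcThreshold]))
    listB <- sort(unique(listBChanges$gene_id[
        listBChanges$hyper & listBChanges$fold_change > fcThreshold]))
    cand <- intersect(listA, listB)
    list(list_a = listA, list_b = listB, candidates = cand,
         sizes = c(list_a = length(listA), list_b = length(listB),
                   candidates = length(cand)))
}

#' Per-patient quadrant analysis of a paired cohort
#'
#' Convenience wrapper running the full integration for each patient:
#' differential methylation of the supplied (cohort-level) peaks on the
#' patient's sample pair, expression changes on the same pair, and
#' quadrant classification; results are stacked with a `patient` column.
#'
#' @param peaks cohort-level peaks from [callPeaks()].
#' @param windows windows SummarizedExperiment.
#' @param expr expression SummarizedExperiment.
#' @param transcripts transcript table.
#' @param fdr,alpha differential methylation thresholds.
#' @param minAbsLog2fc expression direction threshold (default 0, pure sign).
#' @return data.frame of quadrant calls with a `patient` column.
#' @export
quadrantsByPatient <- function(peaks, windows, expr, transcripts,
                               fdr = 0.05, alpha = 0.05, minAbsLog2fc = 0) {
    cd <- SummarizedExperiment::colData(windows)
    out <- lapply(unique(cd$patient), function(p) {
        samp <- rownames(cd)[cd$patient == p]
        dp <- differentialMethylation(peaks, windows, fdr = fdr, alpha = alpha,
                                      samples = samp)
        ec <- expressionChanges(expr, minAbsLog2fc = minAbsLog2fc, samples = samp)
        calls <- classifyQuadrants(dp, ec, transcripts)
        if (nrow(calls)) calls$patient <- p
        calls
    })
    out <- out[vapply(out, nrow, integer(1)) > 0L]
    if (length(out) == 0L)
        return(data.frame(gene_id = character(), meth_direction = character(),
                          expr_direction = character(), quadrant = character(),
                          patient = character(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}
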