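## Plain-text readers and writers. All TSV/BED coordinates on disk are
## 0-based half-open; in-memory GRanges follow the 1-based Bioconductor
## convention. Floats are serialised at 6 significant digits and files are
## written atomically (temp file + rename) so interrupted runs never leave
## half-written outputs.

.atomicWrite <- function(writer, path) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop("cannot write output file: ", path)
    invisible(path)
}

.writeTsv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    .atomicWrite(function(tmp)
        utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE), path)
}

#' Write and read the transcript model table
#'
#' TSV columns: transcript_id, gene_id, utr5_len, cds_len, utr3_len,
#' total_len.
#'
#' @param transcripts transcript data.frame.
#' @param path file path.
#' @return `writeTranscriptsTsv` the path, invisibly; `readTranscriptsTsv`
#'   the data.frame.
#' @export
writeTranscriptsTsv <- function(transcripts, path) .writeTsv(transcripts, path)

#' @rdname writeTranscriptsTsv
#' @export
readTranscriptsTsv <- function(path)
    utils::read.delim(path, stringsAsFactors = FALSE)

#' Write and read the ground-truth table
#'
#' @param truth truth data.frame from [generateTruth()].
#' @param path file path.
#' @export
writeTruthTsv <- function(truth, path) .writeTsv(truth, path)

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path)
    utils::read.delim(path, stringsAsFactors = FALSE)

#' Write and read IP/input window counts
#'
#' Long-format TSV: transcript_id, window_start, window_end (0-based,
#' half-open), sample, condition, patient, ip_count, input_count.
#'
#' @param se windows SummarizedExperiment.
#' @param path file path.
#' @return `readWindowsTsv` reconstructs the SummarizedExperiment.
#' @export
writeWindowsTsv <- function(se, path) {
    rr <- SummarizedExperiment::rowRanges(se)
    cd <- SummarizedExperiment::colData(se)
    ip <- SummarizedExperiment::assay(se, "ip")
    input <- SummarizedExperiment::assay(se, "input")
    nW <- length(rr); nS <- nrow(cd)
    df <- data.frame(
        transcript_id = rep(as.character(GenomicRanges::seqnames(rr)), nS),
        window_start = rep(GenomicRanges::start(rr) - 1L, nS),
        window_end = rep(GenomicRanges::end(rr), nS),
        sample = rep(cd$sample_id, each = nW),
        condition = rep(cd$condition, each = nW),
        patient = rep(cd$patient, each = nW),
        ip_count = as.vector(ip),
        input_count = as.vector(input),
        stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' @rdname writeWindowsTsv
#' @export
readWindowsTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    samples <- unique(df$sample)
    first <- df[df$sample == samples[1], ]
    key <- paste(df$transcript_id, df$window_start, df$window_end)
    firstKey <- paste(first$transcript_id, first$window_start, first$window_end)
    row <- match(key, firstKey)
    col <- match(df$sample, samples)
    nW <- nrow(first); nS <- length(samples)
    ip <- matrix(0L, nW, nS, dimnames = list(NULL, samples))
    input <- matrix(0L, nW, nS, dimnames = list(NULL, samples))
    ip[cbind(row, col)] <- df$ip_count
    input[cbind(row, col)] <- df$input_count
    cd <- unique(df[, c("sample", "condition", "patient")])
    cd <- cd[match(samples, cd$sample), ]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ip = ip, input = input),
        rowRanges = GenomicRanges::GRanges(
            seqnames = first$transcript_id,
            ranges = IRanges::IRanges(start = first$window_start + 1L,
                                      end = first$window_end)),
        colData = S4Vectors::DataFrame(sample_id = cd$sample,
                                       patient = cd$patient,
                                       condition = cd$condition,
                                       row.names = cd$sample))
    SummarizedExperiment::rowData(se)$transcript_id <- first$transcript_id
    se
}

#' Write and read the gene expression matrix
#'
#' Wide-format TSV: gene_id column followed by one column per sample.
#'
#' @param se expression SummarizedExperiment.
#' @param path file path.
#' @export
writeExpressionTsv <- function(se, path) {
    counts <- SummarizedExperiment::assay(se, "counts")
    df <- data.frame(gene_id = SummarizedExperiment::rowData(se)$gene_id,
                     counts, check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    samples <- colnames(counts)
    ## sample naming convention Pxx_A / Pxx_B carries the design
    cond <- sub(".*_", "", samples)
    patient <- sub("_[AB]$", "", samples)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = df$gene_id),
        colData = S4Vectors::DataFrame(sample_id = samples, patient = patient,
                                       condition = cond, row.names = samples))
}

.peaksToDf <- function(peaks) {
    data.frame(transcript_id = as.character(GenomicRanges::seqnames(peaks)),
               start = GenomicRanges::start(peaks) - 1L,
               end = GenomicRanges::end(peaks),
               as.data.frame(S4Vectors::mcols(peaks)),
               stringsAsFactors = FALSE)
}

.dfToPeaks <- function(df) {
    gr <- GenomicRanges::GRanges(
        seqnames = df$transcript_id,
        ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
    S4Vectors::mcols(gr) <- df[, setdiff(names(df), c("transcript_id", "start", "end")),
                               drop = FALSE]
    gr
}

#' Write and read peak tables
#'
#' TSV with 0-based half-open coordinates and all peak metadata columns;
#' `writePeaksBed` additionally exports BED6 (name = transcript:start-end,
#' score = -10*log10(p) capped at 1000, strand "+").
#'
#' @param peaks GRanges of peaks (plain or differential).
#' @param path file path.
#' @export
writePeaksTsv <- function(peaks, path) .writeTsv(.peaksToDf(peaks), path)

#' @rdname writePeaksTsv
#' @export
readPeaksTsv <- function(path)
    .dfToPeaks(utils::read.delim(path, stringsAsFactors = FALSE))

#' @rdname writePeaksTsv
#' @export
writePeaksBed <- function(peaks, path) {
    gr <- GenomicRanges::granges(peaks)
    p <- S4Vectors::mcols(peaks)$p_value
    if (is.null(p)) p <- rep(1, length(peaks))
    GenomicRanges::strand(gr) <- "+"
    gr$name <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(peaks)),
                       GenomicRanges::start(peaks) - 1L,
                       GenomicRanges::end(peaks))
    gr$score <- pmin(1000, round(-10 * log10(pmax(p, 1e-100))))
    .atomicWrite(function(tmp) rtracklayer::export(gr, tmp, format = "BED"), path)
}

#' Write a JSON file with sorted keys and fixed precision
#'
#' Keys are sorted recursively and doubles rounded to 6 significant
#' digits, so identical results serialise byte-identically.
#'
#' @param x a (possibly nested) list.
#' @param path output path.
#' @export
writeJsonSorted <- function(x, path) {
    sortRec <- function(v) {
        if (is.list(v)) {
            if (!is.null(names(v)) && length(v)) v <- v[order(names(v))]
            lapply(v, sortRec)
        } else if (is.double(v)) signif(v, 6) else v
    }
    .atomicWrite(function(tmp)
        jsonlite::write_json(sortRec(x), tmp, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE), path)
}
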