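## End-to-end orchestration: simulate -> peaks -> differential -> quadrants
## -> screen -> gsea -> decay -> msquant, from one config with one global
## seed. Each stage derives its own sub-seed (global seed + fixed offset)
## so stages are reproducible when rerun in isolation, reads only its
## declared inputs from the output directory, and appears once in the run
## manifest.

.STAGES <- c("simulate", "peaks", "differential", "quadrants", "screen",
             "gsea", "decay", "msquant")

## declared file dependencies per stage (inputs must exist or be produced
## by an enabled upstream stage)
.STAGE_INPUTS <- list(
    simulate = character(),
    peaks = "windows.tsv",
    differential = c("windows.tsv", "peaks.tsv"),
    quadrants = c("windows.tsv", "peaks.tsv", "expression.tsv", "transcripts.tsv"),
    screen = c("expression.tsv", "peaks.tsv", "windows.tsv", "transcripts.tsv"),
    gsea = c("expression.tsv", "truth.tsv"),
    decay = character(),
    msquant = character())

.STAGE_OUTPUTS <- list(
    simulate = c("transcripts.tsv", "truth.tsv", "windows.tsv", "expression.tsv"),
    peaks = c("peaks.tsv", "peaks.bed"),
    differential = "differential_peaks.tsv",
    quadrants = c("quadrants.tsv", "quadrant_summary.json"),
    screen = "screen.json",
    gsea = "enrichment.json",
    decay = "decay_fits.tsv",
    msquant = "ms_quant.json")

#' Default pipeline configuration
#'
#' A nested list holding every stage's parameters plus the global seed.
#' Amend individual entries before passing it to [runPipeline()].
#'
#' @param seed global integer seed (mandatory).
#' @param stages character vector of stages to run (default: all, in
#'   dependency order).
#' @param sim a [SimConfig-class]; defaults to `simConfig(seed = seed)`.
#' @return named list of pipeline parameters.
#' @export
pipelineConfig <- function(seed, stages = .STAGES, sim = NULL) {
    if (missing(seed)) stop("a global seed is mandatory")
    stages <- match.arg(stages, .STAGES, several.ok = TRUE)
    list(
        seed = as.integer(seed),
        stages = stages,
        sim = if (is.null(sim)) simConfig(seed = seed) else sim,
        peaks = list(alpha = 0.05, minRun = 2L, maxGap = 1L, pseudocount = 1),
        differential = list(fdr = 0.05, alpha = 0.05, pseudocount = 1),
        quadrants = list(minAbsLog2fc = 0),
        screen = list(fcThreshold = 2, minAbsLog2fc = 0),
        gsea = list(nPermutations = 1000L),
        decay = list(k = c(0.2, 0.5), timepoints = c(0, 1, 2, 4, 6, 8), cv = 0.05),
        msquant = list(trueRatio = 0.005, standards = c(0.5, 1, 2, 5, 10),
                       noise = 0))
}

.paramHash <- function(params) {
    txt <- paste(deparse(params), collapse = "")
    tmp <- tempfile()
    writeLines(txt, tmp)
    on.exit(unlink(tmp))
    unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order inside `outdir`,
#' validating before any stage runs that every declared input either
#' already exists or is produced by an enabled upstream stage. A failing
#' stage is recorded in the manifest and all downstream stages are
#' skipped. Existing outputs are only overwritten when `force = TRUE`.
#'
#' @param config list from [pipelineConfig()].
#' @param outdir output directory (created if absent).
#' @param force overwrite existing outputs (default FALSE).
#' @return the run manifest (also written to `manifest.json`), invisibly.
#' @export
runPipeline <- function(config, outdir, force = FALSE) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stages <- .STAGES[.STAGES %in% config$stages]
    path <- function(f) file.path(outdir, f)

    ## validate all dependencies up front
    produced <- character()
    for (st in .STAGES) {
        if (!st %in% stages) next
        missingIn <- setdiff(.STAGE_INPUTS[[st]], produced)
        missingIn <- missingIn[!file.exists(path(missingIn))]
        if (length(missingIn))
            stop("stage '", st, "' is enabled but its input(s) are neither ",
                 "present nor produced by an enabled stage: ",
                 paste(missingIn, collapse = ", "))
        produced <- union(produced, .STAGE_OUTPUTS[[st]])
    }
    if (!force) {
        clash <- unlist(.STAGE_OUTPUTS[stages])
        clash <- clash[file.exists(path(clash))]
        if (length(clash))
            stop("outputs already exist (use force = TRUE to overwrite): ",
                 paste(clash, collapse = ", "))
    }

    manifest <- list(version = as.character(utils::packageVersion("m6Aquadrant")),
                     seed = config$seed, stages = list())
    failed <- FALSE
    for (st in stages) {
        if (failed) {
            manifest$stages[[st]] <- list(status = "skipped")
            next
        }
        res <- tryCatch({
            .runStage(st, config, path)
            "ok"
        }, error = function(e) paste("failed:", conditionMessage(e)))
        manifest$stages[[st]] <- list(
            status = res,
            params_hash = .paramHash(config[[if (st == "simulate") "sim" else st]]),
            inputs = as.list(.STAGE_INPUTS[[st]]),
            outputs = as.list(.STAGE_OUTPUTS[[st]]))
        if (res != "ok") {
            warning("stage '", st, "' ", res, "; downstream stages skipped")
            failed <- TRUE
        }
    }
    writeJsonSorted(manifest, path("manifest.json"))
    invisible(manifest)
}

.runStage <- function(st, config, path) {
    switch(st,
    simulate = {
        gt <- generateTruth(config$sim)
        writeTranscriptsTsv(gt$transcripts, path("transcripts.tsv"))
        writeTruthTsv(gt$truth, path("truth.tsv"))
        writeWindowsTsv(simulateMeripWindows(gt$truth, gt$transcripts, config$sim),
                        path("windows.tsv"))
        writeExpressionTsv(simulateExpression(gt$truth, config$sim),
                           path("expression.tsv"))
    },
    peaks = {
        se <- readWindowsTsv(path("windows.tsv"))
        pk <- do.call(callPeaks, c(list(se), config$peaks))
        writePeaksTsv(pk, path("peaks.tsv"))
        writePeaksBed(pk, path("peaks.bed"))
    },
    differential = {
        se <- readWindowsTsv(path("windows.tsv"))
        pk <- readPeaksTsv(path("peaks.tsv"))
        dp <- do.call(differentialMethylation, c(list(pk, se), config$differential))
        writePeaksTsv(dp, path("differential_peaks.tsv"))
    },
    quadrants = {
        se <- readWindowsTsv(path("windows.tsv"))
        pk <- readPeaksTsv(path("peaks.tsv"))
        expr <- readExpressionTsv(path("expression.tsv"))
        tr <- readTranscriptsTsv(path("transcripts.tsv"))
        calls <- quadrantsByPatient(pk, se, expr, tr,
                                    minAbsLog2fc = config$quadrants$minAbsLog2fc)
        .writeTsv(calls, path("quadrants.tsv"))
        summ <- quadrantPercentages(calls)
        writeJsonSorted(list(
            per_patient = summ$per_patient,
            cohort_mean = as.list(summ$cohort_mean)),
            path("quadrant_summary.json"))
    },
    screen = {
        expr <- readExpressionTsv(path("expression.tsv"))
        se <- readWindowsTsv(path("windows.tsv"))
        pk <- readPeaksTsv(path("peaks.tsv"))
        tr <- readTranscriptsTsv(path("transcripts.tsv"))
        ec <- expressionChanges(expr)
        dp <- differentialMethylation(pk, se)
        tid <- as.character(GenomicRanges::seqnames(dp))
        hyperGenes <- unique(tr$gene_id[match(
            tid[S4Vectors::mcols(dp)$direction == "hyper"], tr$transcript_id)])
        listA <- data.frame(gene_id = ec$gene_id, fold_change = 2^ec$log2_fc)
        listB <- cbind(listA, hyper = listA$gene_id %in% hyperGenes)
        sc <- screenCandidates(listA, listB, config$screen$fcThreshold)
        writeJsonSorted(list(list_a = sc$list_a, list_b = sc$list_b,
                             candidates = sc$candidates,
                             sizes = as.list(sc$sizes)),
                        path("screen.json"))
    },
    gsea = {
        expr <- readExpressionTsv(path("expression.tsv"))
        truth <- readTruthTsv(path("truth.tsv"))
        ranked <- rankGenesByFoldChange(expr)
        upGenes <- truth$gene_id[truth$expr_direction == "up"]
        if (length(upGenes) == 0L)
            stop("no planted upregulated genes to use as a gene set")
        res <- nesAndPvalue(ranked$gene_id, ranked$score, upGenes,
                            nPermutations = config$gsea$nPermutations,
                            seed = .stageSeed(config$seed, 20))
        writeJsonSorted(list(gene_set = "planted_up_genes",
                             es = res@es, nes = res@nes, p_value = res@pValue,
                             n_permutations = res@nPermutations,
                             n_hits = res@nHits, seed = res@seed),
                        path("enrichment.json"))
    },
    decay = {
        fits <- lapply(seq_along(config$decay$k), function(i) {
            s <- simulateDecaySeries(config$decay$k[i], config$decay$timepoints,
                                     cv = config$decay$cv,
                                     seed = .stageSeed(config$seed, 30 + i))
            f <- fitDecay(s)
            data.frame(series_id = paste0("series", i),
                       true_k = config$decay$k[i], k = f@k, t_half = f@tHalf,
                       r_squared = f@rSquared, n_points = f@nPoints)
        })
        .writeTsv(do.call(rbind, fits), path("decay_fits.tsv"))
    },
    msquant = {
        run <- simulateCalibrationRun(config$msquant$trueRatio,
                                      config$msquant$standards,
                                      noise = config$msquant$noise,
                                      seed = .stageSeed(config$seed, 40))
        curves <- lapply(setNames(c("m6A", "A"), c("m6A", "A")), function(ch) {
            d <- run$standards[run$standards$channel == ch, ]
            fitCalibration(d$concentration, d$response, ch)
        })
        responses <- setNames(run$sample$response, run$sample$channel)
        ratio <- quantifyM6aToARatio(responses, curves)
        writeJsonSorted(list(
            m6a_to_a_ratio = ratio,
            curves = lapply(curves, function(cv) list(
                channel = cv@channel, transition = cv@transition,
                slope = cv@slope, intercept = cv@intercept,
                r_squared = cv@rSquared))),
            path("ms_quant.json"))
    },
    stop("unknown stage: ", st))
    invisible(NULL)
}
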