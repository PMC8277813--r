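#' Compare mutant against wild-type samples
#'
#' Rank-sum test and fold change (mutant over wild type) of a per-sample
#' quantity -- the inclusion score or the isoform ratio -- restricted to
#' samples passing the exclusion-read filter with a defined value.
#'
#' @param scored per-sample results from [scoreEvent()].
#' @param annotation sample annotation (`DataFrame`/`data.frame` with
#'   columns `sample`, `kras_status`).
#' @param which quantity to compare: `"psi"` or `"ratio"`.
#' @return The [rankSumTest()] list, with mutants as group A, plus
#'   element `which`.
#' @export
compareMutantWt <- function(scored, annotation, which = c("psi", "ratio")) {
    which <- match.arg(which)
    ann <- as.data.frame(annotation)
    if (!all(c("sample", "kras_status") %in% colnames(ann)))
        stop("annotation must have columns sample and kras_status",
             call. = FALSE)
    df <- as.data.frame(scored)
    df <- df[df$pass_filter & is.finite(df[[which]]), ]
    status <- ann$kras_status[match(df$sample, ann$sample)]
    mut <- df[[which]][status %in% "mutant"]
    wt <- df[[which]][status %in% "wildtype"]
    if (length(mut) < 2L || length(wt) < 2L)
        stop("need >= 2 mutant and >= 2 wildtype samples passing filters ",
             "(got ", length(mut), " mutant, ", length(wt), " wildtype)",
             call. = FALSE)
    out <- rankSumTest(mut, wt)
    out$which <- which
    out
}

#' Run the full ALE cohort analysis
#'
#' Fixed stage order: score the event and apply the exclusion-read filter;
#' stratify filter-passing samples into high/low ratio extremes; rank genes
#' between the groups (signal-to-noise, low vs high); gene-set enrichment
#' with a permutation null; hypergeometric over-representation of the top-k
#' genes; mutant-vs-wild-type comparison of the inclusion score.  Writes
#' `inclusion.tsv`, `groups.tsv`, `ranked.rnk`, `enrichment.tsv`,
#' `ora.tsv`, `compare.tsv` and `manifest.txt` into `outDir`; all tables
#' are sorted on documented keys so re-running with identical inputs
#' reproduces them byte-identically.
#'
#' @param junctions a [JunctionCounts-class] or path to a junction-matrix
#'   TSV ([readJunctionMatrix()]).
#' @param event an [AleEvent-class] or path to an event-definition TSV
#'   ([readAleEvents()]; the first event is used).
#' @param annotation sample annotation object or TSV path; optional
#'   (`NULL` skips the mutant/WT comparison).
#' @param expression expression `SummarizedExperiment`/matrix or TSV path.
#' @param geneSets a [GeneSetCollection-class] or GMT path.
#' @param outDir output directory, created if needed.
#' @param minExc exclusion-read filter threshold (default 20).
#' @param nHigh,nLow high/low group sizes.
#' @param kTop number of top genes for over-representation (default 100).
#' @param weightP GSEA weighting exponent (default 1).
#' @param nPerm permutations per gene set (default 1000).
#' @param scheme permutation scheme (see [permutationNull()]).
#' @param minSize minimum gene-set overlap (default 5).
#' @param seed root seed for the permutation streams.
#' @param quiet suppress progress messages (logged to stderr).
#' @return Invisibly, a list of the in-memory stage results (`scored`,
#'   `groups`, `ranked`, `enrichment`, `ora`, `compare`, `manifest`).
#' @export
runPipeline <- function(junctions, event, annotation = NULL, expression,
                        geneSets, outDir, minExc = 20, nHigh, nLow,
                        kTop = 100, weightP = 1, nPerm = 1000,
                        scheme = c("gene_set", "phenotype"), minSize = 5,
                        seed = 1, quiet = FALSE) {
    scheme <- match.arg(scheme)
    log <- function(...) if (!quiet) message("INFO [aleSplice] ", ...)
    inputPaths <- c(
        junctions = if (is.character(junctions)) junctions else NA,
        event = if (is.character(event)) event else NA,
        annotation = if (is.character(annotation)) annotation else NA,
        expression = if (is.character(expression)) expression else NA,
        geneSets = if (is.character(geneSets)) geneSets else NA)
    if (is.character(junctions)) junctions <- readJunctionMatrix(junctions)
    if (is.character(event)) event <- readAleEvents(event)[[1L]]
    if (is.character(annotation)) annotation <- readSampleAnnotation(annotation)
    if (is.character(expression)) expression <- readExpressionMatrix(expression)
    if (is.character(geneSets)) geneSets <- readGmt(geneSets)
    exprMat <- if (is(expression, "SummarizedExperiment"))
        assay(expression, "exprs") else as.matrix(expression)
    jxSamples <- colnames(junctions)
    exSamples <- colnames(exprMat)
    sdiff <- c(setdiff(jxSamples, exSamples), setdiff(exSamples, jxSamples))
    if (length(sdiff))
        stop("sample ids differ between junction and expression inputs: ",
             paste(utils::head(sdiff, 10), collapse = ", "), call. = FALSE)

    scored <- scoreEvent(event, junctions, minExc = minExc)
    nPass <- sum(scored$pass_filter)
    log(nrow(scored), " samples scored; ", nrow(scored) - nPass,
        " excluded by the exc < ", minExc, " filter")

    ratios <- scored$ratio
    ratios[!scored$pass_filter] <- NA_real_
    names(ratios) <- scored$sample
    groups <- stratifyByRatio(ratios, nHigh, nLow)
    log("stratified: ", nHigh, " high / ", nLow, " low / ",
        sum(groups$group == "excluded"), " excluded")

    ranked <- rankGenes(exprMat, groups)
    enrichment <- runEnrichment(ranked, geneSets, minSize = minSize,
                                weightP = weightP, nPerm = nPerm,
                                scheme = scheme, seed = seed,
                                expr = exprMat, groups = groups)
    log(nrow(enrichment), " gene sets tested by permutation GSEA")
    top <- topK(ranked, kTop)
    ora <- runOra(top, geneSets, universe = ranked$gene,
                  minSize = minSize)

    compare <- NULL
    if (!is.null(annotation)) {
        compare <- compareMutantWt(scored, annotation, which = "psi")
        log(sprintf("mutant vs WT inclusion: fold change %.3f, p = %.3g",
                    compare$fold_change, compare$p_two_sided))
    }

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeInclusionResults(scored, file.path(outDir, "inclusion.tsv"))
    writeGroups(groups, file.path(outDir, "groups.tsv"))
    writeRnk(ranked, file.path(outDir, "ranked.rnk"))
    writeEnrichment(enrichment, file.path(outDir, "enrichment.tsv"))
    utils::write.table(ora, file.path(outDir, "ora.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    if (!is.null(compare)) {
        cdf <- data.frame(which = compare$which,
                          statistic = compare$statistic,
                          p_two_sided = compare$p_two_sided,
                          fold_change = compare$fold_change,
                          n_mutant = compare$n_a, n_wildtype = compare$n_b)
        utils::write.table(cdf, file.path(outDir, "compare.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           na = "NA")
    }

    manifest <- c(
        sprintf("tool_version: aleSplice %s",
                as.character(utils::packageVersion("aleSplice"))),
        sprintf("run_time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        sprintf("param %s: %s",
                c("min_exc", "n_high", "n_low", "k_top", "weight_p",
                  "n_perm", "scheme", "min_size", "seed"),
                c(minExc, nHigh, nLow, kTop, weightP, nPerm, scheme,
                  minSize, seed)),
        vapply(names(inputPaths), function(nm) {
            p <- inputPaths[[nm]]
            if (is.na(p)) sprintf("input %s: <in-memory>", nm)
            else sprintf("input %s: %s md5=%s", nm, p,
                         unname(tools::md5sum(p)))
        }, character(1)),
        sprintf("count samples_scored: %d", nrow(scored)),
        sprintf("count samples_filtered_out: %d", nrow(scored) - nPass),
        sprintf("count genes_ranked: %d", nrow(ranked)),
        sprintf("count sets_tested: %d", nrow(enrichment)))
    writeLines(manifest, file.path(outDir, "manifest.txt"))
    log("outputs written to ", outDir)
    invisible(list(scored = scored, groups = groups, ranked = ranked,
                   enrichment = enrichment, ora = ora, compare = compare,
                   manifest = manifest))
}

#' Write a simulated cohort to disk in the pipeline's input dialects
#'
#' Emits `junctions.tsv`, `annotation.tsv`, `expression.tsv`,
#' `events.tsv`, `truth.tsv` and `config.tsv` into `dir`, all readable by
#' the package's own readers, so a simulated run exercises the same file
#' interfaces as a real one.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory, created if needed.
#' @return Invisibly, the list returned by [simulateJunctions()] with the
#'   expression matrix added as `expression`.
#' @export
writeSimulation <- function(config, dir) {
    sim <- simulateJunctions(config)
    expr <- simulateExpression(config, sim$truth)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeJunctionMatrix(sim$counts, file.path(dir, "junctions.tsv"))
    writeSampleAnnotation(sim$annotation, file.path(dir, "annotation.tsv"))
    writeExpressionMatrix(expr, file.path(dir, "expression.tsv"))
    jx <- eventJunctions(sim$event)
    utils::write.table(
        data.frame(event_id = eventId(sim$event),
                   gene = eventGene(sim$event),
                   inc1 = junctionKey(jx["inc1"]),
                   inc2 = junctionKey(jx["inc2"]),
                   exc = junctionKey(jx["exc"])),
        file.path(dir, "events.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- data.frame(
        key = c("nSamples", "fracMutant", "meanCoverage", "dispersion",
                "psiWt", "psiEffect", "nGenes", "plantedSet",
                "plantedEffect", "noiseSd", "seed"),
        value = c(config@nSamples, config@fracMutant, config@meanCoverage,
                  config@dispersion, config@psiWt, config@psiEffect,
                  config@nGenes, paste(config@plantedSet, collapse = ","),
                  config@plantedEffect, config@noiseSd, config@seed))
    utils::write.table(cfg, file.path(dir, "config.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sim$expression <- expr
    invisible(sim)
}
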