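#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges strand start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData
NULL

#' Container for junction-by-sample counts
#'
#' `JunctionCounts` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are splice junctions (`rowRanges()` holds the intron interval: start =
#' first intronic base, end = last intronic base, both 1-based inclusive;
#' strand `*` means unknown) and columns are samples.  The single assay,
#' `"counts"`, holds non-negative junction quantifications -- raw
#' junction-spanning read counts or normalized values such as RSEM junction
#' quantifications; formulas downstream are evaluated on reals either way.
#' Row names are canonical junction-key strings
#' (`"chrom:donor-acceptor[:strand]"`).
#'
#' @seealso [JunctionCounts()], [readJunctionMatrix()], [readStarJunctions()]
#' @export
setClass("JunctionCounts",
    contains = "RangedSummarizedExperiment")

setValidity("JunctionCounts", function(object) {
    msg <- character()
    if (!("counts" %in% names(assays(object))))
        msg <- c(msg, "assay 'counts' is required")
    else {
        x <- assay(object, "counts")
        if (any(!is.finite(x)))
            msg <- c(msg, "counts must be finite (no NA/NaN/Inf)")
        else if (any(x < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    if (nrow(object) > 0 &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "junction keys (rownames) must be present and unique")
    if (ncol(object) > 0 &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' An alternative-last-exon splicing event
#'
#' Three junctions define one ALE inclusion/exclusion event, the pattern that
#' distinguishes KRAS4A from KRAS4B: `inc1` joins the upstream exon to the ALE
#' exon (exon 3 to exon 4A for KRAS), `inc2` joins the ALE exon to the
#' downstream exon (4A to 4B), and `exc` skips the ALE exon entirely (3 to 4B).
#' Each slot is a length-1 [GenomicRanges::GRanges] spanning the intron.
#'
#' @slot eventId event identifier.
#' @slot gene gene symbol (upper-cased on construction).
#' @slot inc1,inc2,exc length-1 `GRanges`, the three junction introns.
#' @seealso [AleEvent()], [scoreEvent()]
#' @export
setClass("AleEvent",
    representation(eventId = "character", gene = "character",
                   inc1 = "GRanges", inc2 = "GRanges", exc = "GRanges"))

setValidity("AleEvent", function(object) {
    msg <- character()
    if (length(object@eventId) != 1L || !nzchar(object@eventId))
        msg <- c(msg, "eventId must be a single non-empty string")
    if (length(object@gene) != 1L || !nzchar(object@gene))
        msg <- c(msg, "gene must be a single non-empty string")
    for (nm in c("inc1", "inc2", "exc"))
        if (length(slot(object, nm)) != 1L)
            msg <- c(msg, sprintf("%s must be a single junction", nm))
    if (!length(msg)) {
        keys <- vapply(list(object@inc1, object@inc2, object@exc),
                       junctionKey, character(1))
        if (anyDuplicated(keys))
            msg <- c(msg, "inc1, inc2 and exc must be pairwise distinct")
        chroms <- c(as.character(seqnames(object@inc1)),
                    as.character(seqnames(object@inc2)),
                    as.character(seqnames(object@exc)))
        if (length(unique(chroms)) != 1L)
            msg <- c(msg, "all three junctions must share one chromosome")
        if (start(object@inc1) > start(object@inc2))
            msg <- c(msg, "inc1 donor must not lie downstream of inc2 donor")
        if (start(object@exc) > start(object@inc1) ||
            end(object@exc) < end(object@inc2))
            msg <- c(msg, "exc must span the interval covered by inc1 and inc2")
    }
    if (length(msg)) msg else TRUE
})

#' A collection of named gene sets
#'
#' Thin container for GMT-style gene-set collections: a named list of
#' upper-cased gene symbol vectors plus one description per set.
#'
#' @slot sets named list of character vectors (gene symbols, upper case).
#' @slot descriptions named character vector, parallel to `sets`.
#' @seealso [GeneSetCollection()], [readGmt()]
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nms <- names(object@sets)
    if (is.null(nms) || any(!nzchar(nms)))
        msg <- c(msg, "every set must be named")
    else if (anyDuplicated(nms))
        msg <- c(msg, "set names must be unique")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "empty gene sets are not allowed")
    if (!identical(names(object@descriptions), nms))
        msg <- c(msg, "descriptions must be named parallel to sets")
    bad <- vapply(object@sets, function(g)
        !is.character(g) || any(g != toupper(g)), logical(1))
    if (any(bad))
        msg <- c(msg, "gene symbols must be upper-cased character vectors")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic ALE cohort generator
#'
#' Holds every parameter of the generative model mirrored on the inclusion
#' score: per-sample total event coverage is negative binomial
#' (`meanCoverage`, `dispersion`), true inclusion fraction is
#' `plogis(qlogis(psiWt) + psiEffect)` for mutant samples and `psiWt` for
#' wild type, inclusion reads are binomial thinning of the total and split
#' 50/50 between the two inclusion junctions.  Expression is simulated on log
#' scale with a planted gene set shifted upward in low-inclusion samples.
#'
#' @seealso [simulationConfig()], [simulateJunctions()], [simulateExpression()]
#' @export
setClass("SimulationConfig",
    representation(nSamples = "integer", fracMutant = "numeric",
                   meanCoverage = "numeric", dispersion = "numeric",
                   psiWt = "numeric", psiEffect = "numeric",
                   nGenes = "integer", plantedSet = "character",
                   plantedEffect = "numeric", noiseSd = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    chk1 <- function(x, nm, lo = -Inf, hi = Inf, open = FALSE) {
        if (length(x) != 1L || !is.finite(x))
            return(sprintf("%s must be a single finite value", nm))
        if (open && (x <= lo || x >= hi))
            return(sprintf("%s must lie strictly in (%g, %g)", nm, lo, hi))
        if (!open && (x < lo || x > hi))
            return(sprintf("%s must lie in [%g, %g]", nm, lo, hi))
        NULL
    }
    msg <- c(msg,
        chk1(object@nSamples, "nSamples", lo = 2),
        chk1(object@fracMutant, "fracMutant", 0, 1),
        chk1(object@meanCoverage, "meanCoverage", 0, Inf, open = TRUE),
        chk1(object@dispersion, "dispersion", 0, Inf, open = TRUE),
        chk1(object@psiWt, "psiWt", 0, 1, open = TRUE),
        chk1(object@psiEffect, "psiEffect"),
        chk1(object@nGenes, "nGenes", lo = 1),
        chk1(object@plantedEffect, "plantedEffect"),
        chk1(object@noiseSd, "noiseSd", 0, Inf, open = TRUE),
        chk1(object@seed, "seed"))
    if (!length(object@plantedSet))
        msg <- c(msg, "plantedSet must name at least one gene")
    if (length(msg)) msg else TRUE
})
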