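#' Construct a JunctionCounts object
#'
#' @param counts numeric matrix, junctions x samples; rownames are junction
#'   keys (see [parseJunctionKey()]) and colnames are sample ids.
#' @param junctions optional `GRanges` of the junctions; parsed from the
#'   rownames of `counts` when omitted.
#' @return A [JunctionCounts-class] object.
#' @examples
#' m <- matrix(c(10, 5, 0, 30), 2, 2,
#'             dimnames = list(c("chr1:100-200", "chr1:100-500"),
#'                             c("s1", "s2")))
#' JunctionCounts(m)
#' @export
JunctionCounts <- function(counts, junctions = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(junctions)) {
        if (is.null(rownames(counts)))
            stop("counts must have junction-key rownames", call. = FALSE)
        junctions <- parseJunctionKey(rownames(counts))
    }
    rownames(counts) <- names(junctions)
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = junctions)
    new("JunctionCounts", se)
}

#' @describeIn JunctionCounts junction count matrix accessor.
#' @param object,x a `JunctionCounts` object.
#' @export
junctionCounts <- function(object) assay(object, "counts")

#' Construct an AleEvent
#'
#' @param eventId event identifier.
#' @param gene gene symbol (case-folded to upper case).
#' @param inc1 junction key or length-1 `GRanges`: upstream exon to ALE exon.
#' @param inc2 junction key or length-1 `GRanges`: ALE exon to downstream exon.
#' @param exc junction key or length-1 `GRanges`: skipping junction.
#' @return An [AleEvent-class] object.
#' @examples
#' AleEvent("ALE1", "KRAS", "chr12:1000-2000", "chr12:2500-3500",
#'          "chr12:1000-3500")
#' @export
AleEvent <- function(eventId, gene, inc1, inc2, exc) {
    asJx <- function(x) if (is.character(x)) parseJunctionKey(x) else x
    new("AleEvent", eventId = as.character(eventId),
        gene = toupper(as.character(gene)),
        inc1 = asJx(inc1), inc2 = asJx(inc2), exc = asJx(exc))
}

#' @describeIn AleEvent event identifier.
#' @param object,x an `AleEvent`.
#' @export
eventId <- function(object) object@eventId

#' @describeIn AleEvent gene symbol.
#' @export
eventGene <- function(object) object@gene

#' @describeIn AleEvent the three junctions as a named `GRanges`
#'   (`inc1`, `inc2`, `exc`).
#' @export
eventJunctions <- function(object) {
    gr <- c(object@inc1, object@inc2, object@exc)
    names(gr) <- c("inc1", "inc2", "exc")
    gr
}

setMethod("show", "AleEvent", function(object) {
    jx <- eventJunctions(object)
    cat("AleEvent '", object@eventId, "' (", object@gene, ")\n", sep = "")
    for (nm in names(jx))
        cat(sprintf("  %-4s %s\n", nm, junctionKey(jx[nm])))
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols; symbols are
#'   case-folded to upper case and duplicates within a set collapsed.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' GeneSetCollection(list(S1 = c("tp53", "MYC"), S2 = c("KRAS", "NRAS")))
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
    if (is.null(descriptions))
        descriptions <- rep("", length(sets))
    descriptions <- as.character(descriptions)
    names(descriptions) <- names(sets)
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection the named list of gene sets.
#' @param object,x a `GeneSetCollection`.
#' @export
geneSets <- function(object) object@sets

#' @describeIn GeneSetCollection per-set descriptions.
#' @export
setDescriptions <- function(object) object@descriptions

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @param i set name or index.
#' @rdname GeneSetCollection-class
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object), "sets;",
        "set sizes", paste(range(lengths(object@sets)), collapse = "-"), "\n")
})
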