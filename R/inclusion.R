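#' Exon inclusion score from junction reads
#'
#' The fraction of a gene's transcripts using the ALE-inclusion isoform,
#' computed from the two inclusion-junction read counts and the skipping
#' junction count:
#' \deqn{\psi = \frac{(inc_1 + inc_2)/2}{(inc_1 + inc_2)/2 + exc}}
#' No pseudocounts are added; when all three counts are zero the score is
#' undefined and `NA` is returned (a propagating sentinel, never 0).
#' Counts may be non-integer (e.g. normalized RSEM junction values).
#'
#' @param inc1 reads spanning the upstream-exon to ALE-exon junction.
#' @param inc2 reads spanning the ALE-exon to downstream-exon junction.
#' @param exc reads spanning the skipping junction.  All three are
#'   non-negative and recycled to a common length.
#' @return numeric vector of scores in `[0, 1]`, `NA` where undefined.
#' @examples
#' inclusionScore(10, 10, 10)  # 0.5
#' inclusionScore(20, 10, 45)  # 0.25
#' @export
inclusionScore <- function(inc1, inc2, exc) {
    .checkCounts(inc1, inc2, exc)
    m <- (inc1 + inc2) / 2
    den <- m + exc
    ifelse(den > 0, m / den, NA_real_)
}

#' Inclusion/exclusion isoform ratio
#'
#' The abundance of the inclusion isoform relative to the exclusion isoform
#' (the "KRAS4A/KRAS4B transcript ratio"), estimated as
#' `((inc1 + inc2)/2) / exc`.  This is the monotone transform
#' `psi / (1 - psi)` of the inclusion score, so ranking samples by ratio and
#' by score is identical.  Undefined (`NA`) when `exc` is 0.
#'
#' @inheritParams inclusionScore
#' @return numeric vector of non-negative ratios, `NA` where `exc == 0`.
#' @export
isoformRatio <- function(inc1, inc2, exc) {
    .checkCounts(inc1, inc2, exc)
    ifelse(exc > 0, (inc1 + inc2) / 2 / exc, NA_real_)
}

.checkCounts <- function(inc1, inc2, exc) {
    for (nm in c("inc1", "inc2", "exc")) {
        x <- get(nm)
        if (!is.numeric(x) || any(!is.finite(x)))
            stop(nm, " must be finite numeric", call. = FALSE)
        if (any(x < 0))
            stop(nm, " must be non-negative", call. = FALSE)
    }
    invisible(TRUE)
}

#' Flag samples with insufficient exclusion-read coverage
#'
#' Samples with fewer than `minExc` exclusion reads get artificially low
#' inclusion scores when overall gene coverage is low, so they are flagged
#' and dropped from downstream cohort stages (default threshold 20 reads).
#' Samples are flagged, never deleted, so exclusions can be reported.  The
#' inclusion counts never affect the flag: a sample with zero inc reads but
#' ample exc coverage is valid evidence of minimal inclusion-isoform
#' expression.
#'
#' @param results a `DataFrame`/`data.frame` with an `exc` column, as from
#'   [scoreEvent()].
#' @param minExc minimum exclusion reads required (default 20).
#' @return `results` with logical column `pass_filter` set to
#'   `exc >= minExc`.
#' @export
applyExclusionFilter <- function(results, minExc = 20) {
    stopifnot(is.numeric(minExc), length(minExc) == 1L, minExc >= 0)
    results$pass_filter <- results$exc >= minExc
    results
}

#' qPCR relative expression by the delta-Ct method
#'
#' Expression of a target gene relative to a reference gene (e.g. HPRT1)
#' from TaqMan cycle thresholds, assuming doubling per cycle:
#' `2^-(ctTarget - ctRef)`.  Equal Ct values give 1.
#'
#' @param ctTarget,ctRef finite cycle-threshold values (typically 10-40),
#'   recycled to a common length.
#' @return positive numeric vector of linear-scale relative expression.
#' @examples
#' relativeExpression(25, 20)  # 2^-5 = 0.03125
#' @export
relativeExpression <- function(ctTarget, ctRef) {
    if (!is.numeric(ctTarget) || !is.numeric(ctRef) ||
        any(!is.finite(ctTarget)) || any(!is.finite(ctRef)))
        stop("Ct values must be finite numeric", call. = FALSE)
    2^(-(ctTarget - ctRef))
}

#' Score an ALE event across all samples of a junction table
#'
#' Looks up the event's three junctions in the count table (strand-tolerant:
#' a strand-unknown key matches either stranded key at the same coordinates,
#' with a warning) and computes per-sample inclusion scores, isoform ratios
#' and the exclusion-read filter flag.
#'
#' @param event an [AleEvent-class].
#' @param counts a [JunctionCounts-class] table.
#' @param minExc minimum exclusion reads (default 20); see
#'   [applyExclusionFilter()].
#' @return A [S4Vectors::DataFrame] with columns `sample`, `inc1`, `inc2`,
#'   `exc`, `psi`, `ratio`, `pass_filter`, one row per sample of `counts`.
#' @export
setGeneric("scoreEvent", function(event, counts, minExc = 20)
    standardGeneric("scoreEvent"))

#' @rdname scoreEvent
#' @export
setMethod("scoreEvent", signature(event = "AleEvent",
                                  counts = "JunctionCounts"),
    function(event, counts, minExc = 20) {
        jx <- eventJunctions(event)
        idx <- .resolveJunctions(jx, counts)
        mat <- junctionCounts(counts)
        samples <- colnames(mat)
        res <- DataFrame(
            sample = samples,
            inc1 = unname(mat[idx[["inc1"]], ]),
            inc2 = unname(mat[idx[["inc2"]], ]),
            exc = unname(mat[idx[["exc"]], ]))
        res$psi <- inclusionScore(res$inc1, res$inc2, res$exc)
        res$ratio <- isoformRatio(res$inc1, res$inc2, res$exc)
        res <- applyExclusionFilter(res, minExc)
        rownames(res) <- samples
        res
    })

# Match event junctions against table rows; strand-unknown on either side
# matches any strand at the same coordinates (Xena junction ids are
# unstranded), with a warning.  Stranded-vs-stranded requires equality.
.resolveJunctions <- function(jx, counts) {
    tabKeys <- rownames(counts)
    tabBare <- junctionKey(rowRanges(counts), ignoreStrand = TRUE)
    tabStrand <- as.character(strand(rowRanges(counts)))
    idx <- integer(length(jx))
    names(idx) <- names(jx)
    missing <- character()
    for (i in seq_along(jx)) {
        key <- junctionKey(jx[i])
        bare <- junctionKey(jx[i], ignoreStrand = TRUE)
        st <- as.character(strand(jx[i]))
        hit <- which(tabKeys == key)
        if (!length(hit)) {
            cand <- which(tabBare == bare)
            if (st != "*")
                cand <- cand[tabStrand[cand] %in% c("*", st)]
            if (length(cand)) {
                warning("junction ", key, " matched ", tabKeys[cand[1L]],
                        " by coordinates only (strand-tolerant)",
                        call. = FALSE)
                hit <- cand[1L]
            }
        }
        if (!length(hit)) missing <- c(missing, key)
        else idx[i] <- hit[1L]
    }
    if (length(missing))
        stop("junction(s) not found in count table: ",
             paste(missing, collapse = ", "), call. = FALSE)
    idx
}

#' Write per-sample inclusion results as TSV
#'
#' Fixed column order (`sample`, `inc1`, `inc2`, `exc`, `psi`, `ratio`,
#' `pass_filter`); undefined values serialized as `NA`; rows sorted by
#' sample id.
#'
#' @param results output of [scoreEvent()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInclusionResults <- function(results, path) {
    df <- as.data.frame(results)[, c("sample", "inc1", "inc2", "exc",
                                     "psi", "ratio", "pass_filter")]
    df <- df[order(df$sample), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}
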