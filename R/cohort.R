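#' Stratify samples into high/low isoform-ratio extremes
#'
#' Assigns the `nHigh` samples with the largest ratios to the `high` group
#' and the `nLow` smallest to `low`; everything else (middle samples and
#' samples with undefined ratio) is `excluded`.  Group sizes are explicit,
#' matching cohort designs with asymmetric extremes (e.g. 8 high / 7 low),
#' rather than a median split.  Ties are broken by `(ratio, sample id)`
#' lexicographic order so assignment is deterministic: of two samples tied
#' at the high boundary, the lexicographically smaller id enters `high`.
#'
#' @param ratios named numeric vector of isoform ratios (names are sample
#'   ids); `NA` entries are treated as ineligible.
#' @param nHigh,nLow number of samples for each extreme.
#' @return A `data.frame` with columns `sample`, `group` (factor
#'   `high`/`low`/`excluded`) and `rank_value` (the ratio), sorted by
#'   sample id.
#' @export
stratifyByRatio <- function(ratios, nHigh, nLow) {
    stopifnot(is.numeric(ratios), !is.null(names(ratios)),
              !anyDuplicated(names(ratios)))
    nHigh <- as.integer(nHigh); nLow <- as.integer(nLow)
    stopifnot(nHigh >= 0, nLow >= 0)
    eligible <- names(ratios)[is.finite(ratios)]
    if (nHigh + nLow > length(eligible))
        stop("nHigh + nLow (", nHigh + nLow,
             ") exceeds the ", length(eligible),
             " samples with a defined ratio", call. = FALSE)
    r <- ratios[eligible]
    highIds <- eligible[order(-r, eligible)][seq_len(nHigh)]
    rest <- setdiff(eligible, highIds)
    r2 <- ratios[rest]
    lowIds <- rest[order(r2, rest)][seq_len(nLow)]
    group <- rep("excluded", length(ratios))
    names(group) <- names(ratios)
    group[highIds] <- "high"
    group[lowIds] <- "low"
    out <- data.frame(sample = names(ratios),
                      group = factor(group,
                                     levels = c("high", "low", "excluded")),
                      rank_value = unname(ratios))
    out <- out[order(out$sample), ]
    rownames(out) <- NULL
    out
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney U test.  For small samples (total n <= `exactMax`)
#' the p-value is exact, by full enumeration of all group-label assignments
#' of the combined values (valid with ties); larger samples use the normal
#' approximation with tie correction and continuity correction.  A fold
#' change (ratio of arithmetic means, a/b) is reported alongside when the
#' reference mean is positive.
#'
#' @param valuesA,valuesB numeric vectors, both non-empty.
#' @param exactMax largest total sample size for exact enumeration
#'   (default 12).
#' @return A list with elements `statistic` (U for group A), `p_two_sided`,
#'   `fold_change` (`mean(valuesA)/mean(valuesB)`, `NA` if the reference
#'   mean is not positive), `n_a`, `n_b`, and `method`.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))$p_two_sided  # 2/6
#' @export
rankSumTest <- function(valuesA, valuesB, exactMax = 12) {
    if (!length(valuesA) || !length(valuesB))
        stop("both groups must be non-empty", call. = FALSE)
    stopifnot(is.numeric(valuesA), is.numeric(valuesB),
              all(is.finite(valuesA)), all(is.finite(valuesB)))
    na <- length(valuesA); nb <- length(valuesB)
    comb <- c(valuesA, valuesB)
    uStat <- function(idxA) {
        rk <- rank(comb)
        sum(rk[idxA]) - na * (na + 1) / 2
    }
    uObs <- uStat(seq_len(na))
    mu <- na * nb / 2
    if (na + nb <= exactMax) {
        assigns <- utils::combn(na + nb, na)
        rk <- rank(comb)
        uAll <- apply(assigns, 2L, function(ix)
            sum(rk[ix]) - na * (na + 1) / 2)
        p <- mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
        method <- "exact enumeration"
    } else {
        rk <- rank(comb)
        n <- na + nb
        ties <- table(rk)
        sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) /
                                      (n * (n - 1)))
        z <- (uObs - mu - sign(uObs - mu) * 0.5) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        method <- "normal approximation"
    }
    fc <- if (mean(valuesB) > 0) mean(valuesA) / mean(valuesB) else NA_real_
    list(statistic = unname(uObs), p_two_sided = p, fold_change = fc,
         n_a = na, n_b = nb, method = method)
}

#' Fold change between two groups
#'
#' Ratio of arithmetic means `mean(valuesA) / mean(valuesB)` on linear-scale
#' values; exponentiate log-scale inputs first.
#'
#' @param valuesA numeric vector, group of interest.
#' @param valuesB numeric vector, reference group; its mean must be
#'   positive.
#' @return a single positive number.
#' @export
foldChange <- function(valuesA, valuesB) {
    stopifnot(is.numeric(valuesA), is.numeric(valuesB),
              length(valuesA) > 0, length(valuesB) > 0)
    mb <- mean(valuesB)
    if (!is.finite(mb) || mb <= 0)
        stop("reference group mean must be positive", call. = FALSE)
    mean(valuesA) / mb
}

#' Rank genes between the low- and high-ratio groups
#'
#' Per-gene signal-to-noise statistic
#' `s = (mu_low - mu_high) / (sd_low + sd_high)`, with each standard
#' deviation floored at `max(0.2 * |mu|, 0.2)` of its own group so
#' constant genes are well-defined (the floor used by GSEA's phenotype
#' metric).  Positive scores mean higher expression in the low-ratio group,
#' the direction of interest when asking what is over-expressed in
#' low-inclusion tumors.  Ties are broken by gene symbol.
#'
#' @param expr a `SummarizedExperiment` with assay `"exprs"`, or a
#'   gene-by-sample matrix.
#' @param groups a `data.frame` from [stratifyByRatio()] (columns `sample`,
#'   `group`).
#' @param mode ranking direction; only `"low_vs_high"` is defined.
#' @return A `data.frame` with columns `gene` and `score`, rows in
#'   non-increasing score order.
#' @export
rankGenes <- function(expr, groups, mode = "low_vs_high") {
    mode <- match.arg(mode, "low_vs_high")
    mat <- if (is(expr, "SummarizedExperiment")) assay(expr, "exprs")
           else as.matrix(expr)
    lowIds <- intersect(groups$sample[groups$group == "low"], colnames(mat))
    highIds <- intersect(groups$sample[groups$group == "high"], colnames(mat))
    if (length(lowIds) < 2L || length(highIds) < 2L)
        stop("each group needs >= 2 samples in the expression matrix ",
             "(got ", length(lowIds), " low, ", length(highIds), " high)",
             call. = FALSE)
    snr <- function(ids) {
        sub <- mat[, ids, drop = FALSE]
        mu <- rowMeans(sub)
        sd <- apply(sub, 1L, stats::sd)
        list(mu = mu, sd = pmax(sd, 0.2 * abs(mu), 0.2))
    }
    lo <- snr(lowIds); hi <- snr(highIds)
    score <- (lo$mu - hi$mu) / (lo$sd + hi$sd)
    ord <- order(-score, rownames(mat))
    out <- data.frame(gene = rownames(mat)[ord], score = unname(score[ord]))
    rownames(out) <- NULL
    out
}

#' Take the top k genes of a ranked list
#'
#' @param ranked a `data.frame` from [rankGenes()].
#' @param k number of genes (default 100); must not exceed the list length.
#' @return character vector of the first `k` gene symbols.
#' @export
topK <- function(ranked, k = 100) {
    k <- as.integer(k)
    stopifnot(k >= 0)
    if (k > nrow(ranked))
        stop("k (", k, ") exceeds the ranked list length (", nrow(ranked),
             ")", call. = FALSE)
    ranked$gene[seq_len(k)]
}

#' Write group assignments as TSV
#' @param groups a `data.frame` from [stratifyByRatio()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroups <- function(groups, path) {
    df <- groups[order(groups$sample),
                 c("sample", "group", "rank_value")]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Write a ranked gene list in RNK format
#' @param ranked a `data.frame` from [rankGenes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRnk <- function(ranked, path) {
    utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an RNK ranked gene list
#' @param path path to a two-column (gene, score) tab-separated file.
#' @return A `data.frame` with columns `gene`, `score`, re-sorted
#'   descending by score with gene-symbol tie-break.
#' @export
readRnk <- function(path) {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            col.names = c("gene", "score"),
                            colClasses = c("character", "numeric"))
    df$gene <- toupper(df$gene)
    if (anyDuplicated(df$gene))
        stop("duplicate gene in RNK file", call. = FALSE)
    df <- df[order(-df$score, df$gene), ]
    rownames(df) <- NULL
    df
}
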