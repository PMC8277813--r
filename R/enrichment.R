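#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The GSEA running-sum statistic over a ranked gene list: walking down the
#' list, hits (genes in the set) increment the sum by
#' `|score|^p / sum(|score at hits|^p)` and misses decrement it by
#' `1 / (N - N_hits)`; the enrichment score is the signed maximum deviation
#' from zero.  With weight `p = 0` this is the classical KS statistic on
#' ranks.  Genes of the set absent from the ranked list are ignored;
#' ranked genes absent from the set are misses.
#'
#' @param ranked a `data.frame` from [rankGenes()]/[readRnk()] (columns
#'   `gene`, `score`, already in rank order).
#' @param geneSet character vector of gene symbols.
#' @param weightP weighting exponent on the scores (default 1).
#' @return A list with `es`, `runningSum` (length-N numeric), `hits`
#'   (logical length N), `leadingEdge` (hit genes at or before the maximum
#'   for positive `es`, at or after the minimum for negative `es`) and
#'   `nOverlap`.
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1) {
    genes <- ranked$gene
    scores <- ranked$score
    stopifnot(weightP >= 0)
    hits <- genes %in% toupper(geneSet)
    nh <- sum(hits)
    N <- length(genes)
    if (nh == 0L)
        stop("gene set has no overlap with the ranked list", call. = FALSE)
    if (nh == N)
        stop("gene set covers the whole ranked list", call. = FALSE)
    w <- abs(scores)^weightP
    if (sum(w[hits]) == 0) w[hits] <- 1   # degenerate all-zero hit scores
    inc <- numeric(N)
    inc[hits] <- w[hits] / sum(w[hits])
    dec <- numeric(N)
    dec[!hits] <- 1 / (N - nh)
    running <- cumsum(inc - dec)
    iTop <- which.max(running)
    iBot <- which.min(running)
    # positive extremum wins a tie in magnitude (tolerance absorbs float
    # noise on the exact rational ties of the unweighted statistic)
    if (running[iTop] >= -running[iBot] - 1e-9) {
        es <- running[iTop]; peak <- iTop
    } else {
        es <- running[iBot]; peak <- iBot
    }
    le <- if (es >= 0) genes[hits & seq_len(N) <= peak]
          else genes[hits & seq_len(N) >= peak]
    list(es = es, runningSum = running, hits = hits, leadingEdge = le,
         nOverlap = nh)
}

#' Permutation null, NES and p-value for one gene set
#'
#' Builds a null distribution of enrichment scores and normalizes the
#' observed score against it.  Two schemes:
#' * `"gene_set"` draws `nPerm` random gene sets of the same overlap size
#'   from the ranked universe;
#' * `"phenotype"` permutes the high/low group labels across samples,
#'   re-ranks the genes and recomputes the score (requires `expr` and
#'   `groups`; preserves gene-gene correlation).
#'
#' `nes = es / mean(|null es| of matching sign)` and
#' `p = (1 + #\{same-sign null >= observed\}) / (1 + #\{same-sign null\})`
#' -- the estimate is taken against the matching-sign portion of the null,
#' which keeps null p-values uniform whatever the sign split; p is bounded
#' below by `1/(nPerm+1)`.  Results are reproducible for a fixed `seed`
#' and independent of the order in which sets are tested.
#'
#' @inheritParams enrichmentScore
#' @param nPerm number of permutations (default 1000).
#' @param scheme `"gene_set"` or `"phenotype"`.
#' @param seed integer seed for this set's permutation stream.
#' @param expr,groups expression matrix and group assignment, needed for the
#'   phenotype scheme.
#' @param exhaustive for the gene-set scheme on small universes: enumerate
#'   every same-size gene set instead of sampling (`nPerm` is ignored).
#' @return A list with `es`, `nes`, `pPerm`, `nullEs`, `leadingEdge`,
#'   `nOverlap`.
#' @export
permutationNull <- function(ranked, geneSet, nPerm = 1000,
                            scheme = c("gene_set", "phenotype"),
                            seed = 1, weightP = 1,
                            expr = NULL, groups = NULL,
                            exhaustive = FALSE) {
    scheme <- match.arg(scheme)
    stopifnot(nPerm >= 1)
    obs <- enrichmentScore(ranked, geneSet, weightP)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed %% .Machine$integer.max)
    if (scheme == "gene_set" && exhaustive) {
        N <- nrow(ranked)
        m <- obs$nOverlap
        if (choose(N, m) > 1e5)
            stop("exhaustive enumeration infeasible for choose(", N, ", ",
                 m, ") sets", call. = FALSE)
        nullEs <- apply(utils::combn(N, m), 2L, function(idx)
            .esFromIdx(ranked$score, idx, N, weightP))
        nPerm <- length(nullEs)
    } else if (scheme == "gene_set") {
        N <- nrow(ranked)
        m <- obs$nOverlap
        nullEs <- vapply(seq_len(nPerm), function(i) {
            idx <- sample.int(N, m)
            .esFromIdx(ranked$score, idx, N, weightP)
        }, numeric(1))
    } else {
        if (is.null(expr) || is.null(groups))
            stop("phenotype scheme needs expr and groups", call. = FALSE)
        mat <- if (is(expr, "SummarizedExperiment")) assay(expr, "exprs")
               else as.matrix(expr)
        grp <- groups[groups$group %in% c("high", "low"), ]
        if (min(table(factor(grp$group, c("high", "low")))) < 2L)
            stop("phenotype scheme needs >= 2 samples per group",
                 call. = FALSE)
        nullEs <- vapply(seq_len(nPerm), function(i) {
            perm <- grp
            perm$group <- sample(grp$group)
            rr <- rankGenes(mat, perm)
            enrichmentScore(rr, geneSet, weightP)$es
        }, numeric(1))
    }
    sameSign <- if (obs$es >= 0) nullEs >= 0 else nullEs < 0
    denom <- mean(abs(nullEs[sameSign]))
    nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
    extreme <- sum(sameSign & abs(nullEs) >= abs(obs$es) - 1e-9)
    # p is estimated against the same-sign portion of the null, so it stays
    # uniformly distributed for null sets regardless of the sign split; the
    # exhaustive enumeration contains the observed set itself and needs no
    # add-one correction
    p <- if (scheme == "gene_set" && exhaustive) extreme / sum(sameSign)
         else (1 + extreme) / (1 + sum(sameSign))
    list(es = obs$es, nes = nes, pPerm = p, nullEs = nullEs,
         leadingEdge = obs$leadingEdge, nOverlap = obs$nOverlap)
}

# ES given hit indices only -- the streaming form used for permutations.
.esFromIdx <- function(scores, idx, N, weightP) {
    idx <- sort(idx)
    w <- abs(scores[idx])^weightP
    if (sum(w) == 0) w <- rep(1, length(w))
    phit <- cumsum(w) / sum(w)
    pmiss <- (idx - seq_along(idx)) / (N - length(idx))
    # running sum just before each hit is phit[i-1] - pmiss-at-idx[i];
    # extrema occur at hit positions (top) or just before them (bottom)
    devTop <- phit - pmiss
    devBot <- c(0, phit[-length(phit)]) - pmiss
    iTop <- which.max(devTop)
    iBot <- which.min(devBot)
    if (devTop[iTop] >= -devBot[iBot] - 1e-9) devTop[iTop] else devBot[iBot]
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}
.Random.seed_restore <- function(old) {
    if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a vector of p-values; a thin validating wrapper
#' around [stats::p.adjust()].  Adjusted values satisfy `q >= p`, are
#' order-preserving, and are non-decreasing in the sorted-p order.
#'
#' @param pValues numeric vector with every element in `(0, 1]`.
#' @return numeric vector of q-values.
#' @export
fdrAdjust <- function(pValues) {
    if (!is.numeric(pValues) || any(!is.finite(pValues)) ||
        any(pValues <= 0 | pValues > 1))
        stop("p-values must lie in (0, 1]", call. = FALSE)
    stats::p.adjust(pValues, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a selected gene list (e.g. the top 100 between-group
#' genes) and a gene set, conditioned on the measured universe; equivalent
#' to a one-sided Fisher exact test on the 2x2 table.
#'
#' @param topGenes character vector of selected genes; must be a subset of
#'   `universe`.
#' @param geneSet character vector of set members.
#' @param universe character vector of all measured genes.
#' @return A list with `kOverlap`, `nTop`, `mSet` (set size within the
#'   universe), `universe` (its size) and `pHyper`.
#' @export
oraHypergeometric <- function(topGenes, geneSet, universe) {
    topGenes <- unique(toupper(topGenes))
    geneSet <- unique(toupper(geneSet))
    universe <- unique(toupper(universe))
    out <- setdiff(topGenes, universe)
    if (length(out))
        stop("top genes absent from universe: ",
             paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
    m <- length(intersect(geneSet, universe))
    if (m == 0L)
        stop("gene set has no overlap with the universe", call. = FALSE)
    k <- length(intersect(topGenes, geneSet))
    U <- length(universe)
    nTop <- length(topGenes)
    p <- stats::phyper(k - 1, m, U - m, nTop, lower.tail = FALSE)
    list(kOverlap = k, nTop = nTop, mSet = m, universe = U, pHyper = p)
}

#' Gene-set enrichment over a collection
#'
#' Runs [enrichmentScore()] + [permutationNull()] for every set of a
#' collection that overlaps the ranked universe in at least `minSize`
#' genes, then adjusts the permutation p-values by Benjamini-Hochberg.
#' Each set gets an independent permutation stream derived from the root
#' seed and the set name, so results do not depend on testing order.
#'
#' @inheritParams permutationNull
#' @param gsc a [GeneSetCollection-class].
#' @param minSize minimum overlap with the ranked universe (default 5).
#' @return A `data.frame` with one row per tested set: `set_name`, `size`,
#'   `es`, `nes`, `p_perm`, `q_value`, `leading_edge` (comma-joined),
#'   sorted by set name.
#' @export
runEnrichment <- function(ranked, gsc, minSize = 5, weightP = 1,
                          nPerm = 1000, scheme = c("gene_set", "phenotype"),
                          seed = 1, expr = NULL, groups = NULL) {
    scheme <- match.arg(scheme)
    universe <- ranked$gene
    keep <- vapply(names(gsc), function(nm) {
        ov <- sum(universe %in% gsc[[nm]])
        ov >= minSize && ov < length(universe)
    }, logical(1))
    tested <- names(gsc)[keep]
    rows <- lapply(tested, function(nm) {
        res <- permutationNull(ranked, gsc[[nm]], nPerm = nPerm,
                               scheme = scheme,
                               seed = .deriveSeed(seed, nm),
                               weightP = weightP, expr = expr,
                               groups = groups)
        data.frame(set_name = nm, size = res$nOverlap, es = res$es,
                   nes = res$nes, p_perm = res$pPerm,
                   leading_edge = paste(res$leadingEdge, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(set_name = character(), size = integer(),
                          es = numeric(), nes = numeric(),
                          p_perm = numeric(), q_value = numeric(),
                          leading_edge = character()))
    out$q_value <- fdrAdjust(out$p_perm)
    out <- out[order(out$set_name),
               c("set_name", "size", "es", "nes", "p_perm", "q_value",
                 "leading_edge")]
    rownames(out) <- NULL
    out
}

#' Over-representation analysis over a collection
#'
#' @inheritParams runEnrichment
#' @param topGenes selected gene list (e.g. from [topK()]).
#' @param universe measured-gene universe; defaults in the pipeline to all
#'   genes of the expression matrix.
#' @param minSize minimum set overlap with the universe (default 5).
#' @return A `data.frame`: `set_name`, `k_overlap`, `n_top`, `m_set`,
#'   `universe`, `p_hyper`, `q_value`, sorted by set name.
#' @export
runOra <- function(topGenes, gsc, universe, minSize = 5) {
    keep <- vapply(names(gsc), function(nm)
        length(intersect(toupper(universe), gsc[[nm]])) >= minSize,
        logical(1))
    rows <- lapply(names(gsc)[keep], function(nm) {
        res <- oraHypergeometric(topGenes, gsc[[nm]], universe)
        data.frame(set_name = nm, k_overlap = res$kOverlap,
                   n_top = res$nTop, m_set = res$mSet,
                   universe = res$universe, p_hyper = res$pHyper,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(set_name = character(), k_overlap = integer(),
                          n_top = integer(), m_set = integer(),
                          universe = integer(), p_hyper = numeric(),
                          q_value = numeric()))
    out$q_value <- fdrAdjust(out$p_hyper)
    out <- out[order(out$set_name), ]
    rownames(out) <- NULL
    out
}

#' Write an enrichment table as TSV
#' @param enr a `data.frame` from [runEnrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnrichment <- function(enr, path) {
    utils::write.table(enr, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

# Deterministic order-independent per-set stream: polynomial hash of the
# set name folded into the root seed, kept inside 32-bit integer range.
.deriveSeed <- function(seed, name) {
    h <- 0
    for (v in utf8ToInt(name))
        h <- (h * 31 + v) %% 2147483647
    as.integer((abs(seed) + h) %% 2147483647)
}
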