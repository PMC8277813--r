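test_that("enrichment score handles the canonical boundary cases", {
    rk <- data.frame(gene = c("A", "B", "C", "D"), score = c(4, 3, 2, 1))
    # all hit mass at position 1
    expect_identical(enrichmentScore(rk, "A", weightP = 1)$es, 1.0)
    # single gene ranked last, unweighted: running sum -1/3,-2/3,-1, then 0
    expect_identical(enrichmentScore(rk, "D", weightP = 0)$es, -1.0)
    expect_error(enrichmentScore(rk, "ZZZ"), "no overlap")
    expect_error(enrichmentScore(rk, c("A", "B", "C", "D")), "whole")
})

test_that("streaming ES equals the brute-force running-sum oracle", {
    withr::local_seed(101)
    for (i in 1:200) {
        N <- sample(5:50, 1)
        rk <- randomRanked(N)
        m <- sample(seq_len(N - 1), 1)
        set <- sample(rk$gene, m)
        p <- sample(c(0, 1, 1.5), 1)
        full <- enrichmentScore(rk, set, weightP = p)
        expect_equal(full$es, oracleEs(rk$score, full$hits, p),
                     tolerance = 1e-12)
        # the index-only streaming form used inside permutations agrees
        expect_equal(aleSplice:::.esFromIdx(rk$score, which(full$hits), N, p),
                     full$es, tolerance = 1e-12)
        # running sum returns to zero over the full list
        expect_lt(abs(full$runningSum[N]), 1e-9)
        # |es| <= 1 always
        expect_lte(abs(full$es), 1)
    }
})

test_that("ES agrees with the independent fgsea implementation", {
    skip_if_not_installed("fgsea")
    withr::local_seed(55)
    for (i in 1:50) {
        N <- sample(10:60, 1)
        rk <- randomRanked(N)
        m <- sample(2:(N - 2), 1)
        set <- sample(rk$gene, m)
        ours <- enrichmentScore(rk, set, weightP = 1)$es
        ref <- fgsea::calcGseaStat(rk$score, which(rk$gene %in% set),
                                   gseaParam = 1)
        expect_equal(ours, ref, tolerance = 1e-10)
    }
})

test_that("ES invariances: p = 0 rank statistic, list reversal negates", {
    withr::local_seed(7)
    rk <- randomRanked(30)
    set <- sample(rk$gene, 8)
    es0 <- enrichmentScore(rk, set, weightP = 0)$es
    # monotone rescaling of scores cannot change the p = 0 statistic
    rk2 <- rk; rk2$score <- exp(rk$score) * 3
    expect_identical(enrichmentScore(rk2, set, weightP = 0)$es, es0)
    # reversing the ranked list negates the unweighted ES (no ties here)
    rkRev <- rk[rev(seq_len(nrow(rk))), ]
    expect_equal(enrichmentScore(rkRev, set, weightP = 0)$es, -es0,
                 tolerance = 1e-12)
})

test_that("permutation null is reproducible, bounded and order-independent", {
    withr::local_seed(21)
    rk <- randomRanked(40)
    set <- rk$gene[1:6]   # strongly top-loaded
    r1 <- permutationNull(rk, set, nPerm = 99, seed = 5)
    r2 <- permutationNull(rk, set, nPerm = 99, seed = 5)
    expect_identical(r1[c("es", "nes", "pPerm")], r2[c("es", "nes", "pPerm")])
    expect_gte(r1$pPerm, 1 / 100)   # add-one lower bound
    # p follows the documented same-sign estimator exactly
    same <- if (r1$es >= 0) r1$nullEs >= 0 else r1$nullEs < 0
    expect_equal(r1$pPerm,
                 (1 + sum(same & abs(r1$nullEs) >= abs(r1$es) - 1e-9)) /
                     (1 + sum(same)))
})

test_that("sampled permutation p converges to the exhaustive enumeration", {
    withr::local_seed(31)
    rk <- randomRanked(8)
    set <- rk$gene[c(1, 3)]
    exh <- permutationNull(rk, set, scheme = "gene_set", exhaustive = TRUE)
    expect_equal(length(exh$nullEs), choose(8, 2))
    # oracle: enumerate all C(8,2) same-size sets with the brute-force ES
    allEs <- apply(utils::combn(8, 2), 2L, function(idx)
        oracleEs(rk$score, seq_len(8) %in% idx, 1))
    obs <- enrichmentScore(rk, set)$es
    same <- if (obs >= 0) allEs >= 0 else allEs < 0
    # the observed set is itself a member of the enumeration; p is exact
    # within the matching-sign portion of the permutation group
    pOracle <- sum(same & abs(allEs) >= abs(obs) - 1e-9) / sum(same)
    expect_equal(exh$pPerm, pOracle, tolerance = 1e-12)
    expect_gte(pOracle, 1 / choose(8, 2))
    # a large sampled null lands near the exhaustive answer
    smp <- permutationNull(rk, set, nPerm = 4000, seed = 2)
    expect_lt(abs(smp$pPerm - pOracle), 0.03)
})

test_that("phenotype permutation re-ranks genes under shuffled labels", {
    withr::local_seed(61)
    expr <- matrix(rnorm(50 * 12), 50,
                   dimnames = list(sprintf("R%03d", 1:50),
                                   sprintf("s%02d", 1:12)))
    groups <- data.frame(sample = colnames(expr),
                         group = rep(c("low", "high"), each = 6))
    rk <- rankGenes(expr, groups)
    res <- permutationNull(rk, rk$gene[1:8], nPerm = 50,
                           scheme = "phenotype", seed = 3,
                           expr = expr, groups = groups)
    expect_true(is.finite(res$nes))
    expect_gte(res$pPerm, 1 / 51)
    expect_error(permutationNull(rk, rk$gene[1:8], scheme = "phenotype",
                                 expr = expr,
                                 groups = groups[c(1, 7, 8), ]),
                 ">= 2 samples")
})

test_that("BH adjustment is validated, monotone and order-preserving", {
    expect_identical(fdrAdjust(0.04), 0.04)
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_identical(fdrAdjust(rep(1, 4)), rep(1, 4))
    expect_error(fdrAdjust(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(fdrAdjust(c(0.5, 1.2)), "\\(0, 1\\]")

    withr::local_seed(8)
    p <- runif(50)
    q <- fdrAdjust(p)
    expect_true(all(q >= p))
    expect_false(is.unsorted(q[order(p)]))
})

test_that("hypergeometric ORA matches closed form and Fisher oracle", {
    uni <- sprintf("U%02d", 1:20)
    res <- oraHypergeometric(uni[1:5], uni[1:5], uni)
    expect_equal(res$pHyper, 1 / choose(20, 5), tolerance = 1e-12)
    # set == universe: overlap is certain
    expect_equal(oraHypergeometric(uni[1:5], uni, uni)$pHyper, 1.0)
    expect_error(oraHypergeometric(c(uni[1], "MISSING"), uni[1:5], uni),
                 "absent from universe")

    withr::local_seed(17)
    for (i in 1:40) {
        U <- sample(15:60, 1)
        uni <- sprintf("U%03d", seq_len(U))
        m <- sample(2:(U - 2), 1)
        k <- sample(2:(U - 2), 1)
        set <- sample(uni, m)
        top <- sample(uni, k)
        res <- oraHypergeometric(top, set, uni)
        ov <- res$kOverlap
        tab <- matrix(c(ov, m - ov, k - ov, U - m - k + ov), 2)
        pFisher <- stats::fisher.test(tab, alternative = "greater")$p.value
        expect_equal(res$pHyper, pFisher, tolerance = 1e-9)
    }
})

test_that("collection-level enrichment is order-independent and filtered", {
    withr::local_seed(23)
    rk <- randomRanked(60)
    sets <- list(TOP = rk$gene[1:8], MID = sample(rk$gene, 10),
                 TINY = rk$gene[1:2])
    gsc1 <- GeneSetCollection(sets)
    gsc2 <- GeneSetCollection(rev(sets))
    e1 <- runEnrichment(rk, gsc1, minSize = 5, nPerm = 99, seed = 4)
    e2 <- runEnrichment(rk, gsc2, minSize = 5, nPerm = 99, seed = 4)
    expect_identical(e1, e2)                  # testing order is irrelevant
    expect_false("TINY" %in% e1$set_name)     # below minSize
    expect_equal(e1$q_value, fdrAdjust(e1$p_perm))
})
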