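#' Construct a simulation configuration
#'
#' Defaults describe the reference synthetic cohort used throughout the
#' package's recovery studies: 60 tumors, 30% KRAS-mutant, ~200
#' event-spanning reads per sample (negative binomial, size 5), wild-type
#' inclusion fraction 0.3 with a +1.5 logit shift in mutants, a 1000-gene
#' log-scale expression matrix with a 50-gene set shifted upward by 2
#' standardized units in low-inclusion samples.
#'
#' @param nSamples number of samples.
#' @param fracMutant fraction of mutant samples in `[0, 1]`.
#' @param meanCoverage expected event-spanning reads per sample.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param psiWt wild-type true inclusion fraction, in (0, 1).
#' @param psiEffect additive logit shift of the inclusion fraction in
#'   mutant samples.
#' @param nGenes number of genes in the simulated expression matrix.
#' @param plantedSet genes carrying the planted low-inclusion signature
#'   (default: the first 50 simulated genes).
#' @param plantedEffect standardized expression shift of the planted set in
#'   low-inclusion samples (0 = null).
#' @param noiseSd expression noise standard deviation (log scale).
#' @param seed root seed; every stage derives its own sub-stream from it.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nSamples = 60, fracMutant = 0.3,
                             meanCoverage = 200, dispersion = 5,
                             psiWt = 0.3, psiEffect = 1.5,
                             nGenes = 1000,
                             plantedSet = sprintf("G%04d", 1:50),
                             plantedEffect = 2, noiseSd = 1, seed = 1) {
    new("SimulationConfig", nSamples = as.integer(nSamples),
        fracMutant = fracMutant, meanCoverage = meanCoverage,
        dispersion = dispersion, psiWt = psiWt, psiEffect = psiEffect,
        nGenes = as.integer(nGenes),
        plantedSet = toupper(as.character(plantedSet)),
        plantedEffect = plantedEffect, noiseSd = noiseSd,
        seed = as.integer(seed))
}

# stage sub-streams derived from the root seed (documented protocol:
# root*2 + stage offset, folded into 32-bit range)
.stageSeed <- function(config, stage) {
    as.integer((abs(config@seed) * 2 + stage * 104729) %% 2147483647)
}

#' Simulate junction counts for one synthetic ALE event
#'
#' Generative mirror of the inclusion-score model.  Per sample `s`: true
#' inclusion fraction `psi_s = plogis(qlogis(psiWt) + psiEffect * mutant_s)`;
#' total event-spanning reads `T_s ~ NegBin(mu = meanCoverage,
#' size = dispersion)`.  An inclusion transcript carries two junctions
#' (inc1, inc2) where an exclusion transcript carries one (exc), so a
#' junction-spanning read comes from the inclusion isoform with probability
#' `2 psi_s / (1 + psi_s)`: `I_s ~ Binomial(T_s, 2 psi_s / (1 + psi_s))`,
#' `exc_s = T_s - I_s`, and the inclusion reads split between the two
#' inclusion junctions as `inc1_s ~ Binomial(I_s, 0.5)`,
#' `inc2_s = I_s - inc1_s`.  Under this read-allocation model the
#' inclusion score `((inc1+inc2)/2) / ((inc1+inc2)/2 + exc)` is a
#' consistent, asymptotically unbiased estimator of `psi_s`.
#' Mutant labels go to a random subset of `round(nSamples * fracMutant)`
#' samples.  Regeneration under the same config is bit-identical.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements `counts` ([JunctionCounts-class], 3
#'   junctions x samples), `annotation` (`DataFrame`: sample, kras_status,
#'   cohort), `event` (the synthetic [AleEvent-class]) and `truth`
#'   (`data.frame`: sample, mutant, psi_true, coverage).
#' @export
simulateJunctions <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.stageSeed(config, 1L))
    n <- config@nSamples
    samples <- sprintf("S%04d", seq_len(n))
    nMut <- round(n * config@fracMutant)
    mutant <- logical(n)
    mutant[sample.int(n, nMut)] <- TRUE
    psiTrue <- stats::plogis(stats::qlogis(config@psiWt) +
                                 config@psiEffect * mutant)
    total <- stats::rnbinom(n, mu = config@meanCoverage,
                            size = config@dispersion)
    incl <- stats::rbinom(n, total, 2 * psiTrue / (1 + psiTrue))
    exc <- total - incl
    inc1 <- stats::rbinom(n, incl, 0.5)
    inc2 <- incl - inc1
    event <- AleEvent("synthALE", "SYNGENE",
                      "chrS:1000-2000", "chrS:2500-3500", "chrS:1000-3500")
    mat <- rbind(inc1, inc2, exc)
    rownames(mat) <- junctionKey(eventJunctions(event))
    colnames(mat) <- samples
    ann <- DataFrame(sample = samples,
                     kras_status = ifelse(mutant, "mutant", "wildtype"),
                     cohort = "synthetic")
    rownames(ann) <- samples
    truth <- data.frame(sample = samples, mutant = mutant,
                        psi_true = psiTrue, coverage = total)
    list(counts = JunctionCounts(mat), annotation = ann, event = event,
         truth = truth)
}

#' Simulate an expression matrix with a planted low-inclusion signature
#'
#' Background genes are independent Normal(0, `noiseSd`) on log scale.
#' Genes of the planted set additionally receive `plantedEffect * z_s`,
#' where `z_s` is the standardized negative logit of the sample's true
#' inclusion fraction -- so samples with low true inclusion over-express
#' the planted set, the association the cohort + enrichment stages are
#' meant to recover.
#'
#' @param config a [SimulationConfig-class]; `plantedSet` must be a subset
#'   of the simulated gene symbols `G0001..G<nGenes>`.
#' @param truth the `truth` component of a prior [simulateJunctions()] run
#'   under the same config.
#' @return A `SummarizedExperiment` (assay `"exprs"`,
#'   `metadata()$scale == "log"`), genes x samples.
#' @export
simulateExpression <- function(config, truth) {
    stopifnot(is(config, "SimulationConfig"))
    genes <- sprintf("G%04d", seq_len(config@nGenes))
    missing <- setdiff(config@plantedSet, genes)
    if (length(missing))
        stop("plantedSet genes not among simulated genes: ",
             paste(utils::head(missing, 5), collapse = ", "),
             call. = FALSE)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.stageSeed(config, 2L))
    n <- nrow(truth)
    mat <- matrix(stats::rnorm(config@nGenes * n, 0, config@noiseSd),
                  nrow = config@nGenes,
                  dimnames = list(genes, truth$sample))
    v <- -stats::qlogis(truth$psi_true)
    z <- if (stats::sd(v) > 0) as.numeric(scale(v)) else numeric(n)
    planted <- genes %in% config@plantedSet
    mat[planted, ] <- mat[planted, ] +
        matrix(config@plantedEffect * z, sum(planted), n, byrow = TRUE)
    se <- SummarizedExperiment(assays = list(exprs = mat))
    metadata(se)$scale <- "log"
    se
}

#' Summarize how well the pipeline recovered the simulation truth
#'
#' @param truth the `truth` component of [simulateJunctions()].
#' @param scored per-sample results from [scoreEvent()] on the simulated
#'   counts.
#' @param groups optional group assignment from [stratifyByRatio()].
#' @param enrichment optional enrichment table from [runEnrichment()].
#' @param plantedSetName name of the planted set within the tested
#'   collection (for the NES rank).
#' @return A list: `psi_bias` (mean of estimated minus true inclusion over
#'   filter-passing samples), `n_pass`, `group_concordance` (fraction of
#'   assigned high/low samples whose true inclusion is in the matching
#'   extreme), and `planted_rank` (rank of the planted set by `|NES|`,
#'   1 = most extreme).
#' @export
recoveryReport <- function(truth, scored, groups = NULL,
                           enrichment = NULL, plantedSetName = NULL) {
    if (!setequal(truth$sample, scored$sample))
        stop("sample ids of truth and scored results differ", call. = FALSE)
    scored <- scored[match(truth$sample, scored$sample), ]
    pass <- scored$pass_filter & !is.na(scored$psi)
    out <- list(psi_bias = mean(scored$psi[pass] -
                                    truth$psi_true[pass]),
                n_pass = sum(pass))
    if (!is.null(groups)) {
        gg <- groups[groups$group %in% c("high", "low"), ]
        nH <- sum(gg$group == "high"); nL <- sum(gg$group == "low")
        eligible <- groups$sample[is.finite(groups$rank_value)]
        tr <- truth[truth$sample %in% eligible, ]
        psiOf <- function(ids) tr$psi_true[match(ids, tr$sample)]
        # threshold membership, so ties in true psi never count against
        thrH <- sort(tr$psi_true, decreasing = TRUE)[nH]
        thrL <- sort(tr$psi_true)[nL]
        hit <- sum(psiOf(gg$sample[gg$group == "high"]) >= thrH) +
            sum(psiOf(gg$sample[gg$group == "low"]) <= thrL)
        out$group_concordance <- hit / (nH + nL)
    }
    if (!is.null(enrichment) && !is.null(plantedSetName)) {
        if (!plantedSetName %in% enrichment$set_name)
            stop("planted set not among tested sets", call. = FALSE)
        ord <- order(-abs(enrichment$nes))
        out$planted_rank <-
            which(enrichment$set_name[ord] == plantedSetName)[1L]
    }
    out
}
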