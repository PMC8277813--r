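# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (loops, enumeration) and share no code with
# the implementation they check.

# inclusion score, written directly from the printed formula
oracleInclusion <- function(inc1, inc2, exc) {
    num <- (inc1 + inc2) / 2
    den <- num + exc
    if (den == 0) NA_real_ else num / den
}

# full running-sum ES by explicit walk down the list
oracleEs <- function(scores, hits, weightP = 1) {
    N <- length(scores)
    nh <- sum(hits)
    w <- abs(scores)^weightP
    if (sum(w[hits]) == 0) w[hits] <- 1
    sumw <- sum(w[hits])
    running <- numeric(N)
    cur <- 0
    for (i in seq_len(N)) {
        cur <- if (hits[i]) cur + w[i] / sumw else cur - 1 / (N - nh)
        running[i] <- cur
    }
    top <- max(running); bot <- min(running)
    if (top >= -bot - 1e-9) top else bot
}

# exact two-sided Mann-Whitney p by enumerating label assignments,
# computing U by pair counting (not via ranks)
oracleRankSumP <- function(a, b) {
    na <- length(a); nb <- length(b)
    comb <- c(a, b)
    uOf <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    mu <- na * nb / 2
    uObs <- uOf(a, b)
    idx <- utils::combn(na + nb, na)
    uAll <- apply(idx, 2L, function(ix) uOf(comb[ix], comb[-ix]))
    mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# random junction count table over k junctions and n samples
randomJunctionTable <- function(k = 5, n = 8, lambda = 30) {
    keys <- sprintf("chr1:%d-%d", seq_len(k) * 1000, seq_len(k) * 1000 + 500)
    mat <- matrix(rpois(k * n, lambda), k, n,
                  dimnames = list(keys, sprintf("s%02d", seq_len(n))))
    JunctionCounts(mat)
}

# ranked list of N noise-scored genes
randomRanked <- function(N, sd = 1) {
    df <- data.frame(gene = sprintf("R%03d", seq_len(N)),
                     score = rnorm(N, 0, sd))
    df <- df[order(-df$score, df$gene), ]
    rownames(df) <- NULL
    df
}
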