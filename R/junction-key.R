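#' Parse junction-key strings
#'
#' A junction key is `"chrom:donor-acceptor"` with an optional `":+"`/`":-"`
#' strand suffix.  `donor` and `acceptor` are the first and last intronic
#' bases, 1-based inclusive (the STAR `SJ.out.tab` convention; unstranded
#' Xena-style ids are interpreted identically).  Keys without a strand suffix
#' get strand `*` (unknown).
#'
#' @param text character vector of junction keys.
#' @return A [GenomicRanges::GRanges] of the intron intervals, named by the
#'   canonical key string, so `junctionKey(parseJunctionKey(x))` reproduces
#'   `x` exactly.
#' @examples
#' parseJunctionKey(c("chr12:100-200", "chr12:25362845-25368371:-"))
#' @export
parseJunctionKey <- function(text) {
    stopifnot(is.character(text))
    m <- regmatches(text,
        regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)(:([+-]))?$", text))
    bad <- !vapply(m, function(x) length(x) > 0L, logical(1))
    if (any(bad))
        stop("malformed junction key: '", text[which(bad)[1L]], "'",
             call. = FALSE)
    chrom <- vapply(m, `[`, character(1), 2L)
    donor <- as.integer(vapply(m, `[`, character(1), 3L))
    acceptor <- as.integer(vapply(m, `[`, character(1), 4L))
    strand <- vapply(m, `[`, character(1), 6L)
    strand[!nzchar(strand)] <- "*"
    if (any(donor >= acceptor))
        stop("junction key '", text[which(donor >= acceptor)[1L]],
             "': donor must be < acceptor", call. = FALSE)
    gr <- GRanges(chrom, IRanges(donor, acceptor), strand = strand)
    names(gr) <- junctionKey(gr)
    gr
}

#' Serialize junctions to key strings
#'
#' Inverse of [parseJunctionKey()]: the strand suffix is emitted only for
#' stranded junctions, so parse/serialize round-trips exactly.
#'
#' @param gr a [GenomicRanges::GRanges] of intron intervals.
#' @param ignoreStrand drop the strand suffix (used for strand-tolerant
#'   matching of unstranded tables).
#' @return character vector of junction keys.
#' @export
junctionKey <- function(gr, ignoreStrand = FALSE) {
    key <- paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))
    if (!ignoreStrand) {
        st <- as.character(strand(gr))
        stranded <- st != "*"
        key[stranded] <- paste0(key[stranded], ":", st[stranded])
    }
    key
}
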