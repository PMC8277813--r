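#' Read a STAR SJ.out.tab junction file
#'
#' Parses the STAR splice-junction dialect: whitespace-separated columns with
#' chromosome, intron start and end (1-based inclusive), a strand code
#' (0 unknown, 1 `+`, 2 `-`), and the uniquely-mapping read count in
#' column 7.  Columns beyond the seventh are ignored.
#'
#' @param path path to an `SJ.out.tab`-style file.
#' @return A named `GRanges` (one range per junction, names are junction
#'   keys) with a `count` metadata column.  Empty files yield an empty
#'   `GRanges`.
#' @export
readStarJunctions <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        gr <- GRanges()
        mcols(gr)$count <- numeric()
        return(gr)
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 7L))
        stop("line ", which(nf < 7L)[1L], ": expected >= 7 columns, got ",
             nf[nf < 7L][1L], call. = FALSE)
    getNum <- function(i, what) {
        v <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), i)))
        bad <- which(is.na(v) | v != floor(v))
        if (length(bad))
            stop("line ", bad[1L], ": non-integer ", what, " '",
                 vapply(fields, `[`, character(1), i)[bad[1L]], "'",
                 call. = FALSE)
        v
    }
    chrom <- vapply(fields, `[`, character(1), 1L)
    istart <- getNum(2L, "intron start")
    iend <- getNum(3L, "intron end")
    scode <- getNum(4L, "strand code")
    count <- getNum(7L, "read count")
    if (any(!scode %in% 0:2))
        stop("line ", which(!scode %in% 0:2)[1L],
             ": strand code must be 0, 1 or 2", call. = FALSE)
    gr <- GRanges(chrom, IRanges(istart, iend),
                  strand = c("*", "+", "-")[scode + 1L])
    names(gr) <- junctionKey(gr)
    if (anyDuplicated(names(gr)))
        stop("duplicate junction '",
             names(gr)[duplicated(names(gr))][1L], "' in ", path,
             call. = FALSE)
    mcols(gr)$count <- count
    gr
}

#' Merge per-sample STAR junction files into a JunctionCounts table
#'
#' The junction universe is the union over samples; junctions absent from a
#' sample's file are counted 0 (absence of reads is evidence, not
#' missingness).
#'
#' @param paths named character vector of file paths; names are sample ids.
#' @return A [JunctionCounts-class] object.
#' @export
mergeStarJunctions <- function(paths) {
    if (is.null(names(paths)) || anyDuplicated(names(paths)))
        stop("paths must be uniquely named by sample id", call. = FALSE)
    per <- lapply(paths, readStarJunctions)
    keys <- unique(unlist(lapply(per, names), use.names = FALSE))
    mat <- matrix(0, length(keys), length(per),
                  dimnames = list(keys, names(paths)))
    for (s in names(per))
        mat[names(per[[s]]), s] <- mcols(per[[s]])$count
    JunctionCounts(mat)
}

#' Read a junction-by-sample matrix (TSV)
#'
#' Expects a header row of sample ids and a first column of junction keys,
#' as in Xena-style "reads spanning splice junctions" tables.
#'
#' @param path path to the TSV file.
#' @return A [JunctionCounts-class] object.
#' @seealso [writeJunctionMatrix()]
#' @export
readJunctionMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2L)
        stop("junction matrix needs a key column plus >= 1 sample",
             call. = FALSE)
    keys <- df[[1L]]
    samples <- colnames(df)[-1L]
    if (anyDuplicated(keys))
        stop("duplicate junction key '", keys[duplicated(keys)][1L], "'",
             call. = FALSE)
    if (anyDuplicated(samples))
        stop("duplicate sample id '", samples[duplicated(samples)][1L], "'",
             call. = FALSE)
    mat <- vapply(df[-1L], function(col) suppressWarnings(as.numeric(col)),
                  numeric(nrow(df)))
    mat <- matrix(mat, nrow = nrow(df), dimnames = list(keys, samples))
    if (any(is.na(mat)))
        stop("missing or non-numeric cell in junction matrix", call. = FALSE)
    if (any(mat < 0))
        stop("negative junction count", call. = FALSE)
    JunctionCounts(mat)
}

#' Write a JunctionCounts table as TSV
#'
#' Inverse of [readJunctionMatrix()]: rows sorted by junction key so output
#' is byte-reproducible.
#'
#' @param x a [JunctionCounts-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJunctionMatrix <- function(x, path) {
    mat <- junctionCounts(x)
    mat <- mat[order(rownames(mat)), , drop = FALSE]
    df <- data.frame(junction = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with columns `sample`, `kras_status` (one of `mutant`, `wildtype`,
#' `unknown`) and `cohort`.
#'
#' @param path path to the TSV file.
#' @return A [S4Vectors::DataFrame] with one row per sample, rownames the
#'   sample ids.
#' @export
readSampleAnnotation <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    need <- c("sample", "kras_status", "cohort")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("annotation is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(df$sample))
        stop("duplicate sample id '", df$sample[duplicated(df$sample)][1L],
             "' in annotation", call. = FALSE)
    bad <- !df$kras_status %in% c("mutant", "wildtype", "unknown")
    if (any(bad))
        stop("invalid kras_status '", df$kras_status[bad][1L], "'",
             call. = FALSE)
    out <- DataFrame(sample = df$sample, kras_status = df$kras_status,
                     cohort = df$cohort)
    rownames(out) <- df$sample
    out
}

#' Write a sample annotation table
#' @param annotation a `DataFrame`/`data.frame` with columns `sample`,
#'   `kras_status`, `cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleAnnotation <- function(annotation, path) {
    df <- as.data.frame(annotation)[, c("sample", "kras_status", "cohort")]
    df <- df[order(df$sample), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then gene symbols, all
#' tab-separated.  Symbols are upper-cased and duplicates within a line
#' collapsed.
#'
#' @param path path to the GMT file.
#' @return A [GeneSetCollection-class] object.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("GMT line ", which(nf < 3L)[1L],
             ": expected >= 3 tab-separated fields", call. = FALSE)
    nms <- vapply(fields, `[`, character(1), 1L)
    if (anyDuplicated(nms))
        stop("duplicate gene-set name '", nms[duplicated(nms)][1L], "'",
             call. = FALSE)
    descs <- vapply(fields, `[`, character(1), 2L)
    sets <- lapply(fields, function(x) x[-(1:2)])
    names(sets) <- nms
    GeneSetCollection(sets, descs)
}

#' Write a GeneSetCollection as GMT
#' @param gsc a [GeneSetCollection-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(gsc, path) {
    lines <- vapply(names(gsc), function(nm)
        paste(c(nm, setDescriptions(gsc)[[nm]], gsc[[nm]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene-by-sample expression matrix (TSV)
#'
#' Header row of sample ids, first column gene symbols (case-folded to upper
#' case).  The measurement scale (`"log"` for microarray/log-transformed
#' values, `"linear"` otherwise) is recorded in the object metadata; fold
#' changes exponentiate log-scale values first.
#'
#' @param path path to the TSV file.
#' @param scale `"log"` or `"linear"`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"exprs"` and `metadata()$scale`.
#' @export
readExpressionMatrix <- function(path, scale = c("log", "linear")) {
    scale <- match.arg(scale)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    genes <- toupper(as.character(df[[1L]]))
    if (anyDuplicated(genes))
        stop("duplicate gene symbol '", genes[duplicated(genes)][1L],
             "' after case-folding", call. = FALSE)
    mat <- as.matrix(df[-1L])
    storage.mode(mat) <- "double"
    rownames(mat) <- genes
    if (anyDuplicated(colnames(mat)))
        stop("duplicate sample id in expression matrix", call. = FALSE)
    if (any(!is.finite(mat)))
        stop("expression matrix must contain only finite values",
             call. = FALSE)
    se <- SummarizedExperiment(assays = list(exprs = mat))
    metadata(se)$scale <- scale
    se
}

#' Write an expression matrix as TSV
#' @param se a `SummarizedExperiment` with assay `"exprs"`, or a matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
    mat <- if (is(se, "SummarizedExperiment")) assay(se, "exprs") else se
    mat <- mat[order(rownames(mat)), , drop = FALSE]
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read ALE event definitions
#'
#' TSV with columns `event_id`, `gene`, `inc1`, `inc2`, `exc`; the last
#' three are junction-key strings.
#'
#' @param path path to the TSV file.
#' @return A list of [AleEvent-class] objects, named by event id.
#' @export
readAleEvents <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    need <- c("event_id", "gene", "inc1", "inc2", "exc")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("event table is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    events <- lapply(seq_len(nrow(df)), function(i)
        AleEvent(df$event_id[i], df$gene[i], df$inc1[i], df$inc2[i],
                 df$exc[i]))
    names(events) <- df$event_id
    if (anyDuplicated(names(events)))
        stop("duplicate event_id", call. = FALSE)
    events
}
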