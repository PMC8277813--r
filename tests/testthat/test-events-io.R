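test_that("junction keys parse, validate and round-trip", {
    gr <- parseJunctionKey("chr12:100-200")
    expect_equal(as.character(GenomicRanges::seqnames(gr)), "chr12")
    expect_equal(GenomicRanges::start(gr), 100L)
    expect_equal(GenomicRanges::end(gr), 200L)
    expect_equal(as.character(GenomicRanges::strand(gr)), "*")

    gr2 <- parseJunctionKey("chr12:25362845-25368371:-")
    expect_equal(as.character(GenomicRanges::strand(gr2)), "-")

    expect_error(parseJunctionKey("chr12:200-100"), "donor")
    expect_error(parseJunctionKey("chr12:100"), "malformed")
    expect_error(parseJunctionKey("chr12:100-200:x"), "malformed")

    # parse . serialize is the identity on valid keys
    keys <- c("chr12:100-200", "chrX:5-9:+", "chr12:25362845-25368371:-",
              "scaffold_12:1-1000000")
    expect_identical(junctionKey(parseJunctionKey(keys)), keys)
})

test_that("STAR SJ.out.tab files are read per dialect and fail loudly", {
    f <- withr::local_tempfile()
    writeLines(c("chr12 100 200 1 1 0 15 3 20",
                 "chr12 300 400 2 1 0 7 0 11",
                 "chr1 5 50 0 0 0 3 1 9"), f)
    gr <- readStarJunctions(f)
    expect_equal(unname(S4Vectors::mcols(gr)$count), c(15, 7, 3))
    expect_equal(names(gr),
                 c("chr12:100-200:+", "chr12:300-400:-", "chr1:5-50"))

    empty <- withr::local_tempfile()
    writeLines(character(), empty)
    expect_length(readStarJunctions(empty), 0L)

    dup <- withr::local_tempfile()
    writeLines(c("chr1 5 50 0 0 0 3 1 9", "chr1 5 50 0 0 0 8 1 9"), dup)
    expect_error(readStarJunctions(dup), "duplicate junction")

    bad <- withr::local_tempfile()
    writeLines(c("chr1 5 50 0 0 0 3 1 9", "chr1 5 x 0 0 0 3 1 9"), bad)
    expect_error(readStarJunctions(bad), "line 2")

    short <- withr::local_tempfile()
    writeLines("chr1 5 50 0", short)
    expect_error(readStarJunctions(short), ">= 7 columns")
})

test_that("merging STAR files preserves per-sample column sums, absent = 0", {
    withr::local_seed(11)
    dirTmp <- withr::local_tempdir()
    paths <- c(a = file.path(dirTmp, "a.tab"), b = file.path(dirTmp, "b.tab"))
    writeLines(c("chr1 100 200 1 1 0 10 0 0",
                 "chr2 100 200 2 1 0 4 0 0"), paths["a"])
    writeLines("chr1 100 200 1 1 0 6 0 0", paths["b"])
    jc <- mergeStarJunctions(paths)
    expect_equal(unname(colSums(junctionCounts(jc))), c(14, 6))
    expect_equal(junctionCounts(jc)["chr2:100-200:-", "b"], 0)
})

test_that("junction matrix TSV round-trips and rejects corrupt input", {
    withr::local_seed(4)
    jc <- randomJunctionTable(4, 3)
    f <- withr::local_tempfile()
    writeJunctionMatrix(jc, f)
    back <- readJunctionMatrix(f)
    expect_equal(junctionCounts(back)[rownames(jc), colnames(jc)],
                 junctionCounts(jc))

    neg <- withr::local_tempfile()
    writeLines(c("junction\ts1", "chr1:1-2\t-3"), neg)
    expect_error(readJunctionMatrix(neg), "negative")

    missing <- withr::local_tempfile()
    writeLines(c("junction\ts1", "chr1:1-2\t"), missing)
    expect_error(readJunctionMatrix(missing), "missing|non-numeric")

    dupS <- withr::local_tempfile()
    writeLines(c("junction\ts1\ts1", "chr1:1-2\t1\t2"), dupS)
    expect_error(readJunctionMatrix(dupS), "duplicate sample")

    dupJ <- withr::local_tempfile()
    writeLines(c("junction\ts1", "chr1:1-2\t1", "chr1:1-2\t2"), dupJ)
    expect_error(readJunctionMatrix(dupJ), "duplicate junction")
})

test_that("JunctionCounts validity rejects bad matrices", {
    m <- matrix(1, 1, 1, dimnames = list("chr1:1-2", "s1"))
    expect_s4_class(JunctionCounts(m), "JunctionCounts")
    m2 <- m; m2[1, 1] <- -1
    expect_error(JunctionCounts(m2), "non-negative")
    m3 <- m; m3[1, 1] <- NA
    expect_error(JunctionCounts(m3), "finite")
})

test_that("GMT reading case-folds, deduplicates and validates", {
    f <- withr::local_tempfile()
    writeLines(c("S1\tdesc one\ta\tb\tB", "S2\t\tKRAS\tnras"), f)
    gsc <- readGmt(f)
    expect_equal(length(gsc), 2L)
    expect_equal(gsc[["S1"]], c("A", "B"))
    expect_equal(gsc[["S2"]], c("KRAS", "NRAS"))
    expect_equal(setDescriptions(gsc)[["S1"]], "desc one")

    # round-trip through writeGmt
    f2 <- withr::local_tempfile()
    writeGmt(gsc, f2)
    expect_equal(geneSets(readGmt(f2)), geneSets(gsc))

    dup <- withr::local_tempfile()
    writeLines(c("S1\td\ta", "S1\td\tb"), dup)
    expect_error(readGmt(dup), "duplicate gene-set name")

    short <- withr::local_tempfile()
    writeLines(c("S1\td\ta", "S2\td"), short)
    expect_error(readGmt(short), "line 2")

    expect_error(GeneSetCollection(list(S1 = character())), "empty")
})

test_that("annotation and expression readers enforce their contracts", {
    f <- withr::local_tempfile()
    writeLines(c("sample\tkras_status\tcohort",
                 "s1\tmutant\tluad", "s2\twildtype\tluad"), f)
    ann <- readSampleAnnotation(f)
    expect_equal(ann$kras_status, c("mutant", "wildtype"))

    bad <- withr::local_tempfile()
    writeLines(c("sample\tkras_status\tcohort", "s1\tMUT\tluad"), bad)
    expect_error(readSampleAnnotation(bad), "kras_status")

    ex <- withr::local_tempfile()
    writeLines(c("gene\ts1\ts2", "tp53\t1.5\t2.5", "MYC\t0\t-1"), ex)
    se <- readExpressionMatrix(ex)
    expect_equal(rownames(se), c("TP53", "MYC"))
    expect_equal(S4Vectors::metadata(se)$scale, "log")

    dupG <- withr::local_tempfile()
    writeLines(c("gene\ts1", "tp53\t1", "TP53\t2"), dupG)
    expect_error(readExpressionMatrix(dupG), "duplicate gene")
})

test_that("AleEvent construction enforces geometric invariants", {
    ev <- AleEvent("e1", "kras", "chr12:100-200", "chr12:300-400",
                   "chr12:100-400")
    expect_equal(eventGene(ev), "KRAS")
    expect_equal(names(eventJunctions(ev)), c("inc1", "inc2", "exc"))

    # exc must span both inclusion junctions
    expect_error(AleEvent("e1", "g", "chr12:100-200", "chr12:300-400",
                          "chr12:150-400"), "span")
    # inc1 donor upstream of inc2 donor
    expect_error(AleEvent("e1", "g", "chr12:300-400", "chr12:100-200",
                          "chr12:100-400"), "downstream|span")
    # pairwise distinct
    expect_error(AleEvent("e1", "g", "chr12:100-400", "chr12:100-400",
                          "chr12:100-400"), "distinct")
    # one chromosome
    expect_error(AleEvent("e1", "g", "chr12:100-200", "chr13:300-400",
                          "chr12:100-400"), "chromosome")

    f <- withr::local_tempfile()
    writeLines(c("event_id\tgene\tinc1\tinc2\texc",
                 "e1\tKRAS\tchr12:100-200\tchr12:300-400\tchr12:100-400"), f)
    evs <- readAleEvents(f)
    expect_equal(eventId(evs[["e1"]]), "e1")
})
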