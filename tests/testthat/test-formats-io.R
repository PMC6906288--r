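test_that("copy-number segment parsing maps the caller dialect onto GRanges", {
    f <- withr::local_tempfile()
    writeLines("2\t208605001\t209745000\t7\tgain", f)
    gr <- readFreecCnv(f)
    expect_length(gr, 1)
    expect_equal(as.character(seqnames(gr)), "2")
    expect_equal(start(gr), 208605001)
    expect_equal(end(gr), 209745000)
    expect_equal(gr$copyNumber, 7)
    expect_equal(gr$status, "gain")

    ## chr prefix normalization both ways
    writeLines("chr2\t100\t200\t8", f)
    expect_equal(as.character(seqnames(readFreecCnv(f))), "2")
    expect_equal(as.character(seqnames(readFreecCnv(f, "add"))), "chr2")

    ## whitespace-delimited variant and missing status column
    writeLines("17  1  15000  12", f)
    gr <- readFreecCnv(f)
    expect_equal(gr$copyNumber, 12)
    expect_true(is.na(gr$status))
})

test_that("segment parsing rejects malformed rows with the line number", {
    f <- withr::local_tempfile()
    writeLines(character(), f)
    expect_length(readFreecCnv(f), 0)

    writeLines(c("1\t1\t100\t7", "1\t500\t500\t7"), f)
    expect_error(readFreecCnv(f), "line 2.*start >= end")
    writeLines("1\tabc\t100\t7", f)
    expect_error(readFreecCnv(f), "line 1.*non-numeric")
    writeLines("1\t1\t100", f)
    expect_error(readFreecCnv(f), ">= 4 columns")
})

test_that("segment files round-trip through write and read", {
    withr::local_seed(7)
    gr <- sort(randomSegments(8))
    f <- withr::local_tempfile()
    writeFreecCnv(gr, f)
    back <- readFreecCnv(f)
    expect_equal(start(back), start(gr))
    expect_equal(end(back), end(gr))
    expect_equal(back$copyNumber, gr$copyNumber)
})

test_that("structural-variant parsing maps the ten-column dialect", {
    f <- withr::local_tempfile()
    writeLines(c("#Chr1\tPos1\tOrientation1\tChr2\tPos2\tOrientation2\tType\tSize\tScore\tnum_Reads",
        "2\t209745116\t61+0-\t2\t209749286\t0+37-\tINV\t4170\t99\t37"), f)
    sv <- readBreakdancer(f)
    expect_length(sv, 1)
    df <- as.data.frame(sv)
    expect_equal(df$svType, "INV")
    expect_equal(df$pos1, 209745116)
    expect_equal(df$pos2, 209749286)
    expect_equal(df$score, 99)
    expect_equal(df$orient1, "61+0-")

    writeLines(c("# header only", "#another"), f)
    expect_length(readBreakdancer(f), 0)

    writeLines("2\t1\t+\t2\t2\t-\tBND\t1\t99\t5", f)
    expect_error(readBreakdancer(f), "unknown SV type 'BND'")
    writeLines("2\t1\t+\t2\t2\t-\tINV\t1\t150\t5", f)
    expect_error(readBreakdancer(f), "outside \\[0, 100\\]")
})

test_that("structural-variant files round-trip through write and read", {
    sv <- idExampleSvs()
    f <- withr::local_tempfile()
    writeBreakdancer(sv, f)
    expect_equal(as.data.frame(readBreakdancer(f)), as.data.frame(sv))
})

test_that("BED output is 0-based half-open with capped scores", {
    f <- withr::local_tempfile()
    writeBed(idExampleSegments(), f)
    expect_equal(readLines(f), "chr2\t208605000\t209745000\tamp1\t7")

    writeBed(GRanges(copyNumber = numeric()), f)
    expect_equal(readLines(f), character(0))

    gr <- GRanges("1", IRanges(1, 100), copyNumber = 1500)
    writeBed(gr, f)
    expect_match(readLines(f), "\t1000$")

    ## coordinate conversion is self-inverse: importing the BED recovers
    ## the original 1-based closed interval
    writeBed(idExampleSegments(), f)
    back <- rtracklayer::import(f, format = "BED")
    expect_equal(start(back), start(idExampleSegments()))
    expect_equal(end(back), end(idExampleSegments()))
})

test_that("Circos links carry one line per junction and one color per amplicon", {
    ampA <- findAmplicons(idExampleSegments(), idExampleSvs())
    f <- withr::local_tempfile()
    writeCircosLinks(ampA, f)
    lines <- readLines(f)
    expect_length(lines, 1)
    expect_match(lines, "^chr2 209745116 209745116 chr2 209749286 209749286 color=")

    ## zero junctions -> empty file
    lone <- findAmplicons(idExampleSegments(), StructuralVariants())
    writeCircosLinks(lone, f)
    expect_length(readLines(f), 0)

    ## two amplicons on separate chromosomes get distinct colors
    segs <- suppressWarnings(c(idExampleSegments(), trExampleSegments()))
    svs <- StructuralVariants(
        chrom1 = c("2", "4"), pos1 = c(209745116, 49121104),
        orient1 = c("+", "+"), chrom2 = c("2", "4"),
        pos2 = c(209749286, 49151838), orient2 = c("-", "-"),
        svType = c("INV", "ITX"), size = c(4170, 30734),
        score = c(99, 99), numReads = c(37, 20))
    two <- findAmplicons(segs, svs)
    writeCircosLinks(two, f)
    colors <- sub(".*color=", "", readLines(f))
    expect_length(unique(colors), 2)
})

test_that("the packaged cohort has the expected shape and counts", {
    cohort <- readCohort()
    expect_equal(nrow(cohort), 40)
    counts <- table(cohort$structure)
    expect_equal(unname(counts[["ID"]]), 24)
    expect_equal(unname(counts[["DM"]]), 4)
    expect_equal(unname(counts[["other"]]), 2)
    expect_equal(unname(counts[["NA"]]), 10)

    r <- cohort[cohort$sample_id == "p-6890", ]
    expect_equal(r$primary_site, "Gastric")
    expect_equal(r$stage, "IV")
    expect_equal(r$cn_wgs, 84)
    expect_equal(r$cn_ddpcr, 106)
    expect_equal(r$structure, "ID")
    expect_equal(r$n_segments, 18)

    r <- cohort[cohort$sample_id == "p-13", ]
    expect_equal(r$stage, "IIA")
    expect_equal(r$structure, "ID")
    expect_equal(r$n_segments, 1)
})

test_that("cohort parsing validates its vocabulary", {
    cohort <- readCohort()
    f <- withr::local_tempfile()
    bad <- cohort
    bad$stage[1] <- "IIIB"
    write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCohort(f), "unknown stage")
    bad <- cohort
    bad$structure[1] <- "HSR"
    write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCohort(f), "unknown structure")
})
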