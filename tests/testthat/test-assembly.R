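test_that("breakends associate with the nearest segment edge within tolerance", {
    ## fold-back breakends sit at the right edge
    assoc <- associateBreakends(idExampleSvs(), idExampleSegments())
    expect_equal(assoc$side1, "RIGHT")
    expect_equal(assoc$dist1, 116)
    expect_equal(assoc$side2, "RIGHT")
    expect_equal(assoc$seg1, 1L)

    ## a breakend 41 kb inside a segment still matches the left edge
    assoc <- associateBreakends(trExampleSvs(), trExampleSegments())
    expect_equal(assoc$side1, "LEFT")
    expect_equal(assoc$dist1, 41103)  # 49121104 - 49080001
    expect_equal(assoc$side2, "RIGHT")

    ## no segments on the breakend's chromosome -> NONE
    sv <- StructuralVariants(chrom1 = "9", pos1 = 1e6, orient1 = "+",
        chrom2 = "9", pos2 = 2e6, orient2 = "-", svType = "INV",
        size = 1e6, score = 99, numReads = 5)
    assoc <- associateBreakends(sv, idExampleSegments())
    expect_equal(assoc$side1, "NONE")
    expect_true(is.na(assoc$seg1))
})

test_that("deep-internal breakends are INTERNAL and midpoints break LEFT", {
    seg <- GRanges("1", IRanges(1, 2001), copyNumber = 10)
    mid <- StructuralVariants(chrom1 = "1", pos1 = 1001, orient1 = "+",
        chrom2 = "1", pos2 = 1001, orient2 = "-", svType = "INV",
        size = 0, score = 99, numReads = 5)
    assoc <- associateBreakends(mid, seg, AssemblyConfig(edgeTol = 1500))
    expect_equal(assoc$side1, "LEFT")  # equidistant -> LEFT

    assoc <- associateBreakends(mid, seg, AssemblyConfig(edgeTol = 100))
    expect_equal(assoc$side1, "INTERNAL")
    expect_equal(assoc$seg1, 1L)
})

test_that("widening the edge tolerance never loses edge associations", {
    withr::local_seed(17)
    segs <- sort(randomSegments(6))
    n <- 20
    sv <- StructuralVariants(
        chrom1 = sample(c("1", "17"), n, TRUE),
        pos1 = sample(1:4e6, n), orient1 = rep("+", n),
        chrom2 = sample(c("1", "17"), n, TRUE),
        pos2 = sample(1:4e6, n), orient2 = rep("-", n),
        svType = sample(c("INV", "ITX", "CTX"), n, TRUE),
        size = rep(100, n), score = rep(99, n), numReads = rep(5L, n))
    counts <- vapply(c(0, 1000, 15000, 45000, 100000), function(tol) {
        a <- associateBreakends(sv, segs, AssemblyConfig(edgeTol = tol))
        sum(c(a$side1, a$side2) %in% c("LEFT", "RIGHT"))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("segments connect into amplicons by shared junctions", {
    ## cross-chromosome link joins two segments into one amplicon
    amps <- findAmplicons(dmExampleSegments(), dmExampleSvs())
    expect_length(amps, 1)
    expect_equal(nSegments(amps), 2L)

    ## a lone segment with no call is a single-segment amplicon
    amps <- findAmplicons(idExampleSegments(), StructuralVariants())
    expect_length(amps, 1)
    expect_equal(nSegments(amps), 1L)
    expect_equal(nrow(junctions(amps[[1]])), 0)

    ## three segments with one linking call -> components of size 2 and 1
    segs <- GRanges(c("1", "1", "17"),
                    IRanges(c(1, 1000001, 1), c(150000, 1150000, 150000)),
                    copyNumber = 10)
    sv <- StructuralVariants(chrom1 = "1", pos1 = 150000, orient1 = "+",
        chrom2 = "1", pos2 = 1000001, orient2 = "-", svType = "ITX",
        size = 850001, score = 99, numReads = 8)
    assoc <- associateBreakends(sv, segs)
    amps <- buildAmplicons(segs, sv, assoc)
    expect_length(amps, 2)
    expect_equal(sort(nSegments(amps)), c(1L, 2L))
})

test_that("every prepared segment lands in exactly one amplicon", {
    withr::local_seed(19)
    for (i in 1:10) {
        segs <- sort(randomSegments(sample(2:8, 1)))
        amps <- buildAmplicons(segs, StructuralVariants(),
                               associateBreakends(StructuralVariants(),
                                                  segs))
        total <- sum(nSegments(amps))
        expect_equal(total, length(segs))
    }
})

test_that("assembly matches a brute-force union-find oracle", {
    withr::local_seed(23)
    for (trial in 1:60) {
        n <- sample(1:10, 1)
        ## segments far apart on one chromosome
        segs <- GRanges("1", IRanges(seq(1, by = 2e6, length.out = n),
                                     width = 1e6), copyNumber = 10)
        nEdge <- sample(0:6, 1)
        edges <- if (nEdge && n >= 2)
            t(replicate(nEdge, sample(n, 2))) else
            matrix(integer(), 0, 2)
        if (nrow(edges)) {
            sv <- StructuralVariants(
                chrom1 = rep("1", nrow(edges)),
                pos1 = start(segs)[edges[, 1]],
                orient1 = rep("+", nrow(edges)),
                chrom2 = rep("1", nrow(edges)),
                pos2 = end(segs)[edges[, 2]],
                orient2 = rep("-", nrow(edges)),
                svType = rep("ITX", nrow(edges)),
                size = rep(100, nrow(edges)),
                score = rep(99, nrow(edges)),
                numReads = rep(5L, nrow(edges)))
        } else sv <- StructuralVariants()
        assoc <- associateBreakends(sv, segs, AssemblyConfig(edgeTol = 0))
        amps <- buildAmplicons(segs, sv, assoc)
        ## membership per segment from the amplicon partition
        got <- integer(n)
        for (k in seq_along(amps)) {
            idx <- match(start(ampliconSegments(amps[[k]])), start(segs))
            got[idx] <- k
        }
        want <- unionFindComponents(n, edges)
        ## same partition up to labels
        expect_equal(length(unique(got)), length(unique(want)))
        expect_true(all(tapply(want, got, function(v)
            length(unique(v)) == 1)))
    }
})

test_that("gene lookup returns the amplicon with the largest overlap", {
    segs <- suppressWarnings(c(idExampleSegments(), trExampleSegments()))
    amps <- findAmplicons(segs, StructuralVariants())
    gene <- GRanges("2", IRanges(208800001, 208850000))
    hit <- ampliconForGene(amps, gene)
    expect_equal(as.character(seqnames(ampliconSegments(hit))), "2")

    expect_null(ampliconForGene(amps, GRanges("9", IRanges(1, 1000))))

    ## overlaps of 10 kb vs 1 kb -> the 10 kb amplicon wins
    segs <- GRanges(c("1", "1"), IRanges(c(1, 100001), c(50000, 200000)),
                    copyNumber = 10)
    amps <- findAmplicons(segs, StructuralVariants())
    gene <- GRanges("1", IRanges(40001, 101000))
    hit <- ampliconForGene(amps, gene)
    expect_equal(start(ampliconSegments(hit)), 1)
})

test_that("the minimal common region is the interval intersection", {
    gr <- GRanges("17", IRanges(c(37125001, 36960001),
                                c(38715000, 38070000)))
    mcr <- minimalCommonRegion(gr)
    expect_equal(start(mcr), 37125001)
    expect_equal(end(mcr), 38070000)

    one <- GRanges("17", IRanges(100, 200))
    expect_equal(minimalCommonRegion(one), one)

    disjoint <- GRanges("17", IRanges(c(1, 1000), c(100, 2000)))
    expect_null(minimalCommonRegion(disjoint))

    mixed <- GRanges(c("1", "2"), IRanges(1, 100))
    expect_error(minimalCommonRegion(mixed), "multiple chromosomes")
})
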