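## Shared fixtures: the three worked amplicon examples (a fold-back
## inversion, a head-to-tail tandem junction, a cross-chromosome link),
## small random-input generators, and brute-force oracles.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

idExampleSegments <- function()
    GRanges("2", IRanges(208605001, 209745000), copyNumber = 7,
            status = "gain")

idExampleSvs <- function()
    StructuralVariants(chrom1 = "2", pos1 = 209745116, orient1 = "61+0-",
                       chrom2 = "2", pos2 = 209749286, orient2 = "0+37-",
                       svType = "INV", size = 4170, score = 99,
                       numReads = 37)

trExampleSegments <- function()
    GRanges("4", IRanges(49080001, 49170000), copyNumber = 54,
            status = "gain")

trExampleSvs <- function()
    StructuralVariants(chrom1 = "4", pos1 = 49121104, orient1 = "20+0-",
                       chrom2 = "4", pos2 = 49151838, orient2 = "0+20-",
                       svType = "ITX", size = 30734, score = 99,
                       numReads = 20)

dmExampleSegments <- function()
    GRanges(c("5", "8"),
            IRanges(c(2145001, 117405001), c(3210000, 119805000)),
            copyNumber = c(12, 12), status = c("gain", "gain"))

dmExampleSvs <- function()
    StructuralVariants(chrom1 = "5", pos1 = 3209205, orient1 = "25+0-",
                       chrom2 = "8", pos2 = 119804561, orient2 = "0+25-",
                       svType = "CTX", size = -1, score = 99,
                       numReads = 25)

writeFixturePair <- function(segments, svs, dir = NULL) {
    if (is.null(dir)) {
        dir <- tempfile("fixture")
        dir.create(dir)
    }
    cnv <- file.path(dir, "cnv.tsv")
    sv <- file.path(dir, "sv.txt")
    writeFreecCnv(segments, cnv)
    writeBreakdancer(svs, sv)
    list(cnv = cnv, sv = sv, dir = dir)
}

## random non-overlapping bin-quantized segments on a couple of chromosomes
randomSegments <- function(n, bin = 15000L, chroms = c("1", "17")) {
    chrom <- sample(chroms, n, replace = TRUE)
    starts <- sample(1:200, n) * bin + 1L
    widths <- sample(1:20, n, replace = TRUE) * bin
    gr <- GRanges(chrom, IRanges(starts, starts + widths - 1L),
                  copyNumber = sample(6:40, n, replace = TRUE))
    gr[!duplicated(paste(chrom, starts))]
}

## one-row junction table in the layout buildAmplicons produces
mkJunction <- function(svType, seg1, side1, seg2, side2,
                       chrom1 = "17", pos1 = 1e6, chrom2 = "17",
                       pos2 = 2e6) {
    DataFrame(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
              svType = svType, score = 99, numReads = 30L,
              seg1 = as.integer(seg1), side1 = side1,
              dist1 = 100, seg2 = as.integer(seg2), side2 = side2,
              dist2 = 100,
              evidentiary = !(side1 == "INTERNAL" & side2 == "INTERNAL") &
                  side1 != "NONE" & side2 != "NONE",
              vote = NA_character_, rationale = NA_character_)
}

mkAmplicon <- function(junctionList, nSeg = 2) {
    segs <- GRanges(rep("17", nSeg),
                    IRanges(seq(1, by = 2e6, length.out = nSeg),
                            width = 1e6), copyNumber = rep(10, nSeg))
    jn <- if (length(junctionList)) do.call(rbind, junctionList)
          else NULL
    Amplicon("ampX", segs, jn)
}

## brute-force union-find over an edge list: oracle for the
## connected-component assembly
unionFindComponents <- function(n, edges) {
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    if (nrow(edges)) {
        for (r in seq_len(nrow(edges))) {
            a <- find(edges[r, 1]); b <- find(edges[r, 2])
            if (a != b) parent[b] <- a
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}

## two-sided Fisher p by explicit enumeration with exact choose()
## arithmetic: for all tables with the observed margins, sum the
## probabilities not exceeding the observed table's
fisherEnumOracle <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    m <- a + c; n <- b + d; k <- a + b
    support <- max(0, k - n):min(k, m)
    prob <- choose(m, support) * choose(n, k - support) /
        choose(m + n, k)
    pobs <- prob[support == a]
    min(1, sum(prob[prob <= pobs * (1 + 1e-7)]))
}
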