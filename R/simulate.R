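## Call-level simulator: generates ground-truth amplicon architectures and
## emits matching copy-number and structural-variant caller files with
## configurable noise. Simulation operates at the call level (segment and
## breakpoint files), not the read level, because the pipeline consumes
## caller output.

.DM_CHROM_POOL <- c("5", "8", "10", "20", "2", "3", "9", "11", "12", "6",
                    "7", "13")

## default geometry: an ERBB2-like single segment on 17q for ID/TR
## (37,125,000-38,715,000; ~1.6 Mb, near the cohort's median amplicon
## size), and ~1.07 Mb segments starting at 2,145,000 on distinct
## chromosomes for DM. All boundaries are multiples of the 15-kb bin.
.ID_CHROM <- "17"
.ID_START <- 37125001
.ID_END <- 38715000
.EXTRA_LEN <- 300000L    # extra ID segments: 20 bins
.EXTRA_GAP <- 150000L    # gap between ID segments: 10 bins
.DM_START <- 2145001
.DM_END <- 3210000

.binAlign <- function(start, end, bin) {
    c(floor((start - 1) / bin) * bin + 1, ceiling(end / bin) * bin)
}

.truthGeometry <- function(architecture, nSegments, copyNumber, bin) {
    if (architecture %in% c("ID", "TR")) {
        starts <- .ID_START
        ends <- .ID_END
        if (nSegments > 1) {
            for (k in seq_len(nSegments - 1)) {
                s <- ends[k] + .EXTRA_GAP + 1
                starts <- c(starts, s)
                ends <- c(ends, s + .EXTRA_LEN - 1)
            }
        }
        chroms <- rep(.ID_CHROM, nSegments)
    } else {
        if (nSegments > length(.DM_CHROM_POOL))
            stop("at most ", length(.DM_CHROM_POOL),
                 " DM segments supported")
        chroms <- .DM_CHROM_POOL[seq_len(nSegments)]
        starts <- rep(.DM_START, nSegments)
        ends <- rep(.DM_END, nSegments)
    }
    if (any(ends - starts + 1 < bin))
        stop("impossible geometry: segment shorter than one bin")
    GRanges(chroms, IRanges(starts, ends),
            copyNumber = rep(copyNumber, nSegments))
}

## exact truth junctions implementing each architecture's signature; edge
## offsets mirror realistic read-pair breakend localisation (1e2-4e4 bp)
.truthJunctions <- function(architecture, segments) {
    chrom <- as.character(seqnames(segments))
    s <- start(segments); e <- end(segments)
    jn <- switch(architecture,
        ID = {
            ## fold-back inversion at the right (telomeric) edge of the
            ## first segment: head-to-head self-junction
            out <- data.frame(chrom1 = chrom[1], pos1 = e[1] + 116,
                              chrom2 = chrom[1], pos2 = e[1] + 4286,
                              svType = "INV", stringsAsFactors = FALSE)
            ## additional segments chain via inter-segment inversions from
            ## the centromeric end, as seen in multi-segment amplicons
            if (length(segments) > 1) {
                k <- seq_len(length(segments) - 1)
                out <- rbind(out, data.frame(
                    chrom1 = chrom[k], pos1 = e[k] - 150,
                    chrom2 = chrom[k + 1], pos2 = s[k + 1] + 150,
                    svType = "INV", stringsAsFactors = FALSE))
            }
            out
        },
        TR = {
            if (length(segments) != 1)
                stop("a tandem-repeat amplicon is a single repeated ",
                     "segment; nSegments must be 1")
            ## head-to-tail junction: opposite edges of the one segment
            data.frame(chrom1 = chrom[1], pos1 = s[1] + 41104,
                       chrom2 = chrom[1], pos2 = e[1] - 18162,
                       svType = "ITX", stringsAsFactors = FALSE)
        },
        DM = {
            if (length(segments) < 2)
                stop("a double minute needs >= 2 segments from ",
                     "different chromosomes")
            k <- seq_len(length(segments) - 1)
            data.frame(chrom1 = chrom[k], pos1 = e[k] - 795,
                       chrom2 = chrom[k + 1], pos2 = e[k + 1] - 439,
                       svType = "CTX", stringsAsFactors = FALSE)
        })
    DataFrame(jn)
}

#' Simulate one amplicon dataset
#'
#' Generates a ground-truth amplicon of the requested architecture --
#' \code{"ID"} (fold-back inversion at a segment edge, the minimal
#' breakage-fusion-bridge signature, plus inter-segment inversions when
#' more than one segment is requested), \code{"TR"} (a single segment with
#' a head-to-tail junction), or \code{"DM"} (segments on distinct
#' chromosomes chained by interchromosomal junctions) -- then degrades it
#' into caller-style output under the noise model: segment boundaries
#' rounded outward to bin multiples, Gaussian breakend jitter, true-call
#' dropout, and spurious low-score calls at a Poisson rate.
#'
#' Identical seed and configuration give identical output.
#'
#' @param architecture \code{"ID"}, \code{"TR"} or \code{"DM"}.
#' @param nSegments number of truth segments (default 1 for ID/TR, 2 for
#'   DM; TR supports only 1, DM needs at least 2).
#' @param copyNumber copy number of every truth segment; default 16, the
#'   cohort median ERBB2 copy number. Must be at least 1.
#' @param noise a \code{\link{NoiseConfig}}.
#' @param seed integer seed; overrides \code{noise@seed} when given.
#' @return A list with elements \code{truth}
#'   (\code{\link{SimulatedTruth-class}}), \code{segments} (noisy
#'   \code{GRanges} in the copy-number caller's shape) and \code{svs}
#'   (noisy \code{\link{StructuralVariants}}).
#' @examples
#' sim <- simulateAmplicon("DM", seed = 1)
#' sim$truth
#' @importFrom stats rnorm rpois runif
#' @export
simulateAmplicon <- function(architecture = c("ID", "TR", "DM"),
                             nSegments = NULL, copyNumber = 16,
                             noise = NoiseConfig(), seed = NULL) {
    architecture <- match.arg(architecture)
    if (is.null(nSegments))
        nSegments <- if (architecture == "DM") 2L else 1L
    nSegments <- as.integer(nSegments)
    if (nSegments < 1) stop("'nSegments' must be >= 1")
    if (copyNumber < 1) stop("'copyNumber' must be >= 1")
    if (is.null(seed) && !is.na(noise@seed)) seed <- noise@seed
    if (!is.null(seed)) set.seed(seed)

    truthSegs <- .truthGeometry(architecture, nSegments, copyNumber,
                                noise@binSize)
    truthJn <- .truthJunctions(architecture, truthSegs)
    truth <- new("SimulatedTruth", architecture = architecture,
                 segments = truthSegs, junctions = truthJn,
                 seed = if (is.null(seed)) NA_integer_ else
                     as.integer(seed))

    ## CNV output: truth boundaries rounded outward to bin multiples
    aligned <- t(vapply(seq_along(truthSegs), function(i)
        .binAlign(start(truthSegs)[i], end(truthSegs)[i], noise@binSize),
        numeric(2)))
    segs <- GRanges(seqnames(truthSegs), IRanges(aligned[, 1], aligned[, 2]),
                    copyNumber = truthSegs$copyNumber,
                    status = rep("gain", length(truthSegs)))

    ## SV output: jittered true junctions minus dropout, plus spurious calls
    jdf <- as.data.frame(truthJn)
    kept <- runif(nrow(jdf)) >= noise@svDropout
    jitter <- function(p) round(p + rnorm(length(p), 0, noise@jitterSd))
    pos1 <- jitter(jdf$pos1); pos2 <- jitter(jdf$pos2)
    scores <- sample(seq(noise@scoreTrue[1], noise@scoreTrue[2]),
                     nrow(jdf), replace = TRUE)
    reads <- sample(20:60, nrow(jdf), replace = TRUE)
    jdf <- data.frame(chrom1 = jdf$chrom1, pos1 = pos1,
                      chrom2 = jdf$chrom2, pos2 = pos2,
                      svType = jdf$svType, score = scores,
                      numReads = reads, stringsAsFactors = FALSE)[kept, ,
                                                                  drop = FALSE]
    nSpur <- rpois(1, noise@spuriousRate)
    if (nSpur > 0) {
        type <- sample(.SV_TYPES, nSpur, replace = TRUE)
        c1 <- sample(as.character(1:22), nSpur, replace = TRUE)
        p1 <- round(runif(nSpur, 1e6, 2e8))
        size <- round(runif(nSpur, 1e3, 1e5))
        c2 <- ifelse(type == "CTX",
                     vapply(c1, function(ch)
                         sample(setdiff(as.character(1:22), ch), 1),
                         character(1)),
                     c1)
        p2 <- ifelse(type == "CTX", round(runif(nSpur, 1e6, 2e8)),
                     p1 + size)
        jdf <- rbind(jdf, data.frame(
            chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2, svType = type,
            score = sample(seq(noise@scoreSpurious[1],
                               noise@scoreSpurious[2]), nSpur,
                           replace = TRUE),
            numReads = sample(2:10, nSpur, replace = TRUE),
            stringsAsFactors = FALSE))
    }
    svs <- StructuralVariants(
        chrom1 = jdf$chrom1, pos1 = jdf$pos1,
        orient1 = sprintf("%d+%d-", jdf$numReads, jdf$numReads),
        chrom2 = jdf$chrom2, pos2 = jdf$pos2,
        orient2 = sprintf("%d+%d-", jdf$numReads, jdf$numReads),
        svType = jdf$svType,
        size = ifelse(jdf$svType == "CTX", -1, abs(jdf$pos2 - jdf$pos1)),
        score = jdf$score, numReads = jdf$numReads)

    list(truth = truth, segments = segs, svs = svs)
}

#' Write a simulated dataset to caller-dialect files
#'
#' Emits one copy-number segment file, one structural-variant file (with
#' \code{"#"} header) and one machine-readable ground-truth sidecar
#' (JSON). The files round-trip through \code{\link{readFreecCnv}} /
#' \code{\link{readBreakdancer}} to the in-memory objects, and identical
#' simulations give byte-identical files.
#'
#' @param sim result of \code{\link{simulateAmplicon}}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default \code{"sim"}.
#' @return Named character vector of the three paths (\code{cnv},
#'   \code{sv}, \code{truth}), invisibly.
#' @importFrom jsonlite write_json
#' @export
emitDataset <- function(sim, dir, prefix = "sim") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(cnv = file.path(dir, paste0(prefix, "_cnv.tsv")),
               sv = file.path(dir, paste0(prefix, "_sv.txt")),
               truth = file.path(dir, paste0(prefix, "_truth.json")))
    writeFreecCnv(sim$segments, paths[["cnv"]])
    writeBreakdancer(sim$svs, paths[["sv"]])
    truth <- sim$truth
    segs <- truth@segments
    write_json(list(
        architecture = truth@architecture,
        seed = truth@seed,
        segments = data.frame(
            chrom = as.character(seqnames(segs)), start = start(segs),
            end = end(segs), copyNumber = segs$copyNumber),
        junctions = as.data.frame(truth@junctions)),
        paths[["truth"]], auto_unbox = TRUE, digits = NA, na = "null")
    invisible(paths)
}

#' Recovered structure of a simulated dataset
#'
#' Runs the full pipeline (preprocessing, assembly, classification) on a
#' simulation's caller-style output and returns the structure call of the
#' amplicon overlapping the first truth segment -- the quantity scored in
#' recovery experiments.
#'
#' @param sim result of \code{\link{simulateAmplicon}}.
#' @param prep a \code{\link{PrepConfig}}.
#' @param assembly an \code{\link{AssemblyConfig}}.
#' @return A single character: \code{"ID"}, \code{"TR"}, \code{"DM"},
#'   \code{"other"} or \code{"NA"} (also returned when the truth region
#'   yields no amplicon at all).
#' @export
recoverStructure <- function(sim, prep = PrepConfig(),
                             assembly = AssemblyConfig()) {
    amps <- findAmplicons(sim$segments, sim$svs, prep, assembly)
    target <- ampliconForGene(amps, sim$truth@segments[1])
    if (is.null(target)) return("NA")
    structureCall(target)
}
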