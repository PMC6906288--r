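## Associate structural-variant breakends with segment edges and connect
## segments into amplicons.

.SIDE_LEVELS <- c("LEFT", "RIGHT", "INTERNAL", "NONE")

## Associate one breakend (chrom, pos) with the segments. Returns
## list(seg, side, dist). Edge proximity wins over containment: the nearest
## segment edge within edgeTol is used; otherwise INTERNAL if the breakend
## falls inside a segment; otherwise NONE. A LEFT/RIGHT tie within one
## segment resolves to the nearer edge, an exact midpoint to LEFT; ties
## between segments resolve to the lower segment index (segments are sorted
## by chromosome and start, so this is deterministic).
.associateOne <- function(chrom, pos, segChrom, segStart, segEnd, edgeTol) {
    onChrom <- which(segChrom == chrom)
    if (!length(onChrom))
        return(list(seg = NA_integer_, side = "NONE", dist = NA_real_))
    dLeft <- abs(pos - segStart[onChrom])
    dRight <- abs(pos - segEnd[onChrom])
    side <- ifelse(dLeft <= dRight, "LEFT", "RIGHT")
    dist <- pmin(dLeft, dRight)
    best <- which.min(dist)
    if (dist[best] <= edgeTol)
        return(list(seg = onChrom[best], side = side[best],
                    dist = dist[best]))
    inside <- which(pos >= segStart[onChrom] & pos <= segEnd[onChrom])
    if (length(inside))
        return(list(seg = onChrom[inside[1]], side = "INTERNAL",
                    dist = dist[inside[1]]))
    list(seg = NA_integer_, side = "NONE", dist = NA_real_)
}

#' Associate structural-variant breakends with segment edges
#'
#' For each breakend of each call, finds the nearest segment edge on the
#' same chromosome. A breakend within \code{edgeTol} bp of an edge is
#' associated with that edge (\code{LEFT} or \code{RIGHT}); a breakend
#' inside a segment but farther than \code{edgeTol} from both edges is
#' \code{INTERNAL}; a breakend neither near nor inside any amplified
#' segment is \code{NONE}. Ties between the two edges of one segment break
#' toward the nearer edge, an exact midpoint toward \code{LEFT}.
#'
#' @param svs score-filtered \code{\link{StructuralVariants}}.
#' @param segments copy-number filtered and merged segments
#'   (\code{GRanges}).
#' @param config an \code{\link{AssemblyConfig}}.
#' @return A \code{DataFrame} with one row per call: \code{seg1},
#'   \code{side1}, \code{dist1}, \code{seg2}, \code{side2}, \code{dist2},
#'   where \code{seg*} index into \code{segments}.
#' @examples
#' seg <- GenomicRanges::GRanges("2",
#'     IRanges::IRanges(208605001, 209745000), copyNumber = 7)
#' sv <- StructuralVariants(chrom1 = "2", pos1 = 209745116, orient1 = "+",
#'     chrom2 = "2", pos2 = 209749286, orient2 = "-", svType = "INV",
#'     size = 4170, score = 99, numReads = 37)
#' associateBreakends(sv, seg)
#' @export
associateBreakends <- function(svs, segments, config = AssemblyConfig()) {
    df <- as.data.frame(svs)
    n <- nrow(df)
    segChrom <- as.character(seqnames(segments))
    segStart <- start(segments)
    segEnd <- end(segments)
    out <- DataFrame(seg1 = integer(n), side1 = character(n),
                     dist1 = numeric(n), seg2 = integer(n),
                     side2 = character(n), dist2 = numeric(n))
    for (i in seq_len(n)) {
        a1 <- .associateOne(df$chrom1[i], df$pos1[i], segChrom, segStart,
                            segEnd, config@edgeTol)
        a2 <- .associateOne(df$chrom2[i], df$pos2[i], segChrom, segStart,
                            segEnd, config@edgeTol)
        out$seg1[i] <- a1$seg; out$side1[i] <- a1$side
        out$dist1[i] <- a1$dist
        out$seg2[i] <- a2$seg; out$side2[i] <- a2$side
        out$dist2[i] <- a2$dist
    }
    out
}

#' Connect segments into amplicons
#'
#' Segments are graph nodes; a structural variant whose two breakends
#' associate (\code{LEFT}/\code{RIGHT}) with the edges of two different
#' segments is an edge. Connected components become amplicons; a segment
#' with no linking call forms a single-segment amplicon, so copy-number-only
#' samples are still reported (with structure \code{NA}) rather than
#' dropped. Each amplicon collects every call with at least one breakend
#' associated with one of its member segments; calls whose breakends are
#' both \code{INTERNAL}, or with one breakend \code{NONE} (linking
#' amplified to unamplified genome), are recorded but flagged
#' non-evidentiary.
#'
#' @param segments prepared segments (\code{GRanges}, sorted).
#' @param svs the score-filtered \code{\link{StructuralVariants}}.
#' @param associations result of \code{\link{associateBreakends}}.
#' @param config an \code{\link{AssemblyConfig}}.
#' @return An \code{\link{AmpliconSet}}; amplicons are ordered and named
#'   (\code{"amp1"}, \code{"amp2"}, ...) by their first segment's position.
#' @importFrom igraph make_empty_graph add_edges components
#' @export
buildAmplicons <- function(segments, svs, associations,
                           config = AssemblyConfig()) {
    n <- length(segments)
    if (n == 0) return(AmpliconSet())
    assoc <- as.data.frame(associations)
    linking <- which(assoc$side1 %in% c("LEFT", "RIGHT") &
                     assoc$side2 %in% c("LEFT", "RIGHT") &
                     assoc$seg1 != assoc$seg2)
    g <- make_empty_graph(n, directed = FALSE)
    if (length(linking))
        g <- add_edges(g, rbind(assoc$seg1[linking], assoc$seg2[linking]))
    membership <- components(g)$membership
    ## relabel components in order of first (positional) occurrence
    comp <- match(membership, unique(membership))
    svdf <- as.data.frame(svs)
    amps <- lapply(seq_len(max(comp)), function(k) {
        members <- which(comp == k)
        touches <- (assoc$seg1 %in% members & assoc$side1 != "NONE") |
                   (assoc$seg2 %in% members & assoc$side2 != "NONE")
        jrows <- which(!is.na(touches) & touches)
        jn <- .emptyJunctions()
        if (length(jrows)) {
            jn <- DataFrame(
                chrom1 = svdf$chrom1[jrows], pos1 = svdf$pos1[jrows],
                chrom2 = svdf$chrom2[jrows], pos2 = svdf$pos2[jrows],
                svType = svdf$svType[jrows], score = svdf$score[jrows],
                numReads = svdf$numReads[jrows],
                seg1 = assoc$seg1[jrows], side1 = assoc$side1[jrows],
                dist1 = assoc$dist1[jrows], seg2 = assoc$seg2[jrows],
                side2 = assoc$side2[jrows], dist2 = assoc$dist2[jrows],
                evidentiary = !(assoc$side1[jrows] == "INTERNAL" &
                                assoc$side2[jrows] == "INTERNAL") &
                              assoc$side1[jrows] != "NONE" &
                              assoc$side2[jrows] != "NONE",
                vote = NA_character_, rationale = NA_character_)
        }
        Amplicon(sprintf("amp%d", k), segments[members], jn)
    })
    AmpliconSet(amps)
}

#' Find the amplicon containing a gene
#'
#' Returns the amplicon one of whose segments overlaps the gene interval by
#' at least one bp; when several amplicons overlap, the one with the
#' largest total overlap wins (a deterministic, order-independent
#' tie-break).
#'
#' @param amplicons an \code{\link{AmpliconSet}}.
#' @param gene a length-one \code{GRanges} for the gene of interest (for
#'   ERBB2 amplicon reporting, the ERBB2 locus).
#' @return The matching \code{\link{Amplicon}}, or \code{NULL} when no
#'   segment overlaps the gene.
#' @export
ampliconForGene <- function(amplicons, gene) {
    stopifnot(length(gene) == 1)
    gChrom <- as.character(seqnames(gene))
    gStart <- start(gene); gEnd <- end(gene)
    ov <- vapply(as.list(amplicons), function(a) {
        segs <- ampliconSegments(a)
        same <- as.character(seqnames(segs)) == gChrom
        w <- pmin(end(segs)[same], gEnd) - pmax(start(segs)[same], gStart) + 1
        sum(pmax(w, 0))
    }, numeric(1))
    if (!length(ov) || max(ov) == 0) return(NULL)
    amplicons[[which.max(ov)]]
}

#' Minimal common region of a set of intervals
#'
#' The intersection of intervals on one chromosome: maximum of starts to
#' minimum of ends. Used to report the minimally amplified region shared by
#' a set of amplicons.
#'
#' @param intervals \code{GRanges}, all on a single chromosome.
#' @return A length-one \code{GRanges}, or \code{NULL} when the
#'   intersection is empty.
#' @examples
#' gr <- GenomicRanges::GRanges("17",
#'     IRanges::IRanges(c(37125001, 36960001), c(38715000, 38070000)))
#' minimalCommonRegion(gr)
#' @export
minimalCommonRegion <- function(intervals) {
    if (!length(intervals)) return(NULL)
    chroms <- unique(as.character(seqnames(intervals)))
    if (length(chroms) > 1)
        stop("intervals span multiple chromosomes: ",
             paste(chroms, collapse = ", "))
    s <- max(start(intervals)); e <- min(end(intervals))
    if (s > e) return(NULL)
    GRanges(chroms, IRanges(s, e))
}
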