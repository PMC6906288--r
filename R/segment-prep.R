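## Preprocessing of raw caller output: copy-number floor, score floor, and
## unification of consecutive amplified segments.

#' Filter segments by copy number
#'
#' Keeps segments whose copy number reaches the threshold
#' (\code{copyNumber >= cnThreshold}); input order is preserved. The
#' default floor of 6 copies matches the ddPCR positivity rule of six
#' copies or more.
#'
#' @param segments \code{GRanges} with a \code{copyNumber} metadata column.
#' @param config a \code{\link{PrepConfig}}.
#' @return The retained subset of \code{segments}.
#' @examples
#' gr <- GenomicRanges::GRanges("17", IRanges::IRanges(1, 15000),
#'                              copyNumber = c(5))
#' length(filterSegmentsByCN(gr, PrepConfig()))
#' @export
filterSegmentsByCN <- function(segments, config = PrepConfig()) {
    segments[segments$copyNumber >= config@cnThreshold]
}

#' Filter structural variants by confidence score
#'
#' Keeps calls with \code{score >= scoreThreshold}; the default of 99
#' removes breakpoints scored below 99 (a call scored exactly 99 is kept).
#'
#' @param svs a \code{\link{StructuralVariants}} object.
#' @param config a \code{\link{PrepConfig}}.
#' @return The retained subset of \code{svs}.
#' @export
filterSvsByScore <- function(svs, config = PrepConfig()) {
    svs[svScore(svs) >= config@scoreThreshold]
}

#' Unify consecutive amplified segments
#'
#' Segments on the same chromosome separated by at most \code{mergeGap} bp
#' are unified into one segment spanning both. The merged copy number is
#' the length-weighted mean of the parts, rounded to the nearest integer,
#' which preserves the total copies-times-basepairs mass. Output is sorted
#' by chromosome and start. The operation is idempotent.
#'
#' @param segments \code{GRanges} with a \code{copyNumber} column
#'   (typically already copy-number filtered).
#' @param config a \code{\link{PrepConfig}}; \code{mergeGap} defaults to one
#'   15-kb bin, because adjacent amplified bins are one event.
#' @return A sorted, merged \code{GRanges} with recomputed
#'   \code{copyNumber}.
#' @examples
#' gr <- GenomicRanges::GRanges("17",
#'     IRanges::IRanges(c(1, 15001), c(15000, 45000)), copyNumber = c(6, 12))
#' mergeConsecutiveSegments(gr)  # one segment, CN 10
#' @importFrom GenomicRanges reduce width
#' @importFrom GenomeInfoDb sortSeqlevels
#' @export
mergeConsecutiveSegments <- function(segments, config = PrepConfig()) {
    if (length(segments) <= 1) return(segments)
    segments <- sortSeqlevels(segments)
    segments <- sort(segments)
    merged <- reduce(segments, min.gapwidth = config@mergeGap + 1L,
                     with.revmap = TRUE)
    cn <- vapply(merged$revmap, function(ii) {
        w <- width(segments[ii])
        round(sum(segments$copyNumber[ii] * w) / sum(w))
    }, numeric(1))
    merged$revmap <- NULL
    merged$copyNumber <- cn
    if (!is.null(segments$status))
        merged$status <- rep(NA_character_, length(merged))
    merged
}
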