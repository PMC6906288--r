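## Readers and writers for the upstream caller dialects and report formats.
## Copy-number input follows the Control-FREEC "_CNVs" layout (tab- or
## whitespace-delimited: chromosome, start, end, predicted copy number,
## optional status); structural variants follow the BreakDancer layout
## ("#"-prefixed headers, >= 10 tab-separated columns). Both are 1-based
## inclusive on disk and are kept as GRanges / breakend positions internally;
## BED output converts to 0-based half-open at the boundary.

#' Normalize chromosome names
#'
#' The two upstream callers disagree about the \code{"chr"} prefix in the
#' wild; internally one convention is enforced.
#'
#' @param x character vector of chromosome names.
#' @param chromPrefix \code{"strip"} (default) removes a \code{"chr"}
#'   prefix, \code{"add"} ensures one, \code{"keep"} leaves names as-is.
#' @return normalized character vector.
#' @examples
#' normalizeChrom(c("chr2", "17"))
#' normalizeChrom(c("chr2", "17"), "add")
#' @export
normalizeChrom <- function(x, chromPrefix = c("strip", "add", "keep")) {
    chromPrefix <- match.arg(chromPrefix)
    switch(chromPrefix,
        strip = sub("^chr", "", x),
        add = paste0("chr", sub("^chr", "", x)),
        keep = x)
}

.splitFields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

#' Read copy-number segments (Control-FREEC "_CNVs" dialect)
#'
#' Parses a segment-level copy-number file: one row per segment with
#' chromosome, start, end (1-based inclusive), predicted copy number and an
#' optional status column. No filtering is applied; every row becomes a
#' segment.
#'
#' @param path path to the file.
#' @param chromPrefix chromosome-name normalization, see
#'   \code{\link{normalizeChrom}}.
#' @return A \code{GRanges} with metadata columns \code{copyNumber}
#'   (numeric) and \code{status} (character, \code{NA} when absent).
#'   An empty file yields an empty \code{GRanges}.
#' @examples
#' f <- tempfile()
#' writeLines("2\t208605001\t209745000\t7\tgain", f)
#' readFreecCnv(f)
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
readFreecCnv <- function(path, chromPrefix = c("strip", "add", "keep")) {
    chromPrefix <- match.arg(chromPrefix)
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (!length(idx)) return(.emptySegments())
    rows <- lapply(lines[idx], .splitFields)
    for (i in seq_along(rows)) {
        f <- rows[[i]]
        if (length(f) < 4)
            stop(sprintf("line %d: expected >= 4 columns, got %d",
                         idx[i], length(f)))
        coords <- suppressWarnings(as.numeric(f[2:4]))
        if (anyNA(coords))
            stop(sprintf("line %d: non-numeric coordinates or copy number",
                         idx[i]))
        if (coords[1] >= coords[2])
            stop(sprintf("line %d: degenerate interval (start >= end)",
                         idx[i]))
        if (coords[3] < 0)
            stop(sprintf("line %d: negative copy number", idx[i]))
    }
    chrom <- normalizeChrom(vapply(rows, `[`, character(1), 1), chromPrefix)
    start <- vapply(rows, function(f) as.numeric(f[2]), numeric(1))
    end <- vapply(rows, function(f) as.numeric(f[3]), numeric(1))
    cn <- vapply(rows, function(f) as.numeric(f[4]), numeric(1))
    status <- vapply(rows, function(f)
        if (length(f) >= 5) f[5] else NA_character_, character(1))
    GRanges(chrom, IRanges(start = start, end = end),
            copyNumber = cn, status = status)
}

.emptySegments <- function() {
    GRanges(copyNumber = numeric(), status = character())
}

#' Write copy-number segments in the same segment-file dialect
#'
#' Inverse of \code{\link{readFreecCnv}}: tab-separated chromosome, start,
#' end (1-based inclusive), copy number, status.
#'
#' @param segments \code{GRanges} with a \code{copyNumber} metadata column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @importFrom GenomicRanges start end seqnames
#' @export
writeFreecCnv <- function(segments, path) {
    status <- segments$status
    if (is.null(status)) status <- rep("gain", length(segments))
    status[is.na(status)] <- "gain"
    lines <- sprintf("%s\t%d\t%d\t%g\t%s",
                     as.character(seqnames(segments)),
                     start(segments), end(segments),
                     segments$copyNumber, status)
    writeLines(lines, path)
    invisible(path)
}

.BD_HEADER <- paste("#Chr1", "Pos1", "Orientation1", "Chr2", "Pos2",
                    "Orientation2", "Type", "Size", "Score", "num_Reads",
                    sep = "\t")

#' Read structural-variant calls (BreakDancer dialect)
#'
#' Parses a tab-delimited structural-variant file with \code{"#"}-prefixed
#' header lines and at least ten data columns: Chr1, Pos1, Orientation1,
#' Chr2, Pos2, Orientation2, Type (DEL/INS/INV/ITX/CTX), Size, Score,
#' num_Reads. Orientation strings are retained verbatim; classification
#' works from the Type column.
#'
#' @inheritParams readFreecCnv
#' @return A \code{\link{StructuralVariants}} object (empty for a file with
#'   only header lines).
#' @examples
#' f <- tempfile()
#' writeLines(c("#Chr1\tPos1\t...",
#'   "2\t209745116\t61+0-\t2\t209749286\t0+37-\tINV\t4170\t99\t37"), f)
#' readBreakdancer(f)
#' @export
readBreakdancer <- function(path, chromPrefix = c("strip", "add", "keep")) {
    chromPrefix <- match.arg(chromPrefix)
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (!length(idx)) return(StructuralVariants())
    rows <- lapply(lines[idx], function(l) strsplit(l, "\t")[[1]])
    for (i in seq_along(rows)) {
        f <- rows[[i]]
        if (length(f) < 10)
            stop(sprintf("line %d: expected >= 10 columns, got %d",
                         idx[i], length(f)))
        if (!f[7] %in% .SV_TYPES)
            stop(sprintf("line %d: unknown SV type '%s'", idx[i], f[7]))
        sc <- suppressWarnings(as.numeric(f[9]))
        if (is.na(sc) || sc < 0 || sc > 100)
            stop(sprintf("line %d: score '%s' outside [0, 100]",
                         idx[i], f[9]))
        if (anyNA(suppressWarnings(as.numeric(f[c(2, 5)]))))
            stop(sprintf("line %d: non-numeric breakend position", idx[i]))
    }
    col <- function(j) vapply(rows, `[`, character(1), j)
    StructuralVariants(
        chrom1 = normalizeChrom(col(1), chromPrefix),
        pos1 = as.numeric(col(2)), orient1 = col(3),
        chrom2 = normalizeChrom(col(4), chromPrefix),
        pos2 = as.numeric(col(5)), orient2 = col(6),
        svType = col(7), size = as.numeric(col(8)),
        score = as.numeric(col(9)), numReads = as.integer(col(10)))
}

#' Write structural-variant calls in the same dialect
#'
#' @param svs a \code{\link{StructuralVariants}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBreakdancer <- function(svs, path) {
    df <- as.data.frame(svs)
    lines <- sprintf("%s\t%d\t%s\t%s\t%d\t%s\t%s\t%d\t%g\t%d",
                     df$chrom1, as.integer(df$pos1), df$orient1,
                     df$chrom2, as.integer(df$pos2), df$orient2,
                     df$svType, as.integer(df$size), df$score, df$numReads)
    writeLines(c(.BD_HEADER, lines), path)
    invisible(path)
}

#' Write amplicon segments as BED5
#'
#' Standard BED (0-based half-open): chrom, start, end, name, score. Each
#' segment is named after its amplicon; the score is the segment copy
#' number capped at 1000 (the BED score ceiling).
#'
#' @param x an \code{\link{AmpliconSet}}, or a \code{GRanges} with a
#'   \code{copyNumber} column.
#' @param path output path.
#' @param names segment names; defaults to amplicon ids (for a bare
#'   \code{GRanges}, \code{"amp1"} for every row).
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(x, path, names = NULL) {
    if (is(x, "AmpliconSet")) {
        segs <- unlist(GenomicRanges::GRangesList(
            lapply(as.list(x), ampliconSegments)), use.names = FALSE)
        names <- rep(ampliconId(x), nSegments(x))
        x <- segs
    } else if (is.null(names)) {
        names <- rep("amp1", length(x))
    }
    if (!length(x)) {
        writeLines(character(), path)
        return(invisible(path))
    }
    lines <- sprintf("%s\t%d\t%d\t%s\t%g",
                     normalizeChrom(as.character(seqnames(x)), "add"),
                     start(x) - 1L, end(x), names,
                     pmin(x$copyNumber, 1000))
    writeLines(lines, path)
    invisible(path)
}

.CIRCOS_COLORS <- c("red", "blue", "green", "orange", "purple", "dgrey",
                    "dred", "dblue", "dgreen", "dorange", "dpurple")

#' Write amplicon junctions as a Circos link file
#'
#' One link line per junction (\code{chrom1 start1 end1 chrom2 start2 end2
#' color=<tag>}); all junctions of one amplicon share one color tag so each
#' amplified unit is visually distinct.
#'
#' @param x an \code{\link{AmpliconSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCircosLinks <- function(x, path) {
    lines <- character()
    amps <- as.list(x)
    for (i in seq_along(amps)) {
        jn <- junctions(amps[[i]])
        if (!nrow(jn)) next
        color <- .CIRCOS_COLORS[(i - 1L) %% length(.CIRCOS_COLORS) + 1L]
        lines <- c(lines, sprintf("%s %d %d %s %d %d color=%s",
            normalizeChrom(jn$chrom1, "add"), as.integer(jn$pos1),
            as.integer(jn$pos1), normalizeChrom(jn$chrom2, "add"),
            as.integer(jn$pos2), as.integer(jn$pos2), color))
    }
    writeLines(lines, path)
    invisible(path)
}

.STAGES <- c("IA", "IIA", "IIB", "IIIA", "IIIC", "IV", "LR")

#' Read a cohort characteristics table
#'
#' Reads a tab-separated cohort table with columns \code{sample_id},
#' \code{primary_site}, \code{stage} (IA/IIA/IIB/IIIA/IIIC/IV/LR, where LR
#' is a local recurrence), \code{er_status} (\code{+}, \code{-},
#' \code{unknown}), \code{cn_wgs} and \code{cn_ddpcr} (the ERBB2 copy
#' number measured by low-coverage WGS and by ddPCR), \code{structure}
#' (ID/DM/other/NA) and \code{n_segments}.
#'
#' @param path path to the TSV; defaults to the packaged cohort of 40
#'   ERBB2-amplified HER2+ tumours.
#' @return A \code{data.frame}, one row per sample; \code{structure} is a
#'   character column in which \code{"NA"} denotes "no structure assigned".
#' @examples
#' cohort <- readCohort()
#' table(cohort$structure)
#' @importFrom utils read.delim
#' @export
readCohort <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "her2_cohort.tsv",
                            package = "ampliconStructure", mustWork = TRUE)
    df <- read.delim(path, colClasses = "character", na.strings = NULL)
    need <- c("sample_id", "primary_site", "stage", "er_status",
              "cn_wgs", "cn_ddpcr", "structure", "n_segments")
    if (!all(need %in% names(df)))
        stop("cohort table must have columns: ", paste(need, collapse = ", "))
    bad <- setdiff(unique(df$stage), .STAGES)
    if (length(bad))
        stop("unknown stage token(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$er_status), c("+", "-", "unknown"))
    if (length(bad))
        stop("unknown ER status token(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$structure), .STRUCTURE_LEVELS)
    if (length(bad))
        stop("unknown structure token(s): ", paste(bad, collapse = ", "))
    df$cn_wgs <- as.numeric(df$cn_wgs)
    df$cn_ddpcr <- as.numeric(df$cn_ddpcr)
    df$n_segments <- as.integer(df$n_segments)
    if (any(df$n_segments < 1, na.rm = TRUE))
        stop("'n_segments' must be >= 1")
    if (any(df$cn_wgs < 0 | df$cn_ddpcr < 0, na.rm = TRUE))
        stop("copy numbers must be >= 0")
    df
}
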