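## End-to-end pipeline: preprocessing -> breakend association -> amplicon
## assembly -> structure calling, plus the file-level entry points behind
## the command-line tool.

#' Assemble and classify amplicons
#'
#' The full in-memory pipeline: filter segments by copy number, unify
#' consecutive segments, filter structural variants by score, associate
#' breakends with segment edges, connect segments into amplicons, and call
#' each amplicon's structure.
#'
#' @param segments raw copy-number segments (\code{GRanges} with a
#'   \code{copyNumber} column, e.g. from \code{\link{readFreecCnv}}).
#' @param svs raw \code{\link{StructuralVariants}} (e.g. from
#'   \code{\link{readBreakdancer}}).
#' @param prep a \code{\link{PrepConfig}}.
#' @param assembly an \code{\link{AssemblyConfig}}.
#' @return An \code{\link{AmpliconSet}} with structure calls.
#' @examples
#' seg <- GenomicRanges::GRanges("2",
#'     IRanges::IRanges(208605001, 209745000), copyNumber = 7)
#' sv <- StructuralVariants(chrom1 = "2", pos1 = 209745116, orient1 = "+",
#'     chrom2 = "2", pos2 = 209749286, orient2 = "-", svType = "INV",
#'     size = 4170, score = 99, numReads = 37)
#' structureCall(findAmplicons(seg, sv))
#' @export
findAmplicons <- function(segments, svs, prep = PrepConfig(),
                          assembly = AssemblyConfig()) {
    kept <- filterSegmentsByCN(segments, prep)
    merged <- mergeConsecutiveSegments(kept, prep)
    svKept <- filterSvsByScore(svs, prep)
    assoc <- associateBreakends(svKept, merged, assembly)
    amps <- buildAmplicons(merged, svKept, assoc, assembly)
    AmpliconSet(lapply(as.list(amps), callStructure))
}

#' Run the caller on files
#'
#' Reads a copy-number segment file and a structural-variant file, runs
#' \code{\link{findAmplicons}}, and writes the requested reports into
#' \code{outDir}: the per-amplicon TSV, a BED5 of amplicon segments and a
#' Circos link file. Stage-by-stage counts (segments and calls kept or
#' removed, amplicons, structure calls) are logged via \code{message}.
#'
#' @param cnvPath copy-number segment file (FREEC-style dialect).
#' @param svPath structural-variant file (BreakDancer-style dialect).
#' @param outDir output directory, created if missing.
#' @param genePath optional BED file of gene coordinates; when given, a
#'   \code{gene_amplicons.tsv} mapping each gene to its containing
#'   amplicon (if any) is also written.
#' @param prep a \code{\link{PrepConfig}}.
#' @param assembly an \code{\link{AssemblyConfig}}.
#' @param formats subset of \code{c("tsv", "bed", "circos")}.
#' @param chromPrefix chromosome-name normalization for the inputs.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the \code{AmpliconSet}, the report
#'   \code{data.frame} and the output paths.
#' @importFrom rtracklayer import
#' @export
runCall <- function(cnvPath, svPath, outDir, genePath = NULL,
                    prep = PrepConfig(), assembly = AssemblyConfig(),
                    formats = c("tsv", "bed", "circos"),
                    chromPrefix = "strip", quiet = FALSE) {
    formats <- match.arg(formats, several.ok = TRUE)
    say <- function(...) if (!quiet) message(sprintf(...))
    segments <- readFreecCnv(cnvPath, chromPrefix)
    svs <- readBreakdancer(svPath, chromPrefix)
    kept <- filterSegmentsByCN(segments, prep)
    say("segments: %d read, %d kept (CN >= %g), %d removed",
        length(segments), length(kept), prep@cnThreshold,
        length(segments) - length(kept))
    merged <- mergeConsecutiveSegments(kept, prep)
    say("segments after merging (gap <= %d bp): %d", prep@mergeGap,
        length(merged))
    svKept <- filterSvsByScore(svs, prep)
    say("SV calls: %d read, %d kept (score >= %g), %d removed",
        length(svs), length(svKept), prep@scoreThreshold,
        length(svs) - length(svKept))
    assoc <- associateBreakends(svKept, merged, assembly)
    amps <- buildAmplicons(merged, svKept, assoc, assembly)
    amps <- AmpliconSet(lapply(as.list(amps), callStructure))
    calls <- structureCall(amps)
    say("amplicons: %d (%s)", length(amps),
        if (length(amps)) paste(sprintf("%s=%s", ampliconId(amps), calls),
                                collapse = ", ") else "none")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    paths <- character()
    if ("tsv" %in% formats) {
        paths["report"] <- file.path(outDir, "amplicons.tsv")
        writeAmpliconReport(amps, paths[["report"]])
    }
    if ("bed" %in% formats) {
        paths["bed"] <- file.path(outDir, "amplicons.bed")
        writeBed(amps, paths[["bed"]])
    }
    if ("circos" %in% formats) {
        paths["circos"] <- file.path(outDir, "links.circos")
        writeCircosLinks(amps, paths[["circos"]])
    }
    if (!is.null(genePath)) {
        genes <- rtracklayer::import(genePath, format = "BED")
        GenomeInfoDb::seqlevels(genes) <- normalizeChrom(
            GenomeInfoDb::seqlevels(genes),
            if (chromPrefix == "keep") "keep" else chromPrefix)
        rows <- lapply(seq_along(genes), function(i) {
            amp <- ampliconForGene(amps, genes[i])
            data.frame(
                gene = if (!is.null(genes$name)) genes$name[i] else
                    sprintf("gene%d", i),
                amplicon_id = if (is.null(amp)) NA_character_ else
                    ampliconId(amp),
                structure = if (is.null(amp)) NA_character_ else
                    structureCall(amp),
                n_segments = if (is.null(amp)) NA_integer_ else
                    nSegments(amp),
                stringsAsFactors = FALSE)
        })
        paths["genes"] <- file.path(outDir, "gene_amplicons.tsv")
        write.table(do.call(rbind, rows), paths[["genes"]], sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    invisible(list(amplicons = amps, report = ampliconReport(amps),
                   paths = paths))
}

#' Simulate datasets to files
#'
#' Generates \code{n} simulated datasets of one architecture and writes
#' each as a copy-number file, a structural-variant file and a truth
#' sidecar. Dataset \code{i} uses seed \code{seed + i - 1}, so a run is
#' fully reproducible.
#'
#' @param outDir output directory.
#' @param architecture \code{"ID"}, \code{"TR"} or \code{"DM"}.
#' @param n number of datasets.
#' @param nSegments,copyNumber,noise passed to
#'   \code{\link{simulateAmplicon}}.
#' @param seed integer base seed.
#' @param quiet suppress the truth summary message.
#' @return Invisibly, a \code{data.frame} summarising each dataset's truth
#'   (architecture, segments, junctions, seed, file prefix).
#' @export
runSimulate <- function(outDir, architecture = c("ID", "TR", "DM"), n = 1,
                        nSegments = NULL, copyNumber = 16,
                        noise = NoiseConfig(), seed = 1, quiet = FALSE) {
    architecture <- match.arg(architecture)
    rows <- lapply(seq_len(n), function(i) {
        s <- seed + i - 1L
        sim <- simulateAmplicon(architecture, nSegments, copyNumber,
                                noise, seed = s)
        prefix <- sprintf("%s_%03d", tolower(architecture), i)
        emitDataset(sim, outDir, prefix)
        data.frame(prefix = prefix, architecture = architecture,
                   n_segments = length(sim$truth@segments),
                   n_junctions = nrow(sim$truth@junctions), seed = s,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!quiet)
        message(sprintf("wrote %d %s dataset(s) to %s", n, architecture,
                        outDir))
    invisible(out)
}

#' Cohort summary entry point
#'
#' Computes the cohort summary, the stage-by-segment-count contingency
#' derived from the table, Fisher's exact p-value for a configurable 2x2
#' (by default the contingency reported for the packaged cohort, see
#' \code{\link{reportedStageTable}}), and the ddPCR/lcWGS agreement
#' statistic; optionally writes everything as JSON.
#'
#' @param path cohort TSV (default: the packaged cohort).
#' @param contingency 2x2 matrix for the Fisher test; default
#'   \code{\link{reportedStageTable}()} when the packaged cohort is used,
#'   otherwise the table derived from the cohort itself.
#' @param outPath optional path for a JSON summary.
#' @return A list: the \code{\link{cohortSummary}} fields plus
#'   \code{contingency} (derived), \code{fisher_table},
#'   \code{fisher_p} and \code{r_squared}.
#' @importFrom jsonlite write_json
#' @export
runCohort <- function(path = NULL, contingency = NULL, outPath = NULL) {
    samples <- readCohort(path)
    summary <- cohortSummary(samples)
    derived <- stageContingency(samples)
    if (is.null(contingency))
        contingency <- if (is.null(path)) reportedStageTable() else derived
    r2 <- if (nrow(samples) >= 3 && sd(samples$cn_wgs) > 0 &&
              sd(samples$cn_ddpcr) > 0)
        squaredPearson(samples$cn_ddpcr, samples$cn_wgs) else NA_real_
    out <- c(summary, list(
        contingency = derived,
        fisher_table = contingency,
        fisher_p = fisherExactTwoSided(contingency),
        r_squared = r2))
    if (!is.null(outPath)) {
        json <- out
        json$structure_counts <- as.list(summary$structure_counts)
        json$contingency <- as.data.frame(derived)
        json$fisher_table <- as.data.frame(contingency)
        write_json(json, outPath, auto_unbox = TRUE, digits = NA,
                   na = "null")
    }
    out
}
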