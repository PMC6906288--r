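#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
NULL

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Preprocessing configuration
#'
#' Thresholds applied to raw caller output before amplicons are assembled:
#' the copy-number floor below which segments are discarded, the confidence
#' floor below which structural-variant calls are discarded, and the gap and
#' bin geometry used when unifying consecutive amplified segments.
#'
#' Both filters use "keep at or above threshold" semantics, consistent with
#' the ddPCR positivity rule of six copies or more. The merge gap defaults to
#' one 15-kb bin: copy-number segmentation from low-coverage data is
#' bin-quantized, so two amplified segments separated by no more than one bin
#' are treated as a single event.
#'
#' @param cnThreshold minimum copy number (copies per cell) a segment must
#'   reach to be kept. Default 6.
#' @param scoreThreshold minimum structural-variant confidence score
#'   (0--100) to keep a call. Default 99.
#' @param mergeGap maximum gap in bp between consecutive same-chromosome
#'   segments that are unified. Default 15000 (one bin).
#' @param binSize copy-number bin width in bp. Default 15000.
#' @return A \code{PrepConfig} object.
#' @examples
#' PrepConfig()
#' PrepConfig(cnThreshold = 10)
#' @export
PrepConfig <- function(cnThreshold = 6, scoreThreshold = 99,
                       mergeGap = 15000L, binSize = 15000L) {
    new("PrepConfig",
        cnThreshold = as.numeric(cnThreshold),
        scoreThreshold = as.numeric(scoreThreshold),
        mergeGap = as.integer(mergeGap),
        binSize = as.integer(binSize))
}

#' @rdname PrepConfig
#' @export
setClass("PrepConfig",
    representation(cnThreshold = "numeric", scoreThreshold = "numeric",
                   mergeGap = "integer", binSize = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@cnThreshold) != 1 || object@cnThreshold <= 0)
            msg <- c(msg, "'cnThreshold' must be a single positive number")
        if (length(object@scoreThreshold) != 1 ||
            object@scoreThreshold < 0 || object@scoreThreshold > 100)
            msg <- c(msg, "'scoreThreshold' must lie in [0, 100]")
        if (length(object@mergeGap) != 1 || object@mergeGap < 0)
            msg <- c(msg, "'mergeGap' must be >= 0")
        if (length(object@binSize) != 1 || object@binSize <= 0)
            msg <- c(msg, "'binSize' must be > 0")
        if (length(msg)) msg else TRUE
    })

#' Amplicon assembly configuration
#'
#' @param edgeTol maximum distance in bp between a structural-variant
#'   breakend and a segment edge for the two to be considered coincident.
#'   Default 45000 bp (three 15-kb copy-number bins), which accommodates the
#'   bin quantization of segment boundaries plus breakend localisation error
#'   of read-pair callers at low coverage.
#' @return An \code{AssemblyConfig} object.
#' @examples
#' AssemblyConfig(edgeTol = 30000)
#' @export
AssemblyConfig <- function(edgeTol = 45000L) {
    new("AssemblyConfig", edgeTol = as.integer(edgeTol))
}

#' @rdname AssemblyConfig
#' @export
setClass("AssemblyConfig", representation(edgeTol = "integer"),
    validity = function(object) {
        if (length(object@edgeTol) != 1 || object@edgeTol < 0)
            "'edgeTol' must be a single value >= 0" else TRUE
    })

#' Simulator noise configuration
#'
#' Controls the noise model that degrades ground-truth amplicon
#' architectures into realistic caller output: segment boundaries are
#' quantized to copy-number bins, breakends receive Gaussian jitter, true
#' structural-variant calls are dropped at a fixed probability, and spurious
#' calls with sub-threshold confidence scores are added at a Poisson rate.
#'
#' @param binSize copy-number bin width in bp (segment boundaries are
#'   rounded outward to multiples of this). Default 15000.
#' @param jitterSd standard deviation in bp of the Gaussian jitter applied
#'   to each true breakend. Default 5000.
#' @param svDropout probability in [0, 1] that a true structural-variant
#'   call is lost. Default 0.
#' @param spuriousRate expected number of spurious structural-variant calls
#'   per dataset (Poisson). Default 0.
#' @param scoreTrue integer range (length 2) of confidence scores assigned
#'   to true calls. Default c(99, 100).
#' @param scoreSpurious integer score range for spurious calls.
#'   Default c(25, 98), i.e. entirely below the default score filter.
#' @param seed optional integer seed driving all randomness.
#' @return A \code{NoiseConfig} object.
#' @examples
#' NoiseConfig(svDropout = 0.25, seed = 1)
#' @export
NoiseConfig <- function(binSize = 15000L, jitterSd = 5000, svDropout = 0,
                        spuriousRate = 0, scoreTrue = c(99L, 100L),
                        scoreSpurious = c(25L, 98L), seed = NULL) {
    new("NoiseConfig",
        binSize = as.integer(binSize), jitterSd = as.numeric(jitterSd),
        svDropout = as.numeric(svDropout),
        spuriousRate = as.numeric(spuriousRate),
        scoreTrue = as.integer(scoreTrue),
        scoreSpurious = as.integer(scoreSpurious),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname NoiseConfig
#' @export
setClass("NoiseConfig",
    representation(binSize = "integer", jitterSd = "numeric",
                   svDropout = "numeric", spuriousRate = "numeric",
                   scoreTrue = "integer", scoreSpurious = "integer",
                   seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@binSize <= 0) msg <- c(msg, "'binSize' must be > 0")
        if (object@jitterSd < 0) msg <- c(msg, "'jitterSd' must be >= 0")
        if (object@svDropout < 0 || object@svDropout > 1)
            msg <- c(msg, "'svDropout' must lie in [0, 1]")
        if (object@spuriousRate < 0)
            msg <- c(msg, "'spuriousRate' must be >= 0")
        if (length(object@scoreTrue) != 2 ||
            any(object@scoreTrue < 0 | object@scoreTrue > 100))
            msg <- c(msg, "'scoreTrue' must be two scores in [0, 100]")
        if (length(object@scoreSpurious) != 2 ||
            any(object@scoreSpurious < 0 | object@scoreSpurious > 100))
            msg <- c(msg, "'scoreSpurious' must be two scores in [0, 100]")
        if (length(msg)) msg else TRUE
    })

## ---------------------------------------------------------------------------
## StructuralVariants
## ---------------------------------------------------------------------------

.SV_TYPES <- c("DEL", "INS", "INV", "ITX", "CTX")

.SV_COLUMNS <- c("chrom1", "pos1", "orient1", "chrom2", "pos2", "orient2",
                 "svType", "size", "score", "numReads")

#' Structural-variant call set
#'
#' A set of paired-breakend structural-variant calls as emitted by a
#' read-pair caller: each call has two breakends (chromosome, position,
#' read-orientation summary), a type among DEL, INS, INV, ITX
#' (intrachromosomal translocation) and CTX (interchromosomal
#' translocation), a size estimate, a confidence score in [0, 100] and the
#' number of supporting read pairs.
#'
#' @param chrom1,pos1,orient1 first breakend: chromosome, 1-based position,
#'   orientation string (e.g. \code{"37+42-"}).
#' @param chrom2,pos2,orient2 second breakend.
#' @param svType character vector of call types (DEL/INS/INV/ITX/CTX).
#' @param size caller size estimate in bp (may be negative for CTX).
#' @param score confidence score in [0, 100].
#' @param numReads supporting read-pair count.
#' @return A \code{StructuralVariants} object.
#' @examples
#' sv <- StructuralVariants(chrom1 = "2", pos1 = 209745116, orient1 = "61+0-",
#'                          chrom2 = "2", pos2 = 209749286, orient2 = "0+37-",
#'                          svType = "INV", size = 4170, score = 99,
#'                          numReads = 37)
#' svType(sv)
#' @aliases StructuralVariants-class
#' @export
StructuralVariants <- function(chrom1 = character(), pos1 = integer(),
                               orient1 = character(), chrom2 = character(),
                               pos2 = integer(), orient2 = character(),
                               svType = character(), size = integer(),
                               score = numeric(), numReads = integer()) {
    calls <- DataFrame(
        chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
        orient1 = as.character(orient1), chrom2 = as.character(chrom2),
        pos2 = as.numeric(pos2), orient2 = as.character(orient2),
        svType = as.character(svType), size = as.numeric(size),
        score = as.numeric(score), numReads = as.integer(numReads))
    new("StructuralVariants", calls = calls)
}

#' @export
setClass("StructuralVariants", representation(calls = "DataFrame"),
    validity = function(object) {
        calls <- object@calls
        msg <- character()
        if (!all(.SV_COLUMNS %in% colnames(calls)))
            return("missing structural-variant columns")
        if (nrow(calls) == 0) return(TRUE)
        if (!all(calls$svType %in% .SV_TYPES))
            msg <- c(msg, sprintf("unknown SV type: %s",
                paste(setdiff(unique(calls$svType), .SV_TYPES),
                      collapse = ", ")))
        if (any(calls$score < 0 | calls$score > 100))
            msg <- c(msg, "scores must lie in [0, 100]")
        if (any(calls$numReads < 0))
            msg <- c(msg, "'numReads' must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' @export
setMethod("length", "StructuralVariants", function(x) nrow(x@calls))

#' @export
setMethod("[", "StructuralVariants",
    function(x, i, j, ..., drop = TRUE) {
        initialize(x, calls = x@calls[i, , drop = FALSE])
    })

#' @describeIn StructuralVariants coerce to a plain data.frame
#' @param x a \code{StructuralVariants} object.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "StructuralVariants",
    function(x, ...) as.data.frame(x@calls))

#' @export
setMethod("c", "StructuralVariants", function(x, ...) {
    args <- list(x, ...)
    initialize(x, calls = do.call(rbind, lapply(args, function(a) a@calls)))
})

#' @export
setMethod("show", "StructuralVariants", function(object) {
    cat(sprintf("StructuralVariants with %d call(s)\n", length(object)))
    if (length(object)) {
        tab <- table(factor(object@calls$svType, levels = .SV_TYPES))
        cat("  types:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    }
})

#' @describeIn StructuralVariants SV type of each call
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))

#' @export
setMethod("svType", "StructuralVariants", function(x) x@calls$svType)

#' @describeIn StructuralVariants confidence score of each call
#' @export
setGeneric("svScore", function(x) standardGeneric("svScore"))

#' @export
setMethod("svScore", "StructuralVariants", function(x) x@calls$score)

## ---------------------------------------------------------------------------
## Amplicon and AmpliconSet
## ---------------------------------------------------------------------------

.STRUCTURE_LEVELS <- c("ID", "TR", "DM", "other", "NA")

#' Amplicon: a connected set of amplified segments
#'
#' An amplicon groups copy-number segments that structural-variant junctions
#' connect into one amplified unit, together with those junctions and, once
#' \code{\link{callStructure}} has run, a structure call: \code{"ID"}
#' (inverted duplication, the head-to-head fold-back signature of
#' breakage-fusion-bridge cycles), \code{"TR"} (head-to-tail tandem repeat),
#' \code{"DM"} (double minute, segments of different genomic origin linked
#' together), \code{"other"} (conflicting evidence) or \code{"NA"} (no
#' evidentiary junction).
#'
#' @slot ampliconId character identifier, e.g. \code{"amp1"}.
#' @slot segments \code{GRanges} of member segments with a
#'   \code{copyNumber} metadata column.
#' @slot junctions \code{DataFrame} of associated structural variants with
#'   their breakend-to-edge associations, evidentiary flag and (after
#'   classification) vote and rationale.
#' @slot structure structure call, one of ID/TR/DM/other/NA
#'   (\code{NA_character_} until called).
#' @slot votes named integer vector of evidentiary vote counts (ID, TR, DM).
#' @slot nEvidentiary number of evidentiary junction votes.
#' @aliases Amplicon-class
#' @export
setClass("Amplicon",
    representation(ampliconId = "character", segments = "GRanges",
                   junctions = "DataFrame", structure = "character",
                   votes = "integer", nEvidentiary = "integer"),
    prototype(structure = NA_character_,
              votes = c(ID = 0L, TR = 0L, DM = 0L),
              nEvidentiary = 0L),
    validity = function(object) {
        msg <- character()
        if (length(object@ampliconId) != 1)
            msg <- c(msg, "'ampliconId' must be a single string")
        if (length(object@segments) < 1)
            msg <- c(msg, "an amplicon must contain at least one segment")
        if (is.null(object@segments$copyNumber))
            msg <- c(msg, "segments need a 'copyNumber' metadata column")
        if (!is.na(object@structure) &&
            !object@structure %in% .STRUCTURE_LEVELS)
            msg <- c(msg, "invalid structure call")
        if (length(msg)) msg else TRUE
    })

#' @describeIn Amplicon constructor
#' @param ampliconId,segments,junctions,structure see slots.
#' @export
Amplicon <- function(ampliconId, segments, junctions = NULL,
                     structure = NA_character_) {
    if (is.null(junctions)) junctions <- .emptyJunctions()
    new("Amplicon", ampliconId = ampliconId, segments = segments,
        junctions = junctions, structure = structure)
}

.emptyJunctions <- function() {
    DataFrame(chrom1 = character(), pos1 = numeric(), chrom2 = character(),
              pos2 = numeric(), svType = character(), score = numeric(),
              numReads = integer(), seg1 = integer(), side1 = character(),
              dist1 = numeric(), seg2 = integer(), side2 = character(),
              dist2 = numeric(), evidentiary = logical(),
              vote = character(), rationale = character())
}

#' @describeIn Amplicon amplicon identifier
#' @param x an \code{Amplicon}.
#' @export
setGeneric("ampliconId", function(x) standardGeneric("ampliconId"))

#' @export
setMethod("ampliconId", "Amplicon", function(x) x@ampliconId)

#' @describeIn Amplicon member segments as a \code{GRanges}
#' @export
setGeneric("ampliconSegments", function(x) standardGeneric("ampliconSegments"))

#' @export
setMethod("ampliconSegments", "Amplicon", function(x) x@segments)

#' @describeIn Amplicon junction table
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @export
setMethod("junctions", "Amplicon", function(x) x@junctions)

#' @describeIn Amplicon number of member segments
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @export
setMethod("nSegments", "Amplicon", function(x) length(x@segments))

#' @describeIn Amplicon the structure call (NA_character_ if not yet called)
#' @export
setGeneric("structureCall", function(x) standardGeneric("structureCall"))

#' @export
setMethod("structureCall", "Amplicon", function(x) x@structure)

#' @describeIn Amplicon min/median/max of member-segment copy numbers
#' @export
setGeneric("cnSummary", function(x) standardGeneric("cnSummary"))

#' @importFrom stats median
#' @export
setMethod("cnSummary", "Amplicon", function(x) {
    cn <- x@segments$copyNumber
    c(min = min(cn), median = median(cn), max = max(cn))
})

#' @export
setMethod("show", "Amplicon", function(object) {
    cn <- cnSummary(object)
    cat(sprintf("Amplicon %s: %d segment(s), %d junction(s), CN %g-%g, structure %s\n",
        object@ampliconId, nSegments(object), nrow(object@junctions),
        cn[["min"]], cn[["max"]],
        ifelse(is.na(object@structure), "<uncalled>", object@structure)))
})

#' Set of amplicons
#'
#' A list-like container of \code{\link{Amplicon}} objects, the result of
#' \code{\link{buildAmplicons}} / \code{\link{findAmplicons}}.
#'
#' @aliases AmpliconSet-class
#' @export AmpliconSet
#' @exportClass AmpliconSet
setClass("AmpliconSet", contains = "SimpleList",
    prototype = prototype(elementType = "Amplicon"))

AmpliconSet <- function(...) {
    args <- list(...)
    if (length(args) == 1 && is.list(args[[1]]) && !is(args[[1]], "Amplicon"))
        args <- args[[1]]
    new("AmpliconSet", listData = unname(args))
}

#' @export
setMethod("show", "AmpliconSet", function(object) {
    cat(sprintf("AmpliconSet with %d amplicon(s)\n", length(object)))
    for (a in as.list(object)) show(a)
})

#' @describeIn Amplicon structure calls of all amplicons in a set
#' @export
setMethod("structureCall", "AmpliconSet",
    function(x) vapply(as.list(x), structureCall, character(1)))

#' @export
setMethod("nSegments", "AmpliconSet",
    function(x) vapply(as.list(x), nSegments, integer(1)))

#' @export
setMethod("ampliconId", "AmpliconSet",
    function(x) vapply(as.list(x), ampliconId, character(1)))

## ---------------------------------------------------------------------------
## SimulatedTruth
## ---------------------------------------------------------------------------

#' Ground truth of one simulated amplicon
#'
#' Records the architecture a simulation encoded, the exact (pre-noise)
#' segments and junction breakends, and the seed, so recovery by the
#' assembly/classification pipeline can be scored.
#'
#' @slot architecture one of ID, TR, DM.
#' @slot segments exact truth segments (\code{GRanges}, \code{copyNumber}
#'   metadata column).
#' @slot junctions \code{DataFrame} of exact breakend pairs with
#'   \code{svType}.
#' @slot seed integer seed used (NA if none).
#' @aliases SimulatedTruth-class
#' @export
setClass("SimulatedTruth",
    representation(architecture = "character", segments = "GRanges",
                   junctions = "DataFrame", seed = "integer"),
    validity = function(object) {
        if (!object@architecture %in% c("ID", "TR", "DM"))
            return("architecture must be one of ID, TR, DM")
        TRUE
    })

#' @export
setMethod("show", "SimulatedTruth", function(object) {
    cat(sprintf("SimulatedTruth: %s, %d segment(s), %d junction(s), seed %s\n",
        object@architecture, length(object@segments),
        nrow(object@junctions),
        ifelse(is.na(object@seed), "<none>", object@seed)))
})
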