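## Classify junctions as evidence for an amplicon structure and call the
## structure of each amplicon by strict majority vote.

.VOTE_LEVELS <- c("ID", "TR", "DM", "NONE")

#' Classify one junction as structure evidence
#'
#' Applies the classification rules in order:
#' \enumerate{
#'   \item both breakends \code{INTERNAL} (deep inside segments) ->
#'     \code{NONE}/\code{internal};
#'   \item any breakend \code{NONE} (linking amplified to unamplified
#'     genome) -> \code{NONE}/\code{unanchored};
#'   \item type DEL or INS -> \code{NONE}/\code{type_excluded} (only
#'     INV/ITX/CTX junctions carry structure evidence);
#'   \item type INV -> \code{ID}: a fold-back inversion
#'     (\code{fold_back_inversion}) when both breakends sit at the same
#'     edge of one segment -- the head-to-head signature of
#'     breakage-fusion-bridge -- otherwise \code{inter_segment_inversion};
#'   \item type ITX joining the two opposite edges of one segment
#'     (LEFT + RIGHT) -> \code{TR}/\code{head_to_tail_same_segment};
#'   \item type CTX -> \code{DM}/\code{inter_chromosomal};
#'   \item type ITX linking two different segments ->
#'     \code{DM}/\code{inter_segment_translocation};
#'   \item any remaining ITX pattern (both breakends at one edge, or one
#'     breakend internal) -> \code{NONE}/\code{type_excluded}.
#' }
#'
#' @param svType the call type (DEL/INS/INV/ITX/CTX).
#' @param seg1,side1 segment index and side (\code{LEFT}, \code{RIGHT},
#'   \code{INTERNAL}, \code{NONE}) of the first breakend, as produced by
#'   \code{\link{associateBreakends}}.
#' @param seg2,side2 likewise for the second breakend.
#' @return A list with elements \code{vote} (one of ID, TR, DM, NONE) and
#'   \code{rationale} (a short tag).
#' @examples
#' classifyJunction("INV", 1, "RIGHT", 1, "RIGHT") # fold-back -> ID
#' classifyJunction("ITX", 1, "LEFT", 1, "RIGHT")  # head-to-tail -> TR
#' classifyJunction("CTX", 1, "RIGHT", 2, "RIGHT") # cross-chromosome -> DM
#' @export
classifyJunction <- function(svType, seg1, side1, seg2, side2) {
    edge <- c("LEFT", "RIGHT")
    if (side1 == "INTERNAL" && side2 == "INTERNAL")
        return(list(vote = "NONE", rationale = "internal"))
    if (side1 == "NONE" || side2 == "NONE")
        return(list(vote = "NONE", rationale = "unanchored"))
    if (svType %in% c("DEL", "INS"))
        return(list(vote = "NONE", rationale = "type_excluded"))
    if (svType == "INV") {
        foldBack <- side1 %in% edge && side2 %in% edge &&
            !is.na(seg1) && !is.na(seg2) && seg1 == seg2 && side1 == side2
        return(list(vote = "ID",
                    rationale = if (foldBack) "fold_back_inversion"
                                else "inter_segment_inversion"))
    }
    if (svType == "CTX")
        return(list(vote = "DM", rationale = "inter_chromosomal"))
    ## ITX
    if (side1 %in% edge && side2 %in% edge && seg1 == seg2) {
        if (side1 != side2)
            return(list(vote = "TR",
                        rationale = "head_to_tail_same_segment"))
        return(list(vote = "NONE", rationale = "type_excluded"))
    }
    if (side1 %in% edge && side2 %in% edge && seg1 != seg2)
        return(list(vote = "DM", rationale = "inter_segment_translocation"))
    list(vote = "NONE", rationale = "type_excluded")
}

#' Call the structure of an amplicon
#'
#' Classifies every junction of the amplicon, discards non-voting
#' (\code{NONE}) junctions, and calls the structure by strict majority:
#' the class holding more than half of the evidentiary votes. With no
#' evidentiary vote the call is \code{"NA"}; with votes but no strict
#' majority (including exact ties) it is \code{"other"} -- mixtures are
#' surfaced for manual review, never resolved arbitrarily. The call is
#' permutation-invariant in the junction list.
#'
#' @param amplicon an \code{\link{Amplicon}} whose junctions carry breakend
#'   associations.
#' @return The amplicon with \code{vote}/\code{rationale} columns filled
#'   in, vote counts, and the \code{structure} slot set.
#' @export
callStructure <- function(amplicon) {
    jn <- junctions(amplicon)
    votes <- c(ID = 0L, TR = 0L, DM = 0L)
    if (nrow(jn)) {
        cls <- lapply(seq_len(nrow(jn)), function(i)
            classifyJunction(jn$svType[i], jn$seg1[i], jn$side1[i],
                             jn$seg2[i], jn$side2[i]))
        jn$vote <- vapply(cls, `[[`, character(1), "vote")
        jn$rationale <- vapply(cls, `[[`, character(1), "rationale")
        tab <- table(factor(jn$vote, levels = .VOTE_LEVELS))
        votes <- c(ID = unname(tab[["ID"]]), TR = unname(tab[["TR"]]),
                   DM = unname(tab[["DM"]]))
        votes <- vapply(votes, as.integer, integer(1))
    }
    nEvid <- sum(votes)
    structure <- if (nEvid == 0L) {
        "NA"
    } else if (max(votes) * 2L > nEvid) {
        names(votes)[which.max(votes)]
    } else {
        "other"
    }
    initialize(amplicon, junctions = jn, structure = structure,
               votes = votes, nEvidentiary = as.integer(nEvid))
}

#' Per-amplicon report table
#'
#' One row per amplicon: identifier, spanned regions, segment count,
#' copy-number summary, the structure call, vote counts and the rationale
#' tags behind them.
#'
#' @param amplicons an \code{\link{AmpliconSet}} (after
#'   \code{\link{callStructure}}).
#' @return A \code{data.frame}.
#' @export
ampliconReport <- function(amplicons) {
    amps <- as.list(amplicons)
    rows <- lapply(amps, function(a) {
        segs <- ampliconSegments(a)
        cn <- cnSummary(a)
        jn <- junctions(a)
        rat <- unique(jn$rationale[!is.na(jn$rationale) &
                                   jn$vote != "NONE"])
        data.frame(
            amplicon_id = ampliconId(a),
            chroms = paste(unique(as.character(seqnames(segs))),
                           collapse = ","),
            span = paste(sprintf("%s:%d-%d", as.character(seqnames(segs)),
                                 start(segs), end(segs)), collapse = ";"),
            n_segments = nSegments(a),
            cn_min = cn[["min"]], cn_median = cn[["median"]],
            cn_max = cn[["max"]],
            structure = structureCall(a),
            votes_ID = a@votes[["ID"]], votes_TR = a@votes[["TR"]],
            votes_DM = a@votes[["DM"]],
            n_evidentiary = a@nEvidentiary,
            rationales = paste(rat, collapse = ","),
            stringsAsFactors = FALSE)
    })
    if (!length(rows)) {
        return(data.frame(amplicon_id = character(), chroms = character(),
                          span = character(), n_segments = integer(),
                          cn_min = numeric(), cn_median = numeric(),
                          cn_max = numeric(), structure = character(),
                          votes_ID = integer(), votes_TR = integer(),
                          votes_DM = integer(), n_evidentiary = integer(),
                          rationales = character(),
                          stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
}

#' Write the per-amplicon report as TSV
#'
#' @param amplicons an \code{\link{AmpliconSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @importFrom utils write.table
#' @export
writeAmpliconReport <- function(amplicons, path) {
    write.table(ampliconReport(amplicons), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
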