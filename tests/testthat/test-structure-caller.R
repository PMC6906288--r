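test_that("junction classification follows the rule table", {
    cases <- list(
        ## fold-back inversion: both ends at one edge of one segment
        list("INV", 1, "RIGHT", 1, "RIGHT", "ID", "fold_back_inversion"),
        list("INV", 1, "LEFT", 1, "LEFT", "ID", "fold_back_inversion"),
        ## inversion linking two segments
        list("INV", 1, "RIGHT", 2, "LEFT", "ID", "inter_segment_inversion"),
        ## head-to-tail: opposite edges of one segment
        list("ITX", 1, "LEFT", 1, "RIGHT", "TR", "head_to_tail_same_segment"),
        list("ITX", 1, "RIGHT", 1, "LEFT", "TR", "head_to_tail_same_segment"),
        ## cross-chromosome link
        list("CTX", 1, "RIGHT", 2, "RIGHT", "DM", "inter_chromosomal"),
        ## intrachromosomal link between two segments
        list("ITX", 1, "RIGHT", 2, "LEFT", "DM", "inter_segment_translocation"),
        ## ITX back to the same edge carries no structure signal
        list("ITX", 1, "RIGHT", 1, "RIGHT", "NONE", "type_excluded"),
        ## deletions and insertions never vote
        list("DEL", 1, "LEFT", 1, "RIGHT", "NONE", "type_excluded"),
        list("INS", 1, "LEFT", 1, "RIGHT", "NONE", "type_excluded"),
        ## both breakends deep inside segments
        list("INV", 1, "INTERNAL", 1, "INTERNAL", "NONE", "internal"),
        list("ITX", 1, "INTERNAL", 2, "INTERNAL", "NONE", "internal"),
        ## one breakend in unamplified genome
        list("CTX", 1, "RIGHT", NA, "NONE", "NONE", "unanchored"),
        list("INV", NA, "NONE", 1, "LEFT", "NONE", "unanchored"))
    for (cs in cases) {
        got <- classifyJunction(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]])
        expect_equal(got$vote, cs[[6]],
                     label = paste(cs[[1]], cs[[3]], cs[[5]], "vote"))
        expect_equal(got$rationale, cs[[7]],
                     label = paste(cs[[1]], cs[[3]], cs[[5]], "rationale"))
    }
})

test_that("the amplicon call is the strict majority of evidentiary votes", {
    id <- function() mkJunction("INV", 1, "RIGHT", 1, "RIGHT")
    dm <- function() mkJunction("CTX", 1, "RIGHT", 2, "RIGHT")
    none <- function() mkJunction("DEL", 1, "LEFT", 1, "RIGHT")
    internal <- function() mkJunction("ITX", 1, "INTERNAL", 1, "INTERNAL")

    a <- callStructure(mkAmplicon(list(id(), id(), id(), dm())))
    expect_equal(structureCall(a), "ID")
    expect_equal(a@votes, c(ID = 3L, TR = 0L, DM = 1L))
    expect_equal(a@nEvidentiary, 4L)

    ## only internal calls -> no evidence -> NA
    a <- callStructure(mkAmplicon(list(internal(), internal())))
    expect_equal(structureCall(a), "NA")
    expect_equal(a@nEvidentiary, 0L)

    ## no junctions at all -> NA
    expect_equal(structureCall(callStructure(mkAmplicon(list()))), "NA")

    ## a tie has no strict majority -> other
    a <- callStructure(mkAmplicon(list(id(), dm())))
    expect_equal(structureCall(a), "other")

    ## half is not a strict majority either
    a <- callStructure(mkAmplicon(list(id(), id(), dm(),
                                       mkJunction("ITX", 1, "LEFT", 1,
                                                  "RIGHT"))))
    expect_equal(structureCall(a), "other")
})

test_that("the call ignores junction order and non-voting junctions", {
    withr::local_seed(29)
    jns <- list(mkJunction("INV", 1, "RIGHT", 1, "RIGHT"),
                mkJunction("CTX", 1, "RIGHT", 2, "RIGHT"),
                mkJunction("INV", 1, "RIGHT", 2, "LEFT"),
                mkJunction("DEL", 1, "LEFT", 1, "RIGHT"))
    ref <- structureCall(callStructure(mkAmplicon(jns)))
    for (i in 1:10) {
        perm <- sample(jns)
        expect_equal(structureCall(callStructure(mkAmplicon(perm))), ref)
    }
    ## appending any non-voting junction leaves the call unchanged
    for (extra in list(mkJunction("DEL", 1, "LEFT", 1, "RIGHT"),
                       mkJunction("ITX", 1, "INTERNAL", 1, "INTERNAL"),
                       mkJunction("CTX", 1, "RIGHT", NA, "NONE"))) {
        expect_equal(
            structureCall(callStructure(mkAmplicon(c(jns, list(extra))))),
            ref)
    }
})

test_that("the report table mirrors the amplicon set", {
    amps <- findAmplicons(
        suppressWarnings(c(idExampleSegments(), dmExampleSegments())),
        c(idExampleSvs()[1], dmExampleSvs()[1]))
    rep <- ampliconReport(amps)
    expect_equal(nrow(rep), 2)
    expect_setequal(rep$structure, c("ID", "DM"))
    expect_equal(sum(rep$n_segments), 3)
    expect_true(all(rep$n_evidentiary >= 1))

    f <- withr::local_tempfile()
    writeAmpliconReport(amps, f)
    back <- read.delim(f)
    expect_equal(back$structure, rep$structure)

    ## empty set -> header-only report
    empty <- ampliconReport(AmpliconSet())
    expect_equal(nrow(empty), 0)
})
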