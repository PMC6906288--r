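---
title: "Calling amplicon structure from low-coverage WGS caller output"
author: "ampliconStructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling amplicon structure from low-coverage WGS caller output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(ampliconStructure))
```

## The problem

Focal gene amplification in tumor genomes takes a small number of recurrent
architectures. In an **inverted duplication (ID)** a DNA segment is fused to
its own copy head-to-head — telomeric end to telomeric end or centromeric
end to centromeric end. This is the scar left by breakage-fusion-bridge
(BFB) cycles, in which a broken chromosome fuses with its sister after
replication and is torn again at the next anaphase. In a **tandem repeat
(TR)** the segment is fused head-to-tail. A **double minute (DM)** is an
amplified unit assembled from segments of different genomic origin in
arbitrary orientation, often maintained extrachromosomally (ecDNA).

Low-coverage whole-genome sequencing (3--15x) supports two independent
analyses: read-depth copy-number segmentation and read-pair structural
variant (SV) detection. Neither alone identifies the architecture. The
signal lives in their intersection: the amplified segments' *edges* are
the amplicon's breakpoints, so the SV junction joining two edges says how
the amplified copies are wired together. This package integrates the two
caller outputs and classifies each amplified unit as ID, TR or DM.

It deliberately stops short of full ecDNA-style reconstruction: it does not
infer segment order or multiplicity within the amplicon, nor BFB cycle
counts. Those require cycle-finding on a breakpoint graph at higher
coverage; at 9x median depth, the attainable and clinically useful call is
the architecture class and segment count.

## The pipeline and its parameters

### Preprocessing

* **Copy-number floor, 6 copies.** Segments below 6 copies per cell are not
  part of a high-level amplicon. The floor matches the ddPCR positivity
  rule (6 copies or more is amplified), and both filters use *keep at or
  above threshold* semantics — a segment at exactly 6 copies, or an SV
  scored exactly 99, is kept.
* **SV score floor, 99.** Read-pair callers assign a Poisson-model
  confidence score in [0, 100]; at low coverage nearly all false calls
  score below 99 while junctions of a high-copy amplicon are supported by
  dozens of pairs and saturate the score.
* **Segment unification, gap of one 15-kb bin.** Read-depth segmentation is
  quantized to bins (all segment boundaries are multiples of 15 kb), and a
  one-bin dropout inside an amplified run is segmentation noise, not
  biology. Unified segments take the length-weighted mean copy number,
  which preserves total copies x basepairs; the merge is idempotent.

### Breakend-to-edge association (`edgeTol` = 45,000 bp)

A junction is only informative if its breakends coincide with segment
edges. "Coincide" cannot mean equality: segment boundaries are quantized to
15-kb bins and read-pair breakend estimates carry their own localisation
error. In the three reference examples the observed offsets between a
breakend and its segment edge range from about 100 bp to 41 kb, so the
tolerance is set at three bins (45 kb) — large enough to absorb both error
sources, small enough that distinct segments (which are megabases apart)
are never confused. A breakend inside a segment but farther than the
tolerance from both edges is INTERNAL; one in unamplified genome is NONE.
Ties between a segment's two edges resolve to the nearer edge, an exact
midpoint to LEFT, and ties across segments to the first segment in
positional order — all deterministic.

### Assembly

Segments are nodes; an SV whose two breakends associate with edges of two
different segments is an edge; connected components are amplicons. A
segment with no SV evidence still forms a single-segment amplicon: samples
with clean copy-number amplification but no usable SV data (degraded FFPE
DNA is common) are reported with structure `NA` rather than silently
dropped. Junctions that are internal-internal or touch unamplified genome
are kept on the amplicon's record but flagged non-evidentiary.

### Classification

Each junction casts one vote by an ordered rule set: internal-internal
junctions and junctions touching unamplified genome do not vote; DEL/INS
calls never vote (only INV/ITX/CTX junction geometry encodes architecture);
an INV votes ID (a *fold-back* when both breakends sit at one edge of one
segment — the head-to-head BFB signature — otherwise an inter-segment
inversion, since multi-segment amplicons with ID architecture exist); an
ITX joining a segment's two opposite edges votes TR (head-to-tail); a CTX,
or an ITX linking two different segments, votes DM.

The amplicon call is the **strict majority** of votes: more than half.
With no evidentiary vote the call is `NA`; with votes but no strict
majority (including exact 1:1 ties) it is `other`. Plurality was rejected
deliberately — mixtures of evidence are surfaced for manual review, never
resolved by an arbitrary tie-break, which mirrors how ambiguous samples
are actually handled in practice. The call is invariant to junction order,
and adding non-voting junctions cannot change it.

Two interpretation choices are worth stating. First, the boundary between
`other` and `NA`: `NA` is reserved for *no evidentiary junction at all*;
any evidence that fails to reach a strict majority yields `other`. Second,
read-orientation strings from the SV caller are parsed and stored but not
used by the classifier — the classification rules are stated purely in
terms of call type and edge geometry, which suffices for the three
reference architectures and avoids depending on a caller-specific
orientation encoding.

## Coordinates and formats

Both upstream dialects are 1-based inclusive on disk and are held
internally as `GRanges` (1-based closed) — one convention everywhere, with
conversion to 0-based half-open confined to the BED writer. Chromosome
names are normalized (default: strip a `chr` prefix) because the two
upstream tools disagree in the wild. Degenerate input rows (non-numeric
coordinates, start >= end, out-of-vocabulary SV types, scores outside
[0, 100]) are rejected with the offending line number. The segment-level
`_CNVs` file is the assumed copy-number input; per-bin ratio files are out
of scope.

## The simulator

`simulateAmplicon()` inverts the classification rules to produce ground
truth, then degrades it into realistic caller output. It operates at the
*call* level — segment and breakpoint files, not reads — because that is
what the pipeline consumes; simulating reads would test the upstream
callers, which are not part of this method.

Geometry defaults emulate the ERBB2 setting: ID and TR place a 1.59-Mb
segment on 17q (within a factor of the cohort's 1.4-Mb median amplicon
size), DM places ~1.07-Mb segments on distinct chromosomes; the default
copy number of 16 is the cohort's median ERBB2 copy number. All truth
boundaries are multiples of the 15-kb bin. Truth junctions carry the
architecture's signature: a fold-back INV at the first segment's edge
(plus inter-segment INVs chaining any additional segments from the
centromeric end), a head-to-tail ITX, or CTXs chaining segments on
different chromosomes. A multi-segment TR is rejected as impossible
geometry: the head-to-tail junction is per-segment evidence, and any
junction linking further segments would itself vote DM under the
classifier's own rules, so the request is self-contradictory.

The noise model has four components, each an explicit parameter: outward
rounding of segment boundaries to bin multiples; Gaussian jitter on each
breakend (default SD 5 kb, emulating read-pair localisation error — at
this level a breakend sitting 41 kb from its edge, as in the TR reference
example, is occasionally jittered past the 45-kb tolerance, which is
realistic and is why degradation tests measure rates rather than assume
perfection); dropout of true calls with fixed probability; and spurious
calls at a Poisson rate with scores drawn from [25, 98], i.e. entirely
below the default score filter. Everything is driven by one seed;
identical seed and configuration give byte-identical emitted files.

What passing recovery tests shows — and what it does not: with zero noise,
100% recovery over 100 seeds per class demonstrates the assembly and
classifier invert the generative rules exactly; the dropout sweep
demonstrates graceful, monotone degradation to all-`NA`. Real FFPE samples
add failure modes the simulator does not model (mapping artefacts,
coverage waviness, subclonality, caller-specific biases), so these tests
validate the logic, not clinical sensitivity.

## Cohort statistics

The package ships a 40-sample HER2+ tumor cohort table (ERBB2-amplified by
lcWGS) with both ddPCR and lcWGS copy numbers, stage, ER status, amplicon
structure and segment count. ddPCR copy number is `2 x target/reference`
against the two-copy AP3B1 reference, positive at >= 6 copies, with a
secondary flag at ratio >= 1.8. The stage contingency groups stages
IA--IIIA and local recurrences as localized, IIIC--IV as advanced — the
grouping under which the cohort's 19/9 localized/advanced split of
determined-structure samples arises — and counts only samples with a
determined (ID or DM) structure. Fisher's exact test is the classical
two-sided rule (sum of all margin-consistent tables whose hypergeometric
probability does not exceed the observed table's), computed in log space
with the conventional 1e-7 relative guard; it is verified in the tests
against full enumeration for every table with total up to 40 and against
the independent implementation in `stats`. The agreement statistic between
the two copy-number assays is the squared Pearson correlation, identical
to the R-squared of a simple linear regression with intercept.

One cohort-internal caveat: the published 2x2 for the stage association
(17/2 single/multi localized, 1/8 advanced) differs by one sample from the
table derived row-by-row from the characteristics file (which contains two
advanced single-segment samples). Both are exposed —
`stageContingency()` derives the row-level table and
`reportedStageTable()` returns the published one — and neither is
"corrected" toward the other.

## Problem sizes and numerical choices

The test suite simulates at the scale of the method's real inputs (one
amplicon of 1--3 segments per dataset): 100 seeded datasets per
architecture for noise-free recovery and 90 per dropout level for the
degradation sweep, sizes at which the binomial uncertainty on a recovery
rate is a few percent, comfortably below the ~20-point gaps the sweep
resolves. Copy-number weighting uses `round()` half-to-even on the
length-weighted mean; all position arithmetic is integer-valued doubles
well below 2^53, so no precision is lost.

## Known limitations

* Segment order and multiplicity within an amplicon, and BFB cycle counts,
  are not reconstructed.
* The classifier ignores read-orientation strings; architectures
  distinguishable only by orientation (not by call type and edge geometry)
  are not separated.
* `other` and `NA` calls are boundaries for manual review, not final
  biology.
* The simulator models caller output, not reads; it cannot expose
  alignment- or library-level artefacts.
* Cohort statistics describe the packaged retrospective cohort; they are
  not re-estimated from raw sequencing data, which the package does not
  require or download.
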