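---
title: "Methods: repeat-instability quantification, MSI classification and crosslink validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-instability quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatlens)
```

# Scope and model

`repeatlens` quantifies somatic instability of short tandem repeats from
fragment-analysis peak tables, compares expansion kinetics between
experimental groups, classifies microsatellite instability (MSI) across a
marker panel, and validates crosslinking-MS residue pairs against
structures. This vignette records the models, parameter choices and
numerical conventions, and what the packaged synthetic data does and does
not establish.

## Allele calling and the inclusion threshold

A fragment trace for a biallelic repeat locus is a set of sized peaks.
Sizes in bp are converted to repeat units against a calibrator allele of
known repeat count (`calibration()`), because the amplicon's non-repeat
flank length is assay-specific and capillary sizing has a small systematic
offset; the conversion is `ref_repeat + round((size - ref_size)/unit)`,
with half-unit offsets rounded half-up for determinism. Peaks are
partitioned between the two expected alleles at the arithmetic midpoint in
repeat units (a peak exactly at the midpoint goes to the shorter allele;
expected alleles closer than twice the stutter depth are refused). Within a
window, the **modal** repeat is the tallest peak; a height tie breaks to
the smaller repeat *with a warning*, the programmatic analogue of flagging
a trace for manual review. Only peaks at or above 20% of the modal height
enter downstream indices. Two conventions are deliberate:

* the threshold comparison is **inclusive** (`>= 0.2 * modal`), the
  convention of the widely used instability-index protocol this
  implements;
* the threshold is applied **per allele window** (not across the whole
  trace); biallelic traces with very unequal allele heights would
  otherwise lose the weaker allele's distribution entirely. A whole-trace
  variant would be a one-line change in `allele_call()` callers and is
  intentionally not a hidden default.

## Instability and expansion indices

Both indices are height-weighted mean changes from the modal repeat over
the included set; the instability index is signed, the expansion index
restricts the sum to peaks longer than the modal. Both use the **same
normaliser** (total included height), so the expansion index is bounded by
the instability index plus the contraction mass; an expansion-side-only
normaliser is available via `expansion_index(..., normalizer =
"expansion")` for comparability with protocols that use it. Single-peak
calls score exactly zero by construction. The indices are invariant to
height rescaling and covariant under repeat translation; the test suite
checks both properties and agreement with an independently coded
direct-summation oracle to 1e-12.

## Expansion kinetics and group statistics

Per-replicate time courses (metric versus day, >= 2 distinct days) are fit
by ordinary least squares; the slope is the expansion rate. Which metric's
slope constitutes "the expansion rate" is a configuration choice (`metric`
argument); the packaged fixture and acceptance use the modal repeat, whose
drift has a direct generative interpretation (below). Groups are compared
by one-way ANOVA **on per-replicate slopes**, not by ANCOVA on pooled
points: replicates are the biological unit of analysis, and per-replicate
slopes keep the error structure honest when replicates differ in day
coverage. AUC summaries are computed per replicate by the trapezoidal
rule. Pairwise contrasts use pooled-variance t tests with
Benjamini–Hochberg FDR control at q = 0.05 (the two-stage
Benjamini–Krieger–Yekutieli procedure is selectable via `fdr_adjust(...,
method = "BKY")`; BH is the default because it is the standard step-up
procedure and its behaviour is exactly reproducible by hand). The
Brown–Forsythe check is the median-centred Levene test: a one-way ANOVA on
absolute deviations from group medians. Degenerate inputs are reported,
not hidden: zero within-group variance with unequal means yields an
infinite statistic, a p value floored at 1e-300 and a `"degenerate"`
flag.

## MSI classification

The panel ships with 18 loci: six mononucleotide, five dinucleotide and
five tetranucleotide markers plus two pentanucleotide control loci (Penta
C/D), with unit sizes as printed in the assay kit documentation. (One
published description lists D8S321 inconsistently as di- and
tetra-nucleotide in different places; the panel here follows the
methods-style listing, unit 4.) Allele calling reuses the 20% threshold
machinery in bp space: stutter echoes fall below the cutoff, surviving
peaks are read as alleles (greedy by height, minimum spacing one unit
minus tolerance, up to two alleles). A locus is **unstable** when any
follow-up allele differs from every matched-baseline allele by at least
one repeat unit minus a sizing tolerance of 0.5 bp (half the smallest
unit; no published tolerance exists for this assay). Samples are compared
to their own baseline (day-0/parental line) — a within-line time-course
design — not to population allele frequencies, and clinical MSI-high/low
categories are deliberately not assigned. Instability at any
tetranucleotide marker raises the EMAST flag; instability at a control
locus raises a sample-level QC failure instead.

## Crosslink validation

Crosslink tables are filtered at score **strictly greater than 20**
("higher than" read as strict). Unique residue pairs are counted per
unordered protein pair. Structural validation computes the Cα–Cα
Euclidean distance after mapping sequence positions to author numbering
through a per-chain offset map; residues without coordinates (disordered
regions) are *unresolved*, not errors. The consistency cutoff is 30 Å,
the standard literature ceiling for BS3 in Cα terms; the flag is
inclusive at the boundary. Alignment consensus uses non-gap rows as the
denominator and highlights columns **strictly above** 80%. A minimal
fixed-width PDB / mmCIF `atom_site` coordinate reader is built in because
no structure-reading R package is available in the supported dependency
set; it reads coordinates only and skips alternate locations beyond the
first and models beyond the first.

# The synthetic-data generator

## What it emulates

Each cell carries the configured founder alleles (default biallelic 20/118
CAG, the endogenous/exogenous pair of the U2OS exon-1 model). Every day
each allele steps +1 repeat with probability `p_expand` and −1 with
`p_contract` (default 0: contraction is rare in this assay's direction of
drift). This is the simplest process consistent with the two features the
downstream analysis measures: linear modal drift at `t(p_expand −
p_contract)` units/day and gradual broadening of the repeat distribution.
The population histogram evolves by multinomial redistribution per length
bin, so simulation cost is independent of population size; defaults are
`n_cells = 10000`, days 0/14/28/42 (a six-week course), three replicates,
and three genotype archetypes — `FAN1_FL` 0.05, `FAN1_KO` 0.15, `MMR_null`
0 units/day on the long allele, with the short allele always stable. The
0.15/0 contrast mirrors the qualitative biology (mismatch-repair loss
abolishes expansion; unprotected lines expand fast); 0.05 gives a
realistic intermediate ~2 repeats per six weeks. Replicate-level
variability arises only from the stochastic walk and rendering noise; the
magnitudes are fixture parameters, not claims about any particular
experiment.

Rendering maps repeat `r` to size `flank + r·unit` (flank 87 bp — an
arbitrary realistic value; calibration makes it immaterial), echoes each
true peak into a −1-repeat geometric stutter ladder (ratio 0.15, depth 3 —
typical for CAG PCR, and deliberately *below* the 20% threshold so that
threshold, not deconvolution, suppresses stutter), adds Gaussian sizing
jitter (sd 0.15 bp, typical capillary precision) and multiplicative
log-normal height noise (CV 0.10, mean 1). Heights are arbitrary
fluorescence units scaled to a tallest peak of 8000; only ratios matter
downstream.

## What it does not emulate

No continuous electropherogram waveform, no +1 stutter, no allele-length-
dependent amplification bias, no somatic mosaicism across tissues, no
technical-within-biological replicate hierarchy. Consequently a green test
against fixtures establishes the *computational* contract — calling,
thresholding, index arithmetic, regression and classification behave as
specified on data with known truth — not instrument-level robustness.

## Determinism

All generators are seeded; per-replicate seeds are derived from the base
seed by a fixed integer hash (kept below 2^31) and logged in the manifest.
Equal seeds give byte-identical files; the suite asserts this.

# Numerical conventions collected

* bp→repeat rounding: half-up (`floor(x + 0.5)`), deterministic at exact
  half-units (jitter makes them measure-zero in practice).
* Modal ties: smaller repeat wins, warning emitted.
* Threshold: inclusive at the 20% boundary.
* Score filter: strict at 20. Consensus highlight: strict at 80%.
  Crosslinker consistency: inclusive at 30 Å.
* ANOVA/t degeneracy: exact-zero (or numerically zero, at `t.test`'s own
  tolerance) within-variance handled explicitly with flags; p floor
  1e-300.
* Distances: Cα–Cα Euclidean; the literature sometimes uses solvent-
  accessible surface distance, which is always >= the Euclidean value, so
  the 30 Å Cα cutoff is the permissive, conventional choice.

# Known limitations

* The expansion model is a single well-mixed population with unit steps;
  real repeat dynamics show length-dependent step rates and occasional
  large jumps, which the linear-drift analysis here would average over.
* MSI allele calling reports at most two alleles per locus; a baseline
  heterozygote gaining a third allele would need `max_alleles = 3`.
* The structure reader handles coordinate records only (no assemblies,
  insertion codes collapse into author numbering).
* Packaged reference fixtures for the structure-distance and motif checks
  are synthetic stand-ins (filenames and headers say so): they exercise
  the pipeline with known ground truth but are not the deposited
  structure or the canonical sequence.
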