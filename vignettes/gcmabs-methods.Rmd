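---
title: "Methods: integrative single-cell analysis of GC B cells and their recombinant antibodies"
author: "gcmabs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative single-cell analysis of GC B cells and their recombinant antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmabs)
```

## Scope and model

`gcmabs` implements the downstream analysis that links three measurement
layers recorded on the same single germinal-center (GC) B cells:

1. **Transcriptome** — a plate-based 5'-end scRNA-seq UMI count matrix with
   ERCC spike-ins and mitochondrial genes, used for quality control,
   normalization, gene-signature scoring and supervised gating into the six
   canonical GC states (LZ, DZ, recycling LZtoDZ, preMem, prePC, PC) plus a
   cell-cycle phase call.
2. **BCR sequence** — reconstructed immunoglobulin contigs per cell,
   consolidated to one heavy and one light chain, grouped into clonotypes by
   heavy-chain rearrangement features, and compared to inferred germlines to
   count somatic hypermutation (SHM) split by CDR/framework region and
   silent/non-silent status.
3. **Antigen binding** — index-sort fluorescence (surface binding of
   fluorescent antigen, reported as `asinh(MFI/100)`) and, for cells whose
   BCRs were expressed as recombinant mAbs, an ELISA binding threshold: the
   minimum antibody amount (ng) giving detectable binding in a 4-fold
   serial-dilution ELISA.

The per-cell union of these layers supports the package's comparative
statistics: Kruskal–Wallis with Dunn's post-hoc tests across samples or
subsets, a semi-log least-squares fit of surface binding against the log10
ELISA threshold, candidate-clonotype selection, and a FACS/ELISA discordance
(outlier) rule.

## Quality control and normalization

Four per-cell criteria gate entry into the expression analysis: total
endogenous UMI count, number of genes detected, percent mitochondrial
transcripts, and ERCC quantification accuracy, defined as the Pearson
correlation of `log1p(observed spike-in count)` with `log10(expected
concentration)` across spike-in species; a cell with fewer than three
detected species has undefined accuracy and fails. The numeric defaults
(`min_total_umi = 2000`, `min_genes = 500`, `max_pct_mito = 20`,
`min_ercc_accuracy = 0.8`) are typical for plate-based protocols; they are
configuration, not constants, because appropriate cut-offs depend on the
library depth of each run. The synthetic generator emits thresholds scaled to
its own configuration for the same reason.

Normalization is the standard library-size log transform
`ln(1 + 10000 * count / cell_total)` with spike-ins excluded from totals and
output. The natural logarithm and the 10,000 scale factor follow the
convention of the single-cell toolkit this field uses, so scores computed here
are comparable with common practice. The transform is scale-invariant per
cell and strictly increasing in the raw count, which the test suite asserts
as properties.

## Chain consolidation, clonotypes, and SHM counting

Contig consolidation applies three rules in order: (i) contigs annotated with
the same V(D)J rearrangement — operationalized as an identical
`(locus, v_call, j_call, junction)` tuple, the only rearrangement identity
available in contig annotations — are merged keeping the longest sequence;
(ii) contigs without an in-frame constant region are discarded; (iii) if
several contigs of one chain class survive, the highest-expressed one is
kept. IGK and IGL compete jointly for the light-chain slot.

Clonotypes are called from heavy chains only: cells are blocked by (V gene,
junction nucleotide length) and single-linkage clustered, linking pairs with
junction nucleotide identity ≥ 0.8. This is the field-standard
interpretation of "clonally related by heavy-chain sequence"; both the
identity cut-off and the linkage are configurable because the underlying
choice (junction identity vs full V identity) is genuinely open. Ids are
assigned in order of first appearance over cells sorted by id, so the
partition and labels are independent of input order.

SHM counting aligns the observed chain to its germline V region with a
global end-free (overlap) alignment (match +1, mismatch −1, gap of length L
costs 4 + (L−1)); each aligned substitution is counted once at its germline
position's region. Silent status translates the germline codon against the
codon with that single substitution applied — when two substitutions share a
codon each is judged independently, the same convention the generator uses
when planting mutations, so the two sides of the round-trip agree by
construction. Indels are flagged but not counted: reported mutation counts
are small substitution integers, and SHM indels are rare and ambiguous to
localize. Alignments covering less than 80% of the germline are rejected as
sequence/germline mismatches. An exhaustive affine-gap dynamic-programming
aligner, written independently in the test suite, pins the alignment scores
for sequences up to 60 nt. Allele lookups resolve a missing allele suffix to
`*01` for deterministic behavior on sloppy `v_call` strings.

## Signature scoring and gating

`module_score()` follows the binned control-gene scheme: genes are ranked by
mean normalized expression, cut into 24 equal-size bins, and each signature
gene contributes 100 control genes drawn from its bin; the score is the mean
signature expression minus the mean over the pooled control draw. Control
pools exclude the signature genes themselves, so in the degenerate one-bin
case the score reduces exactly to mean(signature) − mean(non-signature),
which is the hand-checkable contract the tests use. Scores are location-free
and deterministic given the seed. The LZ and DZ signatures are filtered
against a cell-cycle gene list before scoring, because proliferation
otherwise confounds the zonal programs.

Gating is sequential: PC, then prePC, then preMem by threshold; then LZtoDZ
if both the LZ and DZ scores exceed their thresholds; otherwise the larger
of LZ/DZ decides, with exact ties left unassigned. The gate order reflects
the biology (the rarer, transcriptionally extreme states are peeled off
first; the recycling state requires both zonal programs). Thresholds default
to 0 — the natural signal-above-control boundary — and are meant to be tuned
empirically per dataset. `suggest_gate_thresholds()` implements the package's
empirical calibration: the midpoint of each signature's observed score range,
which cleanly separates a positive population from the background bulk when
the signature has real signal. Cell-cycle phase is the positive argmax of
the S and G2M scores, defaulting to G1/quiescent, with a positive tie
resolving to S.

## ELISA binding threshold

The dilution design is a 4-fold series from 1000 ng per well (6 points by
default, duplicate wells). The curve is the mean OD per amount (replicates
are averaged, matching how such curves are reported); the binding threshold
is the smallest amount whose mean OD reaches the detection threshold,
refined by linear interpolation of mean OD against log10(amount) between the
bracketing dilutions — thresholds reported off-grid imply interpolation, and
log-amount is the scale on which such curves are plotted. A curve that never
reaches the detection line is right-censored and printed `">1000"`; a curve
already above it at the smallest amount is left-censored. Non-monotone
curves use the lowest-amount crossing with a warning. The detection
threshold defaults to mean + 3 sd of the no-primary-antibody negative
controls, with a fixed override for assays that define their own line.

Interpolation on log10(amount) is accurate near the curved part of the
saturation response but biased low when the crossing sits deep in the
initial linear regime (OD ≈ od_max·a/K); on a fine dilution grid the
interpolation error vanishes, which is how the oracle test pins it to within
1%. Results that depend on the detection line's numeric value are
config-sensitive by design, since that value is an assay property.

## Integrative statistics

Kruskal–Wallis uses the tie-corrected H; Dunn's z statistics share the tie
correction and are Bonferroni-adjusted over all pairs by default — the
classical Dunn procedure — with Holm or no adjustment available. The
semi-log fit `y = a + b·log10(x)` is solved as a straight-line least squares
on log10(x), which attains the same optimum as an iterative fit of the same
model, deterministically; R² equals the squared Pearson correlation of y
with log10(x), asserted as an identity in the tests. Right-censored
thresholds are handled by two first-class policies, capping at the censoring
limit or excluding the rows. On the bundled 32-mAb reference table the cap
policy reproduces the reference R² (0.466 vs 0.4638 printed) while exclusion
gives 0.347; cap is therefore the documented default, with both reported
side by side by the pipeline. Candidate clonotypes are those with ≥ 5
members and ≥ 1 member above the asinh background of 1; outliers are cells
with surface binding below 1 whose mAb thresholds fall strictly inside
(10, 100) ng.

## The synthetic generator

`simulate_dataset()` produces the full input bundle with known ground truth.
Its defaults are the study conditions the package targets: subset sizes
LZ = 331, DZ = 300, LZtoDZ = 55, preMem = 29, prePC = 27, PC = 5; four
samples (d10p, d20p, d10s, d20s) in proportions 145/205/295/124; SHM rates
increasing across timepoints (multipliers 0.5/1/1.5/2 on a base Poisson mean
of 3 substitutions per heavy V); 10% of cells planted to violate one QC
criterion. UMI counts are negative binomial (size 2) around per-gene
lognormal means, with each subset's five printed marker genes elevated
4-fold in its subset; LZtoDZ additionally elevates the LZ and DZ markers and
preMem the LZ markers, mirroring the described transcriptional overlaps.
Germline references are invented in-frame 294-nt V sequences named in IMGT
style with a fixed FR/CDR layout — bundling invented references keeps full
control of the region maps without any database download. Each cell carries
1–4 heavy and 1–3 light contigs (fragments of the true rearrangement,
contigs lacking an in-frame constant region, and lower-expressed competing
rearrangements) to exercise every consolidation rule.

Antigen binding follows a lineage-level binder flag (probability 0.3):
binder cells get affinity `exp(0.12 · CDR mutations)` and background cells
0.02, scaled by 150 into MFI with lognormal noise (sd 0.3) — producing the
asinh-scale separation around 1 between binders and background. ELISA
curves are saturation responses `od_max·a/(a + K)` with `K = 350/affinity`,
placing binder thresholds in the ~5–20 ng range, background cells in the
hundreds of ng, and germline revertants beyond the 1000 ng censoring limit —
the spread real mAb panels show. The generator's `noise_free` mode switches
off measurement noise only (counts at their rounded expectations, zero
dropout, FACS and ELISA noise); mutations are still drawn because they are
signal. What the generator does not emulate: read-level errors, doublets,
batch effects, ambient contamination, or biologically realistic co-expression
structure — so passing round-trips demonstrate the correctness of the
pipeline's logic, not robustness to every failure mode of real data.

## Problem sizes and numerical choices

The round-trip and acceptance runs use a half-scale cohort (374 cells, of
which 337 pass QC) in noise-free mode — large enough to populate every
subset, clonotype-size class and censoring state while keeping a full run in
tens of seconds. The clonotype oracle comparison uses 50 cells (the
brute-force single-linkage closure is quadratic); the mutation bookkeeping
check runs 1000 random chains; the permutation oracle for Kruskal–Wallis
uses 10,000 draws on 3 groups × 8 values. Ties in ranks are handled by the
standard correction; exact LZ/DZ score ties gate to "unassigned" rather than
guessing; degenerate inputs (all-tied Kruskal–Wallis groups, zero-variance
fits, zero-total cells, empty contig sets) raise errors or defined fallbacks
rather than propagating NaN.

## Known limitations

Clonotyping ignores the light chain; lineage trees and class-switch analysis
are out of scope. Mutation counts cover the V region only, not the junction.
The ELISA model estimates a detection threshold, not an affinity constant;
4PL/EC50 fitting is deliberately not implemented. Gating quality on real
data depends entirely on signature content and empirically tuned thresholds;
the bundled five-gene signatures are a faithful stand-in for the full
published lists, not a reproduction of them.
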