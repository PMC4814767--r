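---
title: "Methods: miRNA and phased siRNA discovery with mirphas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA and phased siRNA discovery with mirphas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirphas)
```

# Scope

`mirphas` implements the standard plant small RNA analysis of two
unreplicated sequencing libraries (a treatment and a control): read
preprocessing and accounting, unique-tag categorisation, known- and
novel-miRNA identification, tag-count differential expression, detection of
21-nt phased siRNA (*PHAS*) loci with their 22-nt trigger miRNAs, and
rule-based miRNA target prediction. A synthetic data generator plants every
feature class into toy genomes so each stage can be validated against known
ground truth.

# Preprocessing and tag categorisation

Reads are quality-filtered (mean Phred below 20, or any N, drops the read;
the threshold is configurable because "low quality" has no universal
definition), then the 3' adapter is located by a seeded prefix match: at
least 8 nt of the adapter prefix, at most 1 mismatch, leftmost occurrence
wins. Each high-quality read lands in exactly one class, tested in this
order: no adapter found; adapter at read start (empty insert); 5' adapter
present in the insert; insert at least 80% A; insert shorter than 18 nt;
otherwise a clean insert. Because the classes are assigned in precedence
order they partition the high-quality reads exactly, which is what makes
the accounting table's percentages sum coherently.

Clean inserts from both libraries are collapsed to unique tags with
per-library counts. Tags are then categorised with this precedence: rRNA /
tRNA / snoRNA contaminant (at most 2 mismatches against a reference set, on
either strand), repeat, exon (interval overlap of any genome placement;
repeat-before-exon is configurable since either order is defensible), known
miRNA, unannotated (mapped but nothing above), unmapped. Genome mapping is
exact full-length matching on both strands; minus-strand placements are
stored as their forward-strand interval plus a strand flag, and coordinates
are 0-based half-open internally.

One deliberate artefact of seeded adapter trimming is worth knowing: an
insert that happens to contain a subsequence within 1 mismatch of the
adapter prefix (about 0.5% of random 21-mers) is truncated and its reads are
lost. This is faithful to real trimmers and is why planted-feature recovery
is always measured against tags that survive preprocessing.

# Novel miRNA prediction

Unannotated tags' genome placements are clustered (strand-aware single
linkage, 200-nt gap, matching the maximal allowed miRNA/miRNA* spacing).
Within each cluster every tag with at least 10 reads in some library is
tried as a putative mature, most abundant first; tags falling inside an
already-accepted precursor are skipped. This per-tag excision matters: at
realistic depth background reads tile the genome densely enough that
single-linkage clusters span many kilobases, and a one-candidate-per-cluster
rule would miss tandem hairpins.

For each candidate mature, windows extending up to 200 nt on either side
(plus 25-nt flanks) are excised and folded. Folding is a pluggable engine:
the default shells out to ViennaRNA's `RNAfold` (thermodynamic
nearest-neighbour model, energies in kcal/mol); a pure-R Nussinov
base-pair-maximisation engine is bundled for structure-shape checks on
short sequences but is never used for energy thresholds, because its
surrogate energy (-1 per pair) is not thermodynamic.

From the dot-bracket structure the mature's *dominant helix* is found: the
longest run of consecutive mature positions whose partners step antiparallel
(so a run can never jump between arms); runs shorter than 4 nt are
rejected. The miRNA* interval then follows from ungapped duplex arithmetic
with the Dicer 2-nt 3' overhang convention, anchored at the middle of that
helix. Anchoring on the dominant helix, rather than on the full set of
paired mature positions, is a deliberate robustness choice: folded
structures routinely let the overhang or terminal bases pair
opportunistically with flanking sequence, and naively including those stray
pairs either rejects genuine precursors (partners on both sides) or
inflates the star interval.

Duplex metrics are duplex-relative: a position counts as paired only when
its partner lies in the opposite duplex element. The bulge is the longest
run of such unpaired positions in either strand (3' overhangs excluded);
asymmetry is the absolute difference of the two strands' unpaired counts.
The accepted candidate is re-excised tightly around the duplex plus 25-nt
flanks and re-folded.

Eleven criteria gate every reported candidate: mature length in [18, 25];
matched reference mature length in [20, 23] when a reference exists (for
fully novel candidates these two are recorded as skipped-passing, since
there is nothing to compare against); at most 20 genomic copies; precursor
free energy at most -18 kcal/mol; at most 200 nt between miRNA and miRNA*;
at least 16 duplex base pairs; bulge at most 4; asymmetry at most 4; 25 nt
of flank on both sides of the duplex. Star support is called when some
other tag maps to the implied miRNA* interval within 1 nt at both ends.
Accepted matures are clustered into families by single linkage at 85%
global-alignment identity (matches divided by alignment length), and a 5'
first-nucleotide bias table is available per length class.

A limitation, verified during validation: the structural criteria alone are
not a standalone specificity guarantee. Random sequence forms gappy 16-pair
helices with small bulges at an appreciable per-locus rate, so specificity
in practice comes from the combination of the criteria with the 10-read
abundance rule — loci without genuine read pileups never reach folding. The
false-positive smoke test therefore uses the generator's background read
model, not artificially abundant random tags.

# Differential expression

Counts are normalised to reads per million of the library's clean total
(RPM = count / total x 10^6; the per-library RPM columns sum to 10^6 by
construction). The fold-change is log2(treatment RPM / control RPM); a
zero operand is floored at 0.001 RPM before the ratio. The floor value is
chosen so that fold-changes of library-specific miRNAs reproduce the
reference arithmetic this package validates against; it is configurable.

The per-tag p-value compares the two library proportions. The default
backend is a two-proportion Z statistic with pooled variance — the test
family conventionally used for unreplicated digital tag counts — with an
exact conditional binomial backend (`count_t` against
Binomial(count_t + count_c, total_t/(total_t + total_c))) selectable when
exactness in the deep tail matters; the two agree within a factor of ~3
for moderate counts and in direction/order of magnitude beyond that. A
record is called responsive when |lfc| > 2 and p < 0.001 on the raw
p-value; no multiple-testing correction is applied in the call, matching
the unreplicated-design convention, but a Benjamini-Hochberg column is
emitted for users who want it. With no replicates these p-values quantify
sampling noise only, not biological variance — a stated design limit, not
an oversight.

# PHAS locus detection

All 21-nt genome placements contribute a phase coordinate: forward reads
their 5' start, antisense reads their forward start + 2, which projects the
two strands of a 2-nt 3' overhang duplex into one 21-nt register. Windows
of 21 x m nt (m = 10 cycles by default, i.e. 210 nt) slide at a 21-nt step
(step 1 is supported); in each window all 21 possible registers are tested
and the best kept — an implicit multiplicity of 21 per window that the null
calibration accounts for by counting per-register tests.

The window p-value is the hypergeometric tail: with n distinct 21-nt reads
in the window, k of them at one of the m phased positions,

$$P = \sum_{j=k}^{\min(m,n)} \frac{\binom{m}{j}\binom{20m}{n-j}}{\binom{21m}{n}},$$

computed in log space from log-binomial coefficients and clipped to [0, 1].
Windows with P < 0.001 are positive; overlapping positive windows merge
into loci (locus p = min window p). The phasing score is
$(k-2)\ln(1 + 10\Sigma P / (1 + \Sigma U))$ over the ten-cycle window,
reported only when more than 3 cycles are occupied; here k counts occupied
cycles, ΣP the 21-nt read count in phase and ΣU the read count out of
phase. Whether ΣU includes non-21-nt reads is genuinely ambiguous in the
field's usage, so both modes exist: the default lenient mode counts them
as out-of-phase mass; `strict21` ignores them entirely.

Trigger assignment scans the locus ±250 nt for a 22-nt miRNA target site
with complementarity expectation at most 4.5 (looser than the 3.0 used for
ordinary target prediction, because known trigger/target pairs are
imperfect), and requires the implied cleavage position to fall exactly in
the locus register. The cleavage-register convention — the first phased
position is the target-site start + 10 (0-based) — is a package contract
shared between the generator and the trigger search; the literature states
the 2-nt antisense offset but not this arithmetic, so the convention is
fixed here once and used consistently on both sides.

# Target prediction

Complementarity is scored ungapped over the miRNA 5'→3' (position 1 pairs
the site's 3' end): mismatch 1.0, G:U wobble 0.5, penalties doubled at
seed positions 2-13; a gap weight (2.0) is carried in the penalty
configuration for auditability although the default scorer introduces no
gaps. At most 19 positions are scored ("hspsize shorter than 20"): longer
matures take their best contiguous 19-position window. Sites with
expectation at most 3.0 are reported; the vectorised transcriptome scan is
checked against a naive per-window rescoring oracle in the tests. A site
is classed as translational inhibition when a true mismatch (wobbles do
not count) occupies miRNA positions 9-11, else as cleavage with the slice
site opposite positions 10/11. Site accessibility (UPE) is available as an
optional stage — the energy to open the site computed by constrained vs
unconstrained folding of the site plus 17 nt upstream and 13 nt downstream
context — and is off by default since it dominates runtime and the
headline outputs are expectation-driven.

# The synthetic data generator

`make_genome()` draws uniform random chromosomes (GC 0.5);
`plant_hairpin()` inserts a precursor arm + loop + arm with the mature/star
duplex reverse-complementary apart from designed mismatches and 2-nt 3'
overhangs (designed mismatches are chosen to not pair at all, wobbles
included, so a "broken" duplex really is broken to a folding engine);
`plant_phas_locus()` inserts a trigger-complementary site with a phased
downstream body; `plant_region()` adds rRNA/tRNA-like, exon and repeat
regions. `simulate_libraries()` draws per-feature read counts Poisson
around the recorded expectations, pads inserts with adapter sequence to a
fixed read length at Phred 40, injects configurable fractions of sub-18-nt
inserts and adapter-free reads, applies optional uniform substitution
errors, and writes FASTQ byte-deterministically under fixed seeds.

What it emulates: planted hairpins with star reads, condition-specific and
fold-changed features, phased 21-nt duplex reads on both strands,
contaminant and exon/repeat reads, a 24-nt-enriched background length
distribution, short/adapter-null junk. What it does not: realistic quality
profiles, ligation bias, indels, degradation fragments beyond uniform
background, or biological replicates (the two-library design is
deliberately replicate-free, as in the study design it mirrors). Passing
tests on this generator therefore demonstrate algorithmic correctness on
idealised signal, not performance on real libraries.

# Validation problem sizes

The test-suite and the acceptance script size their simulations to run
comfortably on a single CPU: null calibration uses 2,000 uniform 21-nt
reads over 100 kb with every register of every window tested (~10^5
tests); phased-locus recovery uses 20 independent 20-kb simulations at 50
expected reads per locus; hairpin recovery plants 10 hairpins in 2 x 40 kb
with ~70 mature reads each across libraries; DE calibration uses 1,000
8-fold features and 6,000 null features at base count 50; the target-scan
oracle covers 50 kb of transcript. These sizes were chosen as the smallest
that leave the binomial error bars well inside the tolerances being
checked.
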