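---
title: "From genome to fingerprint: the ssrkit methods"
author: "ssrkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genome to fingerprint: the ssrkit methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
```

ssrkit implements the complete marker workflow used in plant cultivar
identification studies built on simple sequence repeats (SSRs,
microsatellites): mine perfect and compound repeats from a genome assembly,
map them onto genic regions, design and validate locus-specific primers for
TP-M13 fluorescent genotyping, score a sample panel with co-dominant
fragment-size genotypes, quantify marker diversity, cluster samples by band
similarity, and search for minimal "core" marker sets that give every sample
a unique DNA fingerprint. This vignette documents the models, the tunable
parameters, and the design decisions behind each stage.

## Mining perfect and compound SSRs

A perfect SSR is a maximal uninterrupted tandem run of a 1–6 nt motif. The
miner reports a run when its repeat count reaches the per-motif-length
threshold; the defaults follow the common MISA-style genome screen:
dinucleotide motifs at six or more repeats, tri- to hexanucleotide motifs at
five or more. Mononucleotide runs are excluded by default (the screen this
package models starts at dinucleotides) and can be enabled with
`include_mono = TRUE`, which adds a threshold of ten repeats unless one is
supplied.

Several conventions are fixed so that results are reproducible and
comparable across tools:

* **Coordinates** are 1-based inclusive throughout, as in MISA tables.
* **Phase.** The reported motif is the first k-mer of the maximal run, so a
  `GAGA...` tract and an `AGAG...` tract keep distinct motifs. Motif
  classes pair a motif only with its reverse complement (`GA/TC`), never
  with its rotations (`AG/CT` stays separate), matching how genome-screen
  motif tables are conventionally tallied.
* **Shortest period.** A run whose motif is itself a repetition of a
  shorter word (`ATAT` as a tetramer) is reported at the shortest period
  only, preventing the same tract from being counted once per divisor.
* **Ambiguity codes** terminate runs; an `N` is never inside a reported
  SSR.
* **Overlaps.** When maximal candidate runs of different periods overlap,
  the longer span wins; at equal span the shorter period wins. This makes
  output deterministic without double counting.

Internally the scanner marks every position `i` with `s[i] == s[i + k]` and
extracts maximal marked runs, which yields the maximal repeat tracts of
period `k` in linear time per period. The test suite checks the scanner
against an exhaustive oracle that examines every (position, period) pair
independently.

Two perfect SSRs separated by at most `max_linker` nucleotides (default
100, inclusive) chain transitively into a *compound* SSR. The inclusive
bound was chosen because screens that describe their linker rule as "less
than 100 bp" conventionally report linkers up to and including 100 nt in
their own output; the bound is configurable for users who prefer the strict
inequality. Merging conserves members (every input perfect SSR appears in
exactly one output record) and is idempotent.

`summarize_mining()` reports two tallies deliberately: the *record* count
(standalone perfect SSRs plus compound records, the quantity genome screens
headline and divide by genome megabases for the per-Mb frequency) and the
*motif* tally (every perfect run including compound members). Published
summaries mix the two conventions, so both are exposed rather than guessed
between.

## Region assignment

Given a GFF3 annotation, each SSR is assigned to one of six categories:
5'UTR, 3'UTR, exon, intron, intergenic, or multi-mapped. Choices the GFF3
data model forces us to make explicit:

* A UTR is also an exon in GFF3, so UTR intervals take precedence: the exon
  category covers exonic bases outside any annotated UTR. Without this
  precedence a six-way partition is impossible.
* Introns are derived per transcript as the gaps between that transcript's
  exons; categories are unioned across transcripts before testing for
  multiple mapping.
* Any overlap of at least 1 bp with a category counts; an SSR straddling an
  exon/intron junction overlaps two categories and is therefore
  multi-mapped. Both the precedence and the 1 bp threshold are the
  package's own conventions — annotation-based screens rarely state theirs.
* Strand is ignored; region identity is strand-independent in this scheme.
* SSRs on sequences absent from the annotation are reported `unplaced` and
  tabulated separately, mirroring how genome screens report the fraction of
  markers not localized to chromosomes.

## Primer validation and TP-M13 tailing

The primer stage validates candidates against the four classic constraint
ranges (defaults: length 18–25 nt, Tm 57–62 °C, product 120–400 bp, GC
40–60 %). Melting temperature defaults to nearest-neighbor thermodynamics
with the SantaLucia unified parameter set, terminal initiation terms, the
entropy salt correction `0.368 (L-1) ln[Na+]`, total primer concentration
50 nM and monovalent salt 50 mM; all parameters are arguments and the
Wallace rule `2(A+T) + 4(G+C)` is available as a fallback mode. Full primer
*optimization* — penalty weighting, dimer and hairpin screening — is
deliberately delegated to dedicated designers; this module contributes the
constraint set, the enumeration of the constraint-satisfying search space,
and batch flank extraction (default 200 nt per side, truncated with a
warning at sequence ends).

For TP-M13 genotyping the forward primer is prepended once with a universal
M13 tail so that a dye-labelled universal primer labels every amplicon. The
default tail is the 19-letter sequence printed in widespread three-primer
protocols (`TGTAAAAACGACGGCCAGT`), which those protocols describe as
"18 bp"; because of that off-by-one ambiguity the canonical 18-nt M13(-21)
sequence is available as `m13_tail(variant = "canonical")`. Tailing adds
exactly the tail length to the expected fragment size, which matters when
raw capillary sizes are binned.

## Allele binning and diversity statistics

Raw capillary fragment sizes are snapped to the ladder
`reference + k * motif_length`; a size exactly half a repeat unit from two
rungs is flagged ambiguous instead of silently assigned.

Per locus, with allele frequencies `p` over `2n` gene copies from `n`
non-missing diploid individuals:

* `Na` — observed number of alleles; `Ne = 1 / sum(p^2)` — effective number;
* `I = -sum(p log p)` — Shannon's information index (natural log);
* `He = (2n / (2n-1)) (1 - sum(p^2))` — Nei's unbiased expected
  heterozygosity;
* `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2` — Botstein's polymorphic
  information content;
* `Ho` — the fraction of non-missing individuals that are heterozygous.

These are the POPGEN/PowerMarker conventions. One legacy quirk is handled
explicitly: some population-genetics programs print average homozygosity
complement (`1 - He`) under an "observed heterozygosity" heading. ssrkit
computes true `Ho` from the genotypes *and* exposes `Ho_compat = 1 - He` so
that legacy tables can be reproduced column for column; the two must not be
conflated.

Missing data policy: frequencies are computed over non-missing gene copies
and the `n` in the He correction is the number of non-missing individuals
at that locus. Statistics are kept at full precision and rounded (half to
even, 4 decimals) only at print time.

Within-population gene diversity `Hs` averages `1 - sum(p^2)` over loci and
populations, using each population's own allele frequencies. Because the
estimator convention differs between programs, both the uncorrected default
and a bias-corrected variant (`corrected = TRUE`, factor `2n/(2n-1)` per
population and locus) are available. Populations of size one are excluded
with a warning.

## Similarity, UPGMA and cophenetic validation

Genotypes convert to a binary band matrix — one column per (locus, allele
size), entry 1 iff the sample carries the allele — which is the
presence/absence view a fingerprint gel gives. Pairwise similarity is the
simple-matching coefficient `(a + d) / (a + b + c + d)`: **shared absences
count as matches**. This is the defining difference from Jaccard and it
materially changes both similarities and trees; it is the appropriate
choice for co-dominant band data where absence is an observation, not
missingness.

UPGMA operates on the distance `1 - S` and records fusion levels on both
scales. Ties in the minimal distance are broken toward the smallest (row,
column) pair after sorting labels lexicographically, making the tree
deterministic across platforms. The result is `hclust`-compatible, so
`plot()`, `ape::as.phylo()` and Newick export work directly. Tree quality
is validated by the cophenetic correlation: the Pearson correlation between
the upper triangles of the tree-implied (cophenetic) similarity matrix and
the input matrix, which equals 1 exactly when the input is ultrametric.
The suite verifies topology and heights against an independent
average-linkage implementation on random matrices.

## Fingerprints and core-marker sets

A marker subset *discriminates* a panel when every pair of samples differs
in band pattern at some marker of the subset. The search enumerates subsets
in increasing size, prunes supersets of already-found sets, and reports all
minimal discriminating sets up to `max_size`; with no such set it names the
unresolvable sample pairs. Two policies are explicit:

* Discrimination compares presence/absence band patterns by default (the
  fingerprint-gel view); a strict diploid-genotype mode is available via
  `mode = "genotype"`.
* A missing call makes the affected pair comparison indeterminate at that
  marker, which conservatively counts as non-separating: a core set must
  discriminate on observed data alone.

The suite checks the pruned search against an unpruned brute force over all
subsets, including a panel engineered with the structure often seen in
practice — two high-band-count anchor markers that resolve all but one
pair, completed by any one of several markers.

## The synthetic-data generator

All fixtures are generated, none downloaded. `generate_genome()` assembles
a chromosome from declared planted SSRs (optionally grouped into compounds
with fixed linkers), gene models with UTR/exon/intron layout, and
repeat-free spacers; `generate_panel()` draws diploid genotypes. Design
points that make the ground truth exact:

* Spacers are rejection-sampled until they contain no reportable SSR at
  the active thresholds, so a false positive over spacer sequence is a
  genuine miner bug, never generator noise.
* A random junction base has a 1-in-4 chance of extending an adjacent
  planted run and shifting its phase, so spacer boundary bases are
  constrained: the base before a plant may not equal the last motif base,
  the base after it may not equal the first. One blocked base breaks the
  period-k equality chain across the junction. The assembled genome is
  then verified by mining it — the planted truth must be recovered exactly
  or the assembly is resampled.
* Hardy–Weinberg mode draws each genotype allele-by-allele from the
  declared frequency vector per population. Count-placement mode instead
  realizes an exact allele-count vector deterministically (round-robin
  pairing of gene copies), because reproducing reference statistics to
  four decimals requires exact counts, not a sample.
* A fixed seed gives byte-identical output; the generator saves and
  restores the caller's RNG state.

What the generator does not emulate: mutation processes on repeat tracts
(no stutter, no homoplasy), linkage between loci, null alleles,
amplification failure correlated with allele size, and realistic base
composition beyond a single GC fraction. Passing tests therefore
demonstrate algorithmic correctness on idealized data, not robustness to
every artifact of real capillary genotyping.

## Validation scale and reference values

The automated suite runs at desk scale, chosen so the whole suite completes
in about a minute: scanner-oracle equivalence on 100 sequences up to 20 kb,
planted-recovery genomes of a few kilobases, 50 random 8-sample similarity
matrices for the UPGMA cross-check, core-set brute force on 12 x 12 panels
up to subset size 3, and 1000 Hardy–Weinberg replicates at n = 500 for
estimator calibration. Genome-screen-sized inputs (hundreds of Mb) are
supported by the same code paths but are not part of the test suite.

The package's numerical anchor is a reference panel of 28 markers scored on
12 diploid samples whose integer allele counts were back-derived so that
all four frequency statistics jointly reproduce a published reference table
to four decimals (e.g. counts 14/10 over 24 copies give Ne 1.9459,
I 0.6792, He 0.5072, PIC 0.3680). The panel totals 81 alleles with mean
Na 2.8929, and its PIC classes split 7 below 0.25 and 6 above 0.5;
`scripts/acceptance.R` recomputes representative values from scratch
through the genotype path.

## Known limitations

Imperfect (mismatch-tolerant) repeats are out of scope, as are SSR calling
from reads, F-statistics beyond Hs, Hardy–Weinberg testing, bootstrap
support on trees, and probability-of-identity statistics. The UPGMA
implementation is quadratic per fusion step and intended for marker panels
(tens to hundreds of samples), not thousands.
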