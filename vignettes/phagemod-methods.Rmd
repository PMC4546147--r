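---
title: "Modular genome architecture and typing of Campylobacter group II phages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular genome architecture and typing of Campylobacter group II phages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemod)
```

## The biological model

Campylobacter group II (CP220-like) phages are myoviruses with very
AT-rich genomes of roughly 170--185 kb. Their genomes are not a uniform
gene string: they are built from four large modules (28--55 kb) separated
by long repeat regions (RR1--RR4, 1--2.9 kb). Each repeat region is
bipartite -- two arms of tandem repeat units (72--86 bp, up to 18 per arm)
flanking a short unique spacer that can carry cargo ORFs. Every unit
contains a 13-nt core consensus, `AAACTTAAAGCAA`, within one mismatch.
Because phage DNA is packaged by headful (circular permutation), genomes
are linearised at a conventional origin and treated as circles
internally.

Two subgroups exist. Relative to the CP220-type arrangement
(`A+,B+,C+,D+`), CP21-type genomes carry modules B and C in
reverse-complement orientation (`A+,B-,C-,D+`). The subgroups co-vary in
several independent marker systems: tRNA gene identities (Thr/Pro in the
CP21 type vs Arg/Tyr), an internal 0.2--2.5 kb deletion in the
receptor-binding tail-fibre gene gp047 (CP220 type only), VspI/SmiI
restriction patterns, and host-range breadth. This package implements the
computational side of that comparative analysis end to end: repeat-region
detection, module segmentation, inversion-aware architecture signatures,
in-silico digestion and long-primer PCR typing, contig ordering across
repeat gaps, marker-gene checks, and host-range statistics -- plus a
synthetic-genome generator so the whole pipeline is testable without
downloading accessions.

## Repeat detection

Detection is anchored on the core motif, not on de novo repeat
discovery, because the core is the one invariant of these repeat
families:

1. `scan_core_motif()` reports every window on either strand within
   `max_mismatches` (default 1, the allowance under which the core was
   defined) of the 13-nt core. `N` mismatches everything; circular
   genomes are scanned across the origin.
2. `build_units()` groups cores closer than `max_core_spacing` (300 bp)
   into tandem arrays and places unit boundaries at the midpoint between
   neighbouring cores. The boundary rule is this package's convention --
   the underlying data do not define one. Terminal units extend half the
   median unit length beyond their core centre; an isolated core yields
   one 80 bp unit centred on it.
3. `assemble_regions()` merges units with gaps at most `arm_gap_max`
   (200 bp) into arms, and pairs consecutive arms of at least
   `min_units_per_arm` (2) units separated by at most `inner_gap_max`
   (1500 bp) into bipartite regions. Anything else becomes a
   single-armed region, which is how scattered single units and
   degenerate polymorphic clusters surface; a per-region mean-mismatch
   score lets users filter them. The two gap thresholds are not
   published values: they were calibrated once so that default-parameter
   detection reproduces the published 1--2.9 kb region sizes on default
   synthetic genomes, and they are exposed as arguments everywhere.

Orientation (`classify_region()`) is the majority core strand of each
arm: equal strands mean a direct repeat region, opposite strands an
inverted one, and a within-arm tie is reported as `ambiguous`, never
silently resolved.

`derive_consensus()` answers "what do all units share": the longest
sequence contained in every (core-oriented) unit within the mismatch
allowance, found by exhaustive search over substrings of the first unit,
with ties broken by total mismatch count and then lexicographically.
Within one region this recovers most of the unit (unit interiors are
related beyond the core); pooled over all regions of a genome it
recovers the 13-nt core itself. The exact length-13 result depends on
some units spending their single-mismatch budget inside the core, which
happens at the default unit divergence; on noise-free genomes the shared
sequence can extend by about one flanking base.

## Architecture comparison

`segment_modules()` turns regions into modules: the inter-region
segments, named alphabetically from the origin. Modules plus regions
must tile the genome exactly and this is asserted on every call. On a
circular genome *n* regions give *n* modules (one possibly wrapping the
origin); on a linear genome *n*+1 segments.

`compute_dotplot()` finds exact shared k-mers on both strands and
chains same-diagonal matches (band tolerance 50 bp, chain gap 500 bp)
into runs, dropping runs under 200 bp of matched sequence. The defaults
(k = 31) were chosen for uniqueness at the ~180 kb scale of 27% G+C
genomes while tolerating a few percent divergence; all four knobs are
arguments. `compare_architectures()` assigns each query module to the
reference module with the greatest summed matched length and the
majority orientation of that matched length, requiring 30% coverage and
flagging best matches within 5% of the runner-up as ambiguous. Because
modules are the inter-region segments, the near-identical repeat arms
are excluded structurally and cannot bridge modules; scattered single
units fall below the 200 bp run threshold. The signature string (e.g.
`A+,B-,C-,D+`) is the subgroup-defining object.

`order_contigs()` rebuilds a genome from module-scale contigs: junction
amplicons between primers anchored near contig ends become directed
edges, the gap is `amplicon length` minus the two measured
primer-to-end offsets (measured by locating the primers on the contigs
-- real repeat-region gaps are routinely larger than assembly-predicted
ones, so the gap must be measured, never assumed), contig orientation is
read off the strand each primer matches, and a unique Hamiltonian path
or cycle is demanded. Missing or conflicting junctions are errors that
name the junction.

## In-silico assays

`digest()` cuts at every top-strand occurrence of an enzyme site (VspI
`AT^TAAT`, SmiI `ATTT^AAAT` built in; both AT-only, matching the
extreme AT-richness of these genomes). Fragments honour topology
(linear: s + 1 fragments; circular: s) and always sum to the genome
length. Fragment sizes, not cut ends, drive all comparisons, so the cut
offset is cosmetic but fixed for determinism. One numerical consequence:
for an off-centre cutter like VspI the digest of a linear genome and of
its reverse complement differ in the two terminal fragments by the 2 bp
cut stagger; on circles, and for the centre-cutting SmiI, the multisets
agree exactly.

`pattern_distance()` is one minus the Dice coefficient of greedily
matched fragments, largest first, two fragments matching within a 5%
relative tolerance -- a deliberate emulation of how a gel is read
(log-scale migration, each band used once). Greedy rather than optimal
assignment is deterministic and differs only on pathological size sets.
`cluster_patterns()` runs UPGMA (average linkage) over these distances.

`virtual_pcr()` matches primers with a total mismatch budget (default
2) and an exact 3'-anchor (default 3 bases) -- the two rules that matter
for long primers on AT-rich templates -- and reports every
forward-on-plus / reverse-on-minus product up to `max_product`
(default 6 kb, consistent with a long-elongation protocol). There is no
thermodynamic model: Tm and secondary structure are out of scope by
design. `design_typing_panels()` reproduces the published trick of
reusing one set of module-end flank primers in different pairings, so
that each junction panel amplifies under exactly one of the two module
arrangements, and `typing_pcr()` reduces the results to a
positive/negative junction profile.

## Subgroup calls and host-range statistics

`classify_subgroup()` is a voting classifier over up to five criteria
(architecture signature, tRNA labels, gp047 deletion, digest pattern
nearest prototype, PCR profile nearest expected profile). The call is
the majority of computable votes; ties are `unresolved`; a dissenting
criterion under a clear majority keeps the majority call but raises an
`atypical` flag -- the behaviour wanted for distantly related subgroup
members whose markers drift. A single decisive criterion was rejected
deliberately: the biology is triangulated from several independent
marker systems and the classifier should expose disagreement, not hide
it.

`detect_gp047_deletion()` anchors the tail-fibre locus with exact
21-mer seeds slid inward from the reference ends (both strands), calls
a deletion when the span difference falls in the 200--2500 bp window,
and reports end-anchored C-terminal identity over the last 500 bp.
Failure to place seeds uniquely yields an `unresolved` marker, not an
exception, so one missing criterion never aborts a classification.

Host-range arithmetic follows table conventions: percentages are
rounded half-up to one decimal (`percent_positive()`), profile
similarity is the Jaccard index of lysed-strain sets with the
both-empty case defined as 1 and flagged, and
`subgroup_hostrange_test()` is a label-permutation test on the mean
within-subgroup minus between-subgroup Jaccard similarity with
`p = (1 + #{perm >= obs}) / (1 + B)`. The permutation test is this
package's formalisation -- the original observation was qualitative.
With three phages per subgroup only 20 distinct label splits exist, so
attainable p-values bottom out near 0.1; panels of five per subgroup
are used where small p-values matter.

## The synthetic-data generator

`generate_genome()` plants the architecture described above:
module--region alternation ending with RR4 at the origin (so circular
segmentation recovers exactly four modules), per-base G+C drawn at the
27.2% target, arms built from a per-region base unit with the core at a
fixed offset, and subgroup-dependent markers (module orientations, tRNA
labels, gp047 state, direct-region placement: RR3 direct in the CP21
type; RR1 and RR3 in the CP220 type). `generate_cohort()` shares one
ancestral sequence set per cohort and diverges members from it, so
within- and between-subgroup comparisons are both meaningful on one
cohort. Choices worth knowing:

* **Unit construction.** Units of one region are copies of a base unit
  (flanks related beyond the core, as in the real repeat families) with
  2% per-base substitution; core positions mutate at most once per
  unit, preserving the planted "core within one mismatch" guarantee.
* **Noise model.** `unit_mutation_rate` (2%) and `member_divergence`
  (0.5%) are the two noise knobs. The within-subgroup divergence is not
  a published number; 0.5% was chosen once as a plausible
  closely-related-isolates figure and is exposed in the configuration.
  Per-member arm-size jitter (unit counts varying by one, mirroring the
  published within-subgroup unit-count variability) counts as noise and
  is active only when `unit_mutation_rate > 0`, so noise-free runs are
  structurally exact.
* **Ancestral deletion.** The gp047 deletion is drawn once per cohort
  (a single event in the subgroup ancestor) rather than per member;
  sizes still span the 200--2500 bp window across cohorts. Deletion of
  interior sequence also removes the restriction sites it contained,
  which is why deletion-size differences would otherwise swamp the
  junction signal in digest comparisons.
* **Motif-free background.** Backgrounds, spacers and gp047 are scrubbed
  of chance core near-matches so the truth record is exhaustive and
  recovery can be scored exactly. Real genomes do contain stray core
  copies; the generator plants those deliberately (`scattered_unit_count`,
  default 3, placed > 1.5 kb from any region) so the detector's
  singleton-region path is still exercised.
* **Scaling.** `scale` shrinks module sizes (and the feasibility cap)
  only. Repeat-region geometry -- unit length, units per arm, inner
  spacer, hence region size -- is never scaled, because the 13-nt core,
  the 72--86 bp unit and the detection gap thresholds are absolute
  quantities; scaling them would change the detection problem, not just
  its size. A `scale = 0.25` genome is therefore a ~40--70 kb genome
  with full-size repeat regions.
* **Mutation spectrum.** Substitutions draw the replacement base from
  the background composition (excluding the current base), so mutation
  does not drift G+C toward 50% and the per-base G+C contract holds
  under noise.
* **Inner spacers** are drawn from 320--1150 bp so that a spacer always
  exceeds the default arm gap (otherwise the two arms would merge) and
  stays below the default inner gap (otherwise the region would split);
  region target sizes are drawn from a slightly interior window of the
  1--2.9 kb range so unit-length jitter cannot push spans outside it.
* **Host-range simulation.** Strains carry a latent per-subgroup
  susceptibility; same-subgroup phages read the same latent, with a 5%
  per-cell redraw injecting minor within-subgroup divergence. Marginal
  lysis rates equal the supplied probabilities exactly (defaults
  approximate the published per-subgroup positivity rates); non-host
  species are structurally negative.

What the generator does **not** emulate: real gene content (only gp047,
cargo placeholders and labelled tRNA intervals exist), a phylogenetic
model of divergence, sequencing reads or assembly artefacts, indels
outside the gp047 deletion, and the degenerate high-polymorphism repeat
clusters seen in real genomes (the closest analogue is the scattered
singles). Tests passing on synthetic cohorts therefore demonstrate that
the algorithms recover what was planted under the stated noise model --
not that the noise model captures everything real genomes do.

## Numerical and degenerate-input conventions

All internal coordinates are 0-based half-open on the plus strand;
conversion happens only at format boundaries (BED stays 0-based, GFF3
and GenBank are 1-based inclusive). Percentages round half-up, not
half-even. Palindromic double-strand motif hits at one position keep
both strands, with unit building preferring the lower-mismatch hit and
the plus strand on ties. Empty inputs return empty results
(`build_units`, `assemble_regions`, `typing_pcr`); genuinely
uncomputable requests are errors that name the offending object
(single-armed region classification, missing junctions, degenerate
permutation labels); partial marker failures (gp047 seeds not placed)
degrade to `unresolved` evidence instead of erroring.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
data: one full-scale (~180--210 kb) genome for region-size, consensus
and composition checks, and twenty noise-free cohorts of six genomes at
`scale = 0.25` for the recovery battery (repeat regions, signatures,
gp047 states, subgroup calls, contig ordering, VspI separation), plus
200 random genomes for the motif-scan oracle comparison and 50
simulated panels for the permutation-test null calibration. These sizes
were chosen as the smallest at which every architectural feature is
present at full fidelity.

## Known limitations

* The GenBank reader handles single-interval locations only
  (`a..b`, `complement(a..b)`); compound joins are rejected with an
  error.
* Architecture comparison relies on exact shared k-mers; beyond roughly
  5% divergence between genomes the 31-mer anchors thin out and module
  assignment will start reporting unassigned modules. Real cross-genus
  comparisons need an aligner, which is out of scope.
* `derive_consensus()` is exhaustive relative to the first unit; if the
  first unit is an outlier the consensus is still correct for the set
  containing it, but a curated seed unit gives more interpretable
  per-unit mismatch counts.
* The permutation test treats strains as independent; panel structure
  (clonal strains) would make it anti-conservative.
* Subgroup-specific position reporting is end-anchored and gap-free,
  and is flagged `approximate` accordingly.
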