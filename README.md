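# phagemod

Comparative genomics of *Campylobacter* group II (CP220-like)
bacteriophages: repeat-region detection, modular architecture typing,
in-silico restriction and PCR assays, contig scaffolding across repeat
gaps, and host-range statistics — with a synthetic-genome generator that
makes the whole pipeline testable offline.

## The problem

Group II *Campylobacter* phages (~170–185 kb, ~27% G+C) have genomes
built from four large modules (A–D, 28–55 kb) separated by long bipartite
repeat regions (RR1–RR4, 1–2.9 kb). Each region consists of two arms of
tandem 72–86 bp repeat units around a unique inner spacer, and every unit
carries the 13-nt core consensus

```
5'-AAACTTAAAGCAA-3'   (≤ 1 mismatch per unit)
```

Two subgroups exist, distinguished by the order and orientation of the
modules: relative to the CP220-type arrangement `A+,B+,C+,D+`, CP21-type
genomes carry modules B and C inverted (`A+,B−,C−,D+`). The subgroups
co-vary in tRNA gene identities (Thr/Pro vs Arg/Tyr), an internal
0.2–2.5 kb deletion in the tail-fibre (receptor-binding) gene *gp047*,
VspI/SmiI restriction patterns, and host range. Typing a new phage —
or ordering the contigs of an unfinished assembly whose gaps are exactly
these repeat regions — therefore means combining several independent
lines of sequence evidence. This package implements that analysis for
people working on *Campylobacter* phage biocontrol and, more generally,
for anyone studying repeat-delimited modular phage genomes.

## What is inside

| Stage | Functions |
|---|---|
| I/O (FASTA, GenBank, BED, GFF3, TSV, CSV) | `read_genome()`, `write_intervals()`, `read_hostrange()`, … |
| Repeat detection & consensus | `scan_core_motif()`, `build_units()`, `assemble_regions()`, `classify_region()`, `derive_consensus()` |
| Architecture | `segment_modules()`, `compute_dotplot()`, `compare_architectures()`, `order_contigs()` |
| In-silico assays | `digest()`, `pattern_distance()`, `cluster_patterns()`, `virtual_pcr()`, `typing_pcr()`, `design_typing_panels()` |
| Typing & statistics | `detect_gp047_deletion()`, `classify_subgroup()`, `percent_positive()`, `profile_similarity()`, `subgroup_hostrange_test()`, `genome_summary()` |
| Synthetic data | `generator_config()`, `generate_genome()`, `generate_cohort()`, `generate_hostrange()`, `write_truth()` |

The methods vignette (`vignettes/phagemod-methods.Rmd`) explains every
model choice, default and limitation. A thin command-line front end
lives in `inst/cli/phagemod.R` (`simulate`, `repeats`, `digest`, `pcr`,
`convert` subcommands).

## Worked example

Simulate a scaled-down CP21-type genome, detect its repeat regions,
derive the unit consensus, segment modules, and type it against a
CP220-type reference:

```r
library(phagemod)

res    <- generate_genome(generator_config(seed = 11,
                                           subgroup_label = "CP21like",
                                           scale = 0.25))
genome <- res$genome
genome
#> <phage_genome> CP21like_1: 52,598 bp, circular, 89 feature(s)
#>   features: gene=3, module=4, repeat_region=4, repeat_unit=76, tRNA=2

det     <- find_repeat_regions(genome)
regions <- Filter(function(r) !r$single_armed, det$regions)
region_summary(regions)[, 1:7]
#>    id start   end size units_left units_right orientation
#> 1 RR2  9823 11738 1915         10           8    inverted
#> 2 RR4 21722 23638 1916          8          13    inverted
#> 3 RR6 35716 38130 2414         10          12      direct
#> 4 RR7 50847 52592 1745          6           6    inverted
```

Four bipartite regions, 1.7–2.4 kb, with unequal arms and exactly one
direct-repeat region — the CP21-type pattern. (The gaps in the `RR`
numbering are the detector's single-armed regions: the three scattered
single units the generator planted, filtered out above.) The shared
sequence of all 76 detected units is the 13-nt core:

```r
derive_consensus(det$units, genome)$consensus
#> [1] "AAACTTAAAGCAA"
```

Segmenting at the regions gives four modules (module A wraps the
origin of the circularly permuted genome), and comparing them against a
CP220-type reference reads off the inversion signature:

```r
modules <- segment_modules(genome, regions)
ref <- generate_genome(generator_config(seed = 11,
                                        subgroup_label = "CP220like",
                                        scale = 0.25))
compare_architectures(genome, modules, ref$genome,
                      ref$truth$modules)$signature
#> [1] "A+,B-,C-,D+"

gp <- detect_gp047_deletion(genome)
gp
#> <gp047_comparison> locus [39150, 43150) +: length difference 0 bp,
#>   deletion FALSE, C-term identity 0.976

classify_subgroup(signature = "A+,B-,C-,D+",
                  trna  = genome$features$label[genome$features$kind == "tRNA"],
                  gp047 = gp, phage = genome$id)
#> <subgroup_call> CP21like_1: CP21_subgroup (concordance 1.00)
#>   evidence: architecture=CP21, trna=CP21, gp047=CP21
```

Modules B and C inverted, Thr/Pro tRNAs, intact gp047: three of three
criteria vote CP21 subgroup. `type_phage()` / `type_cohort()` wrap this
whole chain, optionally adding the VspI digest and junction-PCR
criteria, and `order_contigs()` does the same junction-amplicon
arithmetic to scaffold module-scale contigs (gaps are measured from
product sizes, not assumed).

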