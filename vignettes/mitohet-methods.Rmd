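---
title: "Calling mitochondrial heteroplasmy from off-target reads: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mitochondrial heteroplasmy from off-target reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The problem

Human cells carry hundreds to thousands of mitochondrial genomes, and the
copies need not agree: heteroplasmy — two or more mtDNA genotypes in one
individual — is the norm rather than the exception once sequencing is deep
enough to see minor alleles. Because mtDNA mutations become phenotypically
relevant only above a mutation-load threshold, the *fraction* of molecules
carrying a variant matters as much as its presence. Exome sequencing,
although targeted at nuclear genes, co-captures mitochondrial DNA through
probes overlapping nuclear mitochondrial segments (NumtS); after alignment
to the circular mitochondrial reference these off-target reads routinely
reach depths where heteroplasmic fractions can be quantified.

`mitohet` implements that quantification and everything around it. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the built-in simulator does and does not emulate.

## The heteroplasmic-fraction model

For a variant at position $p$ the heteroplasmic fraction is

$$\mathrm{HF} = \frac{d_\text{variant}}{d_\text{total}(p)},$$

the variant read depth over the total read depth at the same position.
Three conventions pin this down:

* **Insertions** have no position of their own; the denominator is the
  depth at the 5′ anchor base (the reference base immediately upstream of
  the inserted sequence), and the supporting count is the number of reads
  whose alignment contains that exact insertion at that anchor.
* **Deletions** use the depth at the *first deleted position*. Reads whose
  deletion spans a position are counted in that position's total depth:
  they are observations of the locus, and excluding them would push
  deletion HFs above 1. With both conventions, a fully penetrant deletion
  gives HF = 1 exactly. The supporting count is the number of reads
  carrying *that* deletion event (start and length); when several distinct
  deletions overlap a position each keeps its own numerator.
* **Multi-allelic sites** emit one call per alternate base, all sharing
  the same denominator; their HFs can sum to at most 1.

HF is stored at full precision. Rounding to two decimals happens only for
classification: a rounded value of 1.00 is *homoplasmic*, 0.91–0.99
*quasi-homoplasmic*, and ≤ 0.10 *low-level*, the extremes of the eleven
HF classes used in cohort profiling. Rounding is half-away-from-zero with
a $10^{-9}$ guard so that values like 0.995 classify identically on every
platform.

## Filters and their boundaries

All comparisons are inclusive, as printed in the thresholds table
(`filter_thresholds()`):

| parameter | default | unit | role |
|---|---|---|---|
| `min_qs` | 25 | Phred | median base quality of the variant support |
| `min_rd` | 5 | reads | depth at the site (anchor for insertions) |
| `flank_len` | 5 | bp | deletion flanking window, each side |
| `consensus_hf` | 0.75 | fraction | substitution threshold in the consensus |
| `min_alt_reads` | 1 | reads | alternate-allele support floor |

A mismatch or insertion passes when depth ≥ `min_rd` and the median Phred
score of its supporting bases is ≥ `min_qs`. A deletion is judged on its
5 bp upstream and 5 bp downstream flanking regions, *each side
separately*: median depth ≥ `min_rd` and median quality ≥ `min_qs`. We
read "the flanking regions" as both-sides-must-pass, the stricter of the
two possible readings. The flank quality median is taken over the five
per-position median quality values (and depth likewise over the five
per-position depths); positions with no coverage contribute zeros, so a
deletion next to a coverage hole fails its flank, which is the intended
behaviour. `min_alt_reads` defaults to 1 — the filters above, not an
arbitrary support floor, are the gatekeepers, which is what makes
low-level heteroplasmy (HF < 0.10) detectable at depth; noisy libraries
can raise it.

Duplicate marking precedes the pileup. Fragments are grouped by the
unclipped 5′ start and orientation of each mate (the standard criterion),
the best summed-base-quality record per group survives, and ties break by
query name so the outcome is deterministic. Both mates' qualities are
summed by default (`pair_sum = TRUE`) since a fragment is the unit of
duplication; per-read scoring is available. MAPQ is deliberately not a
filter — the alignments this tool consumes are already restricted to
uniquely-mapping mitochondrial reads upstream — but the parsed table
retains it for custom filtering.

## Circularity

The mitochondrial genome is circular and all coordinate arithmetic honors
that: flanking windows of deletions near the origin wrap
(`normalize_position()` maps any offset to $((p-1) \bmod L) + 1$), loci
may span the origin (`start > end` denotes a wrapped interval, as the
control region does), and homopolymer runs crossing the origin are
reported once with their wrapped length. Internally every coordinate is
1-based inclusive, the convention of the mitochondrial literature
(m.3946G>A); conversion to 0-based half-open coordinates happens only in
the BED writer, which emits 0-based starts and 1-based ends.

## Consensus and haplogroups

The consensus is length-preserving: indels are annotated but not applied,
so position $p$ in every consensus is position $p$ in the reference.
Per position the rules are, in order: depth < `min_rd` → `N` (a gap); a
PASS mismatch with HF ≥ 0.75 → the alternate base (two such alternates at
one site are impossible, since fractions cannot sum above 1; the code
asserts it); PASS mismatches below 0.75 → the IUPAC code over
{reference} ∪ {alternates}; otherwise the reference base. Sub-threshold
heteroplasmies therefore stay visible downstream through the ambiguity
code rather than vanishing.

Haplogroup assignment is a scoring pass over a user-supplied definitions
table — the package deliberately embeds no phylogeny, so the table (not
the package) fixes the coordinate system and tree version. For each
haplogroup, `Nph` counts defining sites whose consensus character carries
the derived allele, where an IUPAC code matches by set membership and `N`
matches nothing; `P_Hg = Nph / N_ph_exp` and the best haplogroup wins,
ties broken toward the larger defining set, then lexicographically.
Reliability requires `P_Hg > 0.90` strictly: 9 of 10 sites is *not*
reliable. Uncovered (`N`) sites stay in the denominator by default — an
unobserved site is evidence of nothing, and keeping it penalizes
assignments made from gappy genomes, the conservative choice; the
`uncovered = "exclude"` mode drops them from both counts instead. No
phylogenetic path scoring is attempted: back-mutations and missing sites
simply reduce `P_Hg`.

## What the simulator emulates

`simulate_reads()` models heteroplasmy at the *fragment* level: each
fragment independently carries each planted variant with probability
equal to its target HF, so both mates agree — a haplotype mixture, which
is what biology does. Supporting counts at a site are therefore
binomial in the covering fragments, and the truth table's realized HF
(supporting/covering reads, an exact ratio) is the quantity the caller
should recover. Fragment positions are uniform on the circle except that
origin-spanning fragments are resampled: split SAM records are a
complication with no payoff for these analyses, and the cost is a
coverage ramp over roughly two read lengths at either end of the
coordinate system (the cohort generator keeps planted sites away from
those edges for exactly this reason). Qualities follow a clamped Gaussian
Phred model (default 33 ± 3, floor 2, cap 40 — typical of the exome reads
this pipeline targets); sequencing errors substitute a uniformly chosen
other base and reduce the base quality, never raise it. PCR duplicates
re-emit a configurable fraction of fragments at identical coordinates
with freshly drawn qualities.

Not emulated: platform-specific error profiles (notably Illumina's
elevated indel error in homopolymers — planted indels are placed where
the study design wants them, not drawn from a homopolymer-biased error
process), NumtS contamination, alignment artefacts, and multi-base
insertion truncation at read edges is possible but single-base insertions
(the dominant event class in real mitochondrial data) are never
truncated. Passing tests on simulated data therefore demonstrate the
*estimator and filter logic*, not robustness to alignment or chemistry
artefacts.

## Study sizes and numerical choices

The recovery study (`hf_recovery_study()`) runs the full
simulate → pileup → call path at a site whose depth is exactly the
nominal 200: fragments are fixed at twice the read length, so every
fragment covers the mid-genome study site with exactly one mate and site
depth equals fragment count. The grid is HF ∈ {0.05, 0.10, 0.25, 0.50,
0.75, 0.90, 1.00} with 500 replicates each; the acceptance bound is the
binomial 3-sigma envelope $3\sqrt{h(1-h)/d}$, met in ≥ 99% of runs, with
the side conditions that planted h ≤ 0.9 never rounds to homoplasmy and
planted h = 1 always returns exactly 1. Sequencing errors and duplicates
are off in this study — it isolates allele sampling, and the h = 1 rung
has zero tolerance, so any error would measure the error model rather
than the estimator. The simulated genomes are short (200–1000 bp): depth,
not genome length, is what the estimator sees, and short references keep
500-replicate sweeps cheap.

Other numerical choices worth recording: medians of even-length sets are
the mean of the central pair, and an empty quality set has median 0 (a
zero-coverage position can never pass a quality gate); `hclust` with
Euclidean distance and complete linkage is the clustering default (the
convention of the base heatmap stack), with average/single available; the
two-group comparison defaults to the Welch unequal-variance t-test —
nothing guarantees equal variances between blood- and cell-line-derived
count distributions — with the pooled form as an option, and the r×c
Fisher test is Monte-Carlo with a caller-supplied seed and reported
replicate count. For insertion homopolymer annotation, an insertion
belongs to a run when its anchor or the position just 3′ of the anchor
lies in the run: an inserted base extending a run is length heteroplasmy
and should count.

## Known limitations

* Indels are reported but never applied to the consensus; genomes with
  fixed indels keep reference length.
* The haplogroup scorer is a flat per-site matcher, not a tree-walker;
  it needs a definitions table expressed in the consensus coordinate
  system and will not resolve fine subclades whose definitions depend on
  indels or path context.
* The SAM reader handles the text format only; convert BAM with
  `samtools view` first.
* Origin-spanning *reads* are not produced by the simulator (fragments
  there are resampled), although the caller itself handles
  origin-wrapping flanks and loci.
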