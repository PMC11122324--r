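---
title: "Mapping nested chromosomal inversions from marker order: models and methods"
author: "invmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping nested chromosomal inversions from marker order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invmap)
```

## The problem

When one species of a group has an assembled, annotated genome and a
relative has only polytene-chromosome cytology, fixed inversions between
them can be mapped by fluorescence in situ hybridization (FISH): gene
probes designed from the reference genome are localized to cytogenetic
zones of the target species' chromosome, and the order of the localized
markers reveals which segments of the chromosome have been rearranged.
`invmap` implements the computational side of that campaign end to end:

1. iterative selection of FISH markers until breakpoint intervals are
   narrowed to single intergenic gaps;
2. delineation of synteny blocks and breakpoint regions from the
   two-species marker orders;
3. exact reconstruction of the minimal inversion scenario between the two
   block arrangements;
4. statistics on the repeat and gene content of breakpoint regions;
5. ancestry calls for each breakpoint region from outgroup gene
   adjacencies; and
6. term enrichment for the genes of rearranged blocks.

A synthetic chromosome generator with planted inversions provides ground
truth for every stage, so the whole pipeline is testable without any
external data.

## Synteny blocks and breakpoint regions

A *synteny block* is a maximal run of at least two genes that are
consecutive in both species' orders, independent of gene orientation.
Requiring two genes per block guards against breakpoint misidentification
by single-gene transpositions: a lone gene that breaks collinearity is
reported as a singleton and never founds a block. Block membership ignores
strand entirely — FISH gives order, not orientation — and the block *sign*
is derived afterwards from the within-block gene order in the target
species (for a two-gene block, the order of its dual-channel probes).

The *breakpoint region* (BR) between two adjacent blocks is the reference
interval from the end of the last gene of the left block to the start of
the first gene of the right block; regions are labelled I, II, ... left to
right. Block intervals are gene-anchored (first gene start to last gene
end), so BRs are excluded from block lengths and gene density is simply
`genes / (length / 100 kb)`. Densities are reported at full precision and
rounded half-even to two decimals.

All coordinates are 0-based half-open internally. GFF3 input (1-based
inclusive) is converted at the boundary and converted back on output; BED
is native. One arithmetic convention for lengths and densities removes a
whole class of off-by-one errors.

## The inversion model: sorting signed permutations by reversals

The block arrangement of the target species, written against the
reference block indexing, is a signed permutation; a paracentric inversion
is a *signed reversal* — reverse a contiguous segment and flip its signs.
The minimal number of reversals transforming one arrangement into the
other is computed exactly from the breakpoint-graph cycle decomposition:

d = (n + 1) − c + h + f

where `c` is the number of alternating cycles in the breakpoint graph of
the framed, doubled permutation, `h` the number of hurdles (unoriented
components that do not separate two other unoriented components on the
position circle), and `f` the fortress correction (1 when an odd number of
hurdles are all super hurdles). The full correction matters because the
pipeline claims a *minimum*: the cycle bound alone would understate the
distance on unoriented arrangements even though the flagship nested-
inversion instance needs neither correction.

`enumerate_minimal_scenarios()` lists every ordered sequence of exactly
`d` reversals in which each step reduces the remaining distance by one,
in lexicographic step order. For the nested arrangement `1 -4 3 -2 5`
there are exactly two: the inner inversion `reverse[3..3]` first or the
outer `reverse[2..4]` first. The data cannot order the two events, and
the solver deliberately reports both rather than picking one; collapsing
order-equivalent scenarios is available (`dedupe_unordered`) but off by
default. Unsigned permutations are rejected with a message — orientation
is part of the model.

Correctness of the distance is guarded by an independent oracle:
`bfs_distance_oracle()` runs breadth-first search over the full reversal
graph (`n! * 2^n` states, n ≤ 8) and shares no code with the
breakpoint-graph path. The test suite checks equality exhaustively for
all signed permutations with n ≤ 5 (3,840 instances at n = 5) and on 200
random instances with n ∈ {6, 7}. Fortresses are too large to appear in
that range; the fortress rule follows the published theory and is
exercised structurally rather than against the oracle — a known
limitation of the verification.

## Iterative marker mapping

The campaign loop mirrors the experimental design:

* **Round 1** probes a scaffold of markers spaced about 1 Mb apart
  (`round1_spacing`; short chromosomes fall back to a ten-point grid).
* **Classification.** Markers sorted by reference coordinate are split
  into a *collinear* backbone — the longest non-decreasing (or
  non-increasing, whichever is longer) subsequence of target zone ranks —
  and *translocated* markers outside it. Zone ties join the backbone:
  zones are coarse cytogenetic bins and equal zones carry no order
  signal.
* **Candidate intervals** open across every pair of consecutive markers
  whose classification differs. Bounds use gene end/start coordinates, so
  a fully refined interval *is* the intergenic gap at the breakpoint.
* **Proposals.** Each round probes up to `k` available genes per open
  interval, nearest to the interior quantile points `i/(k+1)` — a k-ary
  generalization of bisection. The source experiments used three to four
  probes per FISH, so `k = 3` is the default; the placement rule within
  an interval is this package's design choice, as the experimental
  protocol does not specify one.
* **Termination** when no available gene lies strictly inside any open
  interval. Probes that fail to localize are flagged unmappable and never
  proposed again; with unmappable genes the final interval can only widen
  around the true gap, never miss it.

Interval widths are non-increasing across rounds, and with zero
localization noise the final intervals equal the true intergenic gaps
exactly. On the study-scale chromosome the loop converges in about five
rounds and ~54 markers, matching the scale of the real campaign.

## Breakpoint-region statistics

**Counting rule.** An element belongs to a region iff its *start*
coordinate lies in the region. One stated rule, applied everywhere, means
an element is never counted twice across a tiling.

**Poisson test.** For a BR of length L, the chromosome is tiled with bins
of width L from coordinate 0; the trailing partial bin is excluded from
the rate so the per-bin mean is unbiased. λ is the mean element count
over whole bins and the reported value is the upper tail P(X ≥ x) under
Poisson(λ). The upper tail — not the point probability — is the only
reading under which "significantly denser than the chromosome average"
is coherent, and it is flagged here because the convention matters when
comparing to other implementations. With a coding mask, elements starting
in coding sequence are dropped and the rate becomes per *non-coding* bp,
scaled by the region's non-coding width; an empty mask reproduces the
unmasked test exactly. Whether bins should tile or slide is not
determined by the design being emulated; tiling was chosen (independent
bins, unbiased λ). No multiple-testing correction is applied across the
four BRs by default, matching the practice of reporting raw per-region
p-values; a BH option exists downstream via `adjust_pvalues()`.

**Neighborhood profiles.** Bars of width equal to the BR cover the region
and 50 kb of flank on each side (partial outer bars keep their true width
for normalization; flanks truncate at chromosome ends). `lambda_ref`, the
chromosome mean per full bar, is the reference line. Bar heights are raw
counts with stated widths — counts rather than densities were chosen
because the bar width is constant except at the ends, where the true
width is reported alongside.

**Gene-density ANOVA.** Each block is tiled with 100 kb bins from its
start, trailing partial bins dropped, and per-bin gene counts are
compared across blocks with a classical one-way ANOVA (`stats::aov`).
Blocks contributing fewer than two whole bins raise an error naming the
block. When every bin count is identical the F statistic is reported as
0 (zero between-group variance), not NaN.

## Ancestry from outgroups

Each BR contributes one diagnostic adjacency per ingroup: the flanking
gene pair as arranged in that ingroup. An outgroup supports an ingroup
when it shows the same unordered gene pair in the same adjacency state;
gene orientation is ignored throughout because probe orientation in the
cytology-only species is unknown. The call is `a_ancestral` when at least
`min_support` outgroups (default 1) match A and none match B,
symmetrically for B, and `undetermined` otherwise. Conflicting outgroups
always give `undetermined` — a deliberate refusal to majority-vote
between genomes of very different assembly quality and evolutionary
distance. `unresolved` observations (scaffold breaks, missing orthologs)
never influence a call. The chromosome-level verdict is the majority of
determined calls only.

## Term enrichment

Enrichment of a gene list against a universe is the hypergeometric upper
tail P(X ≥ k), with BH FDR and Bonferroni adjustments computed over all
tested terms before any cutoff filtering, fold enrichment `(k/n)/(K/N)`,
and the sample odds ratio. No continuity correction is applied to the
odds ratio: when a term's genes are fully captured by the list the odds
ratio is reported as infinity, which is informative ("perfect capture")
rather than a numerical accident. Terms are flat labels — the gene-to-term
table is an input and no ontology-graph propagation is attempted, because
the propagation behaviour of hosted annotation services is not
reproducible. The default universe is all genes of the analyzed
chromosome; the true universe of any particular hosted tool is unknowable
and results are sensitive to it, so the universe is always explicit here.

## The synthetic chromosome

`simulation_config()` describes a chromosome as blocks + breakpoint gaps
+ terminal margins. The study-scale preset (`paper_scale_config()`) uses
five blocks of 1,458,895 / 526,550 / 10,348,225 / 2,148,753 / 3,273,690
bp carrying 122 / 42 / 722 / 137 / 199 genes, breakpoint gaps of 9 / 8 /
12 / 7 kb (the observed gaps range over 7–12 kb), and 20 kb margins,
giving a 17,832,113 bp chromosome, with the nested scenario
`reverse[3..3]` + `reverse[2..4]` planted.

Placement and rates, chosen once as realistic study conditions:

* **Genes.** Lengths ~ Normal(3,000, 1,000) bp truncated at 200 bp. The
  first gene of a block starts at the block start and the last ends at
  the block end (so delineated block metrics recover the configured
  lengths exactly); interior genes sit at sorted uniform positions with
  overlaps resolved by a minimal-displacement sweep, keeping the point
  process close to uniform at the 100 kb scales used for density
  statistics.
* **Repeats.** Independent homogeneous Poisson processes per group at
  2 / 20 / 5 / 40 expected elements per 100 kb for retrotransposons, DNA
  transposons, unknown TEs and simple repeats respectively — class II
  more abundant than class I, as observed on this X chromosome, and
  simple repeats commonest of all. Inside true breakpoint gaps the rate
  is multiplied by `br_repeat_multiplier` (exactly: baseline process plus
  an overlay at rate × (multiplier − 1)).
* **FISH.** The target chromosome is divided into `zone_count = 39`
  equal-width zones (fine cytogenetic subdivision granularity; real zone
  maps are irregular, but regularity changes nothing the pipeline tests).
  A probe reports its true zone, perturbed by ±1 zone with probability
  `localization_noise`; each gene is unmappable with probability
  `unmappable_prob`, drawn once at generation time.

All randomness flows from the single config seed; identical seeds give
byte-identical outputs.

**What the generator does not emulate:** nucleotide sequence, assembly
gaps, heterochromatin, irregular zone widths, clustered or nested repeat
insertions, segmental duplications, and gene-density gradients. Passing
tests therefore demonstrate the pipeline's correctness on data satisfying
its model assumptions, not robustness to every artefact of real
assemblies.

## Calibration experiments

Genome-dependent published quantities (per-region Poisson p-values on a
real assembly, the real gene-density ANOVA, hosted-tool GO term counts)
cannot be recomputed without that assembly and annotation service, so the
statistical machinery is validated by properties instead:

* **Super-uniformity.** Under uniform element placement, Poisson
  upper-tail p-values over 1,000 simulated regions satisfy
  P(p ≤ α) ≤ α up to binomial noise at every α checked (discreteness
  makes the test conservative, never anticonservative).
* **Power.** A planted 10× DNA-transposon rate inside one 10 kb BR is
  detected at p < 0.01 in at least 95 of 100 seeded runs (in practice
  100/100 at the default rates).
* **ANOVA calibration.** With equal expected densities (7 genes /
  100 kb), per-block gene totals drawn Poisson, and short genes
  (600 ± 150 bp) keeping packing occupancy low, ANOVA p-values over 100
  seeds pass a Kolmogorov–Smirnov uniformity test at α = 0.01. Short
  genes matter here: at realistic gene lengths the non-overlap
  constraint underdisperses per-bin counts, making the test mildly
  conservative — a property of density testing on packed annotations
  generally, not of this implementation.

Problem sizes throughout the test suite — 1,222 genes for structure
recovery, 1,000 regions and 100-seed batteries for calibration, the full
n ≤ 5 permutation space plus 200 random n ∈ {6, 7} instances for the
solver — were chosen so the whole suite and the acceptance script run
comfortably on a single CPU while keeping every estimate's Monte Carlo
error well below its assertion margin.

## Known limitations

* Scenario enumeration is exponential in distance; `max_count` truncates
  with a flag rather than failing, but large distances are out of scope
  for a chromosome with a handful of blocks.
* The collinear backbone is a longest-monotone-subsequence heuristic; at
  high localization noise or with rearranged segments comprising half the
  markers, classification is genuinely ambiguous and the campaign may
  open spurious intervals (they refine away in later rounds).
* Candidate intervals open only at collinear/translocated boundaries;
  a breakpoint between two adjacent translocated segments of the same
  classification would need zone-discontinuity evidence that the planner
  does not currently use.
* The ancestry module consumes adjacency states; deriving those states
  from outgroup assemblies (ortholog calling, scaffold traversal) is
  upstream of this package.
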