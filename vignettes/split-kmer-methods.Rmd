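---
title: "Methods: positional localization of split 8-mers in promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional localization of split 8-mers in promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitkmer)
```

## The problem

Composite transcription-factor binding sites -- two elements constrained to
a fixed spacing, sometimes overlapping -- are invisible to analyses that
treat each motif in isolation. `splitkmer` takes a deliberately DNA-centric
route: it enumerates every *split 8-mer*, a pair of 4-mers `X4-Nk-X4`
separated by an insert of `k` unspecified bases (`k` = 0 gives an ordinary
continuous 8-mer), and asks at which insert length, if any, each pair of
half-sites concentrates near the transcription start site (TSS). A pair
that localizes sharply at exactly one spacing is the signature of a
composite site; the overlapping ETS and CRE elements (core 11-mer
`CGGAAGTGACG`, in which the `GTG` trinucleotide is shared by both factors)
are the canonical example the genome-context stages of the package are
built around.

## Pattern classes

Double-stranded DNA makes a pattern and its reverse complement the same
biological object, so the 65,536 ordered 4-mer pairs are collapsed into
equivalence classes: `(left, right)` is identified with
`(revcomp(right), revcomp(left))`, and the class representative is the
member whose 8-character concatenation is lexicographically smallest.
Enumeration gives 32,896 classes, 256 of them palindromic
(self-reverse-complement, e.g. `TGAC-Nk-GTCA`), *at every insert length*:
whether a pair equals its own reverse complement does not depend on how
far apart the halves sit. A published variant of the counting formula
treats odd-`k` patterns as having no palindromes (giving 32,768); direct
enumeration contradicts that -- `ACGT-N1-ACGT` is its own reverse
complement -- so the package always enumerates 32,896 classes and exposes
the alternative count only through
`pattern_class_count(k, palindromes = "none_when_odd")` for comparison
with tabulations that used it.

CG classification follows the same class logic. For continuous 8-mers the
test is on the whole 8-character word, so a CG spanning the junction
counts (`TGACGTCA` is CG-containing); for split patterns only a CG inside
a half-site counts, because the insert bases are unspecified. Both
properties are reverse-complement invariant. The resulting partitions --
12,547 / 20,349 (continuous) and 10,951 / 21,945 (split) -- are asserted
against an independent brute-force collapse in the test suite.

## Counting and the bin grid

Promoters are fixed-length windows around the TSS: 1,500 bases spanning
-1000..+500, with no position 0 (offsets 0..1499 map to labels -1000..-1,
+1..+500, so the 75 bins run `[-1000; -981]` through `[+481; +500]` at the
default 20-base width). `scan_promoters()` slides over every offset where
a full site fits, reads the two half-sites by position-indexed table
lookup (one pass per insert length -- never a per-pattern rescan),
collapses the pair onto its canonical class, and adds one count at the bin
of the site's leftmost base. A reverse-strand match is registered at the
same leftmost coordinate, so both strands share one coordinate system, and
palindromic classes count each site once. Sites containing `N` anywhere,
insert included, are skipped. Promoter FASTA is scanned as given
(soft-masked bases count); genome-context scanning excludes masked and `N`
bases instead, reflecting the "unmasked" universe used for genome-wide
occurrence counts.

## Localization statistics

The localization factor of a binned distribution is

$$\mathrm{LF} = \frac{\max_b c_b}{\left(\sum_b c_b\right) / B}$$

with `B` bins: 1 for a uniform distribution, `B` for a point mass, 0 for
an empty one. Non-uniformity is scored with a Bonferroni-corrected exact
binomial tail, `P = min(1, B * Pr[Binomial(n, 1/B) >= max count])`. Both
definitions are fixed here: the analyses this package descends from defer
their LF and P formulas to earlier work without restating them, so
absolute values cannot be matched numerically against printed figures,
only ordinally -- everything downstream (ranking, thresholding) uses
monotone properties both definitions provably have (scale invariance of
LF; P monotone decreasing in the peak at fixed total; conservative under
the multinomial null, which the suite checks by simulation). Peak-bin ties
take the smallest bin index.

Classes with fewer than `min_total = 50` occurrences are reported with
statistics withheld: LF on tiny totals is shot noise. The threshold is an
argument everywhere it applies.

Per pair of 4-mers, `insert_profiles()` collects LF across `k = 0..30`
(insert lengths where the class total falls below `min_total` contribute
LF 0), takes the best insert length, and forms the ratio
LF(Max)/LF(Max-1). A ratio near 1 means the halves co-occur at many
spacings; a large ratio means one precise spacing. When only a single
insert length has any qualifying signal the ratio is `+Inf`, serialised in
TSV output as the string `"inf"` and ordered above every finite ratio.
`select_unique_localizers()` keeps profiles with `lf_max >= lf_min`
(default 2), `ratio >= ratio_min` (default 2) and P at the best insert
length at most `p_max` (default 0.01), sorted by descending ratio then LF.

## Promoter curation

Five sequential filters clean a raw promoter download, with every removal
logged so the accounting always balances: exact-duplicate sequences
(first copy kept), runs of 150 or more `N` (a run, not a total), records
with duplicated identifiers (all copies removed -- the source accounting
is ambiguous between "all" and "all but one", and removing all is the
stricter reading of "removed"), near-duplicate collapsing, and coding
starts within 30 bases of the TSS (inclusive; unannotated records pass).
"Closely identical" promoters are operationalised as records sharing an
exact common substring of at least 250 bases -- any alignment-based
definition would be unverifiable from the published thresholds -- linked
records form connected components, one representative per component (the
lexicographically smallest id) is kept, and records with more than 10
links are removed before grouping. The historical curation also retained
a set of promoters with mixed overlapping sequence by a rule that is not
recoverable; rather than guess, `curate()` takes an explicit `keep_list`.

## The synthetic-data generator

Every input format has a generator counterpart, so the whole pipeline is
exercisable with no downloads, against known truth tables sufficient to
recompute every planted instance:

* `generate_promoters()` plants literal motifs or split patterns (insert
  filled uniformly at random per instance) into background promoters, at a
  uniform or discretised-normal position law, on either strand.
  Planting overwrites background bases, so lengths and the TSS alignment
  are exact. The background is order 0 or a first-order Markov chain with
  a multiplicative depletion of the C-to-G transition;
  `cg_depletion = 0.25` approximates the CpG observed/expected ratio of
  about 0.2-0.25 in bulk mammalian DNA. The planted-recovery simulations
  use that CG-depleted background: the scarcity of CG-containing patterns
  in bulk DNA is precisely what makes a CG-containing composite site
  localize at a unique spacing in real promoter sets, and under a uniform
  background that contrast does not exist (every insert length carries
  ~90 background occurrences of the pair at 2,000 promoters, so the
  max-to-second LF ratio hovers near 1.6 regardless of the plant).
* `generate_genome()` plants motifs with independent per-base probability
  `in_region_density` inside designated regions and `background_density`
  outside, rejecting overlapping placements.
* `generate_track()` scores motif-covered bases `inside_score` and the
  rest `outside_score`, plus optional Gaussian noise -- the step profile a
  conservation scan should recover.
* `generate_methylation()` emits one row per plus-strand CG with binomial
  methylated-read counts at region-dependent fractions -- hypomethylated
  regulatory regions in an otherwise methylated genome.

All generators are pure functions of their parameters and a root seed;
per-stage streams are derived from the root so adding one generator call
never shifts another stream.

What the generator does **not** emulate: dinucleotide periodicity and
nucleosome positioning signals, CpG-island structure (depletion is
homogeneous, not interrupted by islands), read-level bisulfite error, and
the heavy-tailed redundancy of real promoter downloads. Passing the
planted-recovery and calibration tests therefore demonstrates that the
machinery measures what it claims on data with the assumed statistical
structure -- not that real promoters satisfy those assumptions.

## Genome-context stages

`find_occurrences()` reports forward matches of a motif and its reverse
complement at their leftmost plus-strand coordinate (palindromes once per
site), including overlapping occurrences, and skips sites touching masked
or `N` bases. Region membership is by the start base: the published
analyses never state their rule, and start-base membership keeps counts
additive across disjoint region sets and matches the leftmost-base
convention used for binning. Table percentages are rounded half-up to
integers; raw fractions are kept in a machine-readable column.

Extension scans walk a core motif toward a target sequence one base at a
time, evaluating all four choices at each step -- the data behind the
enrichment jump when an extension completes a second CG. Variant
enumeration produces all `3 * length` single-base variants with a flag for
substitutions that destroy an original CG. The CG-pair scan counts
plus-strand `CG-Ng-CG` windows for gaps 0..9; its `exclude_internal_cg`
mode skips windows with a complete CG inside the gap. Following-base
tallies read the two bases after a motif prefix in match orientation on
both strands, skipping occurrences at sequence edges.

Conservation profiles average a per-base score track over occurrences,
position by position, with 15-base flanks by default; minus-strand windows
are reversed so position 0 is always the motif's 5' end; bases without
track data are skipped per occurrence, and positions with no contributing
occurrence are reported absent, never 0; negative scores pass through
(faster-than-neutral evolution under a phyloP reading).

Methylation status per occurrence is derived from the plus-strand C of
each CG in the site: *unmethylated* when every CG has at least
`min_coverage = 5` reads and methylation fraction at most
`unmethylated_max = 0.2`; *methylated* when every CG has such coverage and
fraction at least 0.8; *insufficient* when any CG lacks coverage (or the
site has no CG); *mixed* otherwise. The numeric criterion for
"unmethylated" is not stated in the analyses this package follows, so the
thresholds are explicit arguments, reported in output headers, with a
monotonicity guarantee (raising `unmethylated_max` never removes an
occurrence from the unmethylated class) checked in the suite.

## Problem sizes and reproducibility

The simulations shipped in the test suite use 2,000 promoters for
planted-motif recovery and null calibration (10 seeds for recovery),
genomes of 30-100 kb for scanning oracles, conservation and methylation
recovery, and 400-promoter runs for end-to-end pipeline checks -- sizes
chosen so the whole suite exercises every stage at statistically
meaningful scale while remaining a desk-scale computation. The acceptance
script (`scripts/acceptance.R`) recomputes the combinatorial quantities
(class counts, CG partitions, the CG-pair gap of the composite 11-mer)
from scratch at every run; genome-scale occurrence counts on a reference
assembly are reproducible in principle with the same machinery but
require the assembly and published region sets as inputs.

## Known limitations

* Absolute LF and P values are defined here, not inherited, so they are
  comparable within runs of this package only (ordinal agreement with
  published figures is all that can be claimed).
* The near-duplicate definition (exact shared 250-mer) is a proxy for an
  unpublished similarity rule; it reproduces the published thresholds, not
  necessarily the published partition.
* Pattern scanning is literal by design -- no degenerate alphabets and no
  position-weight matrices; that is the DNA-centric point, but it means
  close variants are separate patterns unless explicitly enumerated.
* Methylation handling keys only plus-strand CG positions; merge
  strand-symmetric bisulfite calls upstream.
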